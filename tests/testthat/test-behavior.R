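test_that("move log-likelihood reduces to the lapse-mixture formula", {
  b <- kboard(3, 3)
  # uniform density probabilities: p_h = 1/9 for every square
  ll <- move_loglik(b, 2, 2, "density", epsilon = 0)
  expect_equal(ll, log(1 / 9))
  # pure lapse: epsilon = 1 gives log(1/#legal) regardless of strategy
  for (strat in c("density", "interaction")) {
    expect_equal(move_loglik(b, 1, 3, strat, epsilon = 1), log(1 / 9))
  }
  # p_h = 0 under a hard shutter: only the lapse term remains
  bb <- kboard(6, 4, x = rbind(c(3, 3)), o = rbind(c(4, 4)))
  mp <- move_probabilities(bb, "interaction", shutter = 0,
                           last_x_move = c(3, 3), player = "O")
  far <- mp[mp$prob == 0, ][1, ]
  ll0 <- move_loglik(bb, far$row, far$col, "interaction", epsilon = 0.05,
                     shutter = 0, last_x_move = c(3, 3), player = "O")
  expect_equal(ll0, log(0.05 / 34))
})

test_that("session log-likelihood matches a naive per-move re-derivation", {
  b <- generate_endgame_board(6, 4, 3, seed = 5)
  s <- simulate_participant(b, "interaction", shutter = 1, epsilon = 0.02,
                            max_moves = 10, seed = 13)
  got <- session_loglik(s, "interaction", epsilon = 0.02, shutter = 1, w = 0.5)
  st <- session_states(s)
  manual <- purrr::pmap_dbl(st, function(board, player, row, col,
                                         last_x_row, last_x_col, ...) {
    lx <- if (is.na(last_x_row)) NULL else c(last_x_row, last_x_col)
    move_loglik(board, row, col, "interaction", epsilon = 0.02, shutter = 1,
                w = 0.5, last_x_move = lx, player = player)
  })
  expect_equal(got$total_ll, sum(manual))
  expect_equal(got$mean_ll, mean(manual))
  expect_equal(got$n_moves, nrow(st))
})

test_that("a single-move session reduces to move_loglik", {
  b <- kboard(6, 4)
  ev <- tibble::tibble(player = "X", action = "place", row = 3L, col = 3L, t = 1)
  s <- kinarow_session(b, ev)
  got <- session_loglik(s, "linear", epsilon = 0.01)
  expect_equal(got$total_ll, move_loglik(b, 3, 3, "linear", epsilon = 0.01))
})

test_that("grid search maximizes the likelihood over the declared grids", {
  b <- generate_endgame_board(6, 4, 3, seed = 5)
  s <- simulate_participant(b, "interaction", shutter = 0, epsilon = 0,
                            max_moves = 25, seed = 21)
  fit <- fit_participant(s, strategies = c("nonlinear", "interaction"))
  td <- tidy(fit)
  # the reported optimum beats a scatter of other grid cells
  for (row_i in which(td$strategy == "interaction")) {
    best <- td$total_ll[row_i]
    for (s_try in c(0, 0.5, 1.5, 3, Inf)) for (e_try in c(0, 0.03, 0.05)) {
      alt <- session_loglik(s, "interaction", epsilon = e_try,
                            shutter = s_try, w = 0.5)$total_ll
      expect_lte(alt, best + 1e-9)
    }
  }
  # AIC bookkeeping: 2 free parameters without w
  expect_equal(glance(fit)$aic, 2 * 2 - 2 * glance(fit)$total_ll)
})

test_that("a deterministic noise-free agent is fitted with zero lapse", {
  b <- generate_endgame_board(6, 4, 3, seed = 5)
  # greedy argmax play: every observed move has maximal model probability
  marks <- b$marks; to_move <- b$to_move; last_x <- NULL
  ev <- list()
  for (i in 1:12) {
    bb <- b; bb$marks <- marks; bb$to_move <- to_move
    if (is_terminal(bb)) break
    mp <- move_probabilities(bb, "interaction", last_x_move = last_x)
    j <- which.max(mp$prob)
    ev[[i]] <- tibble::tibble(player = c("X", "O")[to_move], action = "place",
                              row = mp$row[j], col = mp$col[j], t = i)
    if (to_move == 1L) last_x <- c(mp$row[j], mp$col[j])
    marks[kinarow:::.cell_index(b$size, mp$row[j], mp$col[j])] <- to_move
    to_move <- 3L - to_move
  }
  s <- kinarow_session(b, dplyr::bind_rows(ev))
  fit <- fit_participant(s, strategies = "interaction")
  expect_equal(glance(fit)$epsilon, 0)
})

test_that("grid endpoints are attainable", {
  g <- fit_grid()
  expect_true(3.0 %in% g$shutter)
  expect_true(Inf %in% g$shutter)   # explicit shutter-off cell for nesting
  expect_true(0.05 %in% g$lapse)
  expect_true(0.5 %in% g$w)
})

test_that("adding the shutter parameter never decreases the best likelihood", {
  b <- generate_endgame_board(6, 4, 3, seed = 5)
  for (seed in 31:33) {
    s <- simulate_participant(b, "nonlinear", shutter = 2, epsilon = 0.02,
                              max_moves = 20, seed = seed)
    with_s <- fit_participant(s, strategies = "nonlinear")
    base_ll <- max(vapply(seq(0, 0.05, 0.01), function(e)
      session_loglik(s, "nonlinear", epsilon = e, shutter = Inf)$total_ll,
      numeric(1)))
    expect_gte(tidy(with_s)$total_ll[1], base_ll)
  }
})

test_that("the likelihood-ratio test matches the chi-square tail", {
  expect_equal(lr_test(-10, -10, df = 1)$p_value, 1)
  expect_equal(lr_test(-10, -10 + 3.841 / 2, df = 1)$p_value, 0.05,
               tolerance = 1e-3)
  expect_error(lr_test(-5, -6), "lower likelihood")
  # agreement with numeric integration of the chi-square density
  set.seed(1)
  for (i in 1:5) {
    d <- sample(1:3, 1); delta <- runif(1, 0, 5)
    p <- lr_test(0, delta, df = d)$p_value
    num <- stats::integrate(function(x) stats::dchisq(x, d), 2 * delta,
                            Inf, rel.tol = 1e-10)$value
    expect_equal(p, num, tolerance = 1e-6)
  }
})

test_that("population summary returns shares that sum to one with valid CIs", {
  fits <- tibble::tibble(strategy = c(rep("interaction", 6), rep("forcing", 3),
                                      "density"))
  ps <- population_summary(fits, n_boot = 200, seed = 1)
  expect_equal(sum(ps$share), 1)
  expect_true(all(ps$conf_low <= ps$share + 1e-12))
  expect_true(all(ps$conf_high >= ps$share - 1e-12))
  # degenerate cohort: single strategy, CI collapses to [1, 1]
  ps1 <- population_summary(tibble::tibble(strategy = rep("linear", 5)),
                            n_boot = 50, seed = 1)
  expect_equal(ps1$share[ps1$strategy == "linear"], 1)
  expect_equal(ps1$conf_low[ps1$strategy == "linear"], 1)
  expect_equal(ps1$conf_high[ps1$strategy == "linear"], 1)
})

test_that("a synthetic cohort's mixture is recovered within the bootstrap CIs", {
  boards <- list(b = generate_endgame_board(6, 4, 3, seed = 5))
  mix <- tibble::tibble(strategy = c("nonlinear", "interaction"),
                        shutter = Inf, epsilon = 0.01, w = 0.5,
                        weight = c(0.5, 0.5))
  spec <- cohort_spec(n_participants = 30, mixture = mix, max_moves = 30,
                      seed = 8)
  coh <- generate_cohort(boards, spec)
  fits <- fit_cohort(coh$sessions, strategies = c("nonlinear", "interaction"))
  ps <- population_summary(fits, n_boot = 300, seed = 2)
  for (st in c("nonlinear", "interaction")) {
    row <- ps[ps$strategy == st, ]
    expect_gt(row$conf_high, 0.2)
    expect_lt(row$conf_low, 0.8)
  }
})

test_that("the lapse pulls a move's log-likelihood monotonically toward chance", {
  b <- kboard(6, 4, x = rbind(c(3, 3)), o = rbind(c(4, 4)))
  # a move the model dislikes (p_h < 1/#legal): likelihood rises with epsilon
  mp <- move_probabilities(b, "interaction", player = "X")
  worst <- mp[which.min(mp$prob), ]
  lls <- vapply(seq(0, 1, 0.1), function(e)
    move_loglik(b, worst$row, worst$col, "interaction", epsilon = e,
                player = "X"), numeric(1))
  expect_true(all(diff(lls) >= -1e-12))
  expect_equal(lls[length(lls)], log(1 / nrow(mp)))
  # and a favoured move loses likelihood as epsilon grows
  best <- mp[which.max(mp$prob), ]
  lls2 <- vapply(c(0, 0.5, 1), function(e)
    move_loglik(b, best$row, best$col, "interaction", epsilon = e,
                player = "X"), numeric(1))
  expect_true(all(diff(lls2) <= 1e-12))
})
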