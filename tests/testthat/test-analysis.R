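test_that("entropy has the closed-form values and invariances", {
  expect_equal(entropy(rep(0.25, 4)), 2)
  expect_equal(entropy(1), 0)
  expect_equal(entropy(c(0.5, 0.25, 0.25)), 1.5)
  # relabeling invariance and the uniform maximum
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(entropy(p), entropy(rev(p)))
  expect_lt(entropy(p), log2(4))
  expect_equal(entropy(rep(1 / 7, 7)), log2(7))
})

test_that("move distributions aggregate counts into probabilities", {
  moves <- tibble::tibble(row = c(1, 1, 2, 3, 1), col = c(1, 1, 2, 3, 1))
  d <- move_distribution(moves)
  expect_equal(sum(d$prob), 1)
  expect_equal(d$n[d$row == 1 & d$col == 1], 3)
  expect_equal(attr(d, "n_total"), 5)
})

test_that("matched-state distributions filter full sessions on the truncated prefix", {
  b <- generate_endgame_board(6, 4, 4, seed = 11)
  tb <- truncate_board(b)
  xm <- attr(tb, "x_move"); om <- attr(tb, "o_move")
  full <- lapply(1:40, function(i)
    simulate_participant(b, "interaction", shutter = 0, epsilon = 0,
                         max_moves = 6, seed = 100 + i))
  trunc <- lapply(1:20, function(i)
    simulate_participant(tb, "interaction", shutter = 0, epsilon = 0,
                         max_moves = 2, seed = 200 + i))
  md <- matched_state_distributions(full, trunc, xm, om)
  expect_equal(attr(md$truncated, "n_total"), 20)
  # every counted full-board third move followed the exact prefix
  if (md$n_full > 0) {
    expect_equal(sum(md$full$n), md$n_full)
    expect_equal(sum(md$full$prob), 1)
  }
  # zero qualifying sessions: empty result, no crash
  none <- matched_state_distributions(list(), trunc, xm, om)
  expect_equal(none$n_full, 0)
  expect_equal(nrow(none$full), 0)
})

test_that("participant shutter averages the replayed distances", {
  b <- kboard(6, 4)
  # X d3(4,3), O f1(6,6), X d4(3,3): third move at distance 0 from (4,3)'s
  # paths; O move at whatever distance it replays to
  ev <- tibble::tibble(player = c("X", "O", "X"), action = "place",
                       row = c(4L, 6L, 3L), col = c(3L, 6L, 3L), t = 1:3)
  s <- kinarow_session(b, ev)
  ps <- participant_shutter(s)
  st <- session_states(s)
  manual <- c(
    shutter_distance(st$board[[2]], 6, 6, 4, 3),
    shutter_distance(st$board[[3]], 3, 3, 4, 3))
  expect_equal(ps$n_eligible, 2)
  expect_equal(ps$mean_distance, mean(manual))
  # categories split on the supplied thresholds
  expect_equal(participant_shutter(s, thresholds = c(10, 20))$category, "narrow")
  # no eligible move: explicit undefined
  one <- kinarow_session(b, ev[1, ])
  expect_true(is.na(participant_shutter(one)$mean_distance))
})

test_that("missed wins count exactly the spurned immediate completions", {
  # O has an open k-1 path; the O mover plays elsewhere -> one missed O win
  b <- kboard(4, 3, x = rbind(c(1, 1), c(2, 2)), o = rbind(c(4, 1), c(4, 2)))
  traj <- tibble::tibble(player = c("X", "O"), row = c(1L, 1L), col = c(2L, 4L))
  attr(traj, "board") <- b
  mw <- missed_wins(traj)
  # X's first move also spurned no X win; O missed completing (4,3)
  expect_equal(mw$missed_o, 1L)
  expect_equal(mw$missed_x, 1L)  # X had (3,3) completing the diagonal? no:
  # recompute expectation explicitly from the definition
  g <- kinarow:::.board_geom(b)
  iw_x <- kinarow:::.immediate_win_cells(b$marks, g, 1L)
  expect_equal(mw$missed_x, as.integer(length(iw_x) > 0))
  # no immediate wins anywhere: all zero with an undefined ratio
  b2 <- kboard(4, 3)
  t2 <- tibble::tibble(player = c("X", "O"), row = c(1L, 4L), col = c(1L, 4L))
  attr(t2, "board") <- b2
  mw2 <- missed_wins(t2)
  expect_equal(c(mw2$missed_x, mw2$missed_o), c(0L, 0L))
  expect_true(is.na(mw2$ratio))
})

test_that("pareto analysis flags dominance and trade-offs correctly", {
  mk_runs <- function(acc_by_s, comp_by_s, n = 30) {
    purrr::imap_dfr(acc_by_s, function(a, s)
      tibble::tibble(shutter = as.numeric(s),
                     found_win = stats::rbinom(n, 1, a) > 0,
                     nodes_evaluated = stats::rnorm(n, comp_by_s[[s]], 1)))
  }
  set.seed(3)
  # same accuracy, one cheaper: the cheap one dominates, no trade-off
  r1 <- mk_runs(list(`0` = 0.8, `2` = 0.8), list(`0` = 50, `2` = 100))
  p1 <- pareto_analysis(r1, n_boot = 300, seed = 1)
  expect_true(p1$points$on_front[p1$points$shutter == 0])
  expect_false(p1$trade_off)
  # mutually non-dominated with clear separation: a trade-off
  set.seed(4)
  r2 <- mk_runs(list(`0` = 0.55, `2` = 0.95), list(`0` = 40, `2` = 100))
  p2 <- pareto_analysis(r2, n_boot = 300, seed = 1)
  expect_true(all(p2$points$on_front))
  expect_true(p2$trade_off)
  expect_equal(p2$points$reduction,
               1 - p2$points$computation / max(p2$points$computation))
  expect_error(pareto_analysis(r2[r2$shutter == 0, ]), ">= 2 shutter")
})

test_that("the bootstrap trade-off flag agrees with a permutation test on a small fixture", {
  set.seed(9)
  runs <- tibble::tibble(
    shutter = rep(c(0, 2), each = 10),
    found_win = c(stats::rbinom(10, 1, 0.2), stats::rbinom(10, 1, 0.9)) > 0,
    nodes_evaluated = c(stats::rnorm(10, 30, 2), stats::rnorm(10, 90, 2)))
  pa <- pareto_analysis(runs, n_boot = 1000, seed = 2)
  perm_p <- function(x, y, n_perm = 2000) {
    obs <- abs(mean(x) - mean(y)); z <- c(x, y)
    ge <- replicate(n_perm, {
      i <- sample(length(z), length(x))
      abs(mean(z[i]) - mean(z[-i])) >= obs
    })
    mean(ge)
  }
  sig_acc <- perm_p(as.numeric(runs$found_win[runs$shutter == 0]),
                    as.numeric(runs$found_win[runs$shutter == 2])) < 0.05
  sig_comp <- perm_p(runs$nodes_evaluated[runs$shutter == 0],
                     runs$nodes_evaluated[runs$shutter == 2]) < 0.05
  expect_identical(pa$trade_off, sig_acc && sig_comp)
})

test_that("phase space aggregates per-cell trade-off proportions by direct count", {
  set.seed(6)
  mk <- function(board_id, cx, sigma, acc0, acc2) {
    tidyr::expand_grid(branching = c(3, 10), limit = c(30, 200)) |>
      purrr::pmap_dfr(function(branching, limit)
        tibble::tibble(board_id = board_id, complexity = cx, sigma = sigma,
                       branching = branching, limit = limit,
                       shutter = rep(c(0, 2), each = 12),
                       found_win = c(stats::rbinom(12, 1, acc0),
                                     stats::rbinom(12, 1, acc2)) > 0,
                       nodes_evaluated = c(stats::rnorm(12, 30, 2),
                                           stats::rnorm(12, 95, 2))))
  }
  runs <- dplyr::bind_rows(
    mk("a", 100, 0, 0.9, 0.9),    # no accuracy gap: no trade-off expected
    mk("b", 5000, 1, 0.1, 0.95))  # large gap: trade-offs expected
  ph <- phase_space(runs, bins = 2, n_boot = 300, seed = 1)
  expect_true(all(ph$prop_tradeoff >= 0 & ph$prop_tradeoff <= 1))
  cell_b <- ph[ph$sigma == 1, ]
  cell_a <- ph[ph$sigma == 0, ]
  expect_gt(cell_b$prop_tradeoff, cell_a$prop_tradeoff)
})

test_that("board discriminability is non-negative and zero for identical strategies", {
  b <- generate_endgame_board(6, 4, 3, seed = 5)
  expect_equal(strategy_discriminability(b, c("linear", "linear"), n_states = 6), 0)
  expect_gte(strategy_discriminability(b, c("linear", "interaction"), n_states = 6), 0)
})
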