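## Lapse-rate choice model over session moves, exhaustive grid-search
## fitting, AIC selection, likelihood-ratio tests and population summaries.

#' Fitting grid
#'
#' The exhaustive grids searched per participant and strategy: shutter 0-3
#' in steps of 0.1 (plus an explicit "off" cell, `Inf`, so the
#' shutter-augmented model nests the base model for a valid likelihood-ratio
#' test), lapse rate 0-0.05 in steps of 0.01, opponent weight 0-0.5 in steps
#' of 0.1.
#'
#' @param shutter,lapse,w Numeric grids (inclusive of endpoints).
#' @param include_off Add the shutter-off cell (`Inf`).
#' @return A list of class `fit_grid`.
#' @export
fit_grid <- function(shutter = seq(0, 3, by = 0.1),
                     lapse = seq(0, 0.05, by = 0.01),
                     w = seq(0, 0.5, by = 0.1),
                     include_off = TRUE) {
  if (include_off) shutter <- c(shutter, Inf)
  structure(list(shutter = shutter, lapse = lapse, w = w), class = "fit_grid")
}

#' Log-likelihood of a single move
#'
#' The lapse-mixed log-likelihood of choosing `(row, col)`:
#' `log((1 - eps) * p_h(move) + eps / #legal)`, with `p_h` the strategy's
#' move probability (shutter `s`, opponent weight `w`).
#'
#' @param board Pre-move `kboard`.
#' @param row,col The move (must be legal).
#' @param strategy One of [strategy_names()].
#' @param epsilon Lapse rate in `[0, 1]`.
#' @param shutter Shutter size (`Inf` = off).
#' @param w Opponent weight in `[0, 0.5]`.
#' @param last_x_move `(row, col)` of the mover's previous X move or `NULL`.
#' @param player Mover; defaults to the player to move.
#' @return Log-probability (<= 0).
#' @export
move_loglik <- function(board, row, col, strategy = "interaction",
                        epsilon = 0, shutter = Inf, w = 0.5,
                        last_x_move = NULL, player = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  i <- .check_square_empty(board, row, col)
  probs <- move_probabilities(board, strategy,
                              scoring_params(opponent_weight = w),
                              shutter, last_x_move, player)
  p <- probs$prob[probs$row == row & probs$col == col]
  log((1 - epsilon) * p + epsilon / nrow(probs))
}

## Precompute, per place event and strategy, the one-sided score vectors for
## mover and opponent plus the shutter distance map. Everything downstream
## (any s, eps, w cell) is arithmetic on these.
.session_features <- function(session, strategies, params = scoring_params()) {
  g <- .board_geom(session$board)
  recs <- .replay(session)$records
  lapply(recs, function(r) {
    empty <- which(r$marks == EMPTY)
    d <- if (is.na(r$last_x)) NULL else .shutter_dist_map(r$marks, g, r$last_x)
    cnt <- .line_counts(r$marks, g)
    all_m <- .all_strategy_scores(r$marks, g, r$mover,
                                  params$forcing_bonus, params$win_score, cnt)
    all_o <- .all_strategy_scores(r$marks, g, .other(r$mover),
                                  params$forcing_bonus, params$win_score, cnt)
    sm <- lapply(strategies, function(st) all_m[empty, st])
    so <- lapply(strategies, function(st) all_o[empty, st])
    names(sm) <- names(so) <- strategies
    list(empty = empty, move_pos = match(r$cell, empty),
         d = if (is.null(d)) rep(NA_real_, length(empty)) else d[empty],
         sm = sm, so = so, n_legal = length(empty))
  })
}

## p_h(move) for every shutter value, one event, one strategy, one w.
.pmove_by_shutter <- function(feat, strategy, w, shutters) {
  sc <- (1 - w) * feat$sm[[strategy]] + w * feat$so[[strategy]]
  sc <- pmax(sc, 0)
  vapply(shutters, function(s) {
    wt <- shutter_weight(feat$d, s)
    num <- sc * wt
    z <- sum(num)
    if (z > 0) num[feat$move_pos] / z
    else if (any(wt > 0)) (wt[feat$move_pos] > 0) / sum(wt > 0)
    else 1 / length(num)
  }, numeric(1))
}

#' Log-likelihood of a whole session
#'
#' Sums [move_loglik()] over every `place` event (X and O alike), each
#' evaluated on the board state produced by replaying all prior events; undo
#' and reset only mutate the state. The first move of a session (no prior X
#' move of the participant) uses shutter-off probabilities.
#'
#' @param session A `kinarow_session`.
#' @inheritParams move_loglik
#' @return A list: `total_ll`, `mean_ll`, `n_moves`.
#' @export
session_loglik <- function(session, strategy = "interaction", epsilon = 0,
                           shutter = Inf, w = 0.5) {
  feats <- .session_features(session, strategy)
  ll <- vapply(feats, function(f) {
    p <- .pmove_by_shutter(f, strategy, w, shutter)
    log((1 - epsilon) * p + epsilon / f$n_legal)
  }, numeric(1))
  list(total_ll = sum(ll), mean_ll = mean(ll), n_moves = length(ll))
}

#' Fit the choice model to one participant's session
#'
#' Exhaustive grid search: for each scoring strategy, the shutter value,
#' lapse rate (and optionally opponent weight) maximizing the total
#' log-likelihood of the session's moves; model comparison by
#' `AIC = 2 * #free_parameters - 2 * total_ll` with parameters counted as
#' lapse (always) + shutter (if fitted) + opponent weight (if fitted). The
#' participant is assigned the strategy with the best (lowest) AIC.
#'
#' @param session A `kinarow_session` with at least one place event.
#' @param strategies Strategies to compare (default all five).
#' @param grid A [fit_grid()].
#' @param fit_w Also fit the opponent-weight parameter (otherwise fixed at
#'   0.5).
#' @return An object of class `participant_fit`; see [tidy.participant_fit()]
#'   and [glance.participant_fit()].
#' @export
fit_participant <- function(session, strategies = strategy_names(),
                            grid = fit_grid(), fit_w = FALSE) {
  feats <- .session_features(session, strategies)
  if (!length(feats)) stop("session has no place events", call. = FALSE)
  n_moves <- length(feats)
  n_legal <- vapply(feats, `[[`, numeric(1), "n_legal")
  w_vals <- if (fit_w) grid$w else 0.5
  eps <- grid$lapse
  n_par <- 1 + 1 + as.integer(fit_w)  # lapse + shutter (+ w)
  ## the shutter-weight matrix of an event depends only on its distances:
  ## compute it once per event and reuse across strategies and weights
  for (i in seq_along(feats)) {
    wt <- do.call(rbind, lapply(grid$shutter, function(s)
      shutter_weight(feats[[i]]$d, s)))
    feats[[i]]$wt <- wt                      # n_shutter x n_empty
    feats[[i]]$n_adm <- rowSums(wt > 0)
    feats[[i]]$adm_move <- wt[, feats[[i]]$move_pos] > 0
  }
  pmove_grid <- function(feat, strategy, w) {
    sc <- pmax((1 - w) * feat$sm[[strategy]] + w * feat$so[[strategy]], 0)
    z <- as.vector(feat$wt %*% sc)
    p <- feat$wt[, feat$move_pos] * sc[feat$move_pos] / z
    zero <- z <= 0
    if (any(zero))
      p[zero] <- ifelse(feat$n_adm[zero] > 0,
                        feat$adm_move[zero] / feat$n_adm[zero],
                        1 / length(sc))
    p
  }
  rows <- list()
  for (st in strategies) {
    best <- NULL
    for (w in w_vals) {
      ## moves x shutters matrix of p_h(move)
      P <- t(vapply(feats, pmove_grid, numeric(length(grid$shutter)),
                    strategy = st, w = w))
      for (e in eps) {
        ll_s <- colSums(log((1 - e) * P + e / n_legal))
        j <- which.max(ll_s)
        if (is.null(best) || ll_s[j] > best$total_ll)
          best <- list(epsilon = e, shutter = grid$shutter[j], w = w,
                       total_ll = ll_s[j])
      }
    }
    rows[[st]] <- tibble::tibble(
      strategy = st, epsilon = best$epsilon, shutter = best$shutter,
      w = best$w, total_ll = best$total_ll, mean_ll = best$total_ll / n_moves,
      n_moves = n_moves, n_par = n_par,
      aic = 2 * n_par - 2 * best$total_ll)
  }
  by_strategy <- dplyr::bind_rows(rows)
  assigned <- by_strategy$strategy[which.min(by_strategy$aic)]
  structure(list(id = session$id, by_strategy = by_strategy,
                 assigned = assigned, fit_w = fit_w),
            class = "participant_fit")
}

#' @export
print.participant_fit <- function(x, ...) {
  cat(sprintf("participant fit (%s): assigned strategy \"%s\"\n",
              x$id, x$assigned))
  print(x$by_strategy)
  invisible(x)
}

#' Tidy a participant fit
#'
#' @param x A `participant_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per strategy with the best-fitting parameters,
#'   log-likelihoods and AIC. `glance()`: the single assigned-strategy row
#'   plus `id` and `assigned`.
#' @export
tidy.participant_fit <- function(x, ...) {
  dplyr::mutate(x$by_strategy, id = x$id,
                assigned = x$by_strategy$strategy == x$assigned,
                .before = 1)
}

#' @rdname tidy.participant_fit
#' @export
glance.participant_fit <- function(x, ...) {
  row <- dplyr::filter(x$by_strategy, .data$strategy == x$assigned)
  dplyr::mutate(row, id = x$id, .before = 1)
}

#' Fit a cohort of sessions
#'
#' @param sessions List of `kinarow_session`s.
#' @param ... Passed to [fit_participant()].
#' @return A tibble with one row per participant (the [glance][glance.participant_fit] of each fit).
#' @export
fit_cohort <- function(sessions, ...) {
  purrr::imap_dfr(sessions, function(s, i) {
    gl <- generics::glance(fit_participant(s, ...))
    if (is.na(gl$id) || !nzchar(gl$id)) gl$id <- as.character(i)
    gl
  })
}

#' Likelihood-ratio test for nested choice models
#'
#' `p = 1 - F_chisq(2 * (ll_aug - ll_base); df)`.
#'
#' @param ll_base,ll_aug Total log-likelihoods of the base and augmented
#'   model (`ll_aug >= ll_base`).
#' @param df Difference in free parameters (>= 1).
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(ll_base, ll_aug, df = 1) {
  if (ll_aug < ll_base)
    stop("augmented model must not have lower likelihood", call. = FALSE)
  stopifnot(df >= 1)
  stat <- 2 * (ll_aug - ll_base)
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Population strategy proportions with bootstrap confidence intervals
#'
#' The share of participants assigned to each strategy, with percentile
#' bootstrap 95% confidence intervals over participants.
#'
#' @param fits Tibble from [fit_cohort()] (needs a `strategy` column, one
#'   row per participant).
#' @param n_boot Bootstrap replicates (>= 1000 recommended).
#' @param seed RNG seed for the resampling.
#' @param level Confidence level.
#' @return Tibble: `strategy`, `share`, `conf_low`, `conf_high`, `n`.
#' @export
population_summary <- function(fits, n_boot = 1000, seed = 1, level = 0.95) {
  stopifnot(nrow(fits) >= 1)
  set.seed(seed)
  strat <- factor(fits$strategy, levels = strategy_names())
  n <- length(strat)
  shares <- as.numeric(table(strat)) / n
  boot <- replicate(n_boot, {
    as.numeric(table(strat[sample.int(n, n, replace = TRUE)])) / n
  })
  a <- (1 - level) / 2
  ci <- apply(boot, 1, stats::quantile, probs = c(a, 1 - a))
  tibble::tibble(strategy = levels(strat), share = shares,
                 conf_low = ci[1, ], conf_high = ci[2, ], n = n)
}
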