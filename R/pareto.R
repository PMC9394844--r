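## Pareto-front analysis of the accuracy / computation trade-off across
## shutter sizes, and its aggregation into a complexity-by-noise phase space.

## percentile bootstrap CI of a mean
.boot_ci_mean <- function(x, n_boot, level = 0.95) {
  bm <- replicate(n_boot, mean(sample(x, length(x), replace = TRUE)))
  a <- (1 - level) / 2
  stats::quantile(bm, c(a, 1 - a), names = FALSE)
}

## bootstrap test: is mean(x) != mean(y)? (percentile CI of the difference
## excluding zero at the given level)
.boot_diff_sig <- function(x, y, n_boot, level = 0.95) {
  d <- replicate(n_boot, mean(sample(x, length(x), replace = TRUE)) -
                         mean(sample(y, length(y), replace = TRUE)))
  a <- (1 - level) / 2
  ci <- stats::quantile(d, c(a, 1 - a), names = FALSE)
  ci[1] > 0 || ci[2] < 0
}

#' Pareto analysis of shutter sizes
#'
#' For one sweep configuration (a board, noise level, branching factor and
#' move limit), summarises each shutter value by its mean accuracy
#' (probability of finding the winning move) and mean computation (score
#' evaluations), identifies the Pareto front under (maximize accuracy,
#' minimize computation), and flags a *trade-off*: at least two shutter
#' values mutually non-dominated, with bootstrap-significant differences on
#' both axes (p < 0.05 via percentile bootstrap over runs).
#'
#' @param runs Tibble of sweep rows with columns `shutter`, `found_win`,
#'   `nodes_evaluated` (>= 2 shutter values, >= 2 runs each).
#' @param n_boot Bootstrap replicates (>= 1000 recommended).
#' @param seed RNG seed for the bootstrap.
#' @return A list of class `pareto_result`: `points` (per shutter:
#'   `shutter`, `accuracy`, `acc_low`, `acc_high`, `computation`,
#'   `comp_low`, `comp_high`, `reduction` = 1 - computation /
#'   max(computation), `on_front`, `n`), and `trade_off`.
#' @export
pareto_analysis <- function(runs, n_boot = 1000, seed = 1) {
  set.seed(seed)
  shutters <- sort(unique(runs$shutter))
  if (length(shutters) < 2) stop("need >= 2 shutter values", call. = FALSE)
  if (any(table(runs$shutter) < 2)) stop("need >= 2 runs per shutter", call. = FALSE)
  pts <- purrr::map_dfr(shutters, function(s) {
    r <- runs[runs$shutter == s, ]
    acc <- as.numeric(r$found_win); comp <- r$nodes_evaluated
    ca <- .boot_ci_mean(acc, n_boot); cc <- .boot_ci_mean(comp, n_boot)
    tibble::tibble(shutter = s, accuracy = mean(acc),
                   acc_low = ca[1], acc_high = ca[2],
                   computation = mean(comp), comp_low = cc[1], comp_high = cc[2],
                   n = nrow(r))
  })
  pts$reduction <- 1 - pts$computation / max(pts$computation)
  dominates <- function(i, j)  # i dominates j: no worse on both, better on one
    pts$accuracy[i] >= pts$accuracy[j] && pts$computation[i] <= pts$computation[j] &&
    (pts$accuracy[i] > pts$accuracy[j] || pts$computation[i] < pts$computation[j])
  m <- nrow(pts)
  pts$on_front <- vapply(seq_len(m), function(j)
    !any(vapply(seq_len(m)[-j], dominates, logical(1), j = j)), logical(1))
  ## trade-off: some pair of front points with significant differences on
  ## both axes in opposite directions
  trade_off <- FALSE
  front <- which(pts$on_front)
  if (length(front) >= 2) {
    for (a in front) for (b in front) {
      if (a >= b) next
      xi <- runs[runs$shutter == pts$shutter[a], ]
      xj <- runs[runs$shutter == pts$shutter[b], ]
      if (!dominates(a, b) && !dominates(b, a) &&
          .boot_diff_sig(as.numeric(xi$found_win), as.numeric(xj$found_win), n_boot) &&
          .boot_diff_sig(xi$nodes_evaluated, xj$nodes_evaluated, n_boot)) {
        trade_off <- TRUE
      }
    }
  }
  structure(list(points = pts, trade_off = trade_off), class = "pareto_result")
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(sprintf("Pareto analysis over %d shutter values; trade-off: %s\n",
              nrow(x$points), x$trade_off))
  print(x$points)
  invisible(x)
}

#' Phase space of trade-off proportions
#'
#' Aggregates per-configuration trade-off flags over branching factor and
#' move limit into the proportion of configurations with a trade-off per
#' (board-complexity bin, noise level) cell.
#'
#' @param runs Sweep tibble from [shutter_sweep()] (columns `board_id`,
#'   `complexity`, `sigma`, `branching`, `limit`, `shutter`, `found_win`,
#'   `nodes_evaluated`).
#' @param bins Number of complexity bins (quantile bins over boards).
#' @param n_boot,seed Passed to [pareto_analysis()].
#' @return A tibble of class `phase_space`: `complexity_bin`, `sigma`,
#'   `prop_tradeoff`, `n_configs` (empty cells are absent).
#' @export
phase_space <- function(runs, bins = 2, n_boot = 500, seed = 1) {
  cx <- runs |> dplyr::distinct(.data$board_id, .data$complexity)
  qs <- stats::quantile(cx$complexity, probs = seq(0, 1, length.out = bins + 1))
  cx$complexity_bin <- cut(cx$complexity, unique(qs), include.lowest = TRUE,
                           labels = FALSE)
  runs <- dplyr::left_join(runs, cx, by = c("board_id", "complexity"))
  cfg <- runs |>
    dplyr::group_by(.data$board_id, .data$complexity_bin, .data$sigma,
                    .data$branching, .data$limit) |>
    dplyr::group_modify(function(d, key)
      tibble::tibble(trade_off = pareto_analysis(d, n_boot, seed)$trade_off)) |>
    dplyr::ungroup()
  out <- cfg |>
    dplyr::group_by(.data$complexity_bin, .data$sigma) |>
    dplyr::summarise(prop_tradeoff = mean(.data$trade_off),
                     n_configs = dplyr::n(), .groups = "drop")
  class(out) <- c("phase_space", class(out))
  out
}
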