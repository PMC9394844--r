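## Behavioral analyses: entropy of aggregated move distributions, matched
## full/truncated comparisons, behavioral shutter measurement, missed-win
## accounting.

#' Shannon entropy of a move distribution
#'
#' @param p Either a numeric probability vector (summing to 1) or a
#'   move-distribution tibble with a `prob` column.
#' @return Entropy in bits (base 2).
#' @examples
#' entropy(rep(0.25, 4))  # 2
#' @export
entropy <- function(p) {
  if (is.data.frame(p)) p <- p$prob
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Empirical move distribution
#'
#' Aggregates a set of chosen moves into a probability distribution over
#' squares.
#'
#' @param moves Tibble with `row`, `col` columns (one row per observed
#'   move).
#' @return Tibble: `row`, `col`, `n`, `prob`; attribute `"n_total"`.
#' @export
move_distribution <- function(moves) {
  out <- moves |>
    dplyr::count(.data$row, .data$col, name = "n") |>
    dplyr::mutate(prob = .data$n / sum(.data$n))
  attr(out, "n_total") <- sum(out$n)
  out
}

## nth place event of a session (ignoring undo/reset), as a one-row tibble
.nth_placement <- function(session, n) {
  ev <- dplyr::filter(session$events, .data$action == "place")
  if (nrow(ev) < n) return(NULL)
  ev[n, c("player", "row", "col")]
}

#' Matched full/truncated move distributions
#'
#' Compares move choices over the *identical* board state reached with or
#' without the participant's own prior moves. The truncated-condition
#' distribution aggregates first moves on the truncated board; the
#' full-condition distribution aggregates the third moves of only those
#' full-board sessions whose first X and O placements reproduce the
#' truncated start state.
#'
#' @param sessions_full Sessions played on the full board.
#' @param sessions_trunc Sessions played on the truncated board.
#' @param x_move,o_move Length-2 `(row, col)`: the optimal X move and O
#'   reply that turn the full board into the truncated one (as recorded by
#'   [truncate_board()]).
#' @return A list: `full` and `truncated` move-distribution tibbles (the
#'   full one empty when no session qualifies), `n_full`, `n_trunc`.
#' @export
matched_state_distributions <- function(sessions_full, sessions_trunc,
                                        x_move, o_move) {
  third <- purrr::map_dfr(sessions_full, function(s) {
    m1 <- .nth_placement(s, 1); m2 <- .nth_placement(s, 2); m3 <- .nth_placement(s, 3)
    if (is.null(m3)) return(NULL)
    if (m1$player == "X" && m1$row == x_move[1] && m1$col == x_move[2] &&
        m2$player == "O" && m2$row == o_move[1] && m2$col == o_move[2])
      m3[, c("row", "col")]
    else NULL
  })
  first <- purrr::map_dfr(sessions_trunc, function(s) {
    m1 <- .nth_placement(s, 1)
    if (is.null(m1)) NULL else m1[, c("row", "col")]
  })
  list(full = if (nrow(third)) move_distribution(third) else
         tibble::tibble(row = integer(), col = integer(), n = integer(), prob = numeric()),
       truncated = if (nrow(first)) move_distribution(first) else
         tibble::tibble(row = integer(), col = integer(), n = integer(), prob = numeric()),
       n_full = nrow(third), n_trunc = nrow(first))
}

#' Behavioral shutter size of a session
#'
#' The mean distance between the participant's moves and the potential
#' winning paths induced by their last X move ([shutter_distance()]);
#' placements with no preceding X move, and undefined distances (no open
#' induced path), are skipped.
#'
#' @param session A `kinarow_session`.
#' @param thresholds Optional length-2 numeric cut points for the
#'   narrow/medium/wide categories (values `< t1` are narrow, `< t2` medium,
#'   else wide); see [shutter_categories()] for the tertile default over a
#'   cohort.
#' @return A list: `mean_distance` (NA if no eligible move), `n_eligible`,
#'   `category` (NA unless thresholds given).
#' @export
participant_shutter <- function(session, thresholds = NULL) {
  st <- session_states(session)
  g <- .board_geom(session$board)
  d <- purrr::pmap_dbl(st, function(board, row, col, last_x_row, last_x_col, ...) {
    if (is.na(last_x_row)) return(NA_real_)
    as.numeric(shutter_distance(board, row, col, last_x_row, last_x_col))
  })
  d <- d[!is.na(d)]
  m <- if (length(d)) mean(d) else NA_real_
  cat_ <- NA_character_
  if (!is.null(thresholds) && !is.na(m))
    cat_ <- c("narrow", "medium", "wide")[1 + findInterval(m, sort(thresholds))]
  list(mean_distance = m, n_eligible = length(d), category = cat_)
}

#' Tertile cut points for shutter categories
#'
#' Default narrow/medium/wide categorisation uses the tertiles of the
#' cohort's mean-distance distribution (the published cut points are not
#' available, so they are data-driven and configurable).
#'
#' @param mean_distances Numeric vector of per-participant mean shutter
#'   distances.
#' @return Length-2 numeric cut points.
#' @export
shutter_categories <- function(mean_distances) {
  stats::quantile(mean_distances, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
}

#' How well a board separates two scoring strategies
#'
#' Mean Jensen-Shannon divergence (bits) between the move-probability maps
#' of two strategies over the states visited by a simulated explorer of the
#' board. Boards with many crossing open paths separate path-interaction
#' strategies from purely additive ones; boards with low divergence make
#' model recovery near-impossible regardless of the fitting method. Used to
#' select study stimuli before any model fitting is run.
#'
#' @param board A `kboard`.
#' @param strategies Length-2 character vector of strategies to contrast.
#' @param n_states Number of explorer placements to average over.
#' @param seed RNG seed for the explorer.
#' @return Mean JS divergence in bits (>= 0).
#' @export
strategy_discriminability <- function(board,
                                      strategies = c("nonlinear", "interaction"),
                                      n_states = 30, seed = 99) {
  stopifnot(length(strategies) == 2)
  js <- function(p, q) {
    m <- (p + q) / 2
    0.5 * sum(ifelse(p > 0, p * log2(p / m), 0)) +
      0.5 * sum(ifelse(q > 0, q * log2(q / m), 0))
  }
  ses <- simulate_participant(board, "interaction", shutter = Inf,
                              epsilon = 0.05, max_moves = n_states, seed = seed)
  st <- session_states(ses)
  vals <- purrr::pmap_dbl(st, function(board, player, last_x_row, last_x_col, ...) {
    lx <- if (is.na(last_x_row)) NULL else c(last_x_row, last_x_col)
    p <- move_probabilities(board, strategies[1], player = player,
                            last_x_move = lx)$prob
    q <- move_probabilities(board, strategies[2], player = player,
                            last_x_move = lx)$prob
    js(p, q)
  })
  mean(vals)
}

#' Missed winning moves along a trajectory
#'
#' A miss is a turn on which the mover had at least one immediately
#' completing move available but played none of them. The X/O miss
#' asymmetry (ratio of missed X wins to missed O wins) quantifies blindness
#' to the opponent.
#'
#' @param trajectory Either a `kinarow_session` or a placement tibble
#'   (`player`, `row`, `col`) as returned by [simulate_game()].
#' @param board The starting board (taken from the session / the
#'   trajectory's `"board"` attribute when omitted).
#' @return A list: `missed_x`, `missed_o`, `ratio`
#'   (`missed_x / missed_o`; `NA` sentinel when `missed_o` is 0).
#' @export
missed_wins <- function(trajectory, board = NULL) {
  if (inherits(trajectory, "kinarow_session")) {
    st <- session_states(trajectory)
    recs <- purrr::pmap(st, function(board, player, row, col, ...)
      list(marks = board$marks, mover = .player_code(player),
           cell = .cell_index(board$size, row, col)))
    board <- trajectory$board
  } else {
    if (is.null(board)) board <- attr(trajectory, "board")
    stopifnot(!is.null(board))
    marks <- board$marks
    recs <- vector("list", nrow(trajectory))
    for (i in seq_len(nrow(trajectory))) {
      p <- .player_code(trajectory$player[i])
      cell <- .cell_index(board$size, trajectory$row[i], trajectory$col[i])
      recs[[i]] <- list(marks = marks, mover = p, cell = cell)
      marks[cell] <- p
    }
  }
  g <- .board_geom(board)
  mx <- mo <- 0L
  for (r in recs) {
    wins <- .immediate_win_cells(r$marks, g, r$mover)
    if (length(wins) && !(r$cell %in% wins)) {
      if (r$mover == X) mx <- mx + 1L else mo <- mo + 1L
    }
  }
  list(missed_x = mx, missed_o = mo,
       ratio = if (mo > 0) mx / mo else NA_real_)
}
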