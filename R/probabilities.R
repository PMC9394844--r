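## Shutter weighting and the move-probability map shared by the search and
## the behavioral choice model.

#' Shutter weight of a square at a given distance
#'
#' The shutter of size `s` admits squares near the winning paths induced by
#' the last own move. The weight is the linear clamp
#' `min(max(s - distance + 1, 0), 1)`: distance 0 always has weight 1;
#' at `s = 0` only on-path squares are admissible; at `s = 0.5` distance-1
#' squares are considered with probability 0.5; at integer `s` the clamp is a
#' hard cutoff at distance `s`. An undefined distance (`NA`: no induced
#' paths, or no prior own move) has weight 1 — the shutter is inactive.
#'
#' @param distance Non-negative integer distance(s), `NA` allowed.
#' @param s Shutter size, >= 0 (use `Inf` for "off").
#' @return Weight(s) in `[0, 1]`.
#' @examples
#' shutter_weight(0:3, s = 2)    # 1 1 1 0
#' shutter_weight(1, s = 0.5)    # 0.5
#' @export
shutter_weight <- function(distance, s) {
  if (any(s < 0)) stop("shutter size must be >= 0", call. = FALSE)
  if (is.infinite(s)) return(rep(1, length(distance)))
  w <- pmin(pmax(s - distance + 1, 0), 1)
  w[is.na(distance)] <- 1
  w
}

## internal fast path: probabilities over empty cells.
## marks/g as usual; mover code; last_x = cell index of the anchoring move or
## NA (shutter inactive). Returns list(cells, prob, score, weight, n_eval).
.move_probs <- function(marks, g, mover, strategy, params, shutter = Inf,
                        last_x = NA) {
  empty <- which(marks == EMPTY)
  if (!length(empty)) stop("no legal moves", call. = FALSE)
  sc <- .combined_scores(marks, g, mover, strategy, params)[empty]
  if (!is.na(last_x) && is.finite(shutter)) {
    dmap <- .shutter_dist_map(marks, g, last_x)
    d <- if (is.null(dmap)) rep(NA_real_, length(empty)) else dmap[empty]
  } else d <- rep(NA_real_, length(empty))
  wt <- shutter_weight(d, shutter)
  num <- pmax(sc, 0) * wt
  z <- sum(num)
  if (z > 0) {
    p <- num / z
  } else if (any(wt > 0)) {
    p <- as.numeric(wt > 0) / sum(wt > 0)  # uniform over admissible squares
  } else {
    p <- rep(1 / length(empty), length(empty))  # uniform over legal moves
  }
  list(cells = empty, prob = p, score = sc, weight = wt,
       distance = d, n_eval = length(empty))
}

#' Move-probability map of a scoring strategy
#'
#' The probability of each legal move is proportional to its non-negative
#' combined score times its shutter weight: each score is divided by the
#' total over all squares, negative scores getting probability zero. If every
#' weighted score is zero the distribution is uniform over the admissible
#' (weight > 0) squares, and if no square is admissible, uniform over all
#' legal moves.
#'
#' @param board A `kboard` with at least one legal move.
#' @param strategy One of [strategy_names()].
#' @param params A [scoring_params()].
#' @param shutter Shutter size (`Inf` = off).
#' @param last_x_move Length-2 `(row, col)` of the move anchoring the
#'   shutter (the mover's previous X move), or `NULL` when there is none —
#'   the shutter is then inactive.
#' @param player Mover; defaults to the player to move.
#' @return A tibble with one row per legal move: `row`, `col`, `label`,
#'   `score`, `distance`, `weight`, `prob` (summing to 1).
#' @export
move_probabilities <- function(board, strategy = "interaction",
                               params = scoring_params(), shutter = Inf,
                               last_x_move = NULL, player = NULL) {
  g <- .board_geom(board)
  p <- if (is.null(player)) board$to_move else .player_code(player)
  last_x <- if (is.null(last_x_move)) NA else
    .cell_index(board$size, last_x_move[1], last_x_move[2])
  mp <- .move_probs(board$marks, g, p, strategy, params, shutter, last_x)
  tibble::tibble(row = g$rows[mp$cells], col = g$cols[mp$cells],
                 label = square_label(board$size, g$rows[mp$cells], g$cols[mp$cells]),
                 score = mp$score, distance = mp$distance,
                 weight = mp$weight, prob = mp$prob)
}
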