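## Winning-path queries: open paths, induced paths, shutter distance.

## line-level mark counts; returns list(cnt_x, cnt_o) vectors of length n_lines
.line_counts <- function(marks, g) {
  mm <- matrix(marks[g$line_mat], nrow = g$n_lines)
  list(x = rowSums(mm == X), o = rowSums(mm == O))
}

#' Open winning paths through a square
#'
#' A *potential* (open) path for a player is a contiguous length-`k` line —
#' horizontal, vertical or diagonal — containing no opponent marks, hence
#' still able to realize a win. This enumerates every open path passing
#' through `square`, annotated with the number of the player's marks already
#' on it (the square itself counts only if it is marked).
#'
#' @param board A `kboard`.
#' @param row,col The square (need not be empty).
#' @param player The path owner, `"X"` or `"O"`.
#' @return A tibble with one row per open path: `direction`, `squares`
#'   (list-column of row/col tibbles), `owner`, `count`. Zero rows if every
#'   line through the square is blocked.
#' @examples
#' b <- kboard(3, 3)
#' nrow(open_paths_through(b, 1, 1, "X"))  # corner of empty 3x3: 3 paths
#' @export
open_paths_through <- function(board, row, col, player) {
  g <- .board_geom(board)
  if (row < 1 || row > board$size || col < 1 || col > board$size)
    stop("square off board", call. = FALSE)
  p <- .player_code(player)
  i <- .cell_index(board$size, row, col)
  cnt <- .line_counts(board$marks, g)
  opp <- if (p == X) cnt$o else cnt$x
  own <- if (p == X) cnt$x else cnt$o
  js <- g$cell2lines[[i]]
  js <- js[opp[js] == 0]
  if (!length(js))
    return(tibble::tibble(direction = character(), squares = list(),
                          owner = character(), count = integer()))
  dplyr::bind_rows(lapply(js, function(j) .line_tibble(g, j, board$marks, p)))
}

#' Paths induced by the last X move
#'
#' The open winning paths of the mover that pass through their most recent
#' move; these are the lines the shutter heuristic anchors on.
#'
#' @param board A `kboard`.
#' @param row,col The square of the last move; it must carry a mark.
#' @return As [open_paths_through()], owned by the player whose mark sits on
#'   the square.
#' @export
induced_paths <- function(board, row, col) {
  i <- .cell_index(board$size, row, col)
  p <- board$marks[i]
  if (p == EMPTY) stop("last move square carries no mark", call. = FALSE)
  open_paths_through(board, row, col, .player_char(p))
}

## internal: map of shutter distances for every cell, relative to the open
## paths through `last_cell` (owner = mark at last_cell). Returns a numeric
## vector over cells, or NULL when no induced path exists (the "undefined"
## sentinel: callers treat it as shutter inactive).
.shutter_dist_map <- function(marks, g, last_cell) {
  p <- marks[last_cell]
  if (p == EMPTY) stop("last move square carries no mark", call. = FALSE)
  cnt <- .line_counts(marks, g)
  opp <- if (p == X) cnt$o else cnt$x
  js <- g$cell2lines[[last_cell]]
  js <- js[opp[js] == 0]
  if (!length(js)) return(NULL)
  cells <- unique(as.vector(g$line_mat[js, , drop = FALSE]))
  d <- rep(Inf, g$ncell)
  for (cc in cells) {
    d <- pmin(d, abs(g$rows - g$rows[cc]) + abs(g$cols - g$cols[cc]))
  }
  d
}

#' Shutter distance of a candidate square
#'
#' The minimal Manhattan distance between a candidate square and the
#' potential winning paths stemming from the previous move: squares on an
#' induced path are at distance 0, squares adjacent to one at distance 1,
#' and so on. When the last move induces no open path the distance is
#' *undefined* and `NA` is returned; callers opting in treat `NA` as "all
#' squares admissible".
#'
#' @param board A `kboard`.
#' @param row,col Candidate square (empty).
#' @param last_row,last_col The last move (must carry a mark).
#' @return Non-negative integer distance, or `NA` if no path is induced.
#' @export
shutter_distance <- function(board, row, col, last_row, last_col) {
  g <- .board_geom(board)
  d <- .shutter_dist_map(board$marks, g, .cell_index(board$size, last_row, last_col))
  if (is.null(d)) return(NA_integer_)
  as.integer(d[.cell_index(board$size, row, col)])
}
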