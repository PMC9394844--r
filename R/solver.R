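## Exact forced-win solver. This is the ground-truth verifier behind board
## generation, truncation, and the "found the correct solution" adjudication
## of the stochastic searches. It is a plain AND-OR proof search over X's
## winning strategies, sound and complete within the stated number of X
## moves, with two exact reductions that keep it fast on forcing-rich
## end-game boards:
##   - a player with an immediate completing move wins on the spot;
##   - when X threatens an immediate win, O's only non-losing replies are the
##     squares completing those threats (or an own immediate win, checked
##     first) — any other reply lets X complete next turn.
## Results are memoized per top-level call on the position string. Move
## ordering uses an exponential open-line weight (near-complete lines
## dominate) so forcing moves surface first; ordering never affects the
## verdict, only the time to reach it.

.immediate_win_cells <- function(marks, g, player) {
  cnt <- .line_counts(marks, g)
  own <- if (player == X) cnt$x else cnt$o
  opp <- if (player == X) cnt$o else cnt$x
  hot <- (opp == 0) & (own == g$k - 1L)
  if (!any(hot)) return(integer())
  cells <- unique(as.vector(g$line_mat[hot, , drop = FALSE]))
  cells[marks[cells] == EMPTY]
}

## one pass over the line counts shared by a solver node: immediate wins for
## both players and a cheap ordering score per cell
.solver_node <- function(marks, g) {
  cnt <- .line_counts(marks, g)
  open_x <- cnt$o == 0; open_o <- cnt$x == 0
  hot_x <- open_x & (cnt$x == g$k - 1L)
  hot_o <- open_o & (cnt$o == g$k - 1L)
  win_cells <- function(hot) {
    if (!any(hot)) return(integer())
    cells <- unique(as.vector(g$line_mat[hot, , drop = FALSE]))
    cells[marks[cells] == EMPTY]
  }
  ord <- as.vector(g$inc %*% (open_x * 2^cnt$x + open_o * 2^cnt$o))
  list(iw_x = win_cells(hot_x), iw_o = win_cells(hot_o), ord = ord, cnt = cnt)
}

.memo_key <- function(marks, d) paste0(intToUtf8(marks + 49L), d)

## a node budget (set by callers that probe many speculative positions)
## turns a pathological proof into a clean abort instead of a stall
.solver_tick <- function(memo) {
  n <- memo$.nodes
  if (is.null(n)) n <- 0L
  memo$.nodes <- n + 1L
  if (!is.null(memo$.budget) && memo$.nodes > memo$.budget)
    stop(structure(class = c("solver_budget_exhausted", "error", "condition"),
                   list(message = "solver node budget exhausted", call = NULL)))
}

## Budget-aware candidate restriction (exact, not heuristic). Within a
## budget of b own moves, a line can still matter only if it can reach
## k - 1 own marks (a threat) or k (the win) using that budget, i.e. its
## current count is >= k - 1 - b. A move on no such line is a pass, and a
## pass never helps the attacker: by the usual strategy-stealing argument an
## extra own mark is never harmful, so any winning strategy containing a
## pass can be replayed without it. Cells on no qualifying line are
## therefore excluded without loss.
.cells_on_lines <- function(marks, g, line_sel) {
  if (!any(line_sel)) return(integer())
  cells <- unique(as.vector(g$line_mat[line_sel, , drop = FALSE]))
  cells[marks[cells] == EMPTY]
}

## can X (to move) force a win within `d` further X moves?
.solve_x <- function(marks, g, d, memo) {
  key <- .memo_key(marks, d)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  .solver_tick(memo)
  nd <- .solver_node(marks, g)
  res <- FALSE
  if (length(nd$iw_x)) {
    res <- d >= 1L
  } else if (d >= 2L) {
    ## offensive candidates: open X lines still able to reach k - 1 within
    ## the budget; defensive candidates: open O lines that O could bring to
    ## a threat with its d - 1 replies (X may have to block them en route)
    cnt <- nd$cnt
    cand <- .cells_on_lines(marks, g, (cnt$o == 0 & cnt$x >= g$k - 1L - d) |
                                      (cnt$x == 0 & cnt$o >= g$k - d))
    if (length(cand)) {
      cand <- cand[order(-nd$ord[cand], cand)]
      for (cell in cand) {
        m2 <- marks; m2[cell] <- X
        if (.solve_o(m2, g, d, memo)) { res <- TRUE; break }
      }
    }
  }
  memo[[key]] <- res
  res
}

## O to move, X has just played and needs d - 1 further X moves: does X
## force a win against every O reply? O's useful replies either block an X
## line still feasible within X's remaining budget (count >= k - d) or
## advance an O line feasible within O's own d - 1 remaining replies
## (count >= k - d); every other reply is a pass, and all passes are
## exchangeable — one representative is checked.
.solve_o <- function(marks, g, d, memo) {
  .solver_tick(memo)
  nd <- .solver_node(marks, g)
  if (length(nd$iw_o)) return(FALSE)
  empties <- which(marks == EMPTY)
  if (!length(empties)) return(FALSE)  # draw
  cand <- if (length(nd$iw_x)) {
    nd$iw_x
  } else {
    cnt <- nd$cnt
    thr <- g$k - d
    cc <- .cells_on_lines(marks, g, (cnt$o == 0 & cnt$x >= thr) |
                                    (cnt$x == 0 & cnt$o >= thr))
    if (length(cc) < length(empties))
      cc <- c(cc, setdiff(empties, cc)[1])  # one representative pass
    cc
  }
  if (length(cand) > 1L) cand <- cand[order(-nd$ord[cand], cand)]
  for (cell in cand) {
    m2 <- marks; m2[cell] <- O
    if (!.solve_x(m2, g, d - 1L, memo)) return(FALSE)
  }
  TRUE
}

#' Exact forced-win verification
#'
#' `forced_win()` decides whether X, to move, can force a win within `depth`
#' X moves against best defense. `optimal_first_moves()` lists every first
#' move that realizes such a forced win. `move_forces_win()` checks one
#' candidate first move. These are exact (complete) searches, independent of
#' the heuristic scoring strategies.
#'
#' @param board A `kboard` with X to move and no completed winning path.
#' @param depth Number of X moves allowed (defaults to the board's
#'   `solution_depth`).
#' @param memo Optional environment reusing memoized positions across calls
#'   on related boards.
#' @return `forced_win()` a logical; `optimal_first_moves()` a tibble of
#'   `row`, `col`, `label`; `move_forces_win()` a logical.
#' @export
forced_win <- function(board, depth = board$solution_depth, memo = NULL) {
  stopifnot(!is.null(depth), depth >= 1)
  g <- .board_geom(board)
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  .solve_x(board$marks, g, as.integer(depth), memo)
}

#' @rdname forced_win
#' @param row,col Candidate first move for `move_forces_win()`.
#' @export
move_forces_win <- function(board, row, col, depth = board$solution_depth,
                            memo = NULL) {
  stopifnot(!is.null(depth), depth >= 1)
  g <- .board_geom(board)
  cell <- .cell_index(board$size, row, col)
  if (board$marks[cell] != EMPTY) stop("square is occupied", call. = FALSE)
  m2 <- board$marks; m2[cell] <- X
  if (!is.null(.winning_line(m2, g, X))) return(TRUE)
  if (depth < 2) return(FALSE)
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  .solve_o(m2, g, as.integer(depth), memo)
}

#' @rdname forced_win
#' @export
optimal_first_moves <- function(board, depth = board$solution_depth,
                                memo = NULL) {
  stopifnot(!is.null(depth), depth >= 1)
  g <- .board_geom(board)
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  empties <- which(board$marks == EMPTY)
  ok <- logical(length(empties))
  for (j in seq_along(empties)) {
    m2 <- board$marks; m2[empties[j]] <- X
    ok[j] <- if (!is.null(.winning_line(m2, g, X))) TRUE
             else if (depth < 2) FALSE
             else .solve_o(m2, g, as.integer(depth), memo)
  }
  i <- empties[ok]
  tibble::tibble(row = g$rows[i], col = g$cols[i],
                 label = square_label(board$size, g$rows[i], g$cols[i]))
}

#' Minimal forced-win depth
#'
#' The smallest number of X moves within which X can force a win, checked
#' by increasing depth up to `max_depth`; `NA` if none.
#'
#' @inheritParams forced_win
#' @param max_depth Largest depth to try.
#' @export
forced_win_depth <- function(board, max_depth = 5, memo = NULL) {
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  for (d in seq_len(max_depth))
    if (forced_win(board, d, memo)) return(d)
  NA_integer_
}
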