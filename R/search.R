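## Deterministic alpha-beta search with heuristic scoring, plus the
## board-complexity measure built on it.

## negamax with alpha-beta cuts. Values are from the perspective of the side
## to move: a completed win for the previous mover at ply p is worth
## -(win_score - p) (so faster wins rank higher), a full board 0, and a
## depth-0 leaf the best combined score available to the side to move.
## `counter` (environment) tallies score evaluations: one per square scored,
## including move-ordering and leaf evaluations.
.ab <- function(marks, g, to_move, depth, alpha, beta, ply, strategy, params,
                branching, counter, last_move) {
  if (!is.na(last_move)) {
    prev <- .other(to_move)
    js <- g$cell2lines[[last_move]]
    lcnt <- rowSums(matrix(marks[g$line_mat[js, , drop = FALSE]] == prev,
                           nrow = length(js)))
    if (any(lcnt == g$k)) return(-(params$win_score - ply))
  }
  empties <- which(marks == EMPTY)
  if (!length(empties)) return(0)
  ## immediate-win shortcut: a mover with a completing move plays it — the
  ## fastest win dominates, so the subtree need not be expanded or scored
  cnt <- .line_counts(marks, g)
  own <- if (to_move == X) cnt$x else cnt$o
  opp <- if (to_move == X) cnt$o else cnt$x
  if (depth >= 1L && any(opp == 0 & own == g$k - 1L))
    return(params$win_score - ply - 1)
  sc <- .combined_scores(marks, g, to_move, strategy, params, cnt = cnt)[empties]
  counter$n <- counter$n + length(empties)
  if (depth <= 0L) return(max(sc))
  ord <- order(-sc, empties)
  if (is.finite(branching) && length(ord) > branching)
    ord <- ord[seq_len(branching)]
  best <- -Inf
  for (j in ord) {
    cell <- empties[j]
    ## at the horizon a move is worth its own score (so depth 1 is a greedy
    ## argmax of the scoring strategy); wins were handled by the shortcut,
    ## and a board-filling move is a draw
    v <- if (depth == 1L) {
      if (length(empties) == 1L) 0 else sc[j]
    } else {
      m2 <- marks; m2[cell] <- to_move
      -.ab(m2, g, .other(to_move), depth - 1L, -beta, -alpha, ply + 1L,
           strategy, params, branching, counter, cell)
    }
    if (v > best) best <- v
    if (v > alpha) alpha <- v
    if (alpha >= beta) break
  }
  best
}

#' Depth-limited alpha-beta search
#'
#' Traverses the game tree depth-first assuming optimal play from both
#' players, pruning branches that cannot outperform the best solution found
#' so far. Children are ordered best-first by the scoring strategy (which
#' also values depth-limit leaves); terminal wins are valued at
#' `win_score` minus the ply at which they occur, so faster wins rank
#' higher. `nodes_evaluated` counts score evaluations: one per square for
#' which a combined score was computed, including ordering and leaf
#' evaluations.
#'
#' @param board A non-terminal `kboard`.
#' @param strategy One of [strategy_names()].
#' @param params A [scoring_params()].
#' @param depth Plies of lookahead (>= 1). A forced win for X within `d` X
#'   moves is confirmed at `2 d - 1` plies.
#' @param branching Maximum children expanded per node (`Inf` = all).
#' @return A list of class `search_result`: `move` (row, col), `label`,
#'   `value` (from the mover's perspective), `nodes_evaluated`, `found_win`
#'   (value corresponds to a forced win within the horizon), `depth`.
#' @examples
#' b <- kboard(3, 3)
#' res <- alpha_beta(b, depth = 9)
#' res$value  # 0: tic-tac-toe from empty is a draw
#' @export
alpha_beta <- function(board, strategy = "interaction",
                       params = scoring_params(), depth, branching = Inf) {
  stopifnot(depth >= 1)
  if (is_terminal(board)) stop("board is terminal", call. = FALSE)
  g <- .board_geom(board)
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  to_move <- board$to_move
  empties <- which(board$marks == EMPTY)
  cnt <- .line_counts(board$marks, g)
  own <- if (to_move == X) cnt$x else cnt$o
  opp <- if (to_move == X) cnt$o else cnt$x
  hot <- opp == 0 & own == g$k - 1L
  if (any(hot)) {
    ## the mover completes a win outright
    wc <- unique(as.vector(g$line_mat[hot, , drop = FALSE]))
    cell <- wc[board$marks[wc] == EMPTY][1]
    return(structure(list(move = c(row = g$rows[cell], col = g$cols[cell]),
                          label = square_label(board$size, g$rows[cell], g$cols[cell]),
                          value = params$win_score - 1, nodes_evaluated = 0L,
                          found_win = TRUE, depth = depth),
                     class = "search_result"))
  }
  sc <- .combined_scores(board$marks, g, to_move, strategy, params,
                         cnt = cnt)[empties]
  counter$n <- counter$n + length(empties)
  ord <- order(-sc, empties)
  if (is.finite(branching) && length(ord) > branching)
    ord <- ord[seq_len(branching)]
  best <- -Inf; best_cell <- empties[ord[1]]
  alpha <- -Inf
  for (j in ord) {
    cell <- empties[j]
    v <- if (depth == 1L) {
      if (length(empties) == 1L) 0 else sc[j]
    } else {
      m2 <- board$marks; m2[cell] <- to_move
      -.ab(m2, g, .other(to_move), depth - 1L, -Inf, -alpha, 1L,
           strategy, params, branching, counter, cell)
    }
    if (v > best) { best <- v; best_cell <- cell }
    if (v > alpha) alpha <- v
  }
  structure(list(move = c(row = g$rows[best_cell], col = g$cols[best_cell]),
                 label = square_label(board$size, g$rows[best_cell], g$cols[best_cell]),
                 value = best, nodes_evaluated = counter$n,
                 found_win = best >= params$win_score - (2 * depth - 1),
                 depth = depth),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("move %s, value %.3f, %d evaluations%s\n", x$label, x$value,
              x$nodes_evaluated, if (isTRUE(x$found_win)) " (win found)" else ""))
  invisible(x)
}

#' Board complexity
#'
#' The number of score evaluations a deterministic alpha-beta search with the
#' Interaction scoring strategy needs to explore the board, with the search
#' depth limited to the predefined solution depth (3, 4 or 5 X moves to win,
#' i.e. `2 d - 1` plies).
#'
#' @param board A `kboard` with `solution_depth` set.
#' @param params A [scoring_params()] (noise must be 0 for a deterministic
#'   count).
#' @return Integer node (evaluation) count.
#' @export
board_complexity <- function(board, params = scoring_params()) {
  if (is.null(board$solution_depth))
    stop("board has no solution_depth", call. = FALSE)
  stopifnot(params$noise_sigma == 0)
  res <- alpha_beta(board, "interaction", params,
                    depth = 2L * board$solution_depth - 1L)
  res$nodes_evaluated
}

#' One move of an internal-search agent
#'
#' Models a participant who selects each observed move by a shallow internal
#' alpha-beta search (depth 1-3 plies, limited branching); only the chosen
#' move is observed, not the internal tree.
#'
#' @param board A non-terminal `kboard`.
#' @param strategy One of [strategy_names()].
#' @param depth Internal search depth in plies (1-3 typical).
#' @param branching Children expanded per level (5-10 typical).
#' @param params A [scoring_params()].
#' @return A `search_result`; its `move` is the observed move.
#' @export
internal_search_agent <- function(board, strategy = "interaction", depth = 2,
                                  branching = 7, params = scoring_params()) {
  alpha_beta(board, strategy, params, depth = depth, branching = branching)
}
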