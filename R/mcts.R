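## Monte-Carlo tree search (UCT) with optional persistence of the search
## tree across successive moves, modelling a searcher who retains visit
## counts and outcomes from previous simulations instead of starting anew.

.mcts_node <- function(marks, to_move) {
  e <- new.env(parent = emptyenv())
  e$marks <- marks; e$to_move <- to_move
  e$N <- 0; e$W <- 0  # visits; total reward from the parent mover's view
  e$children <- list()  # keyed by cell index (as character)
  e$untried <- which(marks == EMPTY)
  e
}

## winner code or 0L (none yet / draw)
.winner_after <- function(marks, g, cell, player) {
  js <- g$cell2lines[[cell]]
  cnt <- rowSums(matrix(marks[g$line_mat[js, , drop = FALSE]] == player,
                        nrow = length(js)))
  if (any(cnt == g$k)) player else 0L
}

.rollout <- function(marks, g, to_move) {
  repeat {
    empties <- which(marks == EMPTY)
    if (!length(empties)) return(0L)
    cell <- empties[sample.int(length(empties), 1L)]
    marks[cell] <- to_move
    if (.winner_after(marks, g, cell, to_move) != 0L) return(to_move)
    to_move <- .other(to_move)
  }
}

#' Monte-Carlo tree search
#'
#' UCT-style selection with uniform random rollouts to a terminal state and
#' backpropagated outcomes; the returned move is the root child with the
#' highest visit count. With `persistent = TRUE` the returned tree can be
#' handed to the next call (after the chosen and opponent moves are played)
#' so visit counts and outcomes from earlier simulations are retained.
#'
#' @param board A non-terminal `kboard`.
#' @param n_sim Number of simulations (50, 200 or 500 typical).
#' @param seed Optional RNG seed.
#' @param persistent Keep the search tree for reuse across moves.
#' @param tree A tree returned by a previous call (with `persistent = TRUE`);
#'   the subtree matching the current position is reused.
#' @param c_uct Exploration constant.
#' @return A list of class `mcts_result`: `move`, `label`, `visits` (tibble
#'   of root children: `row`, `col`, `visits`, `value`), and (if persistent)
#'   `tree`.
#' @export
mcts <- function(board, n_sim = 200, seed = NULL, persistent = FALSE,
                 tree = NULL, c_uct = sqrt(2)) {
  stopifnot(n_sim >= 1)
  if (is_terminal(board)) stop("board is terminal", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- .board_geom(board)
  root <- NULL
  if (!is.null(tree)) root <- .find_subtree(tree, board$marks)
  if (is.null(root)) root <- .mcts_node(board$marks, board$to_move)
  for (s in seq_len(n_sim)) .mcts_sim(root, g, c_uct)
  kids <- root$children
  if (!length(kids)) stop("no expanded children", call. = FALSE)
  cells <- as.integer(names(kids))
  visits <- vapply(kids, function(ch) ch$N, numeric(1))
  values <- vapply(kids, function(ch) if (ch$N > 0) ch$W / ch$N else 0, numeric(1))
  best <- cells[order(-visits, cells)][1]
  out <- list(move = c(row = g$rows[best], col = g$cols[best]),
              label = square_label(board$size, g$rows[best], g$cols[best]),
              visits = tibble::tibble(row = g$rows[cells], col = g$cols[cells],
                                      visits = unname(visits),
                                      value = unname(values)),
              n_sim = n_sim)
  if (persistent) out$tree <- root
  structure(out, class = "mcts_result")
}

## one selection/expansion/rollout/backprop pass
.mcts_sim <- function(node, g, c_uct) {
  path <- list(node)
  winner <- NA_integer_
  while (TRUE) {
    nd <- path[[length(path)]]
    empties <- which(nd$marks == EMPTY)
    if (!length(empties)) { winner <- 0L; break }
    if (length(nd$untried)) {
      cell <- nd$untried[sample.int(length(nd$untried), 1L)]
      nd$untried <- setdiff(nd$untried, cell)
      m2 <- nd$marks; m2[cell] <- nd$to_move
      child <- .mcts_node(m2, .other(nd$to_move))
      child$via <- cell
      nd$children[[as.character(cell)]] <- child
      path[[length(path) + 1L]] <- child
      w <- .winner_after(m2, g, cell, nd$to_move)
      winner <- if (w != 0L) w else .rollout(m2, g, child$to_move)
      break
    }
    ## fully expanded: UCT select (child W is from the mover's perspective)
    kids <- nd$children
    ucb <- vapply(kids, function(ch)
      ch$W / ch$N + c_uct * sqrt(log(nd$N + 1) / ch$N), numeric(1))
    child <- kids[[which.max(ucb)]]
    m2 <- child$marks
    cell <- child$via
    w <- .winner_after(m2, g, cell, nd$to_move)
    if (w != 0L) { path[[length(path) + 1L]] <- child; winner <- w; break }
    path[[length(path) + 1L]] <- child
  }
  ## backpropagate: each node's W accumulates reward for the player who just
  ## moved into it (i.e. the parent's mover)
  for (i in seq_along(path)) {
    nd <- path[[i]]
    nd$N <- nd$N + 1
    if (i > 1) {
      mover <- path[[i - 1]]$to_move
      nd$W <- nd$W + if (winner == 0L) 0.5 else if (winner == mover) 1 else 0
    }
  }
}

## locate the node matching `marks` within two plies of the stored root
.find_subtree <- function(tree, marks) {
  if (identical(tree$marks, marks)) return(tree)
  for (ch in tree$children) {
    if (identical(ch$marks, marks)) return(ch)
    for (gc in ch$children) if (identical(gc$marks, marks)) return(gc)
  }
  NULL
}
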