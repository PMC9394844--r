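# Independent oracles used across the suite. These deliberately avoid the
# package's internal geometry cache and search code: paths are enumerated by
# direction scanning, minimax is plain memoized recursion without pruning.

# all length-k windows through (row, col) on a size x size grid, as a list of
# (k x 2) coordinate matrices, by brute-force direction scanning
oracle_windows_through <- function(size, k, row, col) {
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))
  out <- list()
  for (d in dirs) for (off in 0:(k - 1)) {
    rs <- row + d[1] * ((0:(k - 1)) - off)
    cs <- col + d[2] * ((0:(k - 1)) - off)
    if (all(rs >= 1 & rs <= size & cs >= 1 & cs <= size))
      out[[length(out) + 1L]] <- cbind(rs, cs)
  }
  unique(lapply(out, function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]))
}

oracle_mark_at <- function(board, row, col) {
  m <- matrix(board$marks, board$size, board$size)
  m[row, col]
}

# open windows through a square for a player, with own-mark counts
oracle_open_paths <- function(board, row, col, player_code) {
  wins <- oracle_windows_through(board$size, board$k, row, col)
  opp <- 3L - player_code
  keep <- Filter(function(w) {
    marks <- mapply(function(r, c) oracle_mark_at(board, r, c), w[, 1], w[, 2])
    !any(marks == opp)
  }, wins)
  vapply(keep, function(w) {
    marks <- mapply(function(r, c) oracle_mark_at(board, r, c), w[, 1], w[, 2])
    sum(marks == player_code)
  }, numeric(1))
}

# minimal Manhattan distance from (row,col) to any square of any open path
# through the last move; NA if no open path
oracle_shutter_distance <- function(board, row, col, last_row, last_col) {
  p <- oracle_mark_at(board, last_row, last_col)
  wins <- oracle_windows_through(board$size, board$k, last_row, last_col)
  opp <- 3L - p
  open <- Filter(function(w) {
    marks <- mapply(function(r, c) oracle_mark_at(board, r, c), w[, 1], w[, 2])
    !any(marks == opp)
  }, wins)
  if (!length(open)) return(NA_integer_)
  min(vapply(open, function(w) min(abs(w[, 1] - row) + abs(w[, 2] - col)),
             numeric(1)))
}

# plain memoized minimax (no pruning, no ordering) with the same terminal
# convention as the package search: win at ply p is worth win_score - p for
# the winner, draws 0; full depth only (leaves are terminal)
oracle_minimax <- function(board, win_score = 100, memo = NULL) {
  size <- board$size; k <- board$k
  windows <- list()
  for (r in 1:size) for (c in 1:size)
    for (w in oracle_windows_through(size, k, r, c))
      windows[[paste(t(w), collapse = ",")]] <- (w[, 2] - 1L) * size + w[, 1]
  windows <- unname(windows)
  has_win <- function(m, p) {
    any(vapply(windows, function(w) all(m[w] == p), logical(1)))
  }
  # memoized exhaustive minimax on relative ply: a win q plies below the
  # current node is worth win_score - q to the winner (same faster-win
  # preference as the package search, with the node itself at ply 0)
  if (is.null(memo)) memo <- new.env(parent = emptyenv())
  rec <- function(m, to_move) {
    key <- paste0(paste(m, collapse = ""), to_move)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    prev <- 3L - to_move
    v <- if (has_win(m, prev)) {
      -win_score
    } else {
      empties <- which(m == 0L)
      if (!length(empties)) 0 else {
        best <- -Inf
        for (cell in empties) {
          m2 <- m; m2[cell] <- to_move
          vc <- rec(m2, prev)
          pv <- if (vc == 0) 0 else -vc + sign(vc)  # one ply farther away
          if (pv > best) best <- pv
        }
        best
      }
    }
    memo[[key]] <- v
    v
  }
  rec(board$marks, board$to_move)
}

# board fixtures -------------------------------------------------------------

# the worked-example board: an empty square at (5,5) on 10x10/k=5 lying on
# exactly two open X paths holding 3 (row) and 2 (column) X marks, every
# other line through it blocked by O
worked_example_board <- function() {
  kboard(10, 5,
         x = rbind(c(5, 1), c(5, 2), c(5, 3), c(1, 5), c(2, 5)),
         o = rbind(c(5, 6), c(6, 5), c(4, 4), c(6, 6), c(6, 4), c(4, 6)))
}

random_board <- function(size, k, n_pairs, seed) {
  set.seed(seed)
  cells <- sample(size * size, 2 * n_pairs)
  x <- cbind(((cells[seq_len(n_pairs)] - 1) %% size) + 1,
             ((cells[seq_len(n_pairs)] - 1) %/% size) + 1)
  o <- cbind(((cells[n_pairs + seq_len(n_pairs)] - 1) %% size) + 1,
             ((cells[n_pairs + seq_len(n_pairs)] - 1) %/% size) + 1)
  kboard(size, k, x = x, o = o, validate = FALSE)
}
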