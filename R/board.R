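#' @keywords internal
"_PACKAGE"

## player codes used in the internal integer representation
EMPTY <- 0L
X <- 1L
O <- 2L

.player_code <- function(player) {
  if (is.numeric(player)) return(as.integer(player))
  switch(toupper(as.character(player)), X = X, O = O,
         stop("player must be \"X\" or \"O\"", call. = FALSE))
}

.player_char <- function(code) c("X", "O")[code]

.other <- function(code) 3L - code

## Geometry cache: winning lines, incidence and neighbourhoods per (size, k).
.geom_cache <- new.env(parent = emptyenv())

#' Winning-line geometry for a board size and win length
#'
#' Enumerates every length-`k` contiguous line (horizontal, vertical and both
#' diagonals) on a `size` x `size` grid, in the canonical scan order
#' horizontal, vertical, diagonal-down, diagonal-up, top-left first. The
#' result is cached per `(size, k)` and reused by all scoring and search code.
#'
#' @param size Side length of the square grid.
#' @param k Number of marks in a row needed to win.
#' @return A list with the line/cell incidence structures (internal format).
#' @keywords internal
board_geometry <- function(size, k) {
  size <- as.integer(size); k <- as.integer(k)
  key <- paste0(size, "_", k)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  stopifnot(size >= 1, k >= 1, k <= size)
  idx <- function(r, c) (c - 1L) * size + r
  lines <- list()
  dirs <- character()
  ## scan order: horizontal, vertical, diagonal-down, diagonal-up; within a
  ## direction rows before columns, top-left first
  for (r in seq_len(size)) for (c in seq_len(size - k + 1L)) {
    lines[[length(lines) + 1L]] <- idx(r, c:(c + k - 1L)); dirs <- c(dirs, "horizontal")
  }
  for (c in seq_len(size)) for (r in seq_len(size - k + 1L)) {
    lines[[length(lines) + 1L]] <- idx(r:(r + k - 1L), c); dirs <- c(dirs, "vertical")
  }
  for (r in seq_len(size - k + 1L)) for (c in seq_len(size - k + 1L)) {
    lines[[length(lines) + 1L]] <- idx(r:(r + k - 1L), c:(c + k - 1L)); dirs <- c(dirs, "diagonal-down")
  }
  for (r in k:size) for (c in seq_len(size - k + 1L)) {
    lines[[length(lines) + 1L]] <- idx(r:(r - k + 1L), c:(c + k - 1L)); dirs <- c(dirs, "diagonal-up")
  }
  L <- length(lines)
  line_mat <- do.call(rbind, lines)             # L x k cell indices
  ncell <- size * size
  inc <- matrix(0, ncell, L)                    # cell x line incidence
  for (j in seq_len(L)) inc[line_mat[j, ], j] <- 1
  cell2lines <- lapply(seq_len(ncell), function(i) which(inc[i, ] > 0))
  ## Moore (8-square) neighbourhood adjacency for the density strategy
  rows <- ((seq_len(ncell) - 1L) %% size) + 1L
  cols <- ((seq_len(ncell) - 1L) %/% size) + 1L
  adj <- matrix(0, ncell, ncell)
  for (i in seq_len(ncell)) {
    dr <- abs(rows - rows[i]); dc <- abs(cols - cols[i])
    nb <- which(dr <= 1 & dc <= 1 & (dr + dc) > 0)
    adj[i, nb] <- 1
  }
  g <- list(size = size, k = k, ncell = ncell, line_mat = line_mat,
            n_lines = L, dirs = dirs, inc = inc, cell2lines = cell2lines,
            rows = rows, cols = cols, adj = adj)
  .geom_cache[[key]] <- g
  g
}

.cell_index <- function(size, row, col) (as.integer(col) - 1L) * size + as.integer(row)

#' Create a k-in-a-row board
#'
#' A board is a `size` x `size` grid of X / O / empty marks together with the
#' win length `k`, the player to move, and (optionally) the solution depth:
#' the number of X moves within which X can force a win.
#'
#' @param size Side length (6 and 10 are the typical study sizes).
#' @param k Marks in a row needed to win (4 on 6x6, 5 on 10x10).
#' @param x,o Data frames or matrices of 1-based `(row, col)` coordinates of
#'   the X and O marks (row 1 is the top row internally; display labels put
#'   row 1 at the bottom, chess-style).
#' @param to_move `"X"` or `"O"`.
#' @param solution_depth Optional integer: X forces a win within this many X
#'   moves.
#' @param validate If `TRUE` (default) enforce the alternation invariant
#'   (|#X - #O| <= 1), coordinate bounds and that at most one player has a
#'   completed winning path. Scoring fixtures may switch it off.
#' @return An object of class `kboard`.
#' @examples
#' b <- kboard(6, 4, x = rbind(c(3, 3)), o = rbind(c(4, 4)))
#' print(b)
#' @export
kboard <- function(size, k, x = NULL, o = NULL, to_move = "X",
                   solution_depth = NULL, validate = TRUE) {
  marks <- integer(size * size)
  put <- function(marks, coords, code) {
    if (is.null(coords) || NROW(coords) == 0) return(marks)
    coords <- as.matrix(coords)
    if (validate && (any(coords < 1) || any(coords > size)))
      stop("mark coordinates out of bounds", call. = FALSE)
    ii <- .cell_index(size, coords[, 1], coords[, 2])
    if (anyDuplicated(ii) || any(marks[ii] != EMPTY))
      stop("duplicate mark placement", call. = FALSE)
    marks[ii] <- code
    marks
  }
  marks <- put(marks, x, X)
  marks <- put(marks, o, O)
  b <- structure(list(size = as.integer(size), k = as.integer(k),
                      marks = marks, to_move = .player_code(to_move),
                      solution_depth = if (is.null(solution_depth)) NULL else as.integer(solution_depth)),
                 class = "kboard")
  if (validate) validate_board(b)
  b
}

#' Validate a board's structural invariants
#'
#' Checks alternation (|#X - #O| <= 1) and that at most one player has a
#' completed winning path.
#'
#' @param board A `kboard`.
#' @return The board, invisibly; errors on violation.
#' @export
validate_board <- function(board) {
  nx <- sum(board$marks == X); no <- sum(board$marks == O)
  if (abs(nx - no) > 1L)
    stop("alternation violated: |#X - #O| must be <= 1", call. = FALSE)
  wx <- !is.null(.winning_line(board$marks, board_geometry(board$size, board$k), X))
  wo <- !is.null(.winning_line(board$marks, board_geometry(board$size, board$k), O))
  if (wx && wo)
    stop("both players have a completed winning path", call. = FALSE)
  invisible(board)
}

.board_geom <- function(board) board_geometry(board$size, board$k)

#' @export
print.kboard <- function(x, ...) {
  size <- x$size
  ch <- c(".", "X", "O")[x$marks + 1L]
  m <- matrix(ch, size, size)
  cat(sprintf("%dx%d board, %d in a row, %s to move%s\n", size, size, x$k,
              .player_char(x$to_move),
              if (!is.null(x$solution_depth))
                sprintf(", X wins within %d", x$solution_depth) else ""))
  for (r in seq_len(size))
    cat(sprintf("%2d ", size - r + 1L), paste(m[r, ], collapse = " "), "\n", sep = "")
  cat("   ", paste(letters[seq_len(size)], collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Convert between internal coordinates and display labels
#'
#' Labels are chess-like: a column letter (`a` = leftmost) followed by a row
#' number with row 1 at the *bottom* edge. The internal representation is
#' 1-based `(row, col)` with row 1 at the top; this pair of functions is the
#' single place where the orientation is fixed.
#'
#' @param size Board side length.
#' @param row,col 1-based internal coordinates (row 1 = top).
#' @param label Character label such as `"f3"`.
#' @return `square_label()` returns a character vector; `parse_square()` a
#'   matrix with columns `row`, `col`.
#' @examples
#' square_label(6, 6, 6)        # bottom-right corner -> "f1"
#' parse_square(6, "f1")
#' @export
square_label <- function(size, row, col) {
  paste0(letters[col], size - row + 1L)
}

#' @rdname square_label
#' @export
parse_square <- function(size, label) {
  col <- match(substr(label, 1, 1), letters)
  row <- size - as.integer(substring(label, 2)) + 1L
  cbind(row = row, col = col)
}

#' Legal moves on a board
#'
#' @param board A `kboard`.
#' @return A tibble with one row per empty square: `row`, `col`, `label`.
#' @examples
#' nrow(legal_moves(kboard(6, 4)))  # 36
#' @export
legal_moves <- function(board) {
  g <- .board_geom(board)
  i <- which(board$marks == EMPTY)
  tibble::tibble(row = g$rows[i], col = g$cols[i],
                 label = square_label(board$size, g$rows[i], g$cols[i]))
}

#' Place a mark on a board
#'
#' @param board A `kboard`.
#' @param row,col Square to mark (must be empty).
#' @param player `"X"`, `"O"`, or `NULL` to use the player to move.
#' @return A new `kboard` with the mark placed and `to_move` flipped when the
#'   mover was the player to move.
#' @export
place_mark <- function(board, row, col, player = NULL) {
  p <- if (is.null(player)) board$to_move else .player_code(player)
  i <- .cell_index(board$size, row, col)
  if (row < 1 || row > board$size || col < 1 || col > board$size)
    stop("square off board", call. = FALSE)
  if (board$marks[i] != EMPTY) stop("square already occupied", call. = FALSE)
  board$marks[i] <- p
  if (p == board$to_move) board$to_move <- .other(p)
  board
}

## first completed line for `player` in canonical scan order, or NULL
.winning_line <- function(marks, g, player) {
  cnt <- rowSums(matrix(marks[g$line_mat] == player, nrow = g$n_lines))
  j <- which(cnt == g$k)
  if (!length(j)) NULL else j[1L]
}

.line_tibble <- function(g, j, marks, owner_code) {
  cells <- g$line_mat[j, ]
  tibble::tibble(
    direction = g$dirs[j],
    squares = list(tibble::tibble(row = g$rows[cells], col = g$cols[cells])),
    owner = .player_char(owner_code),
    count = sum(marks[cells] == owner_code)
  )
}

#' Detect a completed winning path
#'
#' Returns the first completed path for `player` in the canonical scan order
#' (horizontal, vertical, diagonal-down, diagonal-up, top-left first), or
#' `NULL` if none exists.
#'
#' @param board A `kboard`.
#' @param player `"X"` or `"O"`.
#' @return One-row tibble (`direction`, `squares` list-column, `owner`,
#'   `count`) or `NULL`.
#' @export
detect_win <- function(board, player) {
  g <- .board_geom(board)
  p <- .player_code(player)
  j <- .winning_line(board$marks, g, p)
  if (is.null(j)) return(NULL)
  .line_tibble(g, j, board$marks, p)
}

#' Is the board terminal (someone won, or full)?
#' @param board A `kboard`.
#' @return Logical scalar.
#' @export
is_terminal <- function(board) {
  g <- .board_geom(board)
  !is.null(.winning_line(board$marks, g, X)) ||
    !is.null(.winning_line(board$marks, g, O)) ||
    all(board$marks != EMPTY)
}

## apply one of the 8 symmetries of the square to a board (used in tests and
## the symmetry invariants); sym in 0:7 = rotations 0..3 x optional transpose
#' @keywords internal
transform_board <- function(board, sym) {
  m <- matrix(board$marks, board$size, board$size)
  if (sym >= 4L) m <- t(m)
  for (i in seq_len(sym %% 4L)) m <- t(apply(m, 2L, rev))
  board$marks <- as.integer(m)
  board
}

#' @keywords internal
transform_square <- function(size, row, col, sym) {
  if (sym >= 4L) { tmp <- row; row <- col; col <- tmp }
  for (i in seq_len(sym %% 4L)) { tmp <- row; row <- col; col <- size - tmp + 1L }
  c(row = row, col = col)
}
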