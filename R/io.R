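## Canonical JSON interchange for boards and session logs. Coordinates in
## JSON are 0-based [row, col] pairs (row 0 = top row); the R side is
## 1-based. Round-trips are exact.

#' Read and write board JSON
#'
#' The canonical board format is
#' `{"size": int, "k": int, "to_move": "X"|"O", "solution_depth": int|null,
#'  "x": [[row,col],...], "o": [[row,col],...]}` with 0-based coordinates.
#'
#' @param board A `kboard`.
#' @param path File path.
#' @return `read_board()` returns a `kboard`; `write_board()` the path,
#'   invisibly.
#' @export
write_board <- function(board, path) {
  g <- .board_geom(board)
  coords <- function(code) {
    i <- which(board$marks == code)
    if (!length(i)) return(list())
    unname(lapply(i, function(j) c(g$rows[j] - 1L, g$cols[j] - 1L)))
  }
  obj <- list(size = board$size, k = board$k,
              to_move = .player_char(board$to_move),
              solution_depth = board$solution_depth,
              x = coords(X), o = coords(O))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_board
#' @export
read_board <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(v) {
    if (is.null(v) || length(v) == 0) return(NULL)
    m <- if (is.matrix(v)) v else matrix(unlist(v), ncol = 2, byrow = TRUE)
    m + 1L
  }
  kboard(obj$size, obj$k, x = to_mat(obj$x), o = to_mat(obj$o),
         to_move = obj$to_move,
         solution_depth = if (is.null(obj$solution_depth)) NULL else obj$solution_depth)
}

.session_to_list <- function(s) {
  ev <- s$events
  list(id = s$id, board_id = s$board_id, condition = s$condition,
       board = list(size = s$board$size, k = s$board$k,
                    to_move = .player_char(s$board$to_move),
                    solution_depth = s$board$solution_depth,
                    x = .coord_list(s$board, X), o = .coord_list(s$board, O)),
       events = unname(purrr::pmap(ev, function(player, action, row, col, t, ...) {
         e <- list(player = player, action = action, t = t)
         if (action == "place") e$square <- c(row - 1L, col - 1L)
         e
       })),
       answer = if (is.null(s$answer)) NULL else c(s$answer[1] - 1L, s$answer[2] - 1L),
       solved = s$solved)
}

.coord_list <- function(board, code) {
  g <- .board_geom(board)
  i <- which(board$marks == code)
  if (!length(i)) return(list())
  unname(lapply(i, function(j) c(g$rows[j] - 1L, g$cols[j] - 1L)))
}

.session_from_list <- function(obj) {
  to_mat <- function(v) {
    if (is.null(v) || length(v) == 0) return(NULL)
    matrix(unlist(v), ncol = 2, byrow = TRUE) + 1L
  }
  b <- kboard(obj$board$size, obj$board$k, x = to_mat(obj$board$x),
              o = to_mat(obj$board$o), to_move = obj$board$to_move,
              solution_depth = obj$board$solution_depth)
  ev <- purrr::map_dfr(obj$events, function(e) {
    tibble::tibble(player = e$player, action = e$action,
                   row = if (is.null(e$square)) NA_integer_ else as.integer(e$square[[1]]) + 1L,
                   col = if (is.null(e$square)) NA_integer_ else as.integer(e$square[[2]]) + 1L,
                   t = e$t)
  })
  if (!length(obj$events))
    ev <- tibble::tibble(player = character(), action = character(),
                         row = integer(), col = integer(), t = numeric())
  kinarow_session(b, ev,
                  answer = if (is.null(obj$answer)) NULL else as.integer(unlist(obj$answer)) + 1L,
                  board_id = obj$board_id, condition = obj$condition,
                  solved = if (is.null(obj$solved)) NA else obj$solved,
                  id = if (is.null(obj$id)) NA_character_ else obj$id)
}

#' Read and write session-log JSON
#'
#' Sessions are stored as a JSON array of
#' `{"id", "board_id", "condition", "board", "events":
#'  [{"player","action","square","t"}...], "answer", "solved"}` objects,
#' with 0-based `[row, col]` squares; `undo`/`reset` events carry no square.
#'
#' @param sessions A list of `kinarow_session` objects (or one).
#' @param path File path.
#' @return `read_sessions()` returns a list of sessions; `write_sessions()`
#'   the path, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "kinarow_session")) sessions <- list(sessions)
  jsonlite::write_json(lapply(sessions, .session_to_list), path,
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, .session_from_list)
}
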