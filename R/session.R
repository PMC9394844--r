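## Session logs: ordered place/undo/reset events from a (real or simulated)
## participant searching a board with the sandbox, plus the submitted answer.

#' Create a session log
#'
#' A session records a participant's ordered sandbox events on one board:
#' `place` events carry a player and a square, `undo` removes the most recent
#' placement, `reset` restores the initial position. Undo and reset are not
#' modeled as choices; they only change the board state that subsequent moves
#' are evaluated on.
#'
#' @param board The initial `kboard`.
#' @param events Tibble with columns `player` ("X"/"O"), `action`
#'   ("place"/"undo"/"reset"), `row`, `col` (NA for undo/reset), `t`
#'   (seconds since session start).
#' @param answer Length-2 `(row, col)`: the submitted winning move.
#' @param board_id Identifier of the board.
#' @param condition `"full"` or `"truncated"`.
#' @param solved Logical: was the answer a correct winning move?
#' @param id Participant identifier.
#' @return An object of class `kinarow_session`.
#' @export
kinarow_session <- function(board, events, answer = NULL, board_id = "board",
                            condition = "full", solved = NA, id = NA_character_) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("player", "action", "row", "col", "t") %in% names(events)))
  s <- structure(list(id = id, board_id = board_id, condition = condition,
                      board = board, events = events, answer = answer,
                      solved = solved),
                 class = "kinarow_session")
  replay_session(s)  # errors if the log is not replayable
  s
}

#' @export
print.kinarow_session <- function(x, ...) {
  cat(sprintf("session %s on %s (%s): %d events, answer %s, solved: %s\n",
              x$id, x$board_id, x$condition, nrow(x$events),
              if (is.null(x$answer)) "none"
              else square_label(x$board$size, x$answer[1], x$answer[2]),
              x$solved))
  invisible(x)
}

## internal replay: returns for each *place* event the pre-move state, mover,
## move cell and the anchoring last-X cell (NA if the mover has no X mark on
## the current stack). Deterministic and side-effect free.
.replay <- function(session) {
  b0 <- session$board
  size <- b0$size
  marks <- b0$marks
  stack <- list()  # placements currently on the board: list of (cell, player)
  recs <- list()
  ev <- session$events
  for (i in seq_len(nrow(ev))) {
    act <- ev$action[i]
    if (act == "place") {
      p <- .player_code(ev$player[i])
      cell <- .cell_index(size, ev$row[i], ev$col[i])
      if (marks[cell] != EMPTY)
        stop("unreplayable log: placement on occupied square", call. = FALSE)
      last_x <- NA_integer_
      for (s in rev(stack)) if (s[2] == X) { last_x <- s[1]; break }
      recs[[length(recs) + 1L]] <-
        list(marks = marks, mover = p, cell = cell, last_x = last_x)
      marks[cell] <- p
      stack[[length(stack) + 1L]] <- c(cell, p)
    } else if (act == "undo") {
      if (length(stack)) {
        last <- stack[[length(stack)]]
        marks[last[1]] <- EMPTY
        stack[[length(stack)]] <- NULL
      }
    } else if (act == "reset") {
      marks <- b0$marks
      stack <- list()
    } else stop("unknown action: ", act, call. = FALSE)
  }
  list(records = recs, final_marks = marks)
}

#' Replay a session's events
#'
#' Replays the ordered events from the initial board and returns the final
#' board state. Replay is deterministic and side-effect free; an event that
#' would produce an illegal state (placing on an occupied square) errors.
#'
#' @param session A `kinarow_session`.
#' @return The final `kboard`.
#' @export
replay_session <- function(session) {
  rp <- .replay(session)
  b <- session$board
  b$marks <- rp$final_marks
  b
}

#' Per-move states of a session
#'
#' One row per `place` event with the board state it was evaluated on.
#'
#' @param session A `kinarow_session`.
#' @return Tibble: `move_no`, `player`, `row`, `col`, `n_legal`,
#'   `last_x_row`, `last_x_col` (NA when the mover had no X mark on the
#'   board), and a `board` list-column of pre-move `kboard`s.
#' @export
session_states <- function(session) {
  rp <- .replay(session)$records
  g <- .board_geom(session$board)
  purrr::imap_dfr(rp, function(r, i) {
    b <- session$board; b$marks <- r$marks; b$to_move <- r$mover
    tibble::tibble(move_no = i, player = .player_char(r$mover),
                   row = g$rows[r$cell], col = g$cols[r$cell],
                   n_legal = sum(r$marks == EMPTY),
                   last_x_row = if (is.na(r$last_x)) NA_integer_ else g$rows[r$last_x],
                   last_x_col = if (is.na(r$last_x)) NA_integer_ else g$cols[r$last_x],
                   board = list(b))
  })
}
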