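## Synthetic data: forced-win end-game boards from noisy self-play, board
## truncation, and simulated participant cohorts realizing the generative
## model the choice-model fitting assumes.

#' Generate a verified forced-win end-game board
#'
#' A search agent plays against itself with score noise; the intermediate
#' positions with X to move are scanned with the exact solver for a state
#' from which X forces a win within exactly `target_depth` X moves (a win
#' exists at `target_depth`, none at `target_depth - 1`). Every emitted
#' board is reachable, alternation-valid and non-terminal by construction,
#' and carries its verified `solution_depth` plus the list of optimal first
#' moves in attribute `"optimal_moves"`.
#'
#' @param size Board side (6 or 10 typical).
#' @param k Win length (4 on 6x6, 5 on 10x10).
#' @param target_depth Required solution depth in X moves (3, 4 or 5).
#' @param seed RNG seed; generation is deterministic given it.
#' @param noise_sigma Score noise of the self-play agents.
#' @param min_pieces Minimum number of marks on an emitted board.
#' @param max_games Generation budget: self-play games to try before failing.
#' @param solver_budget Node budget per exact-verification probe; a
#'   candidate state whose proof exceeds it is skipped (never emitted
#'   unverified). The positive check gets ten times this budget.
#' @param optimal_moves Also enumerate and attach the optimal first moves
#'   (needed for truncation; skip to save time on large boards).
#' @return A `kboard` (X to move) with `solution_depth = target_depth`.
#' @export
generate_endgame_board <- function(size = 6, k = 4, target_depth = 4,
                                   seed = 1, noise_sigma = 1,
                                   min_pieces = 2 * (target_depth - 1),
                                   max_games = 500, solver_budget = 20000,
                                   optimal_moves = TRUE) {
  stopifnot(target_depth >= 2)
  set.seed(seed)
  g <- board_geometry(size, k)
  params <- scoring_params(noise_sigma = noise_sigma)
  empty_board <- kboard(size, k)
  ## budget-capped exact check: TRUE/FALSE when the proof completed, NA when
  ## the node budget ran out (the state is then simply not used)
  check <- function(b, d, budget) {
    memo <- new.env(parent = emptyenv())
    memo$.budget <- budget
    tryCatch(forced_win(b, d, memo = memo),
             solver_budget_exhausted = function(e) NA)
  }
  for (game in seq_len(max_games)) {
    traj <- simulate_game(empty_board, "interaction", Inf, params,
                          max_plies = size * size)
    ## replay, collecting candidate states with X to move (even piece count)
    marks <- empty_board$marks
    states <- list()
    for (i in seq_len(nrow(traj))) {
      cell <- .cell_index(size, traj$row[i], traj$col[i])
      marks[cell] <- .player_code(traj$player[i])
      if (i < nrow(traj) && traj$player[i] == "O" && i >= min_pieces)
        states[[length(states) + 1L]] <- marks
    }
    ## walk backwards from the end of the game: the forced depth (weakly)
    ## grows as move pairs are removed, so skip states still forced at
    ## target_depth - 1 and probe the first ones past that for an exact hit
    probes <- 0L
    for (m in rev(states)) {
      b <- empty_board; b$marks <- m; b$to_move <- X
      if (is_terminal(b)) next
      ## threat-potential prefilter: an exact-depth forced win needs raw
      ## material — at least two open X lines close to completion
      cnt <- .line_counts(m, g)
      if (sum(cnt$o == 0 & cnt$x >= k - 2L) < 2L) next
      f_prev <- check(b, target_depth - 1L, solver_budget)
      if (!isFALSE(f_prev)) next
      probes <- probes + 1L
      f_target <- check(b, target_depth, 10L * solver_budget)
      if (isTRUE(f_target)) {
        b$solution_depth <- as.integer(target_depth)
        validate_board(b)
        if (optimal_moves)
          attr(b, "optimal_moves") <- optimal_first_moves(b, target_depth)
        return(b)
      }
      if (probes >= 2L) break  # earlier states are weaker still; next game
    }
  }
  stop("generation budget exhausted: no board found in ", max_games,
       " self-play games", call. = FALSE)
}

#' Truncate a board by one optimal X move and O reply
#'
#' Applies one verified-optimal X move — the one an interaction-scoring
#' searcher is most likely to play, so the truncated prefix is a
#' continuation real sessions reach — and the most resistant O reply (the
#' highest-scoring reply that does not let X win faster than `depth - 1`),
#' producing the truncated condition: the same position one move pair
#' later, with a verified forced win within `target_depth - 1`. Remaining
#' ties break by the canonical scan order.
#'
#' @param board A verified board with `solution_depth >= 2` (from
#'   [generate_endgame_board()]).
#' @return A `kboard` with `solution_depth` one less; attributes
#'   `"x_move"` and `"o_move"` record the applied pair and
#'   `"optimal_moves"` the truncated board's optimal first moves.
#' @export
truncate_board <- function(board) {
  d <- board$solution_depth
  stopifnot(!is.null(d), d >= 2)
  g <- .board_geom(board)
  opt <- attr(board, "optimal_moves")
  if (is.null(opt)) opt <- optimal_first_moves(board, d)
  if (!nrow(opt)) stop("board has no optimal first move", call. = FALSE)
  ## modal optimal move: the verified winning move an interaction-scoring
  ## searcher is most likely to play (ties by scan order), so that the
  ## truncated prefix is a continuation real sessions actually reach
  sc_x <- .combined_scores(board$marks, g, X, "interaction", scoring_params())
  oc <- .cell_index(board$size, opt$row, opt$col)
  oi <- order(-sc_x[oc], oc)
  xm <- c(opt$row[oi[1]], opt$col[oi[1]])
  b1 <- place_mark(board, xm[1], xm[2], "X")
  ## O replies: among the maximally resistant ones (those that do not let X
  ## win faster than d - 1), the one an interaction-scoring O is most likely
  ## to play (ties by scan order)
  empties <- which(b1$marks == EMPTY)
  sc_o <- .combined_scores(b1$marks, g, O, "interaction", scoring_params())
  cand_o <- integer()
  for (cell in empties[order(-sc_o[empties], empties)]) {
    b2 <- b1; b2$marks[cell] <- O; b2$to_move <- X
    if (!is.null(.winning_line(b2$marks, g, O))) next
    if (d >= 3 && forced_win(b2, d - 2L)) next  # X would win faster
    cand_o <- cell; break
  }
  o_cell <- if (length(cand_o)) cand_o else NA_integer_
  if (is.na(o_cell)) o_cell <- empties[1]  # every reply loses fast; take first
  b2 <- b1; b2$marks[o_cell] <- O; b2$to_move <- X
  b2$solution_depth <- d - 1L
  if (!forced_win(b2, d - 1L))
    stop("truncation verification failed", call. = FALSE)
  attr(b2, "x_move") <- xm
  attr(b2, "o_move") <- c(g$rows[o_cell], g$cols[o_cell])
  attr(b2, "optimal_moves") <- optimal_first_moves(b2, d - 1L)
  b2
}

#' Simulate a participant session
#'
#' An agent realizing the generative model the choice model assumes:
#' alternating X/O placements sampled from [move_probabilities()] under the
#' given strategy, shutter and opponent weight, mixed with a lapse — with
#' probability `epsilon` the move is uniform over legal squares. The shutter
#' anchors on the agent's most recent X placement (the first X move is
#' shutter-free). On reaching a terminal state the agent resets the sandbox
#' and keeps exploring; the session ends after `max_moves` placements. The
#' submitted answer is the agent's first X move.
#'
#' @param board Starting `kboard`.
#' @param strategy One of [strategy_names()].
#' @param shutter Shutter size (`Inf` = off).
#' @param epsilon Lapse rate.
#' @param w Opponent weight.
#' @param max_moves Maximum placements.
#' @param seed Optional RNG seed.
#' @param reset_rate Probability, per turn, of a reset event (returning the
#'   sandbox to the initial position) before the move.
#' @param id Participant id stored in the session.
#' @param adjudicate Verify the submitted answer with the exact solver and
#'   record it in `solved` (an exact search per session; off by default,
#'   `solved` is then `NA`).
#' @return A `kinarow_session` (timestamps are synthetic monotone counters).
#' @export
simulate_participant <- function(board, strategy = "interaction",
                                 shutter = Inf, epsilon = 0, w = 0.5,
                                 max_moves = 40, seed = NULL, reset_rate = 0,
                                 id = NA_character_, adjudicate = FALSE) {
  stopifnot(max_moves >= 1, epsilon >= 0, epsilon <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- .board_geom(board)
  params <- scoring_params(opponent_weight = w)
  marks <- board$marks
  to_move <- board$to_move
  last_x <- NA_integer_
  first_x <- NULL
  ev_player <- character(); ev_action <- character()
  ev_row <- integer(); ev_col <- integer()
  tcount <- 0L
  push <- function(action, row, col) {
    ev_player[[length(ev_player) + 1L]] <<- .player_char(to_move)
    ev_action[[length(ev_action) + 1L]] <<- action
    ev_row[[length(ev_row) + 1L]] <<- row
    ev_col[[length(ev_col) + 1L]] <<- col
    tcount <<- tcount + 1L
  }
  n_placed <- 0L
  while (n_placed < max_moves) {
    if (reset_rate > 0 && n_placed > 0 && stats::runif(1) < reset_rate) {
      push("reset", NA_integer_, NA_integer_)
      marks <- board$marks; to_move <- board$to_move; last_x <- NA_integer_
    }
    empties <- which(marks == EMPTY)
    if (!length(empties)) break
    if (stats::runif(1) < epsilon) {
      cell <- empties[sample.int(length(empties), 1L)]
    } else {
      mp <- .move_probs(marks, g, to_move, strategy, params, shutter, last_x)
      cell <- mp$cells[sample.int(length(mp$cells), 1L, prob = mp$prob)]
    }
    push("place", g$rows[cell], g$cols[cell])
    if (to_move == X) {
      last_x <- cell
      if (is.null(first_x)) first_x <- c(g$rows[cell], g$cols[cell])
    }
    marks[cell] <- to_move
    n_placed <- n_placed + 1L
    js <- g$cell2lines[[cell]]
    cnt <- rowSums(matrix(marks[g$line_mat[js, , drop = FALSE]] == to_move,
                          nrow = length(js)))
    if (any(cnt == g$k) || !any(marks == EMPTY)) {
      ## a terminal line ends this exploration; the agent resets the sandbox
      ## and keeps searching until its move budget is spent
      if (n_placed >= max_moves) break
      push("reset", NA_integer_, NA_integer_)
      marks <- board$marks; to_move <- board$to_move; last_x <- NA_integer_
      next
    }
    to_move <- .other(to_move)
  }
  ev <- tibble::tibble(player = ev_player, action = ev_action,
                       row = ev_row, col = ev_col,
                       t = seq_along(ev_player))
  solved <- if (adjudicate && !is.null(board$solution_depth) && !is.null(first_x))
    move_forces_win(board, first_x[1], first_x[2]) else NA
  kinarow_session(board, ev, answer = first_x,
                  board_id = if (is.null(attr(board, "id"))) "board" else attr(board, "id"),
                  condition = if (is.null(attr(board, "x_move"))) "full" else "truncated",
                  solved = solved, id = id)
}

#' Cohort specification
#'
#' @param n_participants Cohort size.
#' @param mixture Tibble with columns `strategy`, `shutter`, `epsilon`, `w`,
#'   `weight` (weights sum to 1): the population mixture of agent
#'   parameters. The default mixture follows the fitted population shares of
#'   the five strategies (density 8%, linear 6%, non-linear 28%, interaction
#'   35%, forcing 23%).
#' @param max_moves Session length (placements per session).
#' @param seed RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 100,
                        mixture = NULL, max_moves = 40, seed = 1) {
  if (is.null(mixture))
    mixture <- tibble::tibble(
      strategy = strategy_names(),
      shutter = Inf, epsilon = 0.02, w = 0.5,
      weight = c(0.08, 0.06, 0.28, 0.35, 0.23))
  stopifnot(abs(sum(mixture$weight) - 1) < 1e-8, n_participants >= 1)
  structure(list(n_participants = n_participants, mixture = mixture,
                 max_moves = max_moves, seed = seed), class = "cohort_spec")
}

#' Generate a simulated cohort
#'
#' Draws participants from the mixture and assigns each one board
#' (between-subject: one session per participant, boards cycled through the
#' supplied list).
#'
#' @param boards A list of `kboard`s (full and/or truncated).
#' @param spec A [cohort_spec()].
#' @return A list: `sessions` (list of `kinarow_session`) and `participants`
#'   (tibble of the true generating parameters per participant).
#' @export
generate_cohort <- function(boards, spec = cohort_spec()) {
  set.seed(spec$seed)
  if (is.null(names(boards)))
    names(boards) <- paste0("board", seq_along(boards))
  comp <- sample.int(nrow(spec$mixture), spec$n_participants, replace = TRUE,
                     prob = spec$mixture$weight)
  board_ix <- rep_len(seq_along(boards), spec$n_participants)
  sessions <- vector("list", spec$n_participants)
  truth <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    mx <- spec$mixture[comp[i], ]
    b <- boards[[board_ix[i]]]
    attr(b, "id") <- names(boards)[board_ix[i]]
    s <- simulate_participant(b, mx$strategy, mx$shutter, mx$epsilon, mx$w,
                              max_moves = spec$max_moves,
                              id = sprintf("p%04d", i))
    s$board_id <- names(boards)[board_ix[i]]
    sessions[[i]] <- s
    truth[[i]] <- tibble::tibble(id = s$id, board_id = s$board_id,
                                 strategy = mx$strategy, shutter = mx$shutter,
                                 epsilon = mx$epsilon, w = mx$w)
  }
  list(sessions = sessions, participants = dplyr::bind_rows(truth))
}

#' Simulate a participant who searches before each move
#'
#' Unlike [simulate_participant()], whose agent samples moves in proportion
#' to the scores (the generative model the likelihood assumes), this agent
#' runs a noisy depth-limited stochastic search for every placement and
#' plays its chosen move — the internal-search searcher: concentrated near
#' the argmax of the (noisy, shutter-restricted) scores. At depth 1 with
#' full branching it is a noisy-greedy chooser. The shutter anchors on the
#' agent's most recent X placement of the trajectory.
#'
#' @param board Starting `kboard`.
#' @param strategy One of [strategy_names()].
#' @param shutter Shutter size (`Inf` = off).
#' @param noise_sigma Score noise of the internal search.
#' @param depth Internal search depth in plies (1-3 typical).
#' @param branching Children sampled per node (`Inf` = all admissible).
#' @param max_moves Number of placements; terminal states reset the sandbox
#'   as in [simulate_participant()].
#' @param seed Optional RNG seed.
#' @param id Participant id.
#' @return A `kinarow_session`.
#' @export
simulate_search_participant <- function(board, strategy = "interaction",
                                        shutter = Inf, noise_sigma = 1,
                                        depth = 1, branching = Inf,
                                        max_moves = 3, seed = NULL,
                                        id = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  g <- .board_geom(board)
  marks <- board$marks
  to_move <- board$to_move
  last_x <- NULL
  first_x <- NULL
  ev_player <- character(); ev_action <- character()
  ev_row <- integer(); ev_col <- integer()
  n_placed <- 0L
  while (n_placed < max_moves) {
    if (!any(marks == EMPTY)) break
    b <- board; b$marks <- marks; b$to_move <- to_move
    cfg <- search_config(depth = depth, branching = branching,
                         noise_sigma = noise_sigma, shutter = shutter)
    r <- stochastic_shutter_search(b, strategy, cfg, adjudicate = FALSE,
                                   last_x_move = last_x)
    cell <- .cell_index(board$size, r$move[1], r$move[2])
    ev_player <- c(ev_player, .player_char(to_move))
    ev_action <- c(ev_action, "place")
    ev_row <- c(ev_row, g$rows[cell]); ev_col <- c(ev_col, g$cols[cell])
    if (to_move == X) {
      last_x <- c(g$rows[cell], g$cols[cell])
      if (is.null(first_x)) first_x <- last_x
    }
    marks[cell] <- to_move
    n_placed <- n_placed + 1L
    js <- g$cell2lines[[cell]]
    cnt <- rowSums(matrix(marks[g$line_mat[js, , drop = FALSE]] == to_move,
                          nrow = length(js)))
    if (any(cnt == g$k) || !any(marks == EMPTY)) {
      if (n_placed >= max_moves) break
      ev_player <- c(ev_player, .player_char(to_move))
      ev_action <- c(ev_action, "reset")
      ev_row <- c(ev_row, NA_integer_); ev_col <- c(ev_col, NA_integer_)
      marks <- board$marks; to_move <- board$to_move; last_x <- NULL
      next
    }
    to_move <- .other(to_move)
  }
  ev <- tibble::tibble(player = ev_player, action = ev_action,
                       row = ev_row, col = ev_col, t = seq_along(ev_player))
  kinarow_session(board, ev, answer = first_x,
                  board_id = if (is.null(attr(board, "id"))) "board" else attr(board, "id"),
                  condition = if (is.null(attr(board, "x_move"))) "full" else "truncated",
                  solved = NA, id = id)
}
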