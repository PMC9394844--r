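## Stochastic shutter-restricted alpha-beta and the simulation machinery
## built on it (self-play trajectories, parameter sweeps).

#' Search configuration
#'
#' The coordinates of the accuracy-versus-computation sweeps.
#'
#' @param depth Plies of lookahead; `NULL` uses `2 * solution_depth - 1`.
#' @param branching Children sampled per node (3-10 in the sweeps).
#' @param move_limit Maximum score evaluations before the search aborts
#'   (30-200 in the sweeps; `Inf` = unlimited).
#' @param noise_sigma SD of Gaussian score noise (0-2.5).
#' @param shutter Shutter size: 0, 0.5, 1, 2, or `Inf` for off.
#' @param seed RNG seed (`NULL` = leave the RNG stream alone).
#' @return A list of class `search_config`.
#' @export
search_config <- function(depth = NULL, branching = 5, move_limit = Inf,
                          noise_sigma = 0, shutter = Inf, seed = NULL) {
  stopifnot(is.null(depth) || depth >= 1, branching >= 1, move_limit >= 1,
            noise_sigma >= 0, shutter >= 0)
  structure(list(depth = depth, branching = branching, move_limit = move_limit,
                 noise_sigma = noise_sigma, shutter = shutter, seed = seed),
            class = "search_config")
}

## stochastic negamax. st: environment carrying counter n, limit, aborted.
## last_x: cell index of the most recent X move on the search path (NA at the
## root: the shutter anchors only on moves made within the search).
.stoch_ab <- function(marks, g, to_move, depth, alpha, beta, ply, strategy,
                      params, cfg, st, last_move, last_x) {
  if (!is.na(last_move)) {
    prev <- .other(to_move)
    js <- g$cell2lines[[last_move]]
    cnt <- rowSums(matrix(marks[g$line_mat[js, , drop = FALSE]] == prev,
                          nrow = length(js)))
    if (any(cnt == g$k)) return(-(params$win_score - ply))
  }
  empties <- which(marks == EMPTY)
  if (!length(empties)) return(0)
  ## immediate-win shortcut: the fastest win dominates and costs no
  ## evaluations (the completing move is recognized, not scored)
  cnt <- .line_counts(marks, g)
  own <- if (to_move == X) cnt$x else cnt$o
  opp <- if (to_move == X) cnt$o else cnt$x
  hot <- opp == 0 & own == g$k - 1L
  if (depth >= 1L && any(hot)) {
    if (ply == 0L) {
      wc <- unique(as.vector(g$line_mat[hot, , drop = FALSE]))
      st$best_cell <- wc[marks[wc] == EMPTY][1]
    }
    return(params$win_score - ply - 1)
  }
  ## shutter admissibility relative to the last X move of the search path;
  ## this applies to O nodes too (the source of O-blindness). When the
  ## shutter admits no square, fall back to all legal moves.
  if (!is.na(last_x) && is.finite(cfg$shutter)) {
    dmap <- .shutter_dist_map(marks, g, last_x)
    wt <- if (is.null(dmap)) rep(1, length(empties))
          else shutter_weight(dmap[empties], cfg$shutter)
    if (!any(wt > 0)) wt <- rep(1, length(empties))
  } else wt <- rep(1, length(empties))
  adm <- which(wt > 0)
  budget <- st$limit - st$n
  if (length(adm) > budget) {
    if (ply > 0L) { st$aborted <- TRUE; return(0) }
    adm <- adm[seq_len(budget)]  # root is always allowed a (truncated) look
  }
  cells <- empties[adm]
  sc <- .combined_scores(marks, g, to_move, strategy, params)[cells]
  st$n <- st$n + length(cells)
  if (depth <= 0L) return(max(sc))
  ## sample branching children without replacement, probability proportional
  ## to the shutter-weighted non-negative scores (uniform if all are zero)
  pr <- pmax(sc, 0) * wt[adm]
  n_pick <- min(cfg$branching, length(cells))
  pos <- which(pr > 0)
  pick <- if (length(cells) == 1L) {
    1L
  } else if (length(pos) >= n_pick) {
    if (length(pos) == 1L) pos else pos[sample.int(length(pos), n_pick, prob = pr[pos])]
  } else {
    ## fewer positive-score squares than the branching factor: take them all
    ## and fill the remainder uniformly from the zero-score admissible ones
    zero <- setdiff(seq_along(cells), pos)
    extra <- if (length(zero) == 1L) zero else
      zero[sample.int(length(zero), min(n_pick - length(pos), length(zero)))]
    c(pos, extra)
  }
  best <- -Inf
  first <- TRUE
  for (j in pick) {
    if (st$aborted) break
    cell <- cells[j]
    ## horizon moves are worth their own score (wins were handled by the
    ## shortcut; a board-filling move is a draw)
    v <- if (depth == 1L) {
      if (length(empties) == 1L) 0 else sc[j]
    } else {
      m2 <- marks; m2[cell] <- to_move
      -.stoch_ab(m2, g, .other(to_move), depth - 1L, -beta, -alpha, ply + 1L,
                 strategy, params, cfg, st, cell,
                 if (to_move == X) cell else last_x)
    }
    if (first || v > best) {
      first <- FALSE
      best <- v
      if (ply == 0L) st$best_cell <- cell
    }
    if (v > alpha) alpha <- v
    if (alpha >= beta) break
  }
  best
}

#' Stochastic shutter-restricted alpha-beta search
#'
#' A non-deterministic variant of alpha-beta: at each node the admissible
#' children are the shutter-weighted squares (relative to the last X move of
#' the search path; the shutter also filters O's replies, producing the
#' characteristic blindness to the opponent), scores receive fresh
#' `N(0, sigma)` noise, and `branching` children are sampled without
#' replacement with probability proportional to the non-negative weighted
#' scores. The search aborts once `move_limit` score evaluations have been
#' spent and returns the best move found so far.
#'
#' @param board A non-terminal `kboard` with X to move.
#' @param strategy One of [strategy_names()].
#' @param config A [search_config()].
#' @param params A [scoring_params()]; its `noise_sigma` is overridden by the
#'   config's.
#' @param adjudicate Verify the chosen move with the exact solver (set
#'   `FALSE` when the caller adjudicates, e.g. through a cache).
#' @param last_x_move Optional `(row, col)` anchoring the shutter at the
#'   root (the searcher's previous X move outside this search); by default
#'   the shutter only engages on moves made within the search.
#' @return A `search_result` with `move`, `value`, `nodes_evaluated`
#'   (<= `move_limit`), and `found_win`: `TRUE` iff the chosen first move
#'   provably forces a win within the board's solution depth (adjudicated by
#'   the exact solver; `NA` when no solution depth is set).
#' @export
stochastic_shutter_search <- function(board, strategy = "interaction",
                                      config = search_config(),
                                      params = scoring_params(),
                                      adjudicate = TRUE,
                                      last_x_move = NULL) {
  if (is_terminal(board)) stop("board is terminal", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  depth <- config$depth
  if (is.null(depth)) {
    if (is.null(board$solution_depth))
      stop("config depth is NULL and board has no solution_depth", call. = FALSE)
    depth <- 2L * board$solution_depth - 1L
  }
  params$noise_sigma <- config$noise_sigma
  g <- .board_geom(board)
  st <- new.env(parent = emptyenv())
  st$n <- 0L; st$limit <- config$move_limit; st$aborted <- FALSE
  st$best_cell <- NA_integer_
  root_last_x <- if (is.null(last_x_move)) NA_integer_ else
    .cell_index(board$size, last_x_move[1], last_x_move[2])
  val <- .stoch_ab(board$marks, g, board$to_move, depth, -Inf, Inf, 0L,
                   strategy, params, config, st, NA_integer_, root_last_x)
  cell <- st$best_cell
  if (is.na(cell)) cell <- which(board$marks == EMPTY)[1]
  fw <- if (!adjudicate || is.null(board$solution_depth)) NA else
    move_forces_win(board, g$rows[cell], g$cols[cell], board$solution_depth)
  structure(list(move = c(row = g$rows[cell], col = g$cols[cell]),
                 label = square_label(board$size, g$rows[cell], g$cols[cell]),
                 value = val, nodes_evaluated = st$n, found_win = fw,
                 aborted = st$aborted, depth = depth),
            class = "search_result")
}

#' Simulate a self-play trajectory under a shutter
#'
#' Both sides choose one move per turn by sampling the move-probability map
#' of the strategy (with score noise), the shutter anchored on the most
#' recent X move of the trajectory — for the O mover as well, which is what
#' produces missed O wins under a narrow shutter. The trajectory is the unit
#' the missed-win accounting consumes.
#'
#' @param board Starting `kboard`.
#' @param strategy One of [strategy_names()].
#' @param shutter Shutter size (`Inf` = off).
#' @param params A [scoring_params()] (noise applies per evaluation).
#' @param max_plies Maximum number of placements.
#' @param seed Optional RNG seed.
#' @return A tibble of placements (`player`, `row`, `col`) with the starting
#'   board in attribute `"board"`.
#' @export
simulate_game <- function(board, strategy = "interaction", shutter = Inf,
                          params = scoring_params(), max_plies = 20,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- .board_geom(board)
  marks <- board$marks
  to_move <- board$to_move
  last_x <- NA_integer_
  out <- vector("list", max_plies)
  for (i in seq_len(max_plies)) {
    if (!any(marks == EMPTY)) break
    mp <- .move_probs(marks, g, to_move, strategy, params, shutter, last_x)
    cell <- mp$cells[sample.int(length(mp$cells), 1L, prob = mp$prob)]
    out[[i]] <- tibble::tibble(player = .player_char(to_move),
                               row = g$rows[cell], col = g$cols[cell])
    marks[cell] <- to_move
    if (to_move == X) last_x <- cell
    js <- g$cell2lines[[cell]]
    cnt <- rowSums(matrix(marks[g$line_mat[js, , drop = FALSE]] == to_move,
                          nrow = length(js)))
    if (any(cnt == g$k)) break
    to_move <- .other(to_move)
  }
  traj <- dplyr::bind_rows(out)
  attr(traj, "board") <- board
  traj
}

#' Sweep stochastic shutter searches over a parameter grid
#'
#' Runs [stochastic_shutter_search()] for every combination of board,
#' shutter, noise level, branching factor and move limit, `n_seeds` times
#' each, and records accuracy (`found_win`), computation
#' (`nodes_evaluated`) and trajectory-level missed wins (from a matched
#' [simulate_game()] playout).
#'
#' @param boards A list of `kboard`s with `solution_depth` set (names become
#'   board ids).
#' @param shutters,sigmas,branchings,limits Parameter menus (the study grid
#'   is shutters 0/0.5/1/2, limits 30/50/100/200, branchings 3/5/7/10,
#'   sigma 0-2.5 by 0.25).
#' @param n_seeds Repetitions per configuration.
#' @param strategy Scoring strategy used throughout.
#' @param seed Master seed; the whole sweep is reproducible given it.
#' @param playout_misses If `TRUE` (default) also simulate one playout per
#'   run for the missed-win columns.
#' @return A tibble with one row per run: `board_id`, `complexity`,
#'   `shutter`, `branching`, `limit`, `sigma`, `rep`, `found_win`,
#'   `nodes_evaluated`, `missed_x_wins`, `missed_o_wins`.
#' @export
shutter_sweep <- function(boards, shutters = c(0, 0.5, 1, 2), sigmas = c(0, 1),
                          branchings = c(3, 10), limits = c(30, 200),
                          n_seeds = 20, strategy = "interaction", seed = 1,
                          playout_misses = TRUE) {
  if (is.null(names(boards)))
    names(boards) <- paste0("board", seq_along(boards))
  set.seed(seed)
  complexity <- vapply(boards, board_complexity, numeric(1))
  grid <- tidyr::expand_grid(board_id = names(boards), shutter = shutters,
                             sigma = sigmas, branching = branchings,
                             limit = limits, rep = seq_len(n_seeds))
  ## the exact adjudication of a first move is deterministic per board:
  ## cache it so repeated runs choosing the same move verify once
  fw_cache <- new.env(parent = emptyenv())
  adjudicate <- function(board_id, b, move) {
    key <- paste0(board_id, ":", move[1], ",", move[2])
    hit <- fw_cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- move_forces_win(b, move[1], move[2], b$solution_depth)
    fw_cache[[key]] <- v
    v
  }
  res <- purrr::pmap_dfr(grid, function(board_id, shutter, sigma, branching,
                                        limit, rep) {
    b <- boards[[board_id]]
    cfg <- search_config(branching = branching, move_limit = limit,
                         noise_sigma = sigma, shutter = shutter)
    sr <- stochastic_shutter_search(b, strategy, cfg, adjudicate = FALSE)
    sr$found_win <- adjudicate(board_id, b, sr$move)
    mx <- mo <- NA_integer_
    if (playout_misses) {
      traj <- simulate_game(b, strategy, shutter,
                            scoring_params(noise_sigma = sigma),
                            max_plies = 2L * b$solution_depth)
      mw <- missed_wins(traj, b)
      mx <- mw$missed_x; mo <- mw$missed_o
    }
    tibble::tibble(board_id = board_id, complexity = complexity[[board_id]],
                   shutter = shutter, branching = branching, limit = limit,
                   sigma = sigma, rep = rep, found_win = sr$found_win,
                   nodes_evaluated = sr$nodes_evaluated,
                   missed_x_wins = mx, missed_o_wins = mo)
  })
  res
}
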