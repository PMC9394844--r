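## The five scoring strategies and their combination (opponent weighting,
## noise). All strategies score *empty* squares from the structure of the
## open winning paths through them.

#' Names of the scoring strategies
#' @return Character vector `c("density", "linear", "nonlinear",
#'   "interaction", "forcing")`.
#' @export
strategy_names <- function() c("density", "linear", "nonlinear", "interaction", "forcing")

#' Scoring parameters
#'
#' @param forcing_bonus Constant added by the forcing strategy when a
#'   placement creates an immediate threat (a path that then holds k-1 own
#'   marks). Default 10.
#' @param opponent_weight Weight `w` in `[0, 0.5]` on the opponent-side score:
#'   the combined score of a square is
#'   `(1 - w) * score(mover) + w * score(opponent)`. `w = 0.5` (default)
#'   weighs creating own threats and blocking the opponent's equally; `w = 0`
#'   ignores the opponent entirely.
#' @param noise_sigma Standard deviation of Gaussian noise added to each
#'   score evaluation (0 = deterministic).
#' @param win_score Value of a terminal winning board in search, and the cap
#'   used for the degenerate double-threat interaction term.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(forcing_bonus = 10, opponent_weight = 0.5,
                           noise_sigma = 0, win_score = 100) {
  stopifnot(opponent_weight >= 0, opponent_weight <= 0.5, noise_sigma >= 0)
  structure(list(forcing_bonus = forcing_bonus, opponent_weight = opponent_weight,
                 noise_sigma = noise_sigma, win_score = win_score),
            class = "scoring_params")
}

## one-sided scores for `player` over all cells (NA at occupied squares).
## Path counts n_i use the marks *before* the candidate placement; the
## forcing threat test uses the count *after* placement. `cnt` can pass
## precomputed line counts so a caller scoring both sides pays for them once.
.strategy_scores <- function(marks, g, player, strategy,
                             forcing_bonus = 10, win_score = 100, cnt = NULL) {
  p <- player
  empty <- marks == EMPTY
  out <- rep(NA_real_, g$ncell)
  if (strategy == "density") {
    s <- as.vector(g$adj %*% (marks == p))
    out[empty] <- s[empty]
    return(out)
  }
  if (is.null(cnt)) cnt <- .line_counts(marks, g)
  own <- if (p == X) cnt$x else cnt$o
  opp <- if (p == X) cnt$o else cnt$x
  open <- as.numeric(opp == 0)
  if (strategy == "linear") {
    s <- as.vector(g$inc %*% (open * own))
    out[empty] <- s[empty]
    return(out)
  }
  ## non-linear per-path term 1/(n - n_i); open paths with n_i = n are
  ## completed wins and do not occur on the non-terminal boards scored here
  nl_term <- open * ifelse(own < g$k, 1 / (g$k - own), 0)
  nl <- as.vector(g$inc %*% nl_term)
  if (strategy == "nonlinear") {
    out[empty] <- nl[empty]
    return(out)
  }
  ## interaction: pairwise bonus n_i*n_j / ((n-1)^2 - n_i*n_j) over unordered
  ## pairs of open paths through the square. Counts are small integers, so
  ## the pair sum factorizes over count classes: with m_c open paths of
  ## count c through a cell, the bonus is sum over class pairs (a <= b) of
  ## f(a*b) * #pairs. A non-positive denominator only arises for two
  ## (n-1)-count paths (a double threat) and is capped at win_score.
  inter <- nl
  denom0 <- (g$k - 1)^2
  mcls <- vapply(seq_len(g$k - 1L), function(cc)
    as.vector(g$inc %*% (open * (own == cc))), numeric(g$ncell))
  for (a in seq_len(g$k - 1L)) for (b in a:(g$k - 1L)) {
    f <- if (denom0 - a * b > 0) a * b / (denom0 - a * b) else win_score
    npairs <- if (a == b) mcls[, a] * (mcls[, a] - 1) / 2 else mcls[, a] * mcls[, b]
    inter <- inter + f * npairs
  }
  if (strategy == "interaction") {
    out[empty] <- inter[empty]
    return(out)
  }
  if (strategy == "forcing") {
    ## threat: some open path through the square holds n-1 own marks once the
    ## mark is placed, i.e. n-2 before placement
    thr <- as.vector(g$inc %*% (open * (own == g$k - 2))) > 0
    out[empty] <- inter[empty] + forcing_bonus * thr[empty]
    return(out)
  }
  stop("unknown strategy: ", strategy, call. = FALSE)
}

.check_square_empty <- function(board, row, col) {
  i <- .cell_index(board$size, row, col)
  if (row < 1 || row > board$size || col < 1 || col > board$size)
    stop("square off board", call. = FALSE)
  if (board$marks[i] != EMPTY) stop("square is occupied", call. = FALSE)
  i
}

#' Score a square under a single scoring strategy
#'
#' One-sided scores from the mover's perspective (no opponent weighting, no
#' noise), for an *empty* square:
#' \describe{
#'   \item{density}{number of the player's marks among the 8 surrounding
#'     squares (fewer at edges).}
#'   \item{linear}{sum over open paths through the square of the number of
#'     the player's marks on each path (a square on a path of 2 and a path
#'     of 3 scores 5).}
#'   \item{nonlinear}{sum of `1/(n - n_i)` over open paths, `n` the win
#'     length and `n_i` the path's mark count (the same square scores
#'     `1/3 + 1/2 = 5/6` at n = 5).}
#'   \item{interaction}{nonlinear plus, for each unordered pair of open paths
#'     through the square, `n_i n_j / ((n-1)^2 - n_i n_j)` (the 2-and-3 pair
#'     adds `6/10 = 0.6` at n = 5).}
#'   \item{forcing}{interaction plus a constant bonus (default 10) when the
#'     placement creates an immediate threat: a still-open path that then
#'     holds `n - 1` of the player's marks.}
#' }
#' Path counts `n_i` are taken *before* the candidate placement; the forcing
#' threat test looks at the count *after* it.
#'
#' @param board A `kboard`.
#' @param row,col The empty square to score.
#' @param player Perspective, `"X"` or `"O"`.
#' @param forcing_bonus,win_score See [scoring_params()].
#' @return A single numeric score.
#' @export
density_score <- function(board, row, col, player) {
  i <- .check_square_empty(board, row, col)
  .strategy_scores(board$marks, .board_geom(board), .player_code(player), "density")[i]
}

#' @rdname density_score
#' @export
linear_score <- function(board, row, col, player) {
  i <- .check_square_empty(board, row, col)
  .strategy_scores(board$marks, .board_geom(board), .player_code(player), "linear")[i]
}

#' @rdname density_score
#' @export
nonlinear_score <- function(board, row, col, player) {
  i <- .check_square_empty(board, row, col)
  .strategy_scores(board$marks, .board_geom(board), .player_code(player), "nonlinear")[i]
}

#' @rdname density_score
#' @export
interaction_score <- function(board, row, col, player, win_score = 100) {
  i <- .check_square_empty(board, row, col)
  .strategy_scores(board$marks, .board_geom(board), .player_code(player),
                   "interaction", win_score = win_score)[i]
}

#' @rdname density_score
#' @export
forcing_score <- function(board, row, col, player, forcing_bonus = 10, win_score = 100) {
  i <- .check_square_empty(board, row, col)
  .strategy_scores(board$marks, .board_geom(board), .player_code(player),
                   "forcing", forcing_bonus = forcing_bonus, win_score = win_score)[i]
}

## all five strategy scores for one side in a single pass (shared line
## counts and count-class incidence); returns a ncell x strategy matrix with
## NA at occupied cells. Used by the fitting hot path.
.all_strategy_scores <- function(marks, g, player, forcing_bonus = 10,
                                 win_score = 100, cnt = NULL) {
  empty <- marks == EMPTY
  if (is.null(cnt)) cnt <- .line_counts(marks, g)
  own <- if (player == X) cnt$x else cnt$o
  opp <- if (player == X) cnt$o else cnt$x
  open <- as.numeric(opp == 0)
  dens <- as.vector(g$adj %*% (marks == player))
  lin <- as.vector(g$inc %*% (open * own))
  nl <- as.vector(g$inc %*% (open * ifelse(own < g$k, 1 / (g$k - own), 0)))
  inter <- nl
  denom0 <- (g$k - 1)^2
  mcls <- vapply(seq_len(g$k - 1L), function(cc)
    as.vector(g$inc %*% (open * (own == cc))), numeric(g$ncell))
  for (a in seq_len(g$k - 1L)) for (b in a:(g$k - 1L)) {
    f <- if (denom0 - a * b > 0) a * b / (denom0 - a * b) else win_score
    npairs <- if (a == b) mcls[, a] * (mcls[, a] - 1) / 2 else mcls[, a] * mcls[, b]
    inter <- inter + f * npairs
  }
  thr <- as.vector(g$inc %*% (open * (own == g$k - 2))) > 0
  out <- cbind(density = dens, linear = lin, nonlinear = nl,
               interaction = inter, forcing = inter + forcing_bonus * thr)
  out[!empty, ] <- NA_real_
  out
}

## combined (opponent-weighted, optionally noisy) scores over all cells for
## the mover; NA at occupied squares. Both sides use the same strategy.
.combined_scores <- function(marks, g, mover, strategy, params, cnt = NULL) {
  w <- params$opponent_weight
  if (is.null(cnt) && strategy != "density") cnt <- .line_counts(marks, g)
  sm <- .strategy_scores(marks, g, mover, strategy,
                         params$forcing_bonus, params$win_score, cnt = cnt)
  s <- if (w > 0) {
    so <- .strategy_scores(marks, g, .other(mover), strategy,
                           params$forcing_bonus, params$win_score, cnt = cnt)
    (1 - w) * sm + w * so
  } else sm
  if (params$noise_sigma > 0) {
    empty <- which(marks == EMPTY)
    s[empty] <- s[empty] + stats::rnorm(length(empty), 0, params$noise_sigma)
  }
  s
}

#' Combined (opponent-weighted) score of a square
#'
#' `(1 - w) * score(mover) + w * score(opponent)`, both sides scored with the
#' same strategy; `w` defaults to 0.5 (equal weight to creating own threats
#' and denying the opponent's). With `noise_sigma > 0` a fresh `N(0, sigma)`
#' draw is added per evaluation.
#'
#' @param board A `kboard`.
#' @param row,col Empty square.
#' @param strategy One of [strategy_names()].
#' @param params A [scoring_params()] object.
#' @param player Mover perspective; defaults to the player to move.
#' @return Numeric score.
#' @export
combined_score <- function(board, row, col, strategy = "interaction",
                           params = scoring_params(), player = NULL) {
  i <- .check_square_empty(board, row, col)
  p <- if (is.null(player)) board$to_move else .player_code(player)
  .combined_scores(board$marks, .board_geom(board), p, strategy, params)[i]
}
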