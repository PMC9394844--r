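# kinarow

Tools for studying how bounded searchers find forced wins in *k-in-a-row*
end-games (tic-tac-toe generalized to larger boards: 4-in-a-row on 6x6,
5-in-a-row on 10x10). The package is aimed at computational cognitive
scientists who model move-by-move search behavior: it couples a game engine
(boards, winning-path geometry, exact forced-win verification, deterministic
and stochastic alpha-beta, MCTS) with a behavioral toolbox (heuristic
scoring strategies, a spatial "shutter" pruning heuristic, lapse-rate choice
models fitted by grid search with AIC selection, entropy / missed-win /
Pareto analyses) and synthetic-data generators, so the whole pipeline runs
end to end with no external data.

## The model in brief

Every empty square is scored from the structure of the *open winning paths*
through it — length-k lines with no opponent mark. With `n` the win length
and `n_i` the number of own marks on open path `i` through a square, the
five scoring strategies are

| strategy    | score of a square                                              |
|-------------|----------------------------------------------------------------|
| density     | own marks among the 8 neighbouring squares                     |
| linear      | sum of `n_i` over open paths                                   |
| nonlinear   | sum of `1 / (n - n_i)`                                         |
| interaction | nonlinear + pairwise `n_i n_j / ((n-1)^2 - n_i n_j)`           |
| forcing     | interaction + 10 if the placement creates an immediate threat  |

Blocking matters too: the combined score of a square is
`(1 - w) * score(mover) + w * score(opponent)` with opponent weight
`w in [0, 0.5]`. Move probabilities divide each non-negative combined score
by their total.

The *shutter* is a spatial pruning heuristic: moves are restricted to lie
near the open paths induced by the searcher's previous own move. A square at
Manhattan distance `d` from those paths is admitted with weight
`clamp(s - d + 1, 0, 1)` for shutter size `s` (so `s = 0` keeps only
on-path squares, and `s = 0.5` admits distance-1 squares with probability
0.5). Narrow shutters cut computation dramatically and concentrate search on
own plans — at the cost of missing the opponent's winning moves.

Observed move sequences (sandbox searches with place/undo/reset events) are
scored by a lapse-rate choice model,

```
L(move | board, h) = log((1 - eps) * p_h(move) + eps / #legal),
```

fitted per participant over exhaustive grids (shutter 0–3 by 0.1, lapse
0–0.05 by 0.01, opponent weight 0–0.5 by 0.1), with the strategy chosen by
AIC.

## A worked example

```r
library(kinarow)

# a verified end-game: X to move forces a win within 4 X moves
b <- generate_endgame_board(size = 6, k = 4, target_depth = 4, seed = 11)
print(b)
#> 6x6 board, 4 in a row, X to move, X wins within 4
#>  6 . . . . . .
#>  5 O . X O . .
#>  4 . X . O . .
#>  3 . . X . . .
#>  2 . . O X . .
#>  1 . . . X O .
#>    a b c d e f
attr(b, "optimal_moves")$label   # every verified winning first move
#> [1] "b5" "b3" "c6" "d6" "d3"

board_complexity(b)          # alpha-beta evaluations to confirm the win
#> [1] 68604

# a simulated participant searching with the interaction strategy and a
# narrow shutter, and its model fit
s <- simulate_participant(b, "interaction", shutter = 0, epsilon = 0.02,
                          max_moves = 40, seed = 3)
fit <- fit_participant(s)
glance(fit)
#> # A tibble: 1 x 10
#>   id    strategy    epsilon shutter     w total_ll mean_ll n_moves n_par   aic
#>   <chr> <chr>         <dbl>   <dbl> <dbl>    <dbl>   <dbl>   <int> <dbl> <dbl>
#> 1 NA    interaction       0       0   0.5    -67.4   -1.68      40     2  139.
```

The fit recovers the generating strategy and the shutter size 0 (the fitted
lapse 0 versus the true 0.02 reflects that a 40-move session carries only
about one lapse move). The `mean_ll` of -1.68 per move (natural log) says
the model predicts each move far better than chance, which is `log(1/26)`,
about -3.26, on this board.

Sweeps and analyses chain with the pipe:

```r
boards <- list(easy = generate_endgame_board(6, 4, 3, seed = 5),
               hard = generate_endgame_board(6, 4, 4, seed = 11))
runs <- shutter_sweep(boards, shutters = c(0, 1, 2), sigmas = c(0, 1),
                      branchings = 5, limits = 100, n_seeds = 30, seed = 1)
runs |> dplyr::filter(board_id == "hard", sigma == 1) |>
  pareto_analysis() |> autoplot()
```

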