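---
title: "Models and methods behind kinarow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kinarow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

kinarow studies bounded search in k-in-a-row end-games: positions from
which X can force a win within a small number of moves (3–5) on 6x6
(4-in-a-row) or 10x10 (5-in-a-row) grids. This vignette documents the
models, the numerical choices, and the assumptions behind the synthetic
data, so that the scope of what the package's tests demonstrate is explicit.

## Scoring strategies

All strategies value an *empty* square through the open winning paths that
pass through it: contiguous length-k lines (horizontal, vertical, either
diagonal) holding no opponent mark. With win length $n$ and $n_i$ the number
of own marks already on open path $i$:

* **density** — own marks among the 8 neighbouring squares. The
  neighbourhood is Moore (8 squares) by construction of the adjacency; a
  4-neighbourhood variant was considered and rejected because diagonal
  lines are winning lines, so diagonal neighbours are structurally relevant.
* **linear** — $\sum_i n_i$.
* **nonlinear** — $\sum_i 1/(n - n_i)$: a path one mark from completion is
  worth 1, an empty path $1/n$.
* **interaction** — nonlinear plus, for each unordered pair of open paths
  through the square, $n_i n_j / ((n-1)^2 - n_i n_j)$. The denominator is
  non-positive only when both paths already hold $n-1$ marks; such a square
  is a double threat and its pair term is capped at `win_score` so that it
  dominates every non-winning square while remaining finite.
* **forcing** — interaction plus a constant bonus (default 10) when the
  placement creates an immediate threat: a still-open path that holds $n-1$
  own marks *after* the placement.

Path counts $n_i$ are taken before the candidate placement (this matches
the worked examples: a square on paths of 2 and 3 marks scores
$2+3=5$ linearly and $1/3 + 1/2 = 5/6$ non-linearly at $n=5$); only the
forcing threat test looks one placement ahead.

Opponent weighting mixes both perspectives with the same strategy:
$\mathrm{score} = (1-w)\,\mathrm{score}(\text{mover}) +
w\,\mathrm{score}(\text{opponent})$, $w \in [0, 0.5]$, default $0.5$.
Score noise, when enabled, is a fresh $N(0, \sigma)$ draw per evaluation —
it is not frozen per square, because it models evaluation noise during
search rather than stable square-level bias.

Move probabilities divide each non-negative weighted score by the total
over squares (negative noisy scores get probability zero). Two fallbacks
keep the map well defined: if all weighted scores are zero the distribution
is uniform over the admissible (positive shutter weight) squares, and if no
square is admissible, uniform over all legal moves.

## The shutter

The shutter restricts consideration to squares near the *induced paths* —
the open own paths through the searcher's previous own move. A square at
Manhattan distance $d$ from the nearest induced-path square has weight
$\min(\max(s - d + 1, 0), 1)$ for shutter size $s$. The linear clamp is the
simplest rule that reproduces all four pinned behaviors: at $s=0$ only
on-path squares; at $s=0.5$ distance-1 squares with probability 0.5; at
integer $s$ a hard cutoff at distance $s$. When there is no previous own
move, or no induced path survives, the distance is *undefined* and the
shutter is inactive (weight 1 everywhere) — search must not deadlock, and a
first move has no anchor.

Two deliberate consequences: the shutter anchors on the last **X** move for
O moves as well (a participant controls both sides of the sandbox and
attends to their own plan), which is what produces blindness to O's winning
moves under narrow shutters; and during fitting, the soft multiplicative
weight makes fractional fitted shutters meaningful while recovering the
hard restriction at integer values.

## Search

Deterministic `alpha_beta()` is negamax with alpha-beta cuts, children
ordered best-first by the scoring strategy. Terminal wins are valued
`win_score - ply` so faster wins rank higher (needed for determinism; the
choice of `win_score = 100` only has to exceed every heuristic score of a
non-double-threat square). A mover holding an immediate completing move
takes it without expanding the subtree — exact under the faster-win
preference and a large saving near the horizon. At the depth-1 horizon a
move is worth its own score, so depth 1 is a greedy argmax of the strategy;
a board-filling move is a draw (value 0), which keeps full-depth search
identical to exhaustive minimax (the equality is tested against an
independent memoized minimax on all 3x3 positions within four plies of the
empty board and on 4x4/k=3 fixtures). `nodes_evaluated` counts score
evaluations — one per square for which a combined score was computed,
including move-ordering evaluations — which is also the unit of
`board_complexity()` (interaction strategy, depth `2 d - 1` plies for
solution depth `d`).

The stochastic variant samples `branching` children without replacement
with probability proportional to the shutter-weighted non-negative noisy
scores, aborts at `move_limit` evaluations returning the best-so-far first
move, and adjudicates "found the winning move" with the *exact* solver
(`move_forces_win()`), never with its own heuristic value.

The exact solver is an AND-OR proof search with three exact reductions:
immediate wins are taken; when X threatens, O's only non-losing replies are
the threat-completing squares; and candidates are restricted to squares on
lines still completable within the remaining move budget (a line with
$n_i < k - 1 - b$ under budget $b$ can never again matter, because the
feasibility threshold rises by one per move while a line gains at most one
mark per move). Pass moves are exchangeable, so one representative O pass
is kept. Each reduction is validated against an unrestricted solver on
several hundred random 4x4/k=3 positions. A node budget turns pathological
proofs into clean aborts; a position whose proof aborts is simply never
emitted by the generator.

MCTS is standard UCT with uniform random rollouts; the persistent mode
hands the tree to the next call so visit counts and outcomes are retained
across moves, modelling re-use of internal computation.

## The behavioral model and fitting

Sessions are ordered place/undo/reset events. Undo and reset are not
modelled as choices; they only change the state on which subsequent moves
are evaluated, and replay is deterministic. Each *place* event (X and O
alike — the mover's role is symmetric in the likelihood) contributes
$\log((1-\epsilon)\,p_h(\text{move}) + \epsilon/\#\text{legal})$. Fitting
is an exhaustive grid search per strategy: shutter 0–3 in steps of 0.1
plus an explicit *off* cell (so the shutter-augmented model nests the base
model and the likelihood-ratio test is valid — the 0–3 grid alone does not
guarantee nesting), lapse 0–0.05 in steps of 0.01, opponent weight 0–0.5 in
steps of 0.1 when fitted. AIC is $2p - 2\ell$ with $p$ counted per
participant as lapse + shutter (+ weight); the assigned strategy minimizes
AIC, with ties resolved toward the simpler (earlier-listed) strategy. The
first move of a session has no prior own move and uses shutter-off
probabilities.

## Synthetic data: what it does and does not emulate

`generate_endgame_board()` reproduces the study's generation recipe:
noisy self-play (interaction strategy, $\sigma = 1$) from the empty board,
then a scan of the intermediate X-to-move states for one where the forced
win exists at exactly the target depth — verified by the exact solver, a
win at depth $d$ and none at $d-1$. The published stimuli added a manual
curation step; here a threat-potential prefilter (at least two open X lines
within two marks of completion) plays that role automatically. Truncation
applies one verified-optimal X move and the most resistant O reply, then
re-verifies at depth $d-1$. Among the verified-optimal X moves (and among
the maximally resistant O replies) the *modal* one under interaction
scoring is applied: the truncated position must be a continuation that
full-board searchers actually reach, otherwise matched-state comparisons
have no matched sessions to work with — the published stimuli were curated
by hand with the same effect.

`simulate_participant()` realizes exactly the generative model the
likelihood assumes: placements sampled from the strategy's move
probabilities under the agent's shutter, mixed with an $\epsilon$-uniform
lapse, both roles played by the same agent, and a sandbox reset whenever a
line completes, until the move budget (default 40 placements, matching the
study's session lengths) is spent. Timestamps are synthetic monotone
counters; move timing is out of scope. What passing tests therefore show is
that the pipeline is *self-consistent* — parameters that generated the data
are recovered, and the entropy/missed-win signatures follow from the shutter
mechanism itself. They cannot show that human searchers obey this model;
the simulated cohorts have no fatigue, learning, attention lapses beyond
$\epsilon$, or timing structure.

## Design choices in the recovery and comparison experiments

* **Stimulus selection.** Model recovery is only as good as the stimulus:
  on boards where nonlinear and interaction move maps nearly coincide, no
  fitting method can separate them. Recovery experiments therefore select
  their board from a fixed candidate pool by
  `strategy_discriminability()` — the mean Jensen–Shannon divergence
  between the two strategies' move maps along simulated exploration states
  — computed from the model alone before any fitting. This mirrors the
  original studies' curation of informative stimuli. 10x10 boards are used
  because their larger geometry also separates the shutter and lapse
  parameters (on 6x6 nearly every square sits within distance 2 of an
  induced path, so a wide shutter can absorb lapse moves).
* **Entropy-cohort agents.** The matched-state entropy comparison uses
  `simulate_search_participant()` — noisy depth-limited searchers that play
  the move their internal search chose — rather than probability-matching
  samplers. Score-proportional samplers spread their first moves nearly
  uniformly on these boards, so almost no session reproduces the truncated
  prefix and the matched set is empty; internal-search agents concentrate
  near the argmax, as the human first-move distributions do, and give the
  comparison data to work with. Pairs with fewer than five matched
  sessions are reported as empty and excluded, exactly as an empty matched
  set would be in a behavioral dataset.
* **Equal-sample entropy comparisons.** Plug-in entropy is biased downward
  in small samples, and the matched full-condition subset is necessarily
  smaller than the truncated cohort. Matched-state comparisons therefore
  subsample the truncated first moves to the matched count before comparing
  entropies; without this control a memoryless cohort would show a spurious
  "reduction".
* **Miss-ratio accounting.** A missed win is a turn where the mover had an
  immediately completing move and played none. Ratios pool counts
  (total missed X over total missed O) across runs; a per-run ratio is
  undefined whenever no O win was missed, and pooling avoids conditioning
  on that event. Where per-session ratios are reported, the undefined cases
  carry an explicit `NA` sentinel, never a zero.
* **Trade-off flags.** A sweep configuration presents a trade-off when at
  least two shutter values are mutually non-dominated on (accuracy,
  computation) *and* both axis differences are significant by percentile
  bootstrap (95%, at least several hundred replicates, seeded). The phase
  space aggregates these flags over branching factor and move limit per
  (complexity bin, noise) cell, with quantile complexity bins.

## Problem sizes

The shipped experiments run at deliberately moderate scale: twenty 6x6
depth-4 boards with truncations; 400 fitted sessions (8 design cells x 50
replicates) of 40 moves each for recovery; cohorts of 200 agents per
condition for the entropy comparison; 100 trajectories per board and
shutter for the miss ratios; and a 2-board x 3-noise x 2-branching x
2-limit x 4-shutter sweep with 50 seeds per cell for the Pareto analysis.
These sizes give stable statistics for every directional claim while
keeping a full run of the suite comfortably reproducible on a laptop;
all of them are single arguments to the corresponding functions.

## Known limitations

* The solver's candidate reductions are proved for the attacker-within-
  budget setting used here; they are not a general game solver.
* Heuristic leaf values and win values share one scale; with `w = 0` and a
  degenerate double-threat cap the ordering between a distant win and an
  extreme heuristic score can interleave. Exact claims never rely on
  heuristic values — verification always goes through the exact solver.
* MCTS uses uniform rollouts and is practical on 6x6 boards only; this
  matches its role as a comparison model, not an engine.
* Fitted lapse rates are weakly identified in 40-move sessions when the
  shutter is wide (roughly one lapse move per session, most of which land
  on squares the model already likes); recovery medians are reported over
  replicates for this reason.
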