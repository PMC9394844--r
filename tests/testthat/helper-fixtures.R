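# Shared, lazily built fixtures for the heavier end-to-end tests. Everything
# is generated in code under fixed seeds; the cache only avoids re-generating
# the same boards across test blocks in one run.

.fixture_cache <- new.env(parent = emptyenv())

# twenty verified 6x6 / k=4 / depth-4 end-game boards and their truncations
endgame_board_set <- function() {
  if (is.null(.fixture_cache$boards)) {
    boards <- lapply(1:20, function(seed)
      generate_endgame_board(6, 4, 4, seed = seed, max_games = 800))
    names(boards) <- sprintf("b%02d", 1:20)
    .fixture_cache$boards <- boards
  }
  .fixture_cache$boards
}

truncated_board_set <- function() {
  if (is.null(.fixture_cache$truncs)) {
    .fixture_cache$truncs <- lapply(endgame_board_set(), truncate_board)
  }
  .fixture_cache$truncs
}

# the 10x10 / k=5 recovery stimulus: a fixed candidate pool of generation
# seeds, the board separating the nonlinear and interaction strategies best
# (by model-based divergence, decided before any fitting)
recovery_board <- function() {
  if (is.null(.fixture_cache$recovery)) {
    cands <- lapply(21:26, function(seed)
      generate_endgame_board(10, 5, 4, seed = seed, max_games = 120,
                             optimal_moves = FALSE))
    disc <- vapply(cands, strategy_discriminability, numeric(1))
    .fixture_cache$recovery <- cands[[which.max(disc)]]
  }
  .fixture_cache$recovery
}
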