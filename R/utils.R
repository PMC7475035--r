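# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, leaving the caller's RNG state
# untouched (all exported stochastic functions take an explicit seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  # scramble before seeding: consecutive raw set.seed values can yield
  # correlated streams, which distorts error-rate estimates over many
  # seeded simulations
  set.seed(.cpp_scramble_int(as.numeric(seed)))
  expr
}

# Round half away from zero (4.5 -> 5, -4.5 -> -5); round() would round
# half to even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

as_dna_string <- function(x) {
  if (is(x, "DNAString")) x else Biostrings::DNAString(as.character(x))
}

as_character_seq <- function(x) {
  if (is.character(x)) x else as.character(x)
}

# Permutation/bootstrap p with the +1 correction: never 0.
mc_p <- function(n_ge, n) (n_ge + 1) / (n + 1)

stopifnot_scalar <- function(x, what) {
  if (length(x) != 1L || is.na(x)) stop(what, " must be a single value")
  invisible(x)
}
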