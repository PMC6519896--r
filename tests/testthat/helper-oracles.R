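# Shared fixtures and independent oracles used across test files.

labels_of <- function(models) sort(vapply(models, model_label, character(1)))

# Truncated-distribution oracle for mean first passage times: propagates the
# probability mass over non-target states and accumulates P(T > t) step by
# step, E[T] = sum_t P(T > t). Independent of the package's linear solve.
mfpt_by_truncation <- function(Tm, target, from, horizon = 10000L) {
  idx <- setdiff(seq_len(nrow(Tm)), target)
  Q <- Tm[idx, idx, drop = FALSE]
  mass <- as.numeric(idx == from)
  total <- 0
  for (t in seq_len(horizon)) {
    total <- total + sum(mass)       # P(T >= t)
    mass <- as.numeric(mass %*% Q)
    if (sum(mass) < 1e-14) break
  }
  total
}

# A hand-specified 3-state chain used by several Markov tests.
toy3 <- function() {
  Tm <- matrix(c(0.5, 0.3, 0.2,
                 0.1, 0.6, 0.3,
                 0.2, 0.2, 0.6), 3, 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  Tm
}

# Small data-generating configurations reused across files.
truth_tm2 <- function(...) true_model_config(parse_model("1+2+3+12"), ...)

# Deterministic dataset from a configuration under a local seed, leaving the
# caller's RNG stream untouched.
dataset_with_seed <- function(config, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  generate_dataset(config)
}
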