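# Session-level fixture cache: expensive objects (synthetic datasets,
# trained pipelines) are built once and shared across test files.
.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small noise-free synthetic dataset with the planted rule.
synth_small <- function() {
  cached_fixture("synth_small",
                 generate_synthetic_dataset(synthetic_spec(n = 160, seed = 101)))
}

# Scaled-down training configuration for desk-scale learning tests:
# the study architectures with fewer epochs and a faster Adam step.
desk_pipeline_config <- function(base_epochs = 2L, meta_epochs = 30L,
                                 seed = 1L) {
  pipeline_config(
    base_cfg = train_config(1e-3, epochs = base_epochs, seed = seed),
    meta_cfg = train_config(1e-3, epochs = meta_epochs, seed = seed))
}

# A tiny trained pipeline manifest reused by pipeline/meta tests.
pipeline_small <- function() {
  cached_fixture("pipeline_small", {
    suppressWarnings(run_stepwise_training(
      generate_synthetic_dataset(synthetic_spec(n = 240, seed = 31)),
      desk_pipeline_config()))
  })
}

# Brute-force AUC oracle: pair counting with half credit for ties.
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force Tanimoto oracle on small sets.
tanimoto_bruteforce <- function(a, b) {
  inter <- sum(a & b); uni <- sum(a | b)
  if (uni == 0) 1 else inter / uni
}
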