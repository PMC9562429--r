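# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small, fast experiment used by most module tests
small_config <- function(...) {
  args <- utils::modifyList(list(n_proteins = 600, marker_fraction = 0.25,
                                 noise_sd = 0.05, seed = 42), list(...))
  do.call(simulation_config, args)
}

small_experiment <- function() {
  cached("small_experiment", simulate_experiment(small_config()))
}

# normalized singles + combined map for one condition
preprocess_maps <- function(raw_maps) {
  singles <- lapply(raw_maps, normalize_profiles)
  list(singles = singles, combined = combine_replicates(singles))
}

small_combined <- function(cond = "A") {
  cached(paste0("small_combined_", cond),
         preprocess_maps(small_experiment()$maps[[cond]]))
}

small_classified <- function(cond = "A") {
  cached(paste0("small_classified_", cond),
         classify_map(small_combined(cond)$combined,
                      small_experiment()$markers, cost = 48, sigma = 1,
                      seed = 7))
}

# independent step-up BH oracle (plain loop over the sorted p-values)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- prev
  }
  adj
}

# exhaustive two-sided Fisher oracle: sum of hypergeometric point
# probabilities not exceeding the observed table's probability
fisher_oracle <- function(a, b, c_, d) {
  m <- a + c_            # annotated
  n <- b + d              # unannotated
  k <- a + b              # foreground size
  probs <- stats::dhyper(0:min(m, k), m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}
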