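## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_cfg <- function(...) {
  sim_config(n_otus = 150L, depth = 3000L, n_events = 3L, ...)
}

small_bundle <- function() {
  cached("small", simulate_reactor_system(small_cfg(), seed = 42))
}

default_bundle <- function() {
  cached("default", simulate_reactor_system(sim_config(), seed = 1))
}

default_growth <- function() {
  cached("default_growth", {
    b <- default_bundle()
    growth_rates(b$otu, b$metadata, b$reactor)
  })
}

as_subset <- function(md) {
  md$sample_id[md$location %in% c("aeration_tank", "clarifier_underflow")]
}

## tiny deterministic count table
toy_table <- function() {
  otu_table(matrix(c(3L, 1L, 0L, 5L), 2, 2,
                   dimnames = list(c("otu1", "otu2"), c("s1", "s2"))))
}
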