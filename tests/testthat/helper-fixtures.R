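# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small panel for unit tests
small_panel <- function() {
  cached("small_panel", simulate_genotype_panel(300, 400, 2, seed = 11))
}

# mid-size panel shared by the slower model checks
mid_panel <- function() {
  cached("mid_panel", simulate_genotype_panel(1200, 1500, 10, seed = 21))
}

# benchmark-scale panel used by the trend checks (p = 3000)
bench_panel <- function() {
  cached("bench_panel", simulate_genotype_panel(2600, 3000, 10, seed = 31))
}

random_dosage_matrix <- function(n, p, seed) {
  withr::with_seed(seed, matrix(sample(0:2, n * p, replace = TRUE), n, p))
}
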