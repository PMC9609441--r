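# Shared objects for the test suite. Everything here is cheap to build;
# expensive fits live in the tests that need them and are cached per session.

default_grid <- function(n_bins = 20) size_grid(0.05e-6, 5e-6, n_bins)

default_psd0 <- function(grid = default_grid()) psd_lognormal(grid, 1.5e-6, 1.5)

# dense polynomial reference profile used by the breakage fitting tests
reference_profile <- function(n_dense = 61, t_end = 3600) {
  poly <- polyfit_profile(milling_experiments(), order = 2)
  augment_profile(poly, seq(0, t_end, length.out = n_dense), extrapolate = TRUE)
}

# session-level cache so the acceptance test and unit tests can share one
# expensive comparison run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  .cache[[key]] <- force(expr)
  .cache[[key]]
}
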