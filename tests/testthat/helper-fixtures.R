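# Shared fixtures: built in code, deterministic.

# A single pinned parameter set with simple round numbers; the expected
# derived quantities in tests are computed by independent hand arithmetic.
pinned_params <- function() {
  tibble::tibble(
    mo_sw = 5e-9, delta_in = 0.5,
    b_fe = 2e6, b_mn = 2e6, b_sad = 3e8, b_eux = 1.2e9,
    # 70% / 1% / 25% / 4% of 3.6e8 km^2
    area_fe = 2.52e8, area_mn = 3.6e6, area_sad = 9.0e7, area_eux = 1.44e7
  )
}

# Small/medium ensembles shared within a test file; memoised per session.
local({
  cache <- new.env(parent = emptyenv())
  shared_ensemble <<- function(n = 2e5, seed = 1) {
    key <- paste0("e", n, "_", seed)
    if (is.null(cache[[key]])) cache[[key]] <- sample_ensemble(n, seed)
    cache[[key]]
  }
})

# Random valid parameter tables for property-style loops.
random_params <- function(n, seed) {
  set.seed(seed)
  pct <- matrix(stats::runif(4 * n, 0.5, 50), ncol = 4)
  pct <- pct / rowSums(pct) * 100
  tibble::tibble(
    mo_sw = stats::runif(n, 1e-11, 1e-7),
    delta_in = stats::runif(n, 0, 0.7),
    b_fe = stats::runif(n, 1e6, 3e6),
    b_mn = stats::runif(n, 1e6, 3e6),
    b_sad = stats::runif(n, 1.75e8, 4.25e8),
    b_eux = stats::runif(n, 0.6e9, 1.8e9),
    area_fe = pct[, 1] / 100 * 3.6e8,
    area_mn = pct[, 2] / 100 * 3.6e8,
    area_sad = pct[, 3] / 100 * 3.6e8,
    area_eux = pct[, 4] / 100 * 3.6e8
  )
}
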