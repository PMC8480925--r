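#' Monte Carlo sampling ranges for the mass-balance parameters
#'
#' Defaults are the published calibration of the model: per-sink
#' depositional area fractions (% of total seafloor), per-sink burial rate
#' constants (liter km^-2 yr^-1), seawater Mo concentration (mol/liter)
#' and riverine input delta98Mo (per mil). Areas, concentration and input
#' composition are drawn uniform; rate constants are drawn from a
#' truncated normal (they are measured modern values with ~25% relative
#' uncertainty), with mean at the range midpoint, standard deviation 25%
#' of the mean, truncated to the range by resampling.
#'
#' @param area_pct List of per-sink `c(lo, hi)` area fractions in percent.
#'   Mn-oxide and euxinic sediments are capped at 10% and 5% of the
#'   seafloor (continental-margin settings); Fe-oxide and sulfidic-at-depth
#'   sediments may cover the whole (ferruginous) deep ocean.
#' @param b List of per-sink `c(lo, hi)` burial rate constants.
#' @param mo_sw `c(lo, hi)` seawater Mo concentration (mol/liter), from
#'   near-zero to the modern 105 nM.
#' @param delta_in `c(lo, hi)` riverine delta98Mo (per mil), from igneous
#'   crust to the modern river mean.
#' @param b_rel_sd Relative standard deviation of the rate-constant
#'   normals.
#' @return A validated list with class `mo_ranges`.
#' @export
sampling_ranges <- function(area_pct = list(fe = c(0.01, 100),
                                            mn = c(0.01, 10),
                                            sad = c(0.01, 100),
                                            eux = c(0.01, 5)),
                            b = list(fe = c(1.0e6, 3.0e6),
                                     mn = c(1.0e6, 3.0e6),
                                     sad = c(1.75e8, 4.25e8),
                                     eux = c(0.6e9, 1.8e9)),
                            mo_sw = c(0.01e-9, 105e-9),
                            delta_in = c(0, 0.7),
                            b_rel_sd = 0.25) {
  check_range <- function(x, nm) {
    if (length(x) != 2 || !is.numeric(x) || x[1] >= x[2]) {
      stop("range `", nm, "` must be numeric c(lo, hi) with lo < hi",
           call. = FALSE)
    }
  }
  for (s in sink_classes()) {
    check_range(area_pct[[s]], paste0("area_pct$", s))
    check_range(b[[s]], paste0("b$", s))
  }
  check_range(mo_sw, "mo_sw")
  check_range(delta_in, "delta_in")
  stopifnot(b_rel_sd > 0)
  structure(
    list(area_pct = area_pct[sink_classes()], b = b[sink_classes()],
         mo_sw = mo_sw, delta_in = delta_in, b_rel_sd = b_rel_sd),
    class = "mo_ranges"
  )
}

# Normal truncated to [lo, hi] by resampling; vector of n draws.
rtruncnorm_resample <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

# Draw per-sink area fractions: uniform on the printed % ranges,
# renormalised to sum to 100%, rejecting draws whose renormalised Mn or
# euxinic fraction exceeds its cap. Returns a matrix (n x 4) of percents.
draw_area_fractions <- function(n, ranges, max_reject = 0.999) {
  ap <- ranges$area_pct
  draw <- function(m) {
    raw <- vapply(sink_classes(),
                  function(s) stats::runif(m, ap[[s]][1], ap[[s]][2]),
                  numeric(m))
    raw <- matrix(raw, nrow = m)
    pct <- raw / rowSums(raw) * 100
    colnames(pct) <- sink_classes()
    pct
  }
  pct <- draw(n)
  ok <- pct[, "mn"] <= ap$mn[2] & pct[, "eux"] <= ap$eux[2]
  n_tried <- n
  n_bad <- sum(!ok)
  while (any(!ok)) {
    m <- sum(!ok)
    repl <- draw(m)
    pct[!ok, ] <- repl
    ok[!ok] <- repl[, "mn"] <= ap$mn[2] & repl[, "eux"] <= ap$eux[2]
    n_tried <- n_tried + m
    n_bad <- n_bad + sum(repl[, "mn"] > ap$mn[2] | repl[, "eux"] > ap$eux[2])
    if (n_bad / n_tried > max_reject && n_tried > 1e4) {
      stop("area rejection rate above ", max_reject,
           ": inconsistent area ranges", call. = FALSE)
    }
  }
  pct
}

#' Sample a Monte Carlo ensemble of mass-balance solutions
#'
#' Draws `n` candidate ocean states from the configured ranges and
#' assembles each into a full mass-balance solution (removal rates, sink
#' fractions, seawater delta98Mo, euxinic enrichment interval). The draw
#' order is fixed — rate constants, then concentration, input composition
#' and area fractions — so an ensemble is exactly reproducible from
#' `(seed, n, ranges)`.
#'
#' @param n Number of solutions (>= 1).
#' @param seed Integer RNG seed.
#' @param ranges A [sampling_ranges()] object.
#' @param mar_max,mar_min Mass accumulation rate bracket passed to
#'   [assemble_solutions()].
#' @param constants A [mo_constants()] list.
#' @return A tibble of class `mo_ensemble` with one row per solution and
#'   attributes `seed`, `n_requested`, `ranges`.
#' @export
#' @examples
#' ens <- sample_ensemble(100, seed = 1)
#' dplyr::glimpse(ens)
sample_ensemble <- function(n, seed, ranges = sampling_ranges(),
                            mar_max = 0.0125, mar_min = 0.00125,
                            constants = mo_constants()) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  b_draw <- lapply(sink_classes(), function(s) {
    r <- ranges$b[[s]]
    mu <- mean(r)
    rtruncnorm_resample(n, mu, ranges$b_rel_sd * mu, r[1], r[2])
  })
  names(b_draw) <- paste0("b_", sink_classes())

  mo_sw <- stats::runif(n, ranges$mo_sw[1], ranges$mo_sw[2])
  delta_in <- stats::runif(n, ranges$delta_in[1], ranges$delta_in[2])
  pct <- draw_area_fractions(n, ranges)
  areas <- pct / 100 * constants$seafloor_area
  colnames(areas) <- paste0("area_", sink_classes())

  params <- tibble::as_tibble(c(
    list(mo_sw = mo_sw, delta_in = delta_in),
    b_draw,
    as.list(as.data.frame(areas))
  ))
  out <- assemble_solutions(params, mar_max = mar_max, mar_min = mar_min,
                            constants = constants)
  attr(out, "seed") <- seed
  attr(out, "n_requested") <- n
  attr(out, "ranges") <- ranges
  class(out) <- c("mo_ensemble", class(out))
  out
}

# Set the RNG deterministically and return the previous state.
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}

#' Box-and-whisker summary of an ensemble quantity
#'
#' Five-number summary used throughout for ensemble distributions: the
#' central quartile box (Q1, median, Q3), whiskers extending to the most
#' extreme data points within 1.5 IQR of the box, and the points beyond
#' the whiskers flagged as outliers. Quartiles use the standard continuous
#' (type 7) rule.
#'
#' @param values Non-empty numeric vector.
#' @return A one-row tibble with `n`, `q1`, `median`, `q3`,
#'   `whisker_lo`, `whisker_hi` and a list-column `outliers`.
#' @export
#' @examples
#' summarize_ensemble(c(1, 2, 3, 4, 5))
summarize_ensemble <- function(values) {
  if (length(values) == 0 || !is.numeric(values)) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  tibble::tibble(
    n = length(values),
    q1 = q[1], median = q[2], q3 = q[3],
    whisker_lo = min(inside),
    whisker_hi = max(inside),
    outliers = list(values[values < lo_fence | values > hi_fence])
  )
}

#' @export
glance.mo_ensemble <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    seed = attr(x, "seed") %||% NA_integer_,
    median_mo_sw_nM = stats::median(x$mo_sw) * 1e9,
    median_r_in = stats::median(x$r_in),
    median_delta_sw = stats::median(x$delta_sw)
  )
}

#' Write an ensemble with its provenance sidecar
#'
#' Writes the solutions as CSV and a JSON sidecar recording the seed,
#' requested size and sampling ranges, sufficient to regenerate the
#' ensemble exactly.
#'
#' @param ensemble An `mo_ensemble`.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  readr::write_csv(ensemble, path)
  sidecar <- list(
    seed = attr(ensemble, "seed"),
    n_requested = attr(ensemble, "n_requested"),
    ranges = unclass(attr(ensemble, "ranges"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
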