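#' Pipeline run configuration
#'
#' Bundles everything a full reproduction run depends on: ensemble size
#' and seed, the periods to analyse, the sampling ranges, the per-period
#' filter constraints, the weathering-curve calibration and the physical
#' constants. Defaults are the published calibration throughout, so
#' `run_mo_pipeline(mo_run_config())` is the canonical reproduction run.
#'
#' @param n_samples Ensemble size.
#' @param seed RNG seed.
#' @param periods Character vector of period names (see
#'   [period_constraints()]).
#' @param ranges A [sampling_ranges()] object.
#' @param constraints A [period_constraints()]-shaped tibble.
#' @param weathering A [weathering_params()] object.
#' @param constants A [mo_constants()] list.
#' @return A list with class `mo_config`.
#' @export
mo_run_config <- function(n_samples = 2e6, seed = 1,
                          periods = period_constraints()$period,
                          ranges = sampling_ranges(),
                          constraints = period_constraints(),
                          weathering = weathering_params(),
                          constants = mo_constants()) {
  stopifnot(n_samples >= 1, all(periods %in% constraints$period))
  structure(
    list(n_samples = n_samples, seed = seed, periods = periods,
         ranges = ranges, constraints = constraints,
         weathering = weathering, constants = constants),
    class = "mo_config"
  )
}

#' Serialize / restore a run configuration
#'
#' JSON round-trip for exact replay of a run. `read_run_config()`
#' revalidates through the constructors, so a tampered file fails loudly.
#'
#' @param config An `mo_config`.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns an `mo_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "mo_config"))
  x <- list(
    n_samples = config$n_samples, seed = config$seed,
    periods = config$periods,
    ranges = unclass(config$ranges),
    constraints = config$constraints,
    weathering = unclass(config$weathering),
    constants = lapply(unclass(config$constants), function(v) {
      if (!is.null(names(v))) as.list(v) else v
    })
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mo_run_config(
    n_samples = x$n_samples, seed = x$seed, periods = x$periods,
    ranges = sampling_ranges(
      area_pct = lapply(x$ranges$area_pct, as.numeric),
      b = lapply(x$ranges$b, as.numeric),
      mo_sw = as.numeric(x$ranges$mo_sw),
      delta_in = as.numeric(x$ranges$delta_in),
      b_rel_sd = x$ranges$b_rel_sd
    ),
    constraints = tibble::as_tibble(x$constraints),
    weathering = weathering_params(
      plateau_flux = x$weathering$plateau_flux,
      transition_po2 = x$weathering$transition_po2,
      order_n = x$weathering$order_n,
      biotic_factor = x$weathering$biotic_factor
    ),
    constants = mo_constants(
      m_mo = x$constants$m_mo,
      seafloor_area = x$constants$seafloor_area,
      delta_offset = unlist(x$constants$delta_offset),
      modern_flux = x$constants$modern_flux,
      mo_s_ratio = x$constants$mo_s_ratio,
      hydrothermal_fraction = x$constants$hydrothermal_fraction,
      closure_tol = x$constants$closure_tol
    )
  )
}

#' Run the full record-to-O2 inference pipeline
#'
#' Samples one Monte Carlo ensemble, then for each selected period:
#' filters it against that period's record constraints, summarises the
#' surviving seawater Mo concentrations and relative input rates
#' (box-and-whisker statistics), and chains the minimum surviving input
#' through the hydrothermal correction, the Mo-to-sulfate conversion, the
#' pyrite-oxidation stoichiometry and the weathering-curve inversion.
#' Per-filter rejection counts are reported for every period; an
#' infeasible period yields a flagged row rather than an error.
#'
#' @param config An [mo_run_config()].
#' @param out_dir Optional directory; when given, results, summaries and
#'   a JSON provenance manifest are written there as CSV/JSON.
#' @param ensemble Optional pre-sampled ensemble (must match the config's
#'   seed/n for the manifest to be faithful); sampled from the config
#'   when omitted.
#' @return A list of class `mo_pipeline`: `results` (per-period flux
#'   tibble), `summaries` (per-period box statistics for seawater Mo in
#'   nM and input as % of modern), `rejections` (per-period filter
#'   counts), `config`.
#' @export
#' @examples
#' run <- run_mo_pipeline(mo_run_config(n_samples = 5000, seed = 1))
#' run$results
run_mo_pipeline <- function(config = mo_run_config(), out_dir = NULL,
                            ensemble = NULL) {
  stopifnot(inherits(config, "mo_config"))
  cst <- config$constants
  if (is.null(ensemble)) {
    ensemble <- sample_ensemble(config$n_samples, config$seed,
                                ranges = config$ranges, constants = cst)
  }
  empty_result <- function(p) tibble::tibble(
    period = p, n_survivors = 0L, r_in_min = NA_real_,
    r_in_min_pct = NA_real_, r_corrected = NA_real_, s_flux = NA_real_,
    o2_flux = NA_real_, po2_abiotic = NA_real_, po2_biotic = NA_real_,
    feasible = FALSE
  )
  per_period <- purrr::map(config$periods, function(p) {
    pc <- config$constraints[config$constraints$period == p, ]
    surv <- apply_filters(ensemble, pc)
    rej <- attr(surv, "rejections")
    message(sprintf(
      "%s: %d survivors (rejected: flux_cap %d, isotope %d, area %d, enrichment %d)",
      p, rej[["survivors"]], rej[["flux_cap"]], rej[["isotope_window"]],
      rej[["area_ordering"]], rej[["enrichment"]]))
    if (nrow(surv) == 0) {
      return(list(result = empty_result(p), summary = NULL, rejections = rej))
    }
    res <- infer_o2_requirements(surv, pc, weathering = config$weathering,
                                 constants = cst)
    res$feasible <- TRUE
    summ <- dplyr::bind_rows(
      dplyr::mutate(summarize_ensemble(surv$mo_sw * 1e9),
                    quantity = "mo_sw_nM", .before = 1),
      dplyr::mutate(summarize_ensemble(surv$r_in / cst$modern_flux * 100),
                    quantity = "r_in_pct", .before = 1)
    )
    summ$period <- p
    list(result = res, summary = summ, rejections = rej)
  })
  results <- dplyr::bind_rows(purrr::map(per_period, "result"))
  summaries <- dplyr::bind_rows(purrr::map(per_period, "summary"))
  rejections <- tibble::as_tibble(
    t(vapply(per_period, function(x) x$rejections, numeric(5)))
  )
  rejections$period <- config$periods

  out <- structure(
    list(results = results, summaries = summaries, rejections = rejections,
         config = config),
    class = "mo_pipeline"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(results, file.path(out_dir, "period_results.csv"))
    readr::write_csv(tidyr::unnest(summaries, "outliers", keep_empty = TRUE),
                     file.path(out_dir, "period_summaries.csv"))
    readr::write_csv(rejections, file.path(out_dir, "filter_rejections.csv"))
    write_run_config(config, file.path(out_dir, "config.json"))
    manifest <- list(
      seed = config$seed, n_samples = config$n_samples,
      periods = config$periods,
      config_hash = config_hash(config),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# Deterministic hash of a config: polynomial rolling hash over the JSON
# serialization (kept dependency-free; collision resistance is not a goal,
# provenance identification is).
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(write_run_config_string(config)))
  h <- 0
  for (byte in bytes) h <- (h * 131 + byte) %% 2147483647
  sprintf("%08x", h)
}

write_run_config_string <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  paste(readLines(tmp), collapse = "\n")
}

#' @export
tidy.mo_pipeline <- function(x, ...) {
  x$results
}

#' @export
glance.mo_pipeline <- function(x, ...) {
  tibble::tibble(
    n_samples = x$config$n_samples,
    seed = x$config$seed,
    n_periods = length(x$config$periods),
    n_feasible = sum(x$results$feasible)
  )
}

#' @export
print.mo_pipeline <- function(x, ...) {
  cat("Mo mass-balance pipeline run\n")
  cat(sprintf("  ensemble: n = %g, seed = %s\n",
              x$config$n_samples, format(x$config$seed)))
  print(x$results)
  invisible(x)
}

#' Mo retention expected in glacial diamictites
#'
#' Only the sulfide-hosted share of crustal Mo is mobilised by oxidative
#' weathering, so even active sulfide oxidation perturbs the bulk Mo
#' content of regolith weakly: liberating `liberated_fraction` of the
#' sulfide-hosted Mo changes the bulk inventory by their product.
#'
#' @param sulfide_host_fraction Fraction of crustal Mo hosted in sulfide
#'   minerals, in `[0, 1]` (about 0.6 for the modern upper crust).
#' @param liberated_fraction Fraction of sulfide-hosted Mo dissolved, in
#'   `[0, 1]`.
#' @return Percent change in bulk Mo content.
#' @export
#' @examples
#' diamictite_retention(0.60, 0.01)
diamictite_retention <- function(sulfide_host_fraction, liberated_fraction) {
  if (any(sulfide_host_fraction < 0 | sulfide_host_fraction > 1) ||
      any(liberated_fraction < 0 | liberated_fraction > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  sulfide_host_fraction * liberated_fraction * 100
}
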