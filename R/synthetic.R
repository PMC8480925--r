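#' Define a synthetic shale-record scenario
#'
#' A scenario fixes a known "true" ocean state and the sampling properties
#' of a simulated euxinic black-shale record deposited under it. Each
#' simulated shale is a mass-weighted mixture of a detrital end-member
#' (unweathered crustal grains carrying `detrital_mo` ug/g of Mo at
#' `detrital_delta` per mil) and an authigenic component scavenged from
#' seawater, whose concentration follows from the true euxinic burial flux
#' and a per-sample mass accumulation rate, and whose delta98Mo is the
#' true seawater value. Bulk isotope values receive Gaussian analytical
#' noise.
#'
#' @param true_solution One-row tibble from [assemble_solutions()] (or a
#'   one-row `mo_ensemble`): the ocean state the record should record.
#' @param n_samples Number of shale samples to simulate.
#' @param detrital_mo Detrital Mo content (ug/g).
#' @param detrital_delta Detrital delta98Mo (per mil), upper-crust-like.
#' @param mar_range `c(min, max)` bracket for the per-sample mass
#'   accumulation rate (g cm^-2 yr^-1); samples draw MAR log-uniform on
#'   it, reflecting the order-of-magnitude spread of anoxic-basin
#'   sedimentation rates.
#' @param delta_noise_sd Analytical noise on bulk delta98Mo (per mil).
#' @param mo_noise_cv Optional lognormal coefficient of variation applied
#'   to the authigenic enrichment (0 = noise-free concentrations).
#' @param seed Integer RNG seed.
#' @return A list with class `mo_scenario`.
#' @export
synthetic_scenario <- function(true_solution, n_samples = 50,
                               detrital_mo = 2, detrital_delta = 0.3,
                               mar_range = c(0.00125, 0.0125),
                               delta_noise_sd = 0.05, mo_noise_cv = 0,
                               seed = 1) {
  stopifnot(
    nrow(true_solution) == 1,
    n_samples >= 1,
    detrital_mo >= 0,
    length(mar_range) == 2, mar_range[1] > 0, mar_range[1] < mar_range[2],
    delta_noise_sd >= 0, mo_noise_cv >= 0
  )
  structure(
    list(true_solution = tibble::as_tibble(true_solution),
         n_samples = as.integer(n_samples),
         detrital_mo = detrital_mo, detrital_delta = detrital_delta,
         mar_range = mar_range, delta_noise_sd = delta_noise_sd,
         mo_noise_cv = mo_noise_cv, seed = seed),
    class = "mo_scenario"
  )
}

#' Simulate a euxinic shale record from a known ocean state
#'
#' For each sample: draw a mass accumulation rate log-uniform on the
#' scenario bracket, compute the authigenic enrichment implied by the true
#' euxinic burial flux at that rate, mix it with the detrital end-member
#' (exact mass balance: bulk Mo = detrital + authigenic; bulk delta is the
#' concentration-weighted mean of the end-member compositions), and add
#' Gaussian analytical noise to the bulk isotope value.
#'
#' @param scenario A [synthetic_scenario()].
#' @param constants A [mo_constants()] list.
#' @return Tibble of class `mo_shale_record`: `sample_id`, `mar`,
#'   `auth_mo`, `bulk_mo` (ug/g), `auth_fraction`, `bulk_delta` (per
#'   mil). Attribute `scenario` holds the generating scenario.
#' @export
#' @examples
#' truth <- assemble_solutions(tibble::tibble(
#'   mo_sw = 25e-9, delta_in = 0.5,
#'   b_fe = 2e6, b_mn = 2e6, b_sad = 3e8, b_eux = 1e9,
#'   area_fe = 2.52e8, area_mn = 3.6e6, area_sad = 9e7, area_eux = 1.44e7
#' ))
#' generate_shale_record(synthetic_scenario(truth, n_samples = 10))
generate_shale_record <- function(scenario, constants = mo_constants()) {
  stopifnot(inherits(scenario, "mo_scenario"))
  old <- withr_seed(scenario$seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- scenario$n_samples
  truth <- scenario$true_solution
  mar <- exp(stats::runif(n, log(scenario$mar_range[1]),
                          log(scenario$mar_range[2])))
  auth <- predicted_euxinic_enrichment(truth$b_eux, truth$mo_sw, mar,
                                       constants$m_mo)
  if (scenario$mo_noise_cv > 0) {
    sdlog <- sqrt(log(1 + scenario$mo_noise_cv^2))
    auth <- auth * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  }
  bulk_mo <- scenario$detrital_mo + auth
  auth_fraction <- ifelse(bulk_mo > 0, auth / bulk_mo, 0)
  bulk_delta <- ifelse(
    bulk_mo > 0,
    (scenario$detrital_mo * scenario$detrital_delta +
       auth * truth$delta_sw) / bulk_mo,
    scenario$detrital_delta
  ) + stats::rnorm(n, 0, scenario$delta_noise_sd)
  out <- tibble::tibble(
    sample_id = seq_len(n), mar = mar, auth_mo = auth, bulk_mo = bulk_mo,
    auth_fraction = auth_fraction, bulk_delta = bulk_delta
  )
  attr(out, "scenario") <- scenario
  class(out) <- c("mo_shale_record", class(out))
  out
}

#' Derive record filter windows from a (synthetic) shale record
#'
#' Mirrors how the per-period constraint windows bracket record maxima:
#' the heaviest bulk delta98Mo is the best available estimate of seawater
#' (shales are detritally diluted toward lighter values, never heavier),
#' and the largest bulk Mo concentration estimates the maximum authigenic
#' enrichment. Both windows are padded by a relative fraction; the
#' enrichment window's lower bound is floored at 2 ug/g, below which
#' apparent enrichments may be purely detrital.
#'
#' @param record A tibble with `bulk_mo` and `bulk_delta` columns.
#' @param pad Relative half-width of the windows.
#' @param mar_max,mar_min MAR bracket for the derived constraints.
#' @param flux_cap Flux cap (mol/yr) for the derived constraints.
#' @param delta_halfwidth_floor Minimum half-width of the delta window
#'   (per mil), so near-zero maxima still get an analytically sensible
#'   window.
#' @return One-row [period_constraints()]-shaped tibble
#'   (`period = "synthetic"`).
#' @export
derive_filter_windows <- function(record, pad = 0.15,
                                  mar_max = 0.0125, mar_min = 0.00125,
                                  flux_cap = 1.35e8,
                                  delta_halfwidth_floor = 0.1) {
  if (nrow(record) == 0) stop("`record` is empty", call. = FALSE)
  mo_max <- max(record$bulk_mo)
  delta_max <- max(record$bulk_delta)
  enr_min <- max(2, mo_max * (1 - pad))
  enr_max <- max(enr_min, mo_max * (1 + pad))
  hw <- max(delta_halfwidth_floor, pad * abs(delta_max))
  tibble::tibble(
    period = "synthetic",
    age_ga = NA_character_,
    delta_min = delta_max - hw,
    delta_max = delta_max + hw,
    enr_min = enr_min,
    enr_max = enr_max,
    mar_max = mar_max,
    mar_min = mar_min,
    flux_cap = flux_cap
  )
}

#' End-to-end parameter-recovery experiment
#'
#' Generates a shale record from the scenario's true ocean state, derives
#' filter windows from that record alone, filters a Monte Carlo ensemble
#' against them, and reports whether the true seawater Mo concentration,
#' seawater delta98Mo and input rate fall inside the hull (min-max) of the
#' surviving solutions — the basic consistency the record-filtering
#' inference should have.
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_mc Ensemble size to sample when `ensemble` is not supplied.
#' @param seed Seed for the sampled ensemble.
#' @param ensemble Optional pre-sampled ensemble to filter (lets many
#'   scenarios share one ensemble).
#' @param pad Window padding passed to [derive_filter_windows()].
#' @param constants A [mo_constants()] list.
#' @return One-row tibble: `feasible` (any survivors), `true_passes`
#'   (the true solution is itself admitted by the windows derived from
#'   its own record — when it is not, e.g. because its required input
#'   exceeds the modern flux cap, the record cannot inform on it and
#'   coverage is meaningless), `n_survivors`, coverage flags
#'   `covered_mo_sw`, `covered_delta_sw`, `covered_r_in`, and quantile
#'   positions `q_mo_sw`, `q_delta_sw`, `q_r_in` of the true values in
#'   the survivor distributions (`NA` when infeasible).
#' @export
recovery_experiment <- function(scenario, n_mc = 2e5, seed = 1,
                                ensemble = NULL, pad = 0.15,
                                constants = mo_constants()) {
  stopifnot(inherits(scenario, "mo_scenario"))
  record <- generate_shale_record(scenario, constants)
  windows <- derive_filter_windows(record, pad = pad,
                                   flux_cap = constants$modern_flux)
  if (is.null(ensemble)) {
    ensemble <- sample_ensemble(n_mc, seed, constants = constants)
  }
  surv <- apply_filters(ensemble, windows)
  truth <- scenario$true_solution
  true_passes <- nrow(apply_filters(truth, windows)) == 1
  if (nrow(surv) == 0) {
    return(tibble::tibble(
      feasible = FALSE, true_passes = true_passes, n_survivors = 0L,
      covered_mo_sw = NA, covered_delta_sw = NA, covered_r_in = NA,
      q_mo_sw = NA_real_, q_delta_sw = NA_real_, q_r_in = NA_real_
    ))
  }
  hull <- function(x, v) v >= min(x) & v <= max(x)
  tibble::tibble(
    feasible = TRUE,
    true_passes = true_passes,
    n_survivors = nrow(surv),
    covered_mo_sw = hull(surv$mo_sw, truth$mo_sw),
    covered_delta_sw = hull(surv$delta_sw, truth$delta_sw),
    covered_r_in = hull(surv$r_in, truth$r_in),
    q_mo_sw = stats::ecdf(surv$mo_sw)(truth$mo_sw),
    q_delta_sw = stats::ecdf(surv$delta_sw)(truth$delta_sw),
    q_r_in = stats::ecdf(surv$r_in)(truth$r_in)
  )
}
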