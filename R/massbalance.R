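#' Mo removal rate to a sedimentary sink
#'
#' Steady-state removal of Mo to one sedimentary environment is the product
#' of an effective burial rate constant, the seawater Mo concentration, and
#' the depositional area of that environment:
#' \deqn{R_{out,i} = b_i \, [Mo]_{sw} \, A_i}
#'
#' @param b Effective burial rate constant (liter km^-2 yr^-1). The
#'   constant folds the areal Mo burial rate and the sediment/seawater
#'   distribution coefficient into a single calibrated value.
#' @param mo_sw Seawater Mo concentration (mol/liter).
#' @param area Depositional area (km^2).
#' @return Removal rate in mol/yr. Vectorised over all arguments.
#' @export
#' @examples
#' sink_removal_rate(b = 1e9, mo_sw = 5e-9, area = 1e6)
sink_removal_rate <- function(b, mo_sw, area) {
  if (any(!is.finite(b)) || any(!is.finite(mo_sw)) || any(!is.finite(area))) {
    stop("all inputs must be finite", call. = FALSE)
  }
  if (any(b < 0) || any(mo_sw < 0) || any(area < 0)) {
    stop("negative rate constant, concentration, or area", call. = FALSE)
  }
  b * mo_sw * area
}

#' Seawater delta98Mo implied by input composition and sink fractions
#'
#' Isotope mass balance at steady state requires the flux-weighted mean of
#' the sediment compositions to equal the input composition:
#' \eqn{\delta_{in} = \sum_i f_i \delta_i}. Sediments are lighter than
#' seawater by their fractionation factor, \eqn{\delta_i = \delta_{sw} -
#' \Delta_{sw-i}} (euxinic sediments record seawater exactly,
#' \eqn{\Delta = 0}), so seawater is driven heavier than the input by the
#' removal of light Mo:
#' \deqn{\delta_{sw} = \delta_{in} + \sum_i f_i \Delta_{sw-i}}
#'
#' @param delta_in Riverine input delta98Mo (per mil).
#' @param f_fe,f_mn,f_sad,f_eux Fraction of total Mo removal carried by
#'   each sink; must sum to 1.
#' @param offsets Named per-sink fractionation factors (per mil); defaults
#'   to `mo_constants()$delta_offset`.
#' @param tol Tolerance on the fraction sum.
#' @return Seawater delta98Mo (per mil), vectorised.
#' @export
#' @examples
#' solve_delta_sw(0.5, f_fe = 0, f_mn = 0, f_sad = 0, f_eux = 1)
solve_delta_sw <- function(delta_in, f_fe, f_mn, f_sad, f_eux,
                           offsets = mo_constants()$delta_offset,
                           tol = 1e-9) {
  fsum <- f_fe + f_mn + f_sad + f_eux
  if (any(abs(fsum - 1) > tol)) {
    stop("sink fractions must sum to 1", call. = FALSE)
  }
  delta_in + f_fe * offsets[["fe"]] + f_mn * offsets[["mn"]] +
    f_sad * offsets[["sad"]] + f_eux * offsets[["eux"]]
}

#' Predicted authigenic Mo enrichment of euxinic sediments
#'
#' The areal Mo burial flux into euxinic sediments
#' (\eqn{b_{eux} [Mo]_{sw}}, mol km^-2 yr^-1) divided by the areal
#' sediment mass accumulation rate gives the authigenic Mo concentration a
#' euxinic shale records:
#' \deqn{[Mo]_{auth} = \frac{b_{eux}\,[Mo]_{sw}\,M_{Mo}}{MAR \times 10^{10}}
#'   \times 10^{6} \;\; \mu g\,g^{-1}}
#' where \eqn{10^{10}} converts cm^2 to km^2. Slowly accumulating
#' sediments (small MAR) concentrate the same Mo flux into less mass and
#' are therefore more enriched.
#'
#' @param b_eux Euxinic burial rate constant (liter km^-2 yr^-1).
#' @param mo_sw Seawater Mo concentration (mol/liter).
#' @param mar Mass accumulation rate (g cm^-2 yr^-1), must be > 0.
#' @param m_mo Molar mass of Mo (g/mol).
#' @return Authigenic enrichment in micrograms Mo per gram sediment.
#' @export
#' @examples
#' predicted_euxinic_enrichment(1e9, 105e-9, mar = 0.0125)
predicted_euxinic_enrichment <- function(b_eux, mo_sw, mar,
                                         m_mo = mo_constants()$m_mo) {
  if (any(mar <= 0)) stop("`mar` must be positive", call. = FALSE)
  if (any(b_eux < 0) || any(mo_sw < 0)) {
    stop("negative rate constant or concentration", call. = FALSE)
  }
  (b_eux * mo_sw * m_mo) / (mar * 1e10) * 1e6
}

#' Assemble full mass-balance solutions from sampled parameters
#'
#' Takes a data frame of candidate ocean states — one row per state, with
#' seawater concentration, input isotope composition, per-sink burial rate
#' constants and depositional areas — and derives everything the filters
#' and flux inference consume: per-sink removal rates, the total input
#' rate required at steady state, sink fractions, seawater and per-sink
#' sediment delta98Mo, and the interval of euxinic authigenic enrichments
#' spanned by the assumed mass-accumulation-rate bracket.
#'
#' Sink fractions are computed as \eqn{f_i = b_i A_i / \sum_j b_j A_j},
#' which is the exact steady-state value and remains defined in the
#' degenerate limit `mo_sw = 0` (all fluxes zero); such rows are flagged
#' `degenerate`.
#'
#' @param params Data frame with columns `mo_sw`, `delta_in`, `b_fe`,
#'   `b_mn`, `b_sad`, `b_eux`, `area_fe`, `area_mn`, `area_sad`,
#'   `area_eux` (areas in km^2, summing to the configured seafloor area).
#' @param mar_max,mar_min Mass accumulation rate bracket (g cm^-2 yr^-1)
#'   at which the euxinic enrichment interval is evaluated; `enr_lo` is
#'   the enrichment at `mar_max` (fast burial, dilute) and `enr_hi` at
#'   `mar_min` (slow burial, concentrated).
#' @param constants A [mo_constants()] list.
#' @return A tibble: the input columns plus `r_fe`, `r_mn`, `r_sad`,
#'   `r_eux`, `r_in`, `f_fe`, `f_mn`, `f_sad`, `f_eux`, `delta_sw`,
#'   `enr_lo`, `enr_hi`, `degenerate`.
#' @export
#' @examples
#' params <- tibble::tibble(
#'   mo_sw = 5e-9, delta_in = 0.5,
#'   b_fe = 2e6, b_mn = 2e6, b_sad = 3e8, b_eux = 1.2e9,
#'   area_fe = 1.8e8, area_mn = 1.8e7, area_sad = 1.4e8, area_eux = 2.2e7
#' )
#' assemble_solutions(params)
assemble_solutions <- function(params, mar_max = 0.0125, mar_min = 0.00125,
                               constants = mo_constants()) {
  needed <- c("mo_sw", "delta_in",
              paste0("b_", sink_classes()), paste0("area_", sink_classes()))
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0) {
    stop("`params` is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  total_area <- params$area_fe + params$area_mn + params$area_sad +
    params$area_eux
  if (any(total_area <= 0)) {
    stop("all-zero depositional areas: degenerate solution", call. = FALSE)
  }
  if (any(abs(total_area / constants$seafloor_area - 1) > 1e-6)) {
    stop("depositional areas must sum to the configured seafloor area",
         call. = FALSE)
  }
  off <- constants$delta_offset

  out <- dplyr::mutate(
    tibble::as_tibble(params),
    r_fe  = sink_removal_rate(.data$b_fe,  .data$mo_sw, .data$area_fe),
    r_mn  = sink_removal_rate(.data$b_mn,  .data$mo_sw, .data$area_mn),
    r_sad = sink_removal_rate(.data$b_sad, .data$mo_sw, .data$area_sad),
    r_eux = sink_removal_rate(.data$b_eux, .data$mo_sw, .data$area_eux),
    r_in  = .data$r_fe + .data$r_mn + .data$r_sad + .data$r_eux,
    ba_total = .data$b_fe * .data$area_fe + .data$b_mn * .data$area_mn +
      .data$b_sad * .data$area_sad + .data$b_eux * .data$area_eux,
    f_fe  = .data$b_fe  * .data$area_fe  / .data$ba_total,
    f_mn  = .data$b_mn  * .data$area_mn  / .data$ba_total,
    f_sad = .data$b_sad * .data$area_sad / .data$ba_total,
    f_eux = .data$b_eux * .data$area_eux / .data$ba_total,
    delta_sw = .data$delta_in + .data$f_fe * off[["fe"]] +
      .data$f_mn * off[["mn"]] + .data$f_sad * off[["sad"]] +
      .data$f_eux * off[["eux"]],
    enr_lo = predicted_euxinic_enrichment(.data$b_eux, .data$mo_sw,
                                          mar_max, constants$m_mo),
    enr_hi = predicted_euxinic_enrichment(.data$b_eux, .data$mo_sw,
                                          mar_min, constants$m_mo),
    degenerate = .data$mo_sw == 0
  )
  out$ba_total <- NULL
  attr(out, "mar_max") <- mar_max
  attr(out, "mar_min") <- mar_min
  out
}

#' Per-sink sediment delta98Mo for assembled solutions
#'
#' Sediment compositions are offset below seawater by the per-sink
#' fractionation factor; euxinic sediments record seawater exactly.
#'
#' @param solutions A tibble from [assemble_solutions()].
#' @param constants A [mo_constants()] list.
#' @return `solutions` with added columns `delta_fe`, `delta_mn`,
#'   `delta_sad`, `delta_eux`.
#' @export
sediment_deltas <- function(solutions, constants = mo_constants()) {
  off <- constants$delta_offset
  dplyr::mutate(
    solutions,
    delta_fe  = .data$delta_sw - off[["fe"]],
    delta_mn  = .data$delta_sw - off[["mn"]],
    delta_sad = .data$delta_sw - off[["sad"]],
    delta_eux = .data$delta_sw - off[["eux"]]
  )
}
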