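#' Physical constants and model configuration
#'
#' Central configuration block for the Mo ocean mass balance. All downstream
#' functions take a `constants` list so that every fixed quantity — molar
#' mass, total seafloor area, per-sink isotope fractionation factors, the
#' modern riverine Mo flux, the riverine Mo/S molar ratio and the assumed
#' hydrothermal share of the modern flux — can be overridden in one place.
#'
#' The four sedimentary sinks are, in fixed order: Fe-oxide-bearing
#' sediments (`fe`), Mn-oxide-bearing sediments (`mn`), sulfidic-at-depth
#' sediments (`sad`), and euxinic sediments (`eux`). Fractionation factors
#' `delta_offset` are expressed as the offset of seawater above the
#' sediment, so sediments are isotopically lighter than seawater by
#' `delta_offset` per mil (euxinic sediments capture seawater exactly,
#' offset 0).
#'
#' @param m_mo Molar mass of Mo (g/mol).
#' @param seafloor_area Total seafloor area (km^2); depositional areas of
#'   the four sinks always sum to this.
#' @param delta_offset Named numeric of per-sink fractionation factors
#'   (per mil), names `fe`, `mn`, `sad`, `eux`.
#' @param modern_flux Modern riverine Mo flux (mol/yr).
#' @param mo_s_ratio Molar Mo/S ratio of modern rivers, used to convert Mo
#'   fluxes to sulfate-sulfur fluxes (see `scripts/derive_mo_s_ratio.R`).
#' @param hydrothermal_fraction Fraction of the modern Mo flux attributed
#'   to hydrothermal sources and subtracted before weathering inferences.
#' @param closure_tol Relative tolerance for mass/isotope closure checks.
#'
#' @return A named list of constants with class `mo_constants`.
#' @export
#' @examples
#' mo_constants()$delta_offset
mo_constants <- function(m_mo = 95.95,
                         seafloor_area = 3.6e8,
                         delta_offset = c(fe = 1.25, mn = 3, sad = 0.7, eux = 0),
                         modern_flux = 1.35e8,
                         mo_s_ratio = 4.5e-5,
                         hydrothermal_fraction = 0.01,
                         closure_tol = 1e-12) {
  stopifnot(
    m_mo > 0, seafloor_area > 0, modern_flux > 0,
    mo_s_ratio > 0, hydrothermal_fraction >= 0, closure_tol > 0
  )
  if (!setequal(names(delta_offset), sink_classes())) {
    stop("`delta_offset` must be named over the four sinks: ",
         paste(sink_classes(), collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      m_mo = m_mo,
      seafloor_area = seafloor_area,
      delta_offset = delta_offset[sink_classes()],
      modern_flux = modern_flux,
      mo_s_ratio = mo_s_ratio,
      hydrothermal_fraction = hydrothermal_fraction,
      closure_tol = closure_tol
    ),
    class = "mo_constants"
  )
}

#' The four sedimentary Mo sinks
#'
#' @return Character vector of the sink identifiers in canonical order:
#'   `"fe"` (Fe oxides), `"mn"` (Mn oxides), `"sad"` (sulfidic at depth),
#'   `"eux"` (euxinic).
#' @export
sink_classes <- function() c("fe", "mn", "sad", "eux")
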