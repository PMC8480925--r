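#' Two-regime oxidative-weathering curve parameters
#'
#' Global Mo release from the oxidative weathering of crustal sulfides is
#' modelled as two regimes in atmospheric PO2. At low PO2 the reaction is
#' O2-limited and the flux scales with PO2 (order `order_n`); at high PO2
#' the supply of pyrite in weathering soils becomes limiting and the flux
#' plateaus at the modern riverine Mo flux, where sulfides dissolve
#' completely. Biologically mediated sulfide oxidation multiplies the
#' O2-limited branch by `biotic_factor` (about one order of magnitude
#' faster than the abiotic reaction); the plateau is sulfide supply and
#' is biology-independent.
#'
#' The defaults calibrate the abiotic O2-limited branch to reach the
#' plateau at PO2 = 10^-3.5 PAL, the log-midpoint of the modelled
#' transition zone (10^-4 to 10^-3 PAL).
#'
#' @param plateau_flux Sulfide-limited Mo release flux (mol Mo/yr);
#'   default the modern riverine flux.
#' @param transition_po2 PAL at which the abiotic O2-limited branch
#'   reaches the plateau.
#' @param order_n Reaction order of the O2-limited branch in PO2.
#' @param biotic_factor Rate multiplier for biotic sulfide oxidation
#'   (>= 1).
#' @return A validated list with class `mo_weathering`.
#' @export
weathering_params <- function(plateau_flux = 1.35e8,
                              transition_po2 = 10^-3.5,
                              order_n = 1,
                              biotic_factor = 10) {
  stopifnot(
    plateau_flux > 0,
    transition_po2 > 0, transition_po2 <= 1,
    order_n > 0,
    biotic_factor >= 1
  )
  structure(
    list(plateau_flux = plateau_flux, transition_po2 = transition_po2,
         order_n = order_n, biotic_factor = biotic_factor),
    class = "mo_weathering"
  )
}

#' Mo release flux at a given atmospheric PO2
#'
#' \deqn{F(P) = F_{plateau} \times \min\{1,\; k (P/P_t)^n\}}
#' with `k = biotic_factor` for biotic oxidation and 1 otherwise.
#' Continuous and non-decreasing in PO2.
#'
#' @param po2 Atmospheric O2 partial pressure (PAL), >= 0. Vectorised.
#' @param params A [weathering_params()] object.
#' @param biotic Use the biotic rate multiplier?
#' @return Mo release flux, mol Mo/yr.
#' @export
#' @examples
#' flux_at_po2(10^-5.5, weathering_params())
flux_at_po2 <- function(po2, params = weathering_params(), biotic = FALSE) {
  if (any(po2 < 0)) stop("`po2` must be non-negative", call. = FALSE)
  k <- if (biotic) params$biotic_factor else 1
  params$plateau_flux *
    pmin(1, k * (po2 / params$transition_po2)^params$order_n)
}

#' Minimum PO2 required to deliver a given Mo flux
#'
#' Exact inverse of [flux_at_po2()] on the O2-limited branch:
#' \deqn{P = P_t \left(\frac{F}{k\,F_{plateau}}\right)^{1/n}}
#' Fluxes above the plateau cannot be delivered by sulfide weathering at
#' any PO2 and raise an error; non-positive fluxes return `NA` (no O2
#' requirement demonstrable).
#'
#' @param flux Mo flux (mol Mo/yr). Vectorised.
#' @inheritParams flux_at_po2
#' @return PO2 in PAL.
#' @export
#' @examples
#' po2_for_flux(5.14e5, weathering_params(), biotic = TRUE)
po2_for_flux <- function(flux, params = weathering_params(), biotic = FALSE) {
  if (any(flux > params$plateau_flux)) {
    stop("flux exceeds the sulfide-limited maximum", call. = FALSE)
  }
  k <- if (biotic) params$biotic_factor else 1
  out <- params$transition_po2 *
    (flux / (k * params$plateau_flux))^(1 / params$order_n)
  out[flux <= 0] <- NA_real_
  out
}

#' PO2 at which the O2-limited branch meets the plateau
#'
#' The regime transition marks the shift of the limiting reactant from O2
#' to pyrite supply; for the biotic curve it sits a factor
#' `biotic_factor^(1/n)` below the abiotic transition.
#'
#' @inheritParams flux_at_po2
#' @return PO2 in PAL.
#' @export
#' @examples
#' regime_transition(weathering_params())
regime_transition <- function(params = weathering_params(), biotic = FALSE) {
  k <- if (biotic) params$biotic_factor else 1
  params$transition_po2 * k^(-1 / params$order_n)
}

#' Tabulate the weathering curve over a PO2 grid
#'
#' @param params A [weathering_params()] object.
#' @param log10_range Log10 PAL range of the grid.
#' @param n Number of grid points (log-spaced).
#' @return Tibble with `po2`, `variant` (`"abiotic"`/`"biotic"`), `flux`.
#' @export
weathering_curve <- function(params = weathering_params(),
                             log10_range = c(-8, 0), n = 200) {
  po2 <- 10^seq(log10_range[1], log10_range[2], length.out = n)
  dplyr::bind_rows(
    tibble::tibble(po2 = po2, variant = "abiotic",
                   flux = flux_at_po2(po2, params, biotic = FALSE)),
    tibble::tibble(po2 = po2, variant = "biotic",
                   flux = flux_at_po2(po2, params, biotic = TRUE))
  )
}
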