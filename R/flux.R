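#' Minimum record-consistent Mo input
#'
#' The smallest total Mo input rate among the filtered solutions: the
#' lower limit on riverine Mo delivery that the shale record of a period
#' demands of any steady-state ocean.
#'
#' @param filtered A non-empty filtered solutions tibble
#'   (see [apply_filters()]).
#' @param modern_flux Modern riverine Mo flux (mol/yr) used for the
#'   percentage.
#' @return One-row tibble with `r_in_min` (mol/yr) and `r_in_min_pct`
#'   (% of the modern flux).
#' @export
#' @examples
#' minimum_input(tibble::tibble(r_in = c(3e6, 5e6, 9e6)))
minimum_input <- function(filtered, modern_flux = mo_constants()$modern_flux) {
  if (nrow(filtered) == 0) {
    stop("no surviving solutions: filters are infeasible for this ensemble",
         call. = FALSE)
  }
  r_min <- min(filtered$r_in)
  tibble::tibble(r_in_min = r_min, r_in_min_pct = r_min / modern_flux * 100)
}

#' Subtract the hydrothermal Mo allowance
#'
#' Hydrothermal fluids could have supplied Mo to an anoxic ocean without
#' any oxidative weathering; to avoid overstating the weathering flux, a
#' fixed share of the modern riverine flux (default 1%) is subtracted
#' from the required input. Results are floored at zero — a zero means the
#' record can be satisfied by hydrothermal Mo alone and no weathering flux
#' is demonstrable.
#'
#' @param r Mo input rate(s), mol/yr, >= 0.
#' @param modern_flux Modern riverine Mo flux (mol/yr).
#' @param fraction Hydrothermal share of the modern flux.
#' @return Corrected rate(s), mol/yr; attribute
#'   `hydrothermal_dominated` is a logical vector marking floored values.
#' @export
#' @examples
#' hydrothermal_correct(1.0e7)
hydrothermal_correct <- function(r, modern_flux = mo_constants()$modern_flux,
                                 fraction = mo_constants()$hydrothermal_fraction) {
  if (any(r < 0)) stop("`r` must be non-negative", call. = FALSE)
  corrected <- pmax(0, r - fraction * modern_flux)
  dominated <- r - fraction * modern_flux <= 0
  if (any(dominated)) {
    message("hydrothermal-dominated: ", sum(dominated),
            " flux value(s) floored at 0")
  }
  structure(corrected, hydrothermal_dominated = dominated)
}

#' Convert a Mo flux to the sulfate-sulfur flux that carried it
#'
#' Mo reaches rivers during the oxidative dissolution of crustal sulfides,
#' so the riverine Mo flux and the sulfate flux are linked by the Mo/S
#' ratio of the weathered sulfides, for which the modern riverine molar
#' Mo/S ratio is the proxy: `S = Mo / ratio`.
#'
#' @param r_mo Mo flux (mol Mo/yr).
#' @param mo_s_ratio Molar Mo/S ratio (> 0); see
#'   `scripts/derive_mo_s_ratio.R` for the default's derivation.
#' @return Sulfate-S flux, mol S/yr.
#' @export
#' @examples
#' mo_to_sulfur(5.14e5)
mo_to_sulfur <- function(r_mo, mo_s_ratio = mo_constants()$mo_s_ratio) {
  if (!is.numeric(mo_s_ratio) || any(mo_s_ratio <= 0)) {
    stop("`mo_s_ratio` must be positive", call. = FALSE)
  }
  r_mo / mo_s_ratio
}

#' O2 consumed by pyrite oxidation for a given sulfate flux
#'
#' Complete oxidation of pyrite sulfur to sulfate,
#' \deqn{FeS_2 + \tfrac{7}{2} O_2 + H_2O \rightarrow Fe^{2+} +
#'   2\,SO_4^{2-} + 2\,H^+}
#' consumes 7/2 mol O2 per 2 mol sulfate-S (iron is assumed to remain
#' Fe(II), so all oxidizing power goes to sulfate). The O2 flux is
#' returned in Tmol/yr.
#'
#' @param s_flux Sulfate-S flux (mol S/yr), >= 0.
#' @return O2 consumption, Tmol O2/yr.
#' @export
#' @examples
#' sulfur_to_o2(1.14e10)
sulfur_to_o2 <- function(s_flux) {
  if (any(s_flux < 0)) stop("`s_flux` must be non-negative", call. = FALSE)
  s_flux * (7 / 2) / 2 * 1e-12
}

#' Minimum O2 requirements implied by one period's Mo record
#'
#' Chains the whole inference for a period: filter the ensemble (if not
#' already filtered), take the minimum surviving Mo input, subtract the
#' hydrothermal allowance, convert to a sulfate flux and to an O2
#' consumption flux, and invert the oxidative-weathering curve for the
#' minimum equivalent atmospheric PO2 under abiotic and biotic sulfide
#' oxidation.
#'
#' @param ensemble An assembled ensemble (filtered or raw).
#' @param period Period name or one-row [period_constraints()] tibble.
#' @param weathering A [weathering_params()] object.
#' @param constants A [mo_constants()] list.
#' @return One-row tibble (class `mo_flux_result`): `period`,
#'   `n_survivors`, `r_in_min`, `r_in_min_pct`, `r_corrected`, `s_flux`,
#'   `o2_flux` (Tmol/yr), `po2_abiotic`, `po2_biotic` (PAL; `NA` with a
#'   message when the corrected flux is zero and no O2 requirement is
#'   demonstrable).
#' @export
#' @examples
#' ens <- sample_ensemble(2e5, seed = 1)
#' infer_o2_requirements(ens, "whiff")
infer_o2_requirements <- function(ensemble, period,
                                  weathering = weathering_params(),
                                  constants = mo_constants()) {
  if (is.character(period)) period <- period_constraints(period)
  stopifnot(nrow(period) == 1)
  filtered <- if (inherits(ensemble, "mo_filtered")) {
    ensemble
  } else {
    apply_filters(ensemble, period)
  }
  if (nrow(filtered) == 0) {
    stop("no surviving solutions for period '", period$period, "'",
         call. = FALSE)
  }
  mi <- minimum_input(filtered, constants$modern_flux)
  r_corr <- suppressMessages(
    hydrothermal_correct(mi$r_in_min, constants$modern_flux,
                         constants$hydrothermal_fraction)
  )
  dominated <- attr(r_corr, "hydrothermal_dominated")
  r_corr <- as.numeric(r_corr)
  s_flux <- mo_to_sulfur(r_corr, constants$mo_s_ratio)
  o2 <- sulfur_to_o2(s_flux)
  if (dominated) {
    message("period '", period$period,
            "': corrected flux is 0, no O2 requirement demonstrable")
    po2_ab <- NA_real_
    po2_bi <- NA_real_
  } else {
    po2_ab <- po2_for_flux(r_corr, weathering, biotic = FALSE)
    po2_bi <- po2_for_flux(r_corr, weathering, biotic = TRUE)
  }
  out <- tibble::tibble(
    period = period$period,
    n_survivors = nrow(filtered),
    r_in_min = mi$r_in_min,
    r_in_min_pct = mi$r_in_min_pct,
    r_corrected = r_corr,
    s_flux = s_flux,
    o2_flux = o2,
    po2_abiotic = po2_ab,
    po2_biotic = po2_bi
  )
  class(out) <- c("mo_flux_result", class(out))
  out
}

#' The coarsened parameter box for minimum-input cross-validation
#'
#' Defines a reduced search space on which an exhaustive grid search and
#' plain Monte Carlo can both locate the constrained minimum Mo input at
#' desk scale. Every pinned coordinate is pinned by a property of the
#' minimum, not by convenience:
#'
#' * burial rate constants sit at their range midpoints (the mode of
#'   their sampling distributions);
#' * the seawater-Mo axis is restricted to the interval on which the
#'   period's enrichment filter can pass at the pinned euxinic rate
#'   constant — outside it every candidate fails filter 4 regardless of
#'   the other coordinates;
#' * the Mn-oxide area sits at the bottom of its range: Mn oxides have
#'   the same rate constant as Fe oxides but a larger fractionation
#'   factor, so any Mn area is strictly dominated by Fe area in a
#'   minimum-input solution;
#' * the sulfidic-at-depth area sits just above the euxinic area: SAD
#'   burial is two orders of magnitude costlier per km^2 than Fe-oxide
#'   burial, so at the minimum its area drops to its lower bound, which
#'   is the strict euxinic-ordering constraint;
#' * only the area ratio matters after renormalisation, so the Fe-oxide
#'   raw fraction is fixed at 100 and the euxinic raw fraction varies.
#'
#' The free coordinates are seawater Mo, input delta98Mo and the euxinic
#' area fraction.
#'
#' @param period Period name or one-row [period_constraints()] tibble.
#' @param ranges A [sampling_ranges()] object.
#' @param constants A [mo_constants()] list.
#' @return List with `mo_sw = c(lo, hi)` (mol/liter), `delta_in`,
#'   `eux_raw` ranges, pinned `fe_raw`, `mn_raw`, `sad_over_eux`, and
#'   `b_mid`, the named midpoint rate constants.
#' @export
coarsened_box <- function(period, ranges = sampling_ranges(),
                          constants = mo_constants()) {
  if (is.character(period)) period <- period_constraints(period)
  stopifnot(nrow(period) == 1)
  b_mid <- vapply(ranges$b, mean, numeric(1))
  names(b_mid) <- sink_classes()
  # enr(mar_max) <= enr_max and enr(mar_min) >= enr_min at pinned b_eux
  mo_hi <- period$enr_max * period$mar_max * 1e10 /
    (b_mid[["eux"]] * constants$m_mo) * 1e-6
  mo_lo <- period$enr_min * period$mar_min * 1e10 /
    (b_mid[["eux"]] * constants$m_mo) * 1e-6
  mo_lo <- max(mo_lo, ranges$mo_sw[1])
  mo_hi <- min(mo_hi, ranges$mo_sw[2])
  if (mo_lo >= mo_hi) {
    stop("enrichment window infeasible at midpoint rate constants",
         call. = FALSE)
  }
  list(
    mo_sw = c(mo_lo, mo_hi),
    delta_in = ranges$delta_in,
    eux_raw = ranges$area_pct$eux,
    fe_raw = ranges$area_pct$fe[2],
    mn_raw = ranges$area_pct$mn[1],
    sad_over_eux = 1.01,
    b_mid = b_mid
  )
}

# Assemble + filter candidates on the coarsened box; shared by the grid
# and Monte Carlo searches.
coarsened_minimum <- function(mo_sw, delta_in, eux_raw, box, period,
                              constants) {
  raw <- cbind(box$fe_raw, box$mn_raw, box$sad_over_eux * eux_raw, eux_raw)
  pct <- raw / rowSums(raw) * 100
  params <- tibble::tibble(
    mo_sw = mo_sw, delta_in = delta_in,
    b_fe = box$b_mid[["fe"]], b_mn = box$b_mid[["mn"]],
    b_sad = box$b_mid[["sad"]], b_eux = box$b_mid[["eux"]],
    area_fe = pct[, 1] / 100 * constants$seafloor_area,
    area_mn = pct[, 2] / 100 * constants$seafloor_area,
    area_sad = pct[, 3] / 100 * constants$seafloor_area,
    area_eux = pct[, 4] / 100 * constants$seafloor_area
  )
  sol <- assemble_solutions(params, mar_max = period$mar_max,
                            mar_min = period$mar_min, constants = constants)
  apply_filters(sol, period)
}

#' Grid-search oracle for the minimum record-consistent Mo input
#'
#' Exhaustive search over the [coarsened_box()]: seawater Mo (log-spaced
#' on its feasible interval), input delta98Mo (linear) and euxinic area
#' fraction (log-spaced) are gridded, every grid point is assembled and
#' passed through the four record filters, and the minimum surviving
#' input is returned. Serves as the independent oracle against which the
#' Monte Carlo minimum is checked.
#'
#' @inheritParams coarsened_box
#' @param n_mo,n_delta,n_eux Grid resolution per free dimension.
#' @return One-row tibble: `r_in_min`, `r_in_min_pct`, `n_grid`,
#'   `n_feasible`.
#' @export
grid_search_minimum <- function(period, n_mo = 40, n_delta = 40, n_eux = 60,
                                ranges = sampling_ranges(),
                                constants = mo_constants()) {
  if (is.character(period)) period <- period_constraints(period)
  stopifnot(nrow(period) == 1)
  box <- coarsened_box(period, ranges, constants)
  g <- tidyr::expand_grid(
    mo_sw = exp(seq(log(box$mo_sw[1]), log(box$mo_sw[2]),
                    length.out = n_mo)),
    delta_in = seq(box$delta_in[1], box$delta_in[2], length.out = n_delta),
    eux_raw = exp(seq(log(box$eux_raw[1]), log(box$eux_raw[2]),
                      length.out = n_eux))
  )
  surv <- coarsened_minimum(g$mo_sw, g$delta_in, g$eux_raw, box, period,
                            constants)
  if (nrow(surv) == 0) {
    stop("grid search found no feasible point for period '",
         period$period, "'", call. = FALSE)
  }
  mi <- minimum_input(surv, constants$modern_flux)
  tibble::tibble(
    r_in_min = mi$r_in_min, r_in_min_pct = mi$r_in_min_pct,
    n_grid = nrow(g), n_feasible = nrow(surv)
  )
}

#' Monte Carlo minimum on the coarsened parameter box
#'
#' Random-search counterpart of [grid_search_minimum()]: draws the three
#' free coordinates of the [coarsened_box()] at random (seawater Mo and
#' euxinic area log-uniform, input delta98Mo uniform), filters, and
#' returns the minimum surviving input. Checks that plain Monte Carlo and
#' exhaustive search agree on the constrained minimum when they explore
#' the same space.
#'
#' @inheritParams coarsened_box
#' @param n Number of random draws.
#' @param seed RNG seed.
#' @return One-row tibble: `r_in_min`, `r_in_min_pct`, `n_feasible`.
#' @export
mc_search_minimum <- function(period, n = 2e5, seed = 1,
                              ranges = sampling_ranges(),
                              constants = mo_constants()) {
  if (is.character(period)) period <- period_constraints(period)
  stopifnot(nrow(period) == 1)
  box <- coarsened_box(period, ranges, constants)
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- as.integer(n)
  surv <- coarsened_minimum(
    exp(stats::runif(n, log(box$mo_sw[1]), log(box$mo_sw[2]))),
    stats::runif(n, box$delta_in[1], box$delta_in[2]),
    exp(stats::runif(n, log(box$eux_raw[1]), log(box$eux_raw[2]))),
    box, period, constants
  )
  if (nrow(surv) == 0) {
    stop("no feasible draw on the coarsened box for period '",
         period$period, "'", call. = FALSE)
  }
  mi <- minimum_input(surv, constants$modern_flux)
  tibble::tibble(r_in_min = mi$r_in_min, r_in_min_pct = mi$r_in_min_pct,
                 n_feasible = nrow(surv))
}
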