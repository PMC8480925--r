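#' Per-period record constraints
#'
#' The shale record between 3.2 and 2.0 Ga is divided into four categories
#' with distinct Mo enrichment and isotope character: the Paleo-Mesoarchean
#' (3.2-2.8 Ga), the Neoarchean (2.8->2.5 Ga), the anomalous 2.5 Ga "whiff"
#' interval (kept separate from the rest of the Neoarchean), and the
#' Paleoproterozoic (2.5-2.0 Ga). For each, the record supplies a window
#' of plausible seawater delta98Mo (the heaviest euxinic-shale values,
#' which carry the least detrital dilution) and a window of maximum
#' authigenic Mo enrichment; all periods share the mass-accumulation-rate
#' bracket and the modern-river Mo flux cap.
#'
#' @param period Optional character vector to subset by `period` name.
#' @return A tibble with columns `period`, `age_ga`, `delta_min`,
#'   `delta_max` (per mil), `enr_min`, `enr_max` (ug/g), `mar_max`,
#'   `mar_min` (g cm^-2 yr^-1), `flux_cap` (mol/yr).
#' @export
#' @examples
#' period_constraints()
#' period_constraints("whiff")
period_constraints <- function(period = NULL) {
  tbl <- tibble::tibble(
    period = c("paleo_mesoarchean", "neoarchean", "whiff", "paleoproterozoic"),
    age_ga = c("3.2-2.8", "2.8-2.55", "2.5", "2.5-2.0"),
    delta_min = c(0.45, 0.90, 1.50, 1.30),
    delta_max = c(0.75, 1.20, 1.80, 2.00),
    enr_min = c(2, 5, 35, 40),
    enr_max = c(5, 10, 50, 70),
    mar_max = 0.0125,
    mar_min = 0.00125,
    flux_cap = 1.35e8
  )
  if (!is.null(period)) {
    bad <- setdiff(period, tbl$period)
    if (length(bad) > 0) {
      stop("unknown period(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    tbl <- tbl[match(period, tbl$period), ]
  }
  tbl
}

#' Record filters for mass-balance solutions
#'
#' Four accept/reject predicates reduce a Monte Carlo ensemble to the
#' solutions consistent with the shale record of a period:
#'
#' 1. `filter_flux_cap()`: the required Mo input must not exceed the
#'    modern riverine flux — oxidative weathering under a low-O2
#'    atmosphere cannot deliver more Mo than the fully oxygenated modern
#'    Earth does (boundary inclusive).
#' 2. `filter_isotope_window()`: seawater delta98Mo (recorded exactly by
#'    euxinic sediments) must fall in the period's closed window.
#' 3. `filter_area_ordering()`: the depositional area of euxinic
#'    sediments must be strictly smaller than that of sulfidic-at-depth
#'    sediments, which form the transition zone around euxinic settings.
#' 4. `filter_enrichment()`: the interval of predicted authigenic
#'    enrichments across the MAR bracket must intersect the period's
#'    observed window; a solution whose whole interval misses the window
#'    on either side is rejected.
#'
#' Each predicate is vectorised over the rows of an assembled solutions
#' tibble and returns a logical vector.
#'
#' @param solutions A tibble from [assemble_solutions()] /
#'   [sample_ensemble()].
#' @param cap Flux cap (mol/yr).
#' @param window Length-2 numeric `c(lo, hi)` closed window.
#' @return Logical vector, `TRUE` for solutions passing the filter.
#' @name record_filters
NULL

#' @rdname record_filters
#' @export
filter_flux_cap <- function(solutions, cap = 1.35e8) {
  solutions$r_in <= cap
}

#' @rdname record_filters
#' @export
filter_isotope_window <- function(solutions, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  solutions$delta_sw >= window[1] & solutions$delta_sw <= window[2]
}

#' @rdname record_filters
#' @export
filter_area_ordering <- function(solutions) {
  solutions$area_sad > solutions$area_eux
}

#' @rdname record_filters
#' @export
filter_enrichment <- function(solutions, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  solutions$enr_lo <= window[2] & solutions$enr_hi >= window[1]
}

#' Apply the four record filters for one period
#'
#' Applies the flux-cap, isotope-window, area-ordering and enrichment
#' filters in that fixed order and returns the surviving solutions (input
#' order preserved). Rejections are attributed to the first filter that
#' fails, and the counts are attached as an attribute. An empty survivor
#' set is returned as an empty tibble (with counts), not an error, so
#' callers can report infeasibility.
#'
#' @param ensemble Assembled solutions tibble (non-empty).
#' @param period A one-row tibble from [period_constraints()], or a period
#'   name.
#' @return Tibble of class `mo_filtered`: the surviving rows, with
#'   attributes `rejections` (named counts per filter plus `survivors`)
#'   and `period`.
#' @export
#' @examples
#' ens <- sample_ensemble(5000, seed = 1)
#' surv <- apply_filters(ens, "paleo_mesoarchean")
#' attr(surv, "rejections")
apply_filters <- function(ensemble, period) {
  if (nrow(ensemble) == 0) {
    stop("`ensemble` must be non-empty", call. = FALSE)
  }
  if (is.character(period)) period <- period_constraints(period)
  stopifnot(nrow(period) == 1)

  p1 <- filter_flux_cap(ensemble, period$flux_cap)
  p2 <- filter_isotope_window(ensemble, c(period$delta_min, period$delta_max))
  p3 <- filter_area_ordering(ensemble)
  p4 <- filter_enrichment(ensemble, c(period$enr_min, period$enr_max))

  first_fail <- rep(0L, nrow(ensemble))
  first_fail[!p4] <- 4L
  first_fail[!p3] <- 3L
  first_fail[!p2] <- 2L
  first_fail[!p1] <- 1L

  keep <- p1 & p2 & p3 & p4
  out <- dplyr::filter(tibble::as_tibble(ensemble), keep)
  counts <- c(
    flux_cap = sum(first_fail == 1L),
    isotope_window = sum(first_fail == 2L),
    area_ordering = sum(first_fail == 3L),
    enrichment = sum(first_fail == 4L),
    survivors = sum(keep)
  )
  attr(out, "rejections") <- counts
  attr(out, "period") <- period$period
  class(out) <- c("mo_filtered", class(out))
  out
}

#' Survivors with per-filter pass flags
#'
#' Returns the full ensemble annotated with one boolean column per filter
#' and an overall `pass` column — the form written to disk when auditing
#' filter behaviour.
#'
#' @inheritParams apply_filters
#' @return The ensemble tibble plus columns `pass_flux_cap`,
#'   `pass_isotope`, `pass_area_order`, `pass_enrichment`, `pass`.
#' @export
flag_filters <- function(ensemble, period) {
  if (is.character(period)) period <- period_constraints(period)
  stopifnot(nrow(period) == 1)
  dplyr::mutate(
    tibble::as_tibble(ensemble),
    pass_flux_cap = filter_flux_cap(ensemble, period$flux_cap),
    pass_isotope = filter_isotope_window(
      ensemble, c(period$delta_min, period$delta_max)),
    pass_area_order = filter_area_ordering(ensemble),
    pass_enrichment = filter_enrichment(
      ensemble, c(period$enr_min, period$enr_max)),
    pass = .data$pass_flux_cap & .data$pass_isotope &
      .data$pass_area_order & .data$pass_enrichment
  )
}
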