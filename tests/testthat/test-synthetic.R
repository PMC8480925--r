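make_truth <- function(mo_sw = 25e-9, delta_in = 0.5, b_eux = 1e9) {
  p <- pinned_params()
  p$mo_sw <- mo_sw; p$delta_in <- delta_in; p$b_eux <- b_eux
  assemble_solutions(p)
}

test_that("shale mixing conserves mass and mixes isotopes exactly", {
  truth <- make_truth()
  sc <- synthetic_scenario(truth, n_samples = 200, delta_noise_sd = 0,
                           seed = 11)
  rec <- generate_shale_record(sc)
  expect_equal(rec$bulk_mo, 2 + rec$auth_mo)
  expect_equal(rec$auth_fraction, rec$auth_mo / rec$bulk_mo)
  # noise-free bulk delta is the exact concentration-weighted mean
  expected <- (2 * 0.3 + rec$auth_mo * truth$delta_sw) / rec$bulk_mo
  expect_equal(rec$bulk_delta, expected)
  # MARs honour the configured bracket
  expect_true(all(rec$mar >= 0.00125 & rec$mar <= 0.0125))
})

test_that("end-member limits: pure detrital and authigenic-dominated shales", {
  barren <- make_truth(mo_sw = 0)
  sc0 <- synthetic_scenario(barren, n_samples = 100, seed = 2)
  rec0 <- generate_shale_record(sc0)
  expect_true(all(rec0$bulk_mo == 2))
  expect_equal(mean(rec0$bulk_delta), 0.3, tolerance = 0.02)

  rich <- make_truth(mo_sw = 100e-9, b_eux = 1.8e9)
  scr <- synthetic_scenario(rich, n_samples = 100, seed = 3)
  recr <- generate_shale_record(scr)
  expect_gt(min(recr$auth_fraction), 0.97)
  expect_equal(mean(recr$bulk_delta), rich$delta_sw, tolerance = 0.05)
})

test_that("authigenic enrichment matches the burial-flux arithmetic", {
  truth <- make_truth(mo_sw = 25e-9, b_eux = 1e9)
  # pin MAR to the fast end of the bracket: 1e9 * 25e-9 * 95.95 g/mol
  # over 0.0125 g/cm2/yr is 19.19 ug/g
  sc <- synthetic_scenario(truth, n_samples = 20,
                           mar_range = c(0.0125, 0.0125 * (1 + 1e-12)),
                           seed = 4)
  rec <- generate_shale_record(sc)
  expect_equal(rec$auth_mo, rep(19.19, 20), tolerance = 1e-4)
})

test_that("shales are never heavier than seawater beyond analytical noise", {
  for (seed in 1:5) {
    truth <- make_truth(mo_sw = 10e-9, delta_in = 0.6)
    sc <- synthetic_scenario(truth, n_samples = 200, seed = seed)
    rec <- generate_shale_record(sc)
    expect_true(all(rec$bulk_delta <= truth$delta_sw + 3 * 0.05))
  }
})

test_that("windows derived from a record bracket its maxima", {
  rec <- tibble::tibble(bulk_mo = c(5, 20, 45), bulk_delta = c(0.4, 1.1, 1.6))
  w <- derive_filter_windows(rec, pad = 0.15)
  expect_equal(w$enr_min, 38.25)
  expect_equal(w$enr_max, 51.75)
  # overlaps the anomalous-interval record window used for 2.5 Ga shales
  expect_lt(w$enr_min, 50)
  expect_gt(w$enr_max, 35)
  expect_equal(w$delta_max - w$delta_min, 2 * 0.15 * 1.6)

  flat <- derive_filter_windows(tibble::tibble(bulk_mo = 2, bulk_delta = 0.3))
  expect_equal(flat$enr_min, 2)  # floored at the detrital cutoff

  heavier <- derive_filter_windows(
    tibble::tibble(bulk_mo = c(5, 20, 45), bulk_delta = c(0.4, 1.1, 1.9)),
    pad = 0.15)
  expect_gt(heavier$delta_max, w$delta_max)
  expect_error(derive_filter_windows(rec[0, ]), "empty")
})

test_that("recovery experiments bracket an admissible truth and sense [Mo]sw", {
  ens <- shared_ensemble(2e5, seed = 5)

  # an admissible truth passing its own derived windows is covered
  pool <- sample_ensemble(3000, seed = 6)
  pool <- pool[filter_flux_cap(pool) & filter_area_ordering(pool), ]
  rep <- NULL
  for (i in seq_len(min(20, nrow(pool)))) {
    sc <- synthetic_scenario(pool[i, ], n_samples = 40, seed = 100 + i)
    cand <- recovery_experiment(sc, ensemble = ens)
    if (isTRUE(cand$feasible) && isTRUE(cand$true_passes)) { rep <- cand; break }
  }
  expect_false(is.null(rep))
  expect_true(rep$covered_r_in)

  # Mo-replete ocean: survivors sit above the nitrogen-fixation threshold
  rich <- make_truth(mo_sw = 60e-9, delta_in = 0.5, b_eux = 1e9)
  sc_rich <- synthetic_scenario(rich, n_samples = 40, seed = 102)
  rep_rich <- recovery_experiment(sc_rich, ensemble = ens)
  if (rep_rich$feasible) {
    surv <- apply_filters(
      ens, derive_filter_windows(generate_shale_record(sc_rich)))
    expect_gt(stats::median(surv$mo_sw) * 1e9, 5)
  }

  # Mo-starved ocean with faint-record windows: survivors sit below it
  poor <- make_truth(mo_sw = 1e-9, delta_in = 0.5, b_eux = 1.2e9)
  sc_poor <- synthetic_scenario(poor, n_samples = 40, seed = 103)
  rec_poor <- generate_shale_record(sc_poor)
  surv_poor <- apply_filters(ens, derive_filter_windows(rec_poor))
  expect_gt(nrow(surv_poor), 0)
  expect_lt(stats::median(surv_poor$mo_sw) * 1e9, 5)
})
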