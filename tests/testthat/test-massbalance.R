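test_that("sink removal rate follows b x [Mo]sw x A with unit consistency", {
  expect_identical(sink_removal_rate(1e9, 0, 1e6), 0)
  expect_equal(sink_removal_rate(1e9, 5e-9, 1e6), 5e6)
  # modern-like euxinic parameters over a small depositional area
  expect_equal(sink_removal_rate(1.2e9, 105e-9, 3.6e4), 4.536e6)
  expect_error(sink_removal_rate(-1, 1e-9, 1e6), "negative")
  expect_error(sink_removal_rate(Inf, 1e-9, 1e6), "finite")
})

test_that("seawater delta98Mo responds to sink fractions as isotope closure demands", {
  # quantitative euxinic removal returns the input composition unchanged
  expect_equal(solve_delta_sw(0.5, 0, 0, 0, 1), 0.5)
  # all-Mn removal drives seawater heavier by the full Mn offset
  expect_equal(solve_delta_sw(0.7, 0, 1, 0, 0), 3.7)
  # equal four-way split: 0.5 + 0.25 * (1.25 + 3 + 0.7 + 0)
  expect_equal(solve_delta_sw(0.5, 0.25, 0.25, 0.25, 0.25), 1.7375)
  expect_error(solve_delta_sw(0.5, 0.5, 0.2, 0.2, 0.2), "sum to 1")
})

test_that("euxinic enrichment prediction matches hand arithmetic and scales", {
  expect_equal(predicted_euxinic_enrichment(1e9, 0, 0.0125), 0)
  e1 <- predicted_euxinic_enrichment(1e9, 105e-9, 0.0125)
  expect_equal(e1, 80.598, tolerance = 1e-6)
  # enrichment is linear in 1/MAR: ten-fold slower burial, ten-fold richer
  expect_equal(predicted_euxinic_enrichment(1e9, 105e-9, 0.00125), 10 * e1)
  expect_error(predicted_euxinic_enrichment(1e9, 1e-9, 0), "positive")

  # strict monotonicity in each argument
  b <- seq(0.6e9, 1.8e9, length.out = 7)
  expect_true(all(diff(predicted_euxinic_enrichment(b, 5e-9, 0.01)) > 0))
  mo <- seq(1e-10, 1e-7, length.out = 7)
  expect_true(all(diff(predicted_euxinic_enrichment(1e9, mo, 0.01)) > 0))
  mar <- seq(0.00125, 0.0125, length.out = 7)
  expect_true(all(diff(predicted_euxinic_enrichment(1e9, 5e-9, mar)) < 0))
})

test_that("assembled solutions reproduce an independently hand-computed fixture", {
  sol <- assemble_solutions(pinned_params())
  expect_equal(sol$r_fe, 2.52e6)
  expect_equal(sol$r_mn, 3.6e4)
  expect_equal(sol$r_sad, 1.35e8)
  expect_equal(sol$r_eux, 8.64e7)
  expect_equal(sol$r_in, 2.23956e8)
  expect_equal(sol$f_sad, 1.35e8 / 2.23956e8, tolerance = 1e-12)
  expect_equal(sol$delta_sw, 0.9365053, tolerance = 1e-6)
  expect_equal(sol$enr_lo, 4.60560, tolerance = 1e-5)
  expect_equal(sol$enr_hi, 46.0560, tolerance = 1e-5)
})

test_that("mass and isotope closure hold to near machine precision", {
  sol <- assemble_solutions(random_params(500, seed = 42))
  expect_true(all(abs(sol$r_in - (sol$r_fe + sol$r_mn + sol$r_sad + sol$r_eux)) /
                    sol$r_in <= 1e-12))
  fsum <- sol$f_fe + sol$f_mn + sol$f_sad + sol$f_eux
  expect_true(all(abs(fsum - 1) <= 1e-12))
  # flux-weighted sediment compositions recover the input composition
  sd <- sediment_deltas(sol)
  recon <- sd$f_fe * sd$delta_fe + sd$f_mn * sd$delta_mn +
    sd$f_sad * sd$delta_sad + sd$f_eux * sd$delta_eux
  expect_true(all(abs(recon - sol$delta_in) <= 1e-12))
  # euxinic sediments record seawater exactly; enrichment interval ordered
  expect_identical(sd$delta_eux, sol$delta_sw)
  expect_true(all(sol$enr_lo < sol$enr_hi))
})

test_that("degenerate and invalid inputs are handled explicitly", {
  p <- pinned_params()
  p$mo_sw <- 0
  sol <- assemble_solutions(p)
  expect_true(sol$degenerate)
  expect_equal(sol$r_in, 0)
  expect_equal(sol$enr_lo, 0)
  # fractions remain defined in the zero-concentration limit
  expect_equal(sol$f_fe + sol$f_mn + sol$f_sad + sol$f_eux, 1)

  bad <- pinned_params()
  bad$area_fe <- 0; bad$area_mn <- 0; bad$area_sad <- 0; bad$area_eux <- 0
  expect_error(assemble_solutions(bad), "degenerate|seafloor")
  short <- pinned_params()[, 1:5]
  expect_error(assemble_solutions(short), "missing columns")
})

test_that("a purely euxinic ocean pins seawater to the input composition", {
  p <- pinned_params()
  # squeeze the other sinks to a vanishing share of the removal flux
  p$area_fe <- 3.6e8 * 1e-10; p$area_mn <- 3.6e8 * 1e-10
  p$area_sad <- 3.6e8 * 1e-10
  p$area_eux <- 3.6e8 * (1 - 3e-10)
  sol <- assemble_solutions(p)
  expect_gt(sol$f_eux, 1 - 1e-6)
  expect_equal(sol$delta_sw, sol$delta_in, tolerance = 1e-6)
})
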