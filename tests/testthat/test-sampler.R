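test_that("sampled parameters respect every configured range and constraint", {
  rg <- sampling_ranges()
  ens <- shared_ensemble(2e5, seed = 1)
  expect_equal(nrow(ens), 2e5)
  expect_true(all(ens$mo_sw >= rg$mo_sw[1] & ens$mo_sw <= rg$mo_sw[2]))
  expect_true(all(ens$delta_in >= rg$delta_in[1] &
                    ens$delta_in <= rg$delta_in[2]))
  # truncation is hard: no rate constant outside its printed range, ever
  for (s in sink_classes()) {
    b <- ens[[paste0("b_", s)]]
    expect_true(all(b >= rg$b[[s]][1] & b <= rg$b[[s]][2]))
  }
  total <- ens$area_fe + ens$area_mn + ens$area_sad + ens$area_eux
  expect_true(all(abs(total / 3.6e8 - 1) <= 1e-9))
  expect_true(all(ens$area_mn / 3.6e8 <= 0.10))
  expect_true(all(ens$area_eux / 3.6e8 <= 0.05))
})

test_that("ensembles are exactly reproducible from their seed", {
  a <- sample_ensemble(2000, seed = 7)
  b <- sample_ensemble(2000, seed = 7)
  c <- sample_ensemble(2000, seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$mo_sw, c$mo_sw))
  expect_error(sample_ensemble(0, seed = 1), ">= 1")
})

test_that("sampled distributions match their specification at large n", {
  rg <- sampling_ranges()
  ens <- shared_ensemble(2e5, seed = 1)
  # truncated normals are symmetric about the printed-range midpoint
  for (s in sink_classes()) {
    mid <- mean(rg$b[[s]])
    expect_lt(abs(mean(ens[[paste0("b_", s)]]) - mid) / mid, 0.02)
  }
  # uniform [Mo]sw fills its range to the edges
  span <- diff(rg$mo_sw)
  expect_lt(min(ens$mo_sw), rg$mo_sw[1] + 0.01 * span)
  expect_gt(max(ens$mo_sw), rg$mo_sw[2] - 0.01 * span)
  ks <- suppressWarnings(
    stats::ks.test(ens$mo_sw, "punif", rg$mo_sw[1], rg$mo_sw[2])
  )
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("box-and-whisker summaries follow the quartile and fence rules", {
  s <- summarize_ensemble(c(1, 2, 3, 4, 5))
  expect_equal(s$q1, 2)
  expect_equal(s$median, 3)
  expect_equal(s$q3, 4)

  const <- summarize_ensemble(c(7, 7, 7))
  expect_equal(const$q1, 7)
  expect_equal(const$whisker_lo, 7)
  expect_equal(const$whisker_hi, 7)
  expect_length(const$outliers[[1]], 0)

  tail_case <- summarize_ensemble(c(1:100, 1000))
  expect_true(1000 %in% tail_case$outliers[[1]])
  expect_lte(tail_case$whisker_hi, 100)  # clamped to the data
  expect_error(summarize_ensemble(numeric(0)), "non-empty")
})

test_that("invalid range configurations are rejected", {
  expect_error(sampling_ranges(mo_sw = c(1e-8, 1e-9)), "lo < hi")
  expect_error(sampling_ranges(b = list(fe = c(3e6, 1e6), mn = c(1e6, 3e6),
                                        sad = c(1.75e8, 4.25e8),
                                        eux = c(0.6e9, 1.8e9))),
               "lo < hi")
})

test_that("ensembles round-trip to CSV with a provenance sidecar", {
  ens <- sample_ensemble(50, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ensemble(ens, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 50)
  expect_equal(back$r_in, ens$r_in)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$seed, 3)
  expect_equal(side$n_requested, 50L)
  expect_equal(unlist(side$ranges$mo_sw), sampling_ranges()$mo_sw)
})
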