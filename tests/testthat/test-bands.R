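test_that("detect_iaf finds the planted alpha peak and applies tie rules", {
  ps <- bumpy_spectrum(list(c(10, 0.8, 8)))
  expect_equal(detect_iaf(ps)$iaf, 10)

  # two equal local maxima: lowest frequency wins, flagged
  two <- bumpy_spectrum(list(c(9, 0.5, 8), c(11, 0.5, 8)), bg = 0, floor = 1)
  r <- detect_iaf(two)
  expect_equal(r$iaf, 9)
  expect_true("iaf_tie" %in% r$flags)

  # monotone spectrum: no interior local max, fallback to range maximum
  mono <- spectrum_from(function(f) 20 / f)
  r2 <- detect_iaf(mono)
  expect_equal(r2$iaf, 5)
  expect_true("iaf_no_local_max" %in% r2$flags)

  expect_error(detect_iaf(spectrum_from(function(f) 0 * f)), "all-zero")
})

test_that("detect_tf finds the theta/alpha trough in the search window", {
  ps <- bumpy_spectrum(list(c(6, 0.7, 6), c(10, 0.8, 8)), bg = 4)
  iaf <- detect_iaf(ps)$iaf
  expect_equal(iaf, 10)
  tf <- detect_tf(ps, iaf)$tf
  # trough of this construction sits between the bumps
  win <- ps$freqs >= 4 & ps$freqs <= 9
  expect_equal(tf, ps$freqs[win][which.min(ps$power[win])])
  expect_gt(tf, 6)
  expect_lt(tf, 10)

  expect_error(detect_tf(ps, 5), "empty")
})

test_that("detect_high_peaks orders peaks and finds trough boundaries", {
  ps <- bumpy_spectrum(list(c(10, 0.8, 10), c(16, 1, 4), c(25, 1, 3.5),
                            c(38, 1, 3)), bg = 8)
  r <- detect_high_peaks(ps, 12.9)
  expect_equal(c(r$ibf1, r$ibf2, r$igf), c(16, 25, 38))
  expect_length(r$flags, 0L)
  # boundaries are the power minima between consecutive peaks
  seg1 <- ps$freqs > 16 & ps$freqs < 25
  expect_equal(r$boundaries[1L],
               ps$freqs[seg1][which.min(ps$power[seg1])])
  seg2 <- ps$freqs > 25 & ps$freqs < 38
  expect_equal(r$boundaries[2L],
               ps$freqs[seg2][which.min(ps$power[seg2])])

  # flat spectrum above alpha3: fallback boundaries, flagged
  flat <- spectrum_from(function(f) rep(1, length(f)))
  rf <- detect_high_peaks(flat, 12.9)
  expect_equal(rf$boundaries, c(19, 32.5))
  expect_true("high_peaks_fallback" %in% rf$flags)
})

test_that("build_bands reproduces the published whole-sample band edges", {
  b <- build_bands(6.9, 10.9)
  expect_equal(b$delta, c(2.9, 4.9))
  expect_equal(b$theta, c(4.9, 6.9))
  expect_equal(b$alpha1, c(6.9, 8.9))
  expect_equal(b$alpha2, c(8.9, 10.9))
  expect_equal(b$alpha3, c(10.9, 12.9))
  expect_equal(b$gamma[2L], 45)
  # alpha3 is exactly 2 Hz wide for any valid anchors
  for (iaf in c(9, 10.5, 12)) {
    bb <- build_bands(iaf - 4, iaf)
    expect_equal(diff(bb$alpha3), 2)
    expect_equal(bb$alpha1[2L], (iaf - 4 + iaf) / 2)
  }
  expect_error(build_bands(11, 10), "tf must be below")
  expect_error(build_bands(6.9, 10.9, boundaries = c(40, 20)), "invalid")
})

test_that("relative band power normalises against the 2-45 Hz mean", {
  flat <- spectrum_from(function(f) rep(3.7, length(f)))
  prof <- relative_band_power(flat, build_bands(6.9, 10.9))
  expect_equal(unname(prof$relative_power), rep(1, 8), tolerance = 1e-12)
  expect_equal(prof$alpha3_alpha2, 1, tolerance = 1e-12)

  # hand oracle on a synthetic spectrum: explicit sums over known bins
  ps <- bumpy_spectrum(list(c(10.9, 1, 6)))
  bands <- build_bands(6.9, 10.9)
  prof2 <- relative_band_power(ps, bands)
  rel <- ps$power / mean(ps$power)
  a2_bins <- which(ps$freqs >= 8.9 & ps$freqs < 10.9)
  a3_bins <- which(ps$freqs >= 10.9 & ps$freqs < 12.9)
  expect_equal(prof2$relative_power[["alpha2"]], sum(rel[a2_bins]) / 4)
  expect_equal(prof2$relative_power[["alpha3"]], sum(rel[a3_bins]) / 4)
  expect_equal(prof2$alpha3_alpha2,
               (sum(rel[a3_bins]) / 4) / (sum(rel[a2_bins]) / 4))

  # a band containing no grid bins errors by name (alpha2 here is a
  # quarter-Hz sliver between bin centers)
  expect_error(relative_band_power(ps, build_bands(6, 6.5, c(19, 32.5))),
               "alpha2")
})

test_that("relative power properties: unit mean, scale invariance, monotone ratio", {
  set.seed(31)
  for (i in 1:100) {
    p <- exp(rnorm(87, sd = 0.8)) * (20 / grid_freqs)
    ps <- power_spectrum(grid_freqs, p)
    expect_equal(mean(ps$power / mean(ps$power)), 1, tolerance = 1e-12)
    bands <- build_bands(6.9, 10.9)
    pr1 <- relative_band_power(ps, bands)
    pr2 <- relative_band_power(power_spectrum(grid_freqs, p * 7.3), bands)
    expect_equal(pr1$relative_power, pr2$relative_power, tolerance = 1e-12)
    expect_equal(pr1$alpha3_alpha2, pr2$alpha3_alpha2, tolerance = 1e-12)
  }

  # ratio strictly increases with planted upper-alpha amplitude
  ratios <- vapply(seq(0, 20, by = 2), function(a) {
    sp <- eeg_spec(tf = 7, iaf = 11, amp_alpha3 = a)
    ps <- power_spectrum(grid_freqs, model_psd(sp))
    analyze_spectrum(ps)$profile$alpha3_alpha2
  }, numeric(1L))
  expect_true(all(diff(ratios) > 0))
})

test_that("detect_anchors integrates IAF, TF, ITF and high peaks", {
  sp <- eeg_spec(tf = 7, iaf = 11)
  ps <- power_spectrum(grid_freqs, model_psd(sp, welch_smooth = TRUE))
  an <- detect_anchors(ps)
  expect_equal(an$iaf, 11)
  expect_equal(an$tf, 7)
  expect_true(an$itf >= an$tf - 2 && an$itf < an$tf)
  expect_true(an$ibf1 < an$ibf2 && an$ibf2 < an$igf)
  expect_s3_class(build_bands(an), "individual_bands")
})

test_that("anchor recovery on noisy synthetic subjects is within one bin", {
  # scaled-down version of the full acceptance check (shorter recordings)
  set.seed(202)
  hits <- 0L
  n_sub <- 25L
  for (i in seq_len(n_sub)) {
    iaf <- round(min(max(rnorm(1, 10.9, 1), 9), 12.5) * 2) / 2
    sp <- eeg_spec(tf = iaf - 4, iaf = iaf, amp_alpha3 = runif(1, 2, 18),
                   duration = 60, n_channels = 8, seed = 5000 + i)
    g <- generate_eeg(sp)
    an <- detect_anchors(compute_psd(epoch_eeg(g$recording), 250))
    if (abs(an$iaf - g$truth$iaf) <= 0.5 && abs(an$tf - g$truth$tf) <= 0.5) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_sub, 0.9)
})
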