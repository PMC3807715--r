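test_that("fit_background recovers the Gaussian intensity model", {
  set.seed(1)
  lv <- generate_lesion_volume(dims = c(32L, 32L, 32L), mu = 100, sigma = 10,
                               seed = 1)
  m <- fit_background(lv$volume)
  expect_lt(abs(m$mu - 100), 0.5)
  expect_lt(abs(m$sigma - 10), 0.5)
  expect_equal(m$k, 3.5)

  const <- volume_image(array(5, c(10, 10, 10)))
  expect_error(fit_background(const), "degenerate")
  tiny <- volume_image(array(rnorm(27), c(3, 3, 3)))
  expect_error(fit_background(tiny), "100 voxels")
})

test_that("robust fit resists bright-lesion contamination", {
  set.seed(2)
  vox <- array(rnorm(40^3, 100, 10), c(40, 40, 40))
  idx <- sample(length(vox), round(0.1 * length(vox)))
  vox[idx] <- vox[idx] + 60                      # 10% of voxels at +6 sigma
  vol <- volume_image(vox)
  m <- fit_background(vol, robust = TRUE)
  expect_lt(abs(m$mu / 100 - 1), 0.05)
  expect_lt(abs(m$sigma / 10 - 1), 0.05)
})

test_that("segmentation thresholds at mu + k sigma and is monotone in k", {
  set.seed(3)
  les <- list(list(center = c(16, 16, 16), radii = c(4, 3, 3), contrast = 6))
  lv <- generate_lesion_volume(dims = c(32L, 32L, 32L), lesions = les, seed = 3)
  m <- fit_background(lv$volume, robust = TRUE)
  seg <- segment_wmh(lv$volume, m)
  # nearly all lesion voxels are above threshold
  expect_gte(sum(seg & lv$truth_mask) / sum(lv$truth_mask), 0.99)
  # false positives near the Gaussian tail expectation
  bg <- lv$volume$brain_mask & !lv$truth_mask
  fp <- sum(seg & bg) / sum(bg)
  expect_lt(fp, 2 * pnorm(3.5, lower.tail = FALSE))

  k_masks <- lapply(c(2, 3.5, 5), function(k) segment_wmh(lv$volume, m, k = k))
  expect_true(all(k_masks[[2]] <= k_masks[[1]]))
  expect_true(all(k_masks[[3]] <= k_masks[[2]]))
  expect_equal(sum(segment_wmh(lv$volume, m, k = 50)), 0L)
})

test_that("lesion volume is voxel count times voxel size", {
  mask <- array(FALSE, c(10, 10, 10))
  expect_equal(lesion_volume(mask), 0)
  mask[1:10, 1:10, 1] <- TRUE
  expect_equal(lesion_volume(mask, 1.44), 144)
  expect_error(lesion_volume(array(1, c(2, 2, 2))), "logical")

  # voxelised-ellipsoid oracle: count voxels analytically from the equation
  dims <- c(32L, 32L, 32L)
  ctr <- c(16, 16, 16); radii <- c(5, 4, 3)
  ax <- seq_len(dims[1]); ay <- seq_len(dims[2]); az <- seq_len(dims[3])
  d2 <- outer(outer((ax - ctr[1])^2 / radii[1]^2,
                    (ay - ctr[2])^2 / radii[2]^2, `+`),
              (az - ctr[3])^2 / radii[3]^2, `+`)
  n_expected <- sum(d2 <= 1)
  lv <- generate_lesion_volume(dims = dims,
                               lesions = list(list(center = ctr, radii = radii,
                                                   contrast = 6)),
                               seed = 4)
  expect_equal(lesion_volume(lv$truth_mask, 1.44), n_expected * 1.44)
})

test_that("lesion volume recovery stays within 5% for 6-sigma lesions", {
  for (s in 1:3) {
    les <- list(list(center = c(20, 16, 16), radii = c(4, 3, 3), contrast = 6),
                list(center = c(10, 14, 16), radii = c(3, 3, 2.5), contrast = 6))
    lv <- generate_lesion_volume(dims = c(32L, 32L, 32L), lesions = les,
                                 seed = 100 + s)
    m <- fit_background(lv$volume, robust = TRUE)
    seg <- segment_wmh(lv$volume, m)
    truth_vol <- lesion_volume(lv$truth_mask, 1.44)
    expect_gte(sum(lv$truth_mask), 50)
    expect_lt(abs(lesion_volume(seg, 1.44) - truth_vol) / truth_vol, 0.05)
  }
})

test_that("T1 intensity correction replaces lesions by their surround", {
  # empty mask: output identical
  vol <- volume_image(array(rnorm(27, 100), c(3, 3, 3)))
  out <- correct_t1_intensity(vol, array(FALSE, c(3, 3, 3)))
  expect_identical(out$volume$voxels, vol$voxels)

  # constant surround: lesion becomes the surround value
  vox <- array(100, c(12, 12, 12))
  mask <- array(FALSE, c(12, 12, 12))
  mask[6:7, 6:7, 6] <- TRUE
  vox[mask] <- 200
  t1 <- volume_image(vox)
  cor <- correct_t1_intensity(t1, mask)
  expect_equal(unname(cor$volume$voxels[mask]), rep(100, 4))
  expect_identical(cor$volume$voxels[!mask], vox[!mask])

  # linear ramp: corrected values match a brute-force shell average oracle
  ramp <- array(0, c(14, 14, 14))
  for (i in 1:14) ramp[i, , ] <- i * 3
  mask2 <- array(FALSE, c(14, 14, 14))
  mask2[7:8, 7, 7] <- TRUE
  t1r <- volume_image(ramp + 0)
  t1r$voxels[mask2] <- 500
  shell <- array(FALSE, c(14, 14, 14))
  for (dx in -2:2) for (dy in -2:2) for (dz in -2:2) {
    sh <- c(dx, dy, dz)
    for (v in list(c(7, 7, 7), c(8, 7, 7))) {
      w <- v + sh
      shell[w[1], w[2], w[3]] <- TRUE
    }
  }
  shell[mask2] <- FALSE
  oracle <- mean(t1r$voxels[shell])
  corr <- correct_t1_intensity(t1r, mask2)
  expect_equal(unname(corr$volume$voxels[mask2]), rep(oracle, 2),
               tolerance = 1e-12)
  # voxels outside the mask are untouched
  expect_identical(corr$volume$voxels[!mask2], t1r$voxels[!mask2])
})

test_that("26-connectivity labelling separates diagonal-touching components", {
  mask <- array(FALSE, c(6, 6, 6))
  mask[2, 2, 2] <- TRUE
  mask[3, 3, 3] <- TRUE        # diagonal neighbour: same component under 26
  mask[6, 6, 6] <- TRUE        # far away: separate
  lab <- neuroband:::label_components_26(mask)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2, 2], lab[3, 3, 3])
  expect_true(lab[6, 6, 6] != lab[2, 2, 2])
})

test_that("lesion generator validates placement and is deterministic", {
  expect_error(generate_lesion_volume(
    dims = c(20L, 20L, 20L),
    lesions = list(list(center = c(1, 1, 1), radii = c(3, 3, 3), contrast = 6))),
    "outside")
  a <- generate_lesion_volume(seed = 9)
  b <- generate_lesion_volume(seed = 9)
  expect_identical(a$volume$voxels, b$volume$voxels)
})
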