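test_that("grid surface geometry is consistent", {
  surf <- make_grid_surface(5, 6)
  expect_length(surf$vertex_area, 30L)
  # total area equals the number of cells times the cell area
  expect_equal(sum(surf$vertex_area), 4 * 5 * 1)
  # interior vertices of a unit grid carry 1 mm^2
  interior <- surf$vertex_area[setdiff(seq_len(30),
    c(1:6, 25:30, seq(7, 19, by = 6), seq(12, 24, by = 6)))]
  expect_true(all(abs(interior - 1) < 1e-12))
  # adjacency is symmetric
  for (v in seq_along(surf$adjacency)) {
    for (w in surf$adjacency[[v]]) {
      expect_true(v %in% surf$adjacency[[w]])
    }
  }
})

test_that("vertexwise GLM absorbs covariates and flags collinearity", {
  set.seed(10)
  surf <- make_grid_surface(5, 5)
  n <- 40
  group <- factor(rep(c("high", "low"), each = n / 2))
  cov <- data.frame(age = rnorm(n, 70, 7), sex = rbinom(n, 1, 0.5),
                    education = rnorm(n, 8, 3), mmse = rnorm(n, 27, 1.5),
                    wmh = rlnorm(n, 1, 0.8))
  # thickness driven purely by age; groups age-matched in expectation
  thick <- outer(cov$age - 70, rep(-0.01, 25)) + 2.4 +
    matrix(rnorm(n * 25, 0, 0.02), n, 25)
  ds <- thickness_dataset(surf, thick, cov, group)
  fit <- vertexwise_glm(ds, c("high", "low"))
  expect_lt(max(abs(fit$coef)), 0.03)
  expect_equal(fit$df, n - 7)

  # invariance to affine covariate rescaling
  cov2 <- cov
  cov2$age <- (cov$age - 70) / 7
  ds2 <- thickness_dataset(surf, thick, cov2, group)
  fit2 <- vertexwise_glm(ds2, c("high", "low"))
  expect_equal(fit2$coef, fit$coef, tolerance = 1e-9)
  expect_equal(fit2$t, fit$t, tolerance = 1e-6)

  cov3 <- cov
  cov3$wmh <- 2 * cov3$age                 # collinear with age
  ds3 <- thickness_dataset(surf, thick, cov3, group)
  expect_error(vertexwise_glm(ds3, c("high", "low")), "wmh|collinear")
  expect_error(vertexwise_glm(ds, c("high", "absent")), "non-empty")
})

test_that("type-I rate at p < 0.001 matches the nominal level", {
  rates <- vapply(1:25, function(s) {
    ds <- null_thickness(nv_side = 14, seed = s)
    fit <- vertexwise_glm(ds, c("high", "low"))
    mean(fit$p < 0.001)
  }, numeric(1L))
  expect_lt(abs(mean(rates) - 0.001), 0.002)
})

test_that("planted group difference at published scale is recovered", {
  surf <- make_grid_surface(12, 12)
  patch <- select_patch(surf, 66, 61)
  hits <- vapply(1:30, function(s) {
    ds <- generate_thickness_dataset(
      surf, factor(rep(c("high", "low"), each = 18)),
      clusters = list(list(vertices = patch,
                           means = c(high = 2.00, low = 2.25))),
      noise_sd = 0.17, seed = 1000 + s)
    res <- group_contrast(ds, c("high", "low"))
    any(vapply(res$clusters, function(cl) {
      length(intersect(cl$vertices, patch)) > 0
    }, TRUE))
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("cluster extraction filters by area and sums vertex areas exactly", {
  surf <- make_grid_surface(12, 12)
  p_map <- rep(1, 144)
  t_map <- rep(0, 144)
  expect_length(extract_clusters(p_map, t_map, surf$vertex_area,
                                 surf$adjacency), 0L)

  big <- select_patch(surf, 40, 40)   # ~40 mm^2 patch
  small <- select_patch(surf, 133, 10)
  expect_lt(sum(surf$vertex_area[small]), 30)
  p_map[c(big, small)] <- 1e-5
  t_map[c(big, small)] <- -4
  cl <- extract_clusters(p_map, t_map, surf$vertex_area, surf$adjacency,
                         p_thresh = 0.001, min_area = 30)
  expect_length(cl, 1L)
  expect_equal(cl[[1L]]$vertices, sort(big))
  # brute-force area oracle
  expect_equal(cl[[1L]]$area, sum(surf$vertex_area[big]))
  expect_equal(cl[[1L]]$direction, -1)
  expect_equal(total_atrophy_extent(cl), cl[[1L]]$area)

  # idempotence / vertex-order independence: permuting seeds cannot matter
  cl2 <- extract_clusters(p_map, t_map, surf$vertex_area, surf$adjacency,
                          p_thresh = 0.001, min_area = 30)
  expect_identical(cl, cl2)
})

test_that("with no thresholds clusters partition the surface by sign", {
  set.seed(12)
  surf <- make_grid_surface(8, 8)
  t_map <- rnorm(64)
  t_map[t_map == 0] <- 1
  p_map <- runif(64, 0, 0.5)
  cl <- extract_clusters(p_map, t_map, surf$vertex_area, surf$adjacency,
                         p_thresh = 1, min_area = 0)
  all_v <- sort(unlist(lapply(cl, `[[`, "vertices")))
  expect_equal(all_v, 1:64)
  for (c1 in cl) {
    expect_true(all(sign(t_map[c1$vertices]) == c1$direction))
  }
})

test_that("total_atrophy_extent sums printed cluster sizes", {
  expect_equal(total_atrophy_extent(numeric(0)), 0)
  expect_equal(total_atrophy_extent(list()), 0)
  expect_equal(total_atrophy_extent(c(61, 60, 35, 58, 59, 52, 85, 61)), 471)
})

test_that("correlation map matches the textbook two-pass oracle", {
  set.seed(14)
  surf <- make_grid_surface(5, 5)
  n <- 18
  thick <- matrix(rnorm(n * 25, 2.4, 0.2), n, 25)
  cov <- data.frame(age = rnorm(n, 70, 7), sex = rbinom(n, 1, 0.5),
                    education = rnorm(n, 8, 3), mmse = rnorm(n, 27, 1),
                    wmh = rlnorm(n, 1, 0.5))
  score <- rnorm(n, 10, 3)
  ds <- thickness_dataset(surf, thick, cov, factor(rep("high", n)),
                          memory = data.frame(babcock = score))
  cm <- correlation_map(ds, "babcock", "high")
  oracle <- vapply(1:25, function(v) {
    x <- score; y <- thick[, v]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }, numeric(1L))
  expect_equal(cm$r, oracle, tolerance = 1e-12)

  # score equal to one vertex's thickness gives r = 1 there
  ds$memory$babcock <- thick[, 7]
  cm2 <- correlation_map(ds, "babcock", "high")
  expect_equal(cm2$r[7], 1, tolerance = 1e-12)

  ds$memory$babcock <- rep(5, n)
  expect_error(correlation_map(ds, "babcock", "high"), "zero-variance")
  expect_error(correlation_map(ds, "babcock", "middle"), "at least 4")
})

test_that("independent scores produce about the nominal cluster false positives", {
  set.seed(15)
  n_clusters <- vapply(1:20, function(s) {
    ds <- null_thickness(n_per_group = 18, nv_side = 10, seed = 300 + s)
    score <- rnorm(18, 10, 3)
    cm <- correlation_map(ds, score, "high", min_area = 15)
    length(cm$clusters)
  }, numeric(1L))
  # a 15 mm^2 cluster of independently significant vertices is essentially
  # impossible under the null
  expect_lte(mean(n_clusters), 0.1)
})

test_that("neighbour-averaging smoothing preserves the mean and reduces variance", {
  set.seed(16)
  ds <- null_thickness(n_per_group = 6, nv_side = 10, seed = 5)
  sm <- smooth_thickness(ds, iterations = 3)
  expect_equal(mean(sm$thickness), mean(ds$thickness), tolerance = 1e-3)
  expect_lt(var(as.numeric(sm$thickness)), var(as.numeric(ds$thickness)))
})
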