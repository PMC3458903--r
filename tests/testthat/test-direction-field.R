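test_that("build_mask realises the Gaussian ridge profile and its rotations", {
  mp <- mask_params_29x19()
  m0 <- build_mask(mp, 0)
  # centre row all at the maximum
  expect_equal(unname(unclass(m0)[15, ]), rep(4, 19))
  # value at row offset 3 sigma from the profile formula
  expect_equal(unclass(m0)[15 + 3, 10], -2 + 6 * exp(-4.5), tolerance = 1e-12)
  expect_equal(unclass(m0)[15 - 3, 10], -2 + 6 * exp(-4.5), tolerance = 1e-12)
  # square support: theta = 90 is the transpose of theta = 0
  mps <- mask_params(sigma = 1.5, rows = 11L, cols = 11L)
  expect_equal(unclass(build_mask(mps, 90)), t(unclass(build_mask(mps, 0))),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(mask_params(rows = 10L, cols = 11L), "odd")
  expect_error(mask_params(eps_mi = 2, eps_ma = 1), "eps_ma")
})

test_that("the sweep equals brute-force correlation of the effective kernel", {
  withr::with_seed(7, img <- matrix(runif(21 * 21, 0, 100), 21, 21))
  mp <- mask_params(sigma = 1, rows = 5L, cols = 5L)
  for (support in c("rectangular", "circular")) {
    for (th in c(0, 50, 90, 137)) {
      kern <- effective_kernel(mp, th, zero_mean = TRUE, support = support)
      expect_equal(
        correlate_image(img, kern),
        oracle_correlate(img, kern),
        tolerance = 1e-9
      )
    }
    # multi-orientation sweep: l_ma is the pointwise max, l_theta the argmax
    resp <- sweep_orientations(img, mp, theta_step_deg = 45, support = support)
    per_theta <- lapply(c(0, 45, 90, 135), function(th) {
      oracle_correlate(img, effective_kernel(mp, th, support = support))
    })
    stack <- simplify2array(per_theta)
    expect_equal(resp$l_ma, apply(stack, c(1, 2), max), tolerance = 1e-9)
    expect_equal(resp$l_theta, (apply(stack, c(1, 2), which.max) - 1) * 45,
                 tolerance = 1e-9)
  }
})

test_that("a constant image gives an orientation-indifferent response", {
  img <- matrix(42, 24, 24)
  resp <- sweep_orientations(img, mask_params(sigma = 1, rows = 7L, cols = 7L),
                             theta_step_deg = 15)
  # every balanced kernel sums to zero, so every response is numerically zero
  expect_lt(max(abs(resp$l_ma)), 1e-6)
  expect_lt(diff(range(resp$l_ma)), 1e-8)
})

test_that("tangent angles are recovered within 2 degrees on straight phantoms", {
  mp <- mask_params(sigma = 2)
  for (width in c(1, 2, 3)) {
    for (ang in c(30, 120)) {
      tr <- straight_phantom(ang, width_sd = width, size = 128L, r = 20, length = 60)
      resp <- sweep_orientations(median3x3(tr$image), mp)
      cl <- interior_centreline(tr)
      err <- circular_err(resp$l_theta[cl], tr$tangent_angle_map[cl])
      expect_lte(mean(err), 2)
    }
  }
})

test_that("a vessel of width ~ sigma is recovered within the sweep resolution", {
  tr <- straight_phantom(30, width_sd = 2, size = 128L, r = 20, length = 60)
  resp <- sweep_orientations(median3x3(tr$image), mask_params(sigma = 2))
  cl <- interior_centreline(tr)
  expect_true(all(resp$l_theta[cl] >= 28 & resp$l_theta[cl] <= 32))
  expect_true(mean(resp$l_theta[cl] >= 29 & resp$l_theta[cl] <= 31) > 0.9)
})

test_that("rotating the image by 90 degrees shifts recovered angles by 90", {
  tr <- straight_phantom(25, width_sd = 2, size = 128L, r = 20, length = 60)
  mp <- mask_params(sigma = 2)
  resp <- sweep_orientations(median3x3(tr$image), mp)
  rot <- rot90ccw(unclass(median3x3(tr$image)))
  resp_rot <- sweep_orientations(rot, mp)
  cl <- interior_centreline(tr)
  cl_rot <- cbind(129L - cl[, 2], cl[, 1])   # image rotation of the pixel set
  err <- circular_err(resp_rot$l_theta[cl_rot], resp$l_theta[cl] + 90)
  expect_lte(max(err), 1)
})

test_that("otsu_threshold equals the exhaustive 256-level search", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      v <- c(rnorm(120, 30, 6), rnorm(80, 150, 20))
      expect_equal(otsu_threshold(v), oracle_otsu(v), tolerance = 1e-12)
    }
  })
  # unequal clusters are still separated
  v2 <- c(rep(20, 190), rep(240, 10))
  p <- otsu_threshold(v2)
  expect_equal(p, oracle_otsu(v2), tolerance = 1e-12)
  expect_true(all(v2[v2 <= p] == 20) && all(v2[v2 > p] == 240))
  # perfect bimodality: threshold strictly between the modes
  v3 <- c(rep(10, 100), rep(200, 100))
  expect_gt(otsu_threshold(v3), 10)
  expect_lt(otsu_threshold(v3), 200)
  expect_error(otsu_threshold(rep(5, 50)), "constant")
})

test_that("otsu_threshold is invariant under affine rescaling and close to EBImage", {
  withr::with_seed(9, v <- c(rnorm(150, 40, 8), rnorm(100, 120, 15)))
  p <- otsu_threshold(v)
  p2 <- otsu_threshold(3 * v + 7)
  expect_equal(p2, 3 * p + 7, tolerance = 1e-9)
  # independent implementation agrees within one quantisation level
  rng <- range(v)
  eb <- EBImage::otsu(matrix((v - rng[1]) / diff(rng), 25, 10), range = c(0, 1))
  expect_lt(abs((rng[1] + eb * diff(rng)) - p), diff(rng) / 256 * 5)
})

test_that("angle_field gates strictly above the threshold with a separate mask", {
  resp <- structure(
    list(
      l_ma = matrix(c(1, 5, 3, 7), 2, 2),
      l_theta = matrix(c(0, 0, 20, 30), 2, 2),
      theta_step_deg = 1
    ),
    class = "orientation_response"
  )
  am <- angle_field(resp, 3)
  expect_identical(am$mask, matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  # response exactly equal to the threshold is excluded (strict inequality)
  expect_false(angle_field(resp, 5)$mask[2, 1])
  expect_equal(am$angles, matrix(c(0, 0, 0, 30), 2, 2))
  # a genuine 0-degree vessel pixel is distinguishable from background via mask
  expect_true(am$mask[2, 1])
  expect_identical(am$angles[2, 1], am$angles[1, 1])
  # everything at/below threshold: empty map
  am2 <- angle_field(resp, 10)
  expect_false(any(am2$mask))
})

test_that("otsu gating keeps most of the vessel core", {
  tr <- straight_phantom(60, width_sd = 2, size = 128L, r = 20, length = 60)
  resp <- sweep_orientations(median3x3(tr$image), mask_params(sigma = 2))
  lw <- angle_field(resp, otsu_threshold(resp$l_ma))
  # the centreline dilated to the full width at half maximum: the part of
  # the profile a segmentation is expected to retain (the faint sub-half-
  # maximum skirt of the Gaussian is legitimately thresholded away)
  core <- tr$vessel_mask & (unclass(tr$image) - tr$spec$background_level > 120 * 0.5)
  covered <- sum(lw$mask & core) / sum(core)
  expect_gte(covered, 0.8)
})
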