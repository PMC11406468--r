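test_that("trivial inputs decompose to their textbook magnitudes", {
  r_id <- lu_chipman(diag(4))
  expect_equal(r_id$Delta, 0, tolerance = 1e-12)
  expect_equal(r_id$R, 0, tolerance = 1e-7)
  expect_equal(r_id$D, 0, tolerance = 1e-12)

  r_dep <- lu_chipman(diag(c(1, 0, 0, 0)))
  expect_equal(r_dep$Delta, 1, tolerance = 1e-12)

  r_hw <- lu_chipman(mm_linear_retarder(pi, 0.3))
  expect_equal(r_hw$R, pi, tolerance = 1e-6)
})

test_that("composition/recovery oracle over a depolarizer-retarder-diattenuator grid", {
  for (a in c(0.1, 0.5, 0.9)) {
    for (delta in c(0.1, 1.5, 3.0)) {
      for (D in c(0, 0.45, 0.9)) {
        m <- mm_depolarizer(a, a * 0.95, a * 0.9) %*%
          mm_linear_retarder(delta, 0.35) %*%
          mm_linear_diattenuator(D, -0.6)
        res <- lu_chipman(m)
        expect_lt(res$residual, 1e-8)
        expect_equal(res$R, delta, tolerance = 1e-6)
        expect_equal(res$D, D, tolerance = 1e-6)
        expect_equal(res$Delta, 1 - (a + 0.95 * a + 0.9 * a) / 3, tolerance = 1e-6)
      }
    }
  }
})

test_that("randomized composition recovery keeps residual < 1e-8 and ranges valid", {
  set.seed(61)
  for (i in 1:300) {
    a <- sort(runif(3, 0.15, 0.95), decreasing = TRUE) # distinct eigenvalues
    delta <- runif(1, 0.05, 3.05)
    th <- runif(1, -pi / 2 + 0.01, pi / 2)
    D <- runif(1, 0, 0.9)
    ax <- runif(1, -pi / 2 + 0.01, pi / 2)
    m <- mm_depolarizer(a[1], a[2], a[3]) %*%
      mm_linear_retarder(delta, th) %*%
      mm_linear_diattenuator(D, ax)
    res <- lu_chipman(m)
    expect_lt(res$residual, 1e-8)
    expect_lt(abs(res$R - delta), 1e-6)
    expect_lt(abs(res$D - D), 1e-6)
    expect_true(res$Delta >= -1e-9 && res$Delta <= 1 + 1e-9)
    expect_true(res$R >= 0 && res$R <= pi)
    # retarder block orthogonal
    b <- res$M_R[2:4, 2:4]
    expect_lt(max(abs(crossprod(b) - diag(3))), 1e-8)
  }
})

test_that("scalar ranges hold on random physical matrices", {
  pool <- draw_physical_pool(300, seed = 77)
  for (M in pool) {
    res <- lu_chipman(mm_normalize(M)$m)
    expect_true(res$Delta >= -1e-6 && res$Delta <= 1 + 1e-6)
    expect_true(res$R >= 0 && res$R <= pi)
    expect_true(res$D >= 0 && res$D <= 1)
  }
})

test_that("retarder split separates linear retardance from rotation", {
  s_rot <- retarder_split(mm_rotator(0.3))
  expect_equal(s_rot$delta, 0, tolerance = 1e-9)
  expect_equal(s_rot$psi, 0.3, tolerance = 1e-9)

  s_lr <- retarder_split(mm_linear_retarder(1.2, 20 * pi / 180))
  expect_equal(s_lr$delta, 1.2, tolerance = 1e-9)
  expect_equal(s_lr$psi, 0, tolerance = 1e-9)

  MR <- mm_linear_retarder(1.2, 20 * pi / 180) %*% mm_rotator(0.3)
  s <- retarder_split(MR)
  expect_lt(s$residual, 1e-8)
  expect_equal(s$delta, 1.2, tolerance = 1e-9)
  expect_equal(s$psi, 0.3, tolerance = 1e-9)

  expect_error(retarder_split(mm_polarizer(0)), "orthogonal")
})

test_that("axis estimator recovers factory axes with correct quadrant", {
  expect_equal(retardance_axis(mm_linear_retarder(1.0, 0)), 0, tolerance = 1e-12)
  th <- 30 * pi / 180
  expect_equal(retardance_axis(mm_linear_retarder(1.0, th)), th, tolerance = 1e-12)
  th_neg <- -80 * pi / 180
  expect_equal(retardance_axis(mm_linear_retarder(1.0, th_neg)), th_neg,
    tolerance = 1e-12
  )
  # against brute-force search
  MLR <- mm_linear_retarder(0.8, 1.1)
  expect_equal(retardance_axis(MLR), brute_force_axis(MLR, 0.8), tolerance = 1e-3)
  # undefined for the identity
  expect_true(is.na(retardance_axis(diag(4))))
})

test_that("axis recovery holds over a fine theta and delta grid", {
  thetas <- seq(-89, 90, by = 1) * pi / 180
  for (delta in c(0.2, 1.0, 2.5)) {
    for (th in thetas) {
      expect_lt(abs(retardance_axis(mm_linear_retarder(delta, th)) - th), 1e-8)
    }
  }
})

test_that("polar maps agree with the single-matrix path and mask NA policy", {
  fx <- make_test_image(size = 12)
  mp <- polar_maps(fx$img)
  expect_true(all(is.na(mp$Delta[!fx$img$mask])))
  tr <- fx$truth
  expect_lt(max(abs(mp$Delta[tr$pixel] - tr$Delta)), 1e-6)
  expect_lt(max(abs(mp$R[tr$pixel] - tr$R)), 1e-6)
  expect_lt(max(abs(mp$D[tr$pixel] - tr$D)), 1e-6)
  # theta ground truth away from degenerate retardance
  ok <- tr$R > 0.05 & tr$R < pi - 0.05
  expect_lt(max(abs(mp$theta[tr$pixel[ok]] - tr$theta[ok])), 0.5 * pi / 180)
  # consistency of one pixel with the R implementation
  idx <- tr$pixel[1]
  ij <- arrayInd(idx, dim(fx$labels))
  res <- lu_chipman(pixel_matrix(fx$img, ij[1], ij[2]))
  expect_equal(mp$Delta[idx], res$Delta, tolerance = 1e-10)
  expect_equal(mp$theta[idx], res$theta, tolerance = 1e-10)
})
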