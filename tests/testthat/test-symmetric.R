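G_METRIC_local <- function(M) {
  G <- diag(c(1, -1, -1, -1))
  G %*% t(M) %*% G %*% M
}

test_that("diagonalizability precondition accepts valid media, rejects defects", {
  expect_true(is_symmetric_diagonalizable(diag(4)))
  expect_true(is_symmetric_diagonalizable(
    mm_depolarizer(0.6, 0.5, 0.4) %*% mm_linear_retarder(0.9, 0.2)
  ))
  pool <- draw_physical_pool(50, seed = 13)
  ok <- vapply(pool, function(M) {
    is_symmetric_diagonalizable(mm_normalize(M)$m)
  }, logical(1))
  expect_gt(mean(ok), 0.9) # generic physical matrices are diagonalizable

  # complex eigenvalues of N = G M^T G M
  shear <- diag(4)
  shear[1, 2] <- 1
  expect_false(is_symmetric_diagonalizable(shear))

  # defective (Jordan-block) N: null shear gives all-unit eigenvalues with a
  # rank-deficient eigenvector matrix
  null_shear <- diag(4) + (c(1, 1, 0, 0) / 2) %*% t(c(1, -1, 0, 0))
  N <- G_METRIC_local(null_shear)
  expect_lt(abs(max(Mod(eigen(N)$values)) - 1), 1e-9)
  expect_false(is_symmetric_diagonalizable(null_shear))
})

test_that("pure diagonal depolarizer is a fixed point", {
  m <- mm_depolarizer(0.6, 0.5, 0.4)
  res <- symmetric_decompose(m)
  expect_equal(res$d, c(1, 0.6, 0.5, 0.4), tolerance = 1e-9)
  expect_equal(res$M_D1, diag(4), tolerance = 1e-9)
  expect_equal(res$M_D2, diag(4), tolerance = 1e-9)
  expect_equal(res$M_R1[2:4, 2:4], diag(3), tolerance = 1e-9)
  expect_equal(res$M_R2[2:4, 2:4], diag(3), tolerance = 1e-9)
  expect_lt(res$residual, 1e-9)
})

test_that("pure retarder input yields identity depolarizer and exact total retarder", {
  for (pars in list(c(0.9, 0.4), c(2.1, -0.8), c(0.3, 1.2))) {
    m <- mm_linear_retarder(pars[1], pars[2])
    res <- symmetric_decompose(m)
    expect_equal(res$d, c(1, 1, 1, 1), tolerance = 1e-8)
    expect_equal(res$Delta, 0, tolerance = 1e-8)
    expect_lt(max(abs(res$M_R - m)), 1e-8)
    expect_equal(res$R, pars[1], tolerance = 1e-6)
    expect_lt(res$residual, 1e-8)
  }
})

random_symmetric_factors <- function() {
  list(
    MD1 = mm_linear_diattenuator(runif(1, 0, 0.7), runif(1, -1.4, 1.4)),
    MD2 = mm_linear_diattenuator(runif(1, 0, 0.7), runif(1, -1.4, 1.4)),
    MR1 = mm_linear_retarder(runif(1, 0.1, 2.9), runif(1, -1.4, 1.4)) %*%
      mm_rotator(runif(1, -1, 1)),
    MR2 = mm_linear_retarder(runif(1, 0.1, 2.9), runif(1, -1.4, 1.4)) %*%
      mm_rotator(runif(1, -1, 1)),
    d = sort(runif(3, 0.1, 0.9), decreasing = TRUE)
  )
}

test_that("composition/recovery on random five-layer products", {
  set.seed(23)
  n_ok <- 0
  for (i in 1:300) {
    f <- random_symmetric_factors()
    Mdd <- diag(c(1, f$d))
    m <- f$MD2 %*% f$MR2 %*% Mdd %*% t(f$MR1) %*% f$MD1
    m <- m / m[1, 1]
    res <- symmetric_decompose(m)
    expect_true(res$valid)
    expect_lt(res$residual, 1e-8)
    expect_equal(sort(abs(res$d[2:4]), decreasing = TRUE) / res$d[1],
      f$d,
      tolerance = 1e-6
    )
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 300)
})

test_that("depolarizer diagonal is dominated by d0 on valid decompositions", {
  pool <- draw_physical_pool(150, seed = 29)
  for (M in pool) {
    m <- mm_normalize(M)$m
    if (!is_symmetric_diagonalizable(m)) next
    res <- symmetric_decompose(m)
    if (!res$valid) next
    expect_true(all(abs(res$d[2:4]) <= res$d[1] + 1e-6))
  }
})

test_that("total retarder is invariant to the SVD rotation gauge", {
  set.seed(37)
  f <- random_symmetric_factors()
  MR1 <- f$MR1
  MR2 <- f$MR2
  base <- total_retarder(MR1, MR2)
  for (i in 1:20) {
    O <- diag(4)
    O[2:4, 2:4] <- random_rotation3()
    re_gauged <- total_retarder(MR1 %*% O, MR2 %*% O)
    expect_lt(max(abs(re_gauged$M_R - base$M_R)), 1e-10)
    expect_equal(re_gauged$R, base$R, tolerance = 1e-10)
  }
  expect_equal(total_retarder(MR1, MR1)$R, 0, tolerance = 1e-7)
})

test_that("symmetric Delta matches Lu-Chipman Delta without diattenuation", {
  set.seed(41)
  for (i in 1:40) {
    a <- sort(runif(3, 0.2, 0.95), decreasing = TRUE)
    m <- mm_linear_retarder(runif(1, 0.1, 2.5), runif(1, -1, 1)) %*%
      mm_depolarizer(a[1], a[2], a[3]) %*%
      mm_linear_retarder(runif(1, 0.1, 2.5), runif(1, -1, 1))
    res_sym <- symmetric_decompose(m)
    res_lc <- lu_chipman(m)
    expect_equal(res_sym$Delta, res_lc$Delta, tolerance = 1e-6)
  }
})

test_that("symmetric maps agree with the single-matrix path", {
  fx <- make_test_image(size = 10)
  sm <- symmetric_maps(fx$img)
  tr <- fx$truth
  expect_lt(max(abs(sm$Delta[tr$pixel] - tr$Delta)), 1e-6)
  expect_true(all(is.na(sm$Delta[!fx$img$mask])))
  idx <- tr$pixel[3]
  ij <- arrayInd(idx, dim(fx$labels))
  res <- symmetric_decompose(pixel_matrix(fx$img, ij[1], ij[2]))
  expect_equal(sm$R[idx], res$R, tolerance = 1e-8)
  expect_equal(sm$D1[idx], res$D1, tolerance = 1e-8)
})
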