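test_that("matrix log handles closed forms and round-trips through expm", {
  expect_equal(mueller_log(diag(4))$L, matrix(0, 4, 4), tolerance = 1e-12)

  lg <- mueller_log(mm_depolarizer(0.5))
  expect_equal(lg$L, diag(c(0, log(0.5), log(0.5), log(0.5))), tolerance = 1e-12)

  for (m in c(
    list(mm_linear_retarder(0.8, 0), mm_rotator(0.4),
      mm_depolarizer(0.7, 0.6, 0.5) %*% mm_linear_retarder(1.1, 0.3)
    ),
    lapply(draw_physical_pool(30, seed = 51), function(M) mm_normalize(M)$m)
  )) {
    lg <- mueller_log(m)
    if (!lg$defined) next
    expect_lt(max(abs(expm_oracle(lg$L) - m)), 1e-9)
  }
})

test_that("log is refused on the negative real axis", {
  # half-wave retarder: eigenvalues include -1
  lg <- mueller_log(mm_linear_retarder(pi, 0))
  expect_false(lg$defined)
  expect_true(all(is.na(lg$L)))
  # singular ideal depolarizer
  expect_false(mueller_log(diag(c(1, 0, 0, 0)))$defined)
})

test_that("log cross-checks an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(53)
  for (i in 1:10) {
    m <- mm_normalize(random_physical_mueller(3))$m
    lg <- mueller_log(m)
    if (!lg$defined) next
    expect_lt(max(abs(lg$L - pracma::logm(m))), 1e-7)
  }
})

test_that("G-split produces exact G-antisymmetric / G-symmetric parts", {
  set.seed(57)
  G <- diag(c(1, -1, -1, -1))
  for (i in 1:25) {
    L <- matrix(rnorm(16), 4, 4)
    sp <- g_split(L)
    expect_equal(sp$Lm + sp$Lu, L, tolerance = 1e-15)
    expect_lt(max(abs(G %*% t(sp$Lm) %*% G + sp$Lm)), 1e-12)
    expect_lt(max(abs(G %*% t(sp$Lu) %*% G - sp$Lu)), 1e-12)
  }
  # pure retarder: no fluctuation part
  sp_r <- g_split(mueller_log(mm_linear_retarder(0.9, 0.2))$L)
  expect_lt(max(abs(sp_r$Lu)), 1e-10)
  # isotropic depolarizer: no mean anisotropy part
  sp_d <- g_split(mueller_log(mm_depolarizer(0.4))$L)
  expect_lt(max(abs(sp_d$Lm)), 1e-12)
})

test_that("spectroscopic means read the template for elementary media", {
  delta <- 0.85
  means_r <- spectroscopic_means(g_split(mueller_log(mm_linear_retarder(delta, 0))$L)$Lm)
  expect_equal(means_r$LBH, -delta, tolerance = 1e-10)
  expect_equal(abs(means_r$LB45) + abs(means_r$CB) + abs(means_r$LDH) +
    abs(means_r$LD45) + abs(means_r$CD), 0, tolerance = 1e-10)

  psi <- 0.35
  means_rot <- spectroscopic_means(g_split(mueller_log(mm_rotator(psi))$L)$Lm)
  expect_equal(means_rot$CB, -2 * psi, tolerance = 1e-10)

  D <- 0.25
  means_d <- spectroscopic_means(g_split(mueller_log(mm_linear_diattenuator(D, 0))$L)$Lm)
  expect_equal(means_d$LDH, -atanh(D), tolerance = 1e-10)
  expect_equal(abs(means_d$LBH), 0, tolerance = 1e-10)

  # 45-degree axis moves the dichroism into the LD45 channel
  means_d45 <- spectroscopic_means(
    g_split(mueller_log(mm_linear_diattenuator(D, pi / 4))$L)$Lm
  )
  expect_equal(means_d45$LD45, -atanh(D), tolerance = 1e-10)
  expect_equal(means_d45$LDH, 0, tolerance = 1e-10)
})

test_that("means are additive for commuting generators", {
  A <- mm_linear_retarder(0.6, 0)
  B <- mm_linear_retarder(0.9, 0) # same axis: logs commute
  mA <- spectroscopic_means(g_split(mueller_log(A)$L)$Lm)
  mAB <- spectroscopic_means(g_split(mueller_log(A %*% B)$L)$Lm)
  expect_equal(mAB$LBH, mA$LBH + -0.9, tolerance = 1e-9)
})

test_that("fluctuation statistics vanish for pure media and match diagonal closed form", {
  fs_r <- fluctuation_stats(g_split(mueller_log(mm_linear_retarder(1.2, 0.4))$L)$Lu)
  expect_lt(abs(fs_r$var_LH) + abs(fs_r$var_L45) + abs(fs_r$var_C), 1e-10)
  expect_lt(abs(Re(fs_r$cov_LH_L45)) + abs(Re(fs_r$cov_LH_C)), 1e-10)
  expect_true(fs_r$physical)

  a <- 0.55
  fs_d <- fluctuation_stats(g_split(mueller_log(mm_depolarizer(a))$L)$Lu)
  expect_equal(fs_d$var_LH, -log(a), tolerance = 1e-10)
  expect_equal(fs_d$var_L45, -log(a), tolerance = 1e-10)
  expect_equal(fs_d$var_C, -log(a), tolerance = 1e-10)
  expect_equal(Re(fs_d$cov_LH_L45), 0, tolerance = 1e-12)
})

# direct R-side Monte Carlo used as an independent path for the covariance
# case (the packaged simulator draws independent channels)
fluctuation_mc_direct <- function(Lm, X) {
  acc <- matrix(0, 4, 4)
  for (i in seq_len(nrow(X))) {
    dL <- generator_matrix(
      LDH = X[i, 1], LD45 = X[i, 2], CD = X[i, 3],
      LBH = X[i, 4], LB45 = X[i, 5], CB = X[i, 6]
    )
    acc <- acc + expm_oracle(Lm + dL)
  }
  acc / nrow(X)
}

test_that("Gaussian-fluctuation Monte Carlo recovers configured variances", {
  # medium with mean linear birefringence and fluctuation on the LBH channel
  Lm <- generator_matrix(LBH = 0.4)
  v <- 0.2
  M <- simulate_fluctuating_medium(Lm, sd = c(0, 0, 0, sqrt(v), 0, 0),
    n = 2e4, seed = 7
  )
  res <- differential_decompose(mm_normalize(M)$m)
  expect_true(res$defined)
  expect_equal(res$means$LBH, 0.4, tolerance = 0.02)
  expect_lt(abs(res$fluctuations$var_LH - v), 0.05 * v)
  expect_lt(abs(res$fluctuations$var_L45), 0.02)
  expect_true(res$applicable)

  # cross-channel covariance: correlated LBH and LB45 fluctuations about a
  # zero mean (keeps the cumulant expansion exact)
  set.seed(8)
  X <- matrix(rnorm(2e4), ncol = 1) %*% matrix(c(0, 0, 0, sqrt(v), sqrt(v), 0), 1)
  Mc <- fluctuation_mc_direct(generator_matrix(), X)
  resc <- differential_decompose(mm_normalize(Mc)$m)
  # var(LBH) = var(LB45) = v and cov = v on the birefringent (imaginary) axis
  expect_equal(resc$fluctuations$var_LH, v, tolerance = 0.1 * v)
  expect_equal(resc$fluctuations$var_L45, v, tolerance = 0.1 * v)
  expect_equal(Re(resc$fluctuations$cov_LH_L45), v, tolerance = 0.1 * v)
})

test_that("variance recovery improves with draw count", {
  Lm <- generator_matrix(LBH = 0.3)
  v <- 0.15
  err_at <- function(n) {
    # average over seeds: a single draw can be lucky at small n
    mean(vapply(11:15, function(sd_i) {
      M <- simulate_fluctuating_medium(Lm, sd = c(0, 0, 0, sqrt(v), 0, 0),
        n = n, seed = sd_i
      )
      res <- differential_decompose(mm_normalize(M)$m)
      abs(res$fluctuations$var_LH - v)
    }, numeric(1)))
  }
  errs <- vapply(c(1e2, 1e3, 1e4), err_at, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("applicability detects manufactured negative fluctuation spectra", {
  # physical depolarizing products
  expect_true(differential_applicable(
    mueller_log(mm_depolarizer(0.7, 0.65, 0.6) %*% mm_linear_retarder(0.8, 0.1))$L
  ))
  # pure retarder: zero matrix is PSD
  expect_true(differential_applicable(mueller_log(mm_linear_retarder(0.7, 0))$L))
  # manufactured negative variance: flip the sign of a depolarizer log
  L_bad <- -mueller_log(mm_depolarizer(0.5))$L
  expect_false(differential_applicable(L_bad))
})

test_that("differential maps agree with the single-matrix path and count undefined pixels", {
  fx <- make_test_image(size = 10)
  dm <- differential_maps(fx$img)
  idx <- fx$truth$pixel[2]
  ij <- arrayInd(idx, dim(fx$labels))
  res <- differential_decompose(pixel_matrix(fx$img, ij[1], ij[2]))
  expect_equal(dm$LBH[idx], res$means$LBH, tolerance = 1e-9)
  expect_equal(dm$var_LH[idx], res$fluctuations$var_LH, tolerance = 1e-9)
  expect_true(all(is.na(dm$LBH[!fx$img$mask])))
  expect_equal(attr(dm, "log_undefined_count"), 0)

  smry <- differential_summary(dm)
  expect_equal(nrow(smry), 12)
  expect_equal(
    as.character(smry$quantity),
    c(
      "LBH", "LB45", "CB", "LDH", "LD45", "CD",
      "var_LH", "var_L45", "var_C",
      "cov_LH_L45", "cov_LH_C", "cov_L45_C"
    )
  )
})
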