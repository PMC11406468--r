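test_that("config validates parameter ranges", {
  expect_s3_class(phantom_config(), "phantom_config")
  expect_error(phantom_config(delta_gm = rep(1.2, 6)), "config error")
  expect_error(phantom_config(r_wm = rep(3.2, 6)), "config error")
  expect_error(phantom_config(dip_gm = 1.1), "config error")
})

test_that("phantom is deterministic under its seed and varies across specimens", {
  cfg <- phantom_config(size = 16, seed = 9)
  a <- generate_phantom(cfg, specimen = 2, region = 3)
  b <- generate_phantom(cfg, specimen = 2, region = 3)
  expect_identical(a$images[[1]]$data, b$images[[1]]$data)
  expect_identical(a$truth, b$truth)

  # different specimens share geometry but differ in class means
  c2 <- generate_phantom(cfg, specimen = 5, region = 3)
  expect_identical(a$labels, c2$labels)
  gm_a <- mean(a$truth$Delta[a$truth$class == "GM" & a$truth$wavelength == 450])
  gm_c <- mean(c2$truth$Delta[c2$truth$class == "GM" & c2$truth$wavelength == 450])
  expect_gt(abs(gm_a - gm_c), 1e-4)
})

test_that("noiseless phantom decomposes back to its exact truth everywhere", {
  cfg <- phantom_config(size = 20, seed = 4)
  ph <- generate_phantom(cfg, specimen = 1, region = 1, noiseless = TRUE)
  for (w in c(1, 4)) {
    img <- screen_image(ph$images[[w]])
    tr <- ph$truth[ph$truth$wavelength == cfg$wavelengths[w], ]
    mp <- polar_maps(img)
    expect_lt(max(abs(mp$Delta[tr$pixel] - tr$Delta)), 1e-6)
    expect_lt(max(abs(mp$R[tr$pixel] - tr$R)), 1e-6)
    expect_lt(max(abs(mp$D[tr$pixel] - tr$D)), 1e-6)
  }
})

test_that("default phantom passes the ensemble criterion at every labeled pixel", {
  cfg <- phantom_config(size = 24, seed = 6)
  ph <- generate_phantom(cfg, specimen = 1, region = 1)
  for (img in ph$images) {
    scr <- screen_image(img, tol = 1e-5)
    expect_true(all(scr$mask[ph$labels != 0]))
  }
})

test_that("the 550 nm depolarization dip shows up in class medians", {
  cfg <- phantom_config(size = 32, seed = 14)
  ph <- generate_phantom(cfg, specimen = 1, region = 1)
  med <- vapply(seq_along(cfg$wavelengths), function(w) {
    tr <- ph$truth[ph$truth$wavelength == cfg$wavelengths[w] & ph$truth$class == "GM", ]
    median(tr$Delta)
  }, numeric(1))
  # local minimum at 550 relative to the 500-590 trend line
  trend_550 <- (med[2] + med[4]) / 2
  expect_lt(med[3], trend_550)
})

test_that("corrupt_frames is the identity at zero noise and drives screen failures", {
  cfg <- phantom_config(size = 16, seed = 2)
  ph <- generate_phantom(cfg, specimen = 1, region = 1, noiseless = TRUE)
  fs <- forward_measure(ph$images[[1]], ideal_instrument())
  same <- corrupt_frames(fs, 0, 0)
  expect_equal(same$frames, fs$frames)

  # specular saturation: masked-out fraction at least the corruption rate
  cor <- corrupt_frames(fs, 0, p_specular = 0.05, seed = 77)
  frac <- attr(cor, "specular_fraction")
  expect_gte(frac, 0.05)
  rec <- reconstruct_mueller(cor)
  rec$m00 <- NULL # use raw reconstructed M00 for passivity
  scr <- screen_image(rec)
  spec_mask <- attr(cor, "specular_mask")
  expect_gte(mean(!scr$mask[spec_mask]), 0.9)
})

test_that("Mueller RMSE grows with frame noise through the full chain", {
  cfg <- phantom_config(size = 12, seed = 8)
  ph <- generate_phantom(cfg, specimen = 1, region = 1, noiseless = TRUE)
  img <- ph$images[[1]]
  fs <- forward_measure(img, ideal_instrument())
  rmse_at <- function(sig) {
    cor <- corrupt_frames(fs, sigma_gauss = sig, seed = 5)
    rec <- reconstruct_mueller(cor)
    sqrt(mean((rec$data - img$data)^2))
  }
  r <- vapply(c(0.005, 0.01, 0.02), rmse_at, numeric(1))
  expect_lt(r[1], r[2])
  expect_lt(r[2], r[3])
})

test_that("study generation yields the full cube inventory and is reproducible", {
  cfg <- phantom_config(size = 8, seed = 3)
  st <- generate_study(cfg, n_specimens = 6, n_regions = 20)
  expect_equal(nrow(st$manifest), 20)
  expect_equal(sum(st$manifest$n_cubes), 120)
  expect_setequal(unique(st$manifest$specimen), 1:6)

  st2 <- generate_study(cfg, n_specimens = 6, n_regions = 20)
  expect_identical(
    st$regions[[7]]$truth,
    st2$regions[[7]]$truth
  )

  cfg16 <- phantom_config(size = 16, seed = 3)
  st_small <- generate_study(cfg16, n_specimens = 2, n_regions = 2)
  ft <- build_feature_table(st_small, max_per_cell = 50)
  cv <- losocv_knn(balance_classes(ft), feature_names(450), k = 3)
  expect_equal(cv$train_fraction, 0.5)

  expect_error(generate_study(cfg, n_specimens = 1), ">= 2")
})
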