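# Shared fixtures and independent oracles used across the suite.

# Deterministic pool of random physical Mueller matrices.
draw_physical_pool <- function(n, seed = 42, components = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- if (is.null(components)) sample(1:5, 1) else components
    random_physical_mueller(n_components = k)
  })
}

# Brute-force retardance-axis search: scan theta and match the factory
# element against a linear retarder of the same retardance.
brute_force_axis <- function(MLR, delta) {
  grid <- seq(-pi / 2 + 1e-4, pi / 2, length.out = 3601)
  errs <- vapply(grid, function(th) {
    max(abs(MLR - mm_linear_retarder(delta, th)))
  }, numeric(1))
  grid[which.min(errs)]
}

# Independent matrix exponential (Matrix package) for round-trip oracles.
expm_oracle <- function(L) {
  as.matrix(Matrix::expm(L))
}

# Random proper rotation (3x3) for gauge-invariance checks.
random_rotation3 <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Small screened phantom image for map-level tests.
make_test_image <- function(size = 16, seed = 5, noiseless = TRUE, w = 1) {
  cfg <- phantom_config(size = size, seed = seed)
  ph <- generate_phantom(cfg, specimen = 1, region = 1, noiseless = noiseless)
  list(
    img = screen_image(ph$images[[w]]),
    truth = ph$truth[ph$truth$wavelength == cfg$wavelengths[w], ],
    labels = ph$labels,
    config = cfg
  )
}

# Synthetic separable feature table for classifier tests.
make_separable_table <- function(n_per_cell = 30, n_specimens = 4, seed = 1,
                                 gap = 6) {
  set.seed(seed)
  rows <- list()
  for (sp in seq_len(n_specimens)) {
    for (cl in c("GM", "WM")) {
      mu <- if (cl == "GM") 0 else gap
      rows[[length(rows) + 1L]] <- tibble::tibble(
        specimen = sp, region = sp, class = cl,
        f1 = stats::rnorm(n_per_cell, mu, 1),
        f2 = stats::rnorm(n_per_cell, 0, 1),
        f3 = stats::rnorm(n_per_cell, 0, 1)
      )
    }
  }
  dplyr::bind_rows(rows)
}
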