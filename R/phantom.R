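# Synthetic multispectral Mueller phantom: grey-matter ribbon, branching
# white-matter core, and thin vessels, with per-class wavelength-dependent
# depolarization/retardance/diattenuation curves and specimen effects.
#
# Default curves follow the observed tissue trends: GM depolarization rising
# from 0.6 to almost 0.9 across 450-680 nm, WM from just below 0.9 to almost
# 0.95, both with a small dip at 550 nm (9% for GM, 2% for WM); GM median
# retardance 0.16 -> 0.32 rad, WM 0.42 -> 0.72 rad; diattenuation below 0.04
# with GM about half of WM. Within-class pixel spread mirrors the measured
# boxplots: broad GM depolarization distributions, narrower WM ones, both
# widening toward the red end where the signal is noisier, and heavily
# overlapping retardance/diattenuation distributions. Each ground-truth pixel
# matrix is composed as depolarizer . retarder . diattenuator, so the forward
# polar decomposition is an exact inverse of the noiseless phantom.

.label_codes <- c(background = 0L, GM = 1L, WM = 2L, vessel = 3L)

interp_curve <- function(wl, wl_ref, val_ref) {
  stats::approx(wl_ref, val_ref, xout = wl, rule = 2)$y
}

#' Phantom configuration
#'
#' Collects the generator's study conditions. Defaults emulate the measured
#' tissue trends (see the package vignette); all parameter curves are checked
#' against their physical ranges.
#'
#' @param size Image side in pixels (square regions).
#' @param wavelengths Wavelengths in nm (default the six filters 450, 500,
#'   550, 590, 650, 680).
#' @param delta_gm,delta_wm,delta_vessel Per-wavelength depolarization
#'   curves, each in `[0, 1)`.
#' @param r_gm,r_wm,r_vessel Per-wavelength retardance curves (radians, in
#'   `[0, pi)`).
#' @param d_gm,d_wm,d_vessel Per-wavelength diattenuation curves in `[0, 1)`.
#' @param dip_gm,dip_wm Fractional 550 nm depolarization dip applied
#'   multiplicatively to the trend (defaults 0.09 and 0.02).
#' @param specimen_sd Log-normal SD of the per-specimen multiplicative effect
#'   on the class curves (specimen-to-specimen variability).
#' @param pixel_sd_delta Named numeric vector of within-class per-pixel
#'   depolarization SDs for `GM`, `WM`, `vessel` (GM distributions are
#'   visibly broader than WM in measured data).
#' @param pixel_sd_r,pixel_sd_d Within-class per-pixel SDs for retardance
#'   (radians) and diattenuation; both distributions overlap heavily between
#'   classes in measured tissue.
#' @param red_noise_factor Multiplicative growth of the pixel SDs from the
#'   bluest to the reddest wavelength (the red filters are noisier).
#' @param axis_amplitude Amplitude (radians) of the smooth spatial
#'   retardance-axis field.
#' @param axis_dispersion Axis rotation per wavelength step (radians),
#'   emulating the small spectral axis shift.
#' @param noise_sigma Relative Gaussian intensity noise used when the phantom
#'   is pushed through the instrument model (fraction of the maximum frame
#'   intensity).
#' @param m00_scale Reflectance scale assigned to every pixel (`M00`).
#' @param seed Master seed for all phantom randomness.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(size = 64,
                           wavelengths = .wavelengths_default,
                           delta_gm = NULL, delta_wm = NULL, delta_vessel = NULL,
                           r_gm = NULL, r_wm = NULL, r_vessel = NULL,
                           d_gm = NULL, d_wm = NULL, d_vessel = NULL,
                           dip_gm = 0.09, dip_wm = 0.02,
                           specimen_sd = 0.08,
                           pixel_sd_delta = c(GM = 0.13, WM = 0.07, vessel = 0.10),
                           pixel_sd_r = 0.28,
                           pixel_sd_d = 0.012,
                           red_noise_factor = 1.3,
                           axis_amplitude = pi / 4,
                           axis_dispersion = 2 * pi / 180,
                           noise_sigma = 0.01,
                           m00_scale = 0.4,
                           seed = 1L) {
  wl <- wavelengths
  wl_ref <- .wavelengths_default
  dip <- function(base, frac) {
    # multiplicative dip applied at 550 nm only
    ifelse(abs(wl - 550) < 1e-9, base * (1 - frac), base)
  }
  if (is.null(delta_gm)) {
    delta_gm <- dip(interp_curve(wl, wl_ref, c(0.60, 0.68, 0.72, 0.78, 0.85, 0.88)), dip_gm)
  }
  if (is.null(delta_wm)) {
    delta_wm <- dip(interp_curve(wl, wl_ref, c(0.88, 0.895, 0.905, 0.92, 0.94, 0.945)), dip_wm)
  }
  if (is.null(delta_vessel)) delta_vessel <- pmin(0.97, (delta_gm + delta_wm) / 2 + 0.02)
  if (is.null(r_gm)) r_gm <- interp_curve(wl, wl_ref, c(0.16, 0.19, 0.22, 0.25, 0.29, 0.32))
  if (is.null(r_wm)) r_wm <- interp_curve(wl, wl_ref, c(0.42, 0.48, 0.53, 0.59, 0.67, 0.72))
  if (is.null(r_vessel)) r_vessel <- pmin(pi - 0.2, r_wm * 1.15)
  if (is.null(d_gm)) d_gm <- interp_curve(wl, wl_ref, c(0.012, 0.011, 0.010, 0.009, 0.008, 0.008))
  if (is.null(d_wm)) d_wm <- interp_curve(wl, wl_ref, c(0.024, 0.022, 0.020, 0.018, 0.017, 0.016))
  if (is.null(d_vessel)) d_vessel <- d_wm
  stopifnot(all(c("GM", "WM", "vessel") %in% names(pixel_sd_delta)))
  cfg <- list(
    size = as.integer(size), wavelengths = wl,
    delta = list(GM = delta_gm, WM = delta_wm, vessel = delta_vessel),
    r = list(GM = r_gm, WM = r_wm, vessel = r_vessel),
    d = list(GM = d_gm, WM = d_wm, vessel = d_vessel),
    dip_gm = dip_gm, dip_wm = dip_wm,
    specimen_sd = specimen_sd,
    pixel_sd_delta = pixel_sd_delta, pixel_sd_r = pixel_sd_r,
    pixel_sd_d = pixel_sd_d, red_noise_factor = red_noise_factor,
    axis_amplitude = axis_amplitude, axis_dispersion = axis_dispersion,
    noise_sigma = noise_sigma, m00_scale = m00_scale,
    seed = as.integer(seed)
  )
  for (cl in c("GM", "WM", "vessel")) {
    if (any(cfg$delta[[cl]] < 0 | cfg$delta[[cl]] >= 1)) {
      stop("config error: depolarization curves must lie in [0, 1)", call. = FALSE)
    }
    if (any(cfg$r[[cl]] < 0 | cfg$r[[cl]] >= pi)) {
      stop("config error: retardance curves must lie in [0, pi)", call. = FALSE)
    }
    if (any(cfg$d[[cl]] < 0 | cfg$d[[cl]] >= 1)) {
      stop("config error: diattenuation curves must lie in [0, 1)", call. = FALSE)
    }
  }
  if (dip_gm < 0 || dip_gm >= 1 || dip_wm < 0 || dip_wm >= 1) {
    stop("config error: dip fractions must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "phantom_config")
}

# Smooth random field on an n x n grid: white noise blurred by a separable
# Gaussian kernel, standardized to zero mean / unit SD.
smooth_field <- function(n, scale = 8) {
  z <- matrix(stats::rnorm(n * n), n, n)
  k <- stats::dnorm(seq(-3, 3, length.out = 2 * scale + 1))
  k <- k / sum(k)
  pad <- length(k) %/% 2
  blur1 <- function(M) {
    Mp <- rbind(
      M[rev(seq_len(pad)), , drop = FALSE], M,
      M[nrow(M) - seq_len(pad) + 1, , drop = FALSE]
    )
    out <- apply(Mp, 2, function(col) stats::filter(col, k, sides = 2))
    out[(pad + 1):(pad + nrow(M)), , drop = FALSE]
  }
  z <- blur1(z)
  z <- t(blur1(t(z)))
  (z - mean(z)) / stats::sd(z)
}

# Label geometry: branching WM core from a thresholded smooth field, a GM
# ribbon around it, thin curvilinear vessels, and a background border.
phantom_labels <- function(size, seed) {
  set.seed(seed)
  f <- smooth_field(size, scale = max(4, size %/% 8))
  labels <- matrix(.label_codes[["GM"]], size, size)
  wm <- f > stats::quantile(f, 0.65)
  labels[wm] <- .label_codes[["WM"]]
  # thin curvilinear vessels: two sinusoidal tracks
  xs <- seq_len(size)
  for (v in 1:2) {
    amp <- size / stats::runif(1, 6, 10)
    ph <- stats::runif(1, 0, 2 * pi)
    base <- stats::runif(1, 0.25, 0.75) * size
    ys <- round(base + amp * sin(2 * pi * xs / size + ph))
    ok <- ys >= 1 & ys <= size
    labels[cbind(ys[ok], xs[ok])] <- .label_codes[["vessel"]]
  }
  border <- 2L
  labels[c(seq_len(border), size - seq_len(border) + 1L), ] <- .label_codes[["background"]]
  labels[, c(seq_len(border), size - seq_len(border) + 1L)] <- .label_codes[["background"]]
  labels
}

#' Generate one phantom region (all wavelengths)
#'
#' Builds the label geometry, draws specimen and pixel effects, and composes
#' per-pixel ground-truth Mueller matrices `M = M_Delta(1 - Delta) %*%
#' M_R(R, theta) %*% M_D(D, theta)`. With `noiseless = TRUE` the pixel-level
#' parameter jitter is skipped (matrices equal the class curves exactly at
#' every pixel), which makes decomposition-recovery oracles exact.
#'
#' @param config A [phantom_config()].
#' @param specimen Specimen id (integer; drives the specimen effect).
#' @param region Region id (drives the geometry).
#' @param noiseless Suppress pixel-level parameter jitter.
#' @return A list of class `phantom_region`: `images` (list of
#'   [mueller_image()] per wavelength), `labels` (integer matrix, codes
#'   background 0 / GM 1 / WM 2 / vessel 3), `truth` (tibble of per-pixel
#'   ground-truth `Delta`, `R`, `D`, `theta` per wavelength), `specimen`,
#'   `region`.
#' @export
generate_phantom <- function(config = phantom_config(), specimen = 1L,
                             region = 1L, noiseless = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$size
  wl <- config$wavelengths
  geo_seed <- config$seed + 7919L * as.integer(region)
  labels <- phantom_labels(n, geo_seed)

  # specimen effect: one multiplicative log-normal factor per class per
  # property, shared across wavelengths within a specimen
  set.seed(config$seed + 104729L * as.integer(specimen))
  spec_eff <- list()
  for (cl in c("GM", "WM", "vessel")) {
    spec_eff[[cl]] <- exp(stats::rnorm(3, 0, config$specimen_sd))
  }

  set.seed(geo_seed + 31L * as.integer(specimen) + 1L)
  xs <- matrix(rep(seq_len(n) / n, each = n), n, n)
  ys <- matrix(rep(seq_len(n) / n, times = n), n, n)
  theta0 <- config$axis_amplitude * sin(2 * pi * xs) * cos(pi * ys)

  idx <- which(labels != .label_codes[["background"]])
  cls <- names(.label_codes)[match(labels[idx], .label_codes)]
  images <- vector("list", length(wl))
  truth_list <- vector("list", length(wl))
  for (w in seq_along(wl)) {
    delta <- r <- dd <- rep(NA_real_, length(idx))
    for (cl in c("GM", "WM", "vessel")) {
      sel <- cls == cl
      if (!any(sel)) next
      delta[sel] <- config$delta[[cl]][w] * spec_eff[[cl]][1]
      r[sel] <- config$r[[cl]][w] * spec_eff[[cl]][2]
      dd[sel] <- config$d[[cl]][w] * spec_eff[[cl]][3]
    }
    if (!noiseless) {
      red <- 1 + (config$red_noise_factor - 1) *
        (w - 1) / max(1, length(wl) - 1)
      sd_delta <- config$pixel_sd_delta[cls] * red
      delta <- delta + stats::rnorm(length(idx), 0, sd_delta)
      r <- r + stats::rnorm(length(idx), 0, config$pixel_sd_r * red)
      dd <- dd + stats::rnorm(length(idx), 0, config$pixel_sd_d * red)
    }
    delta <- pmin(0.995, pmax(0.002, delta))
    r <- pmin(pi - 1e-3, pmax(1e-3, r))
    dd <- pmin(0.8, pmax(0, dd))
    theta <- fold_axis(theta0[idx] + (w - 1) * config$axis_dispersion)

    data <- array(0, dim = c(n, n, 4L, 4L))
    for (i in 1:4) data[, , i, i] <- 1 # background pixels: identity
    cube <- phantom_compose_cpp(1 - delta, r, dd, theta)
    flat <- matrix(data, n * n, 16L)
    flat[idx, ] <- cube
    data <- array(flat, dim = c(n, n, 4L, 4L))
    images[[w]] <- mueller_image(
      data, wl[w],
      mask = labels != .label_codes[["background"]],
      specimen = as.character(specimen), region = as.character(region),
      m00 = matrix(config$m00_scale, n, n)
    )
    truth_list[[w]] <- tibble::tibble(
      specimen = as.integer(specimen), region = as.integer(region),
      wavelength = wl[w], pixel = idx, class = cls,
      Delta = delta, R = r, D = dd, theta = theta
    )
  }
  structure(
    list(
      images = images, labels = labels,
      truth = dplyr::bind_rows(truth_list),
      specimen = as.integer(specimen), region = as.integer(region),
      config = config
    ),
    class = "phantom_region"
  )
}

#' @export
print.phantom_region <- function(x, ...) {
  cat(sprintf(
    "<phantom_region> specimen %d region %d: %d x %d px, %d wavelengths (%s nm)\n",
    x$specimen, x$region, nrow(x$labels), ncol(x$labels),
    length(x$images), paste(x$config$wavelengths, collapse = ", ")
  ))
  invisible(x)
}

#' Corrupt a frame stack with noise and specular saturation
#'
#' Adds Gaussian intensity noise (SD expressed as a fraction of the maximum
#' frame intensity) and saturates circular "specular" patches at several
#' times the maximum intensity, emulating the bright reflections and sample
#' edges that fail the realizability screen in measured data. The fraction of
#' corrupted pixels is stored in the `"specular_fraction"` attribute so
#' screening results can be audited.
#'
#' @param stack A [forward_measure()] frame stack.
#' @param sigma_gauss Relative Gaussian noise SD (>= 0).
#' @param p_specular Target fraction of pixels inside specular patches, in
#'   `[0, 1)`.
#' @param seed Optional seed.
#' @return The corrupted `frame_stack`.
#' @export
corrupt_frames <- function(stack, sigma_gauss = 0, p_specular = 0, seed = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (sigma_gauss < 0 || p_specular < 0 || p_specular >= 1) {
    stop("sigma_gauss must be >= 0 and p_specular in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- dim(stack$frames)
  mx <- max(stack$frames)
  spec_mask <- matrix(FALSE, d[3], d[4])
  if (sigma_gauss > 0) {
    stack$frames <- stack$frames + array(stats::rnorm(prod(d), 0, sigma_gauss * mx), d)
    stack$frames[stack$frames < 0] <- 0
  }
  if (p_specular > 0) {
    target <- p_specular * d[3] * d[4]
    radius <- max(1.5, sqrt(target / (2 * pi)))
    while (sum(spec_mask) < target) {
      ci <- stats::runif(1, 1, d[3])
      cj <- stats::runif(1, 1, d[4])
      ii <- matrix(rep(seq_len(d[3]), d[4]), d[3], d[4])
      jj <- matrix(rep(seq_len(d[4]), each = d[3]), d[3], d[4])
      spec_mask <- spec_mask | ((ii - ci)^2 + (jj - cj)^2 <= radius^2)
    }
    sat <- 3 * mx
    for (a in seq_len(d[1])) {
      for (g in seq_len(d[2])) {
        fr <- stack$frames[a, g, , ]
        fr[spec_mask] <- sat
        stack$frames[a, g, , ] <- fr
      }
    }
  }
  attr(stack, "specular_fraction") <- mean(spec_mask)
  attr(stack, "specular_mask") <- spec_mask
  stack
}

#' Generate a full synthetic study
#'
#' Produces `n_regions` phantom regions distributed round-robin over
#' `n_specimens` specimens at all configured wavelengths (defaults: 6
#' specimens, 20 regions, 6 wavelengths -- 120 Mueller cubes), plus a
#' manifest enabling the leave-one-specimen-out protocol.
#'
#' @param config A [phantom_config()].
#' @param n_specimens Number of specimens (>= 2).
#' @param n_regions Total number of regions across all specimens.
#' @param noiseless Passed through to [generate_phantom()].
#' @return Object of class `phantom_study`: `regions` (list of
#'   `phantom_region`), `manifest` (tibble: region, specimen, wavelengths,
#'   n_cubes), `config`.
#' @export
generate_study <- function(config = phantom_config(), n_specimens = 6,
                           n_regions = 20, noiseless = FALSE) {
  if (n_specimens < 2) stop("n_specimens must be >= 2", call. = FALSE)
  if (n_regions < n_specimens) {
    stop("need at least one region per specimen", call. = FALSE)
  }
  spec_of <- rep(seq_len(n_specimens), length.out = n_regions)
  regions <- lapply(seq_len(n_regions), function(rg) {
    generate_phantom(config, specimen = spec_of[rg], region = rg, noiseless = noiseless)
  })
  manifest <- tibble::tibble(
    region = seq_len(n_regions),
    specimen = spec_of,
    n_wavelengths = length(config$wavelengths),
    n_cubes = length(config$wavelengths)
  )
  structure(
    list(regions = regions, manifest = manifest, config = config),
    class = "phantom_study"
  )
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf(
    "<phantom_study> %d regions over %d specimens, %d cubes total\n",
    nrow(x$manifest), length(unique(x$manifest$specimen)), sum(x$manifest$n_cubes)
  ))
  invisible(x)
}
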