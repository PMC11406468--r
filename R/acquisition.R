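# Forward instrument model and least-squares Mueller reconstruction from
# intensity frame stacks.
#
# The emulated instrument measures 32 frames per Mueller matrix: the
# polarization state generator (PSG) is a fixed linear polarizer followed by
# a quarter-wave retarder at 4 orientations; the analyzer (PSA) is a
# division-of-focal-plane camera with 4 micropolarizer orientations
# (0/45/90/135 degrees) behind a retractable quarter-wave slider
# (out then in), giving K = 8 analyzer rows x 4 generator states.

# QWP orientations of the ideal PSG, chosen to minimize the condition number
# of the 4x4 state matrix for a rotating quarter-wave generator.
.psg_angles_deg <- c(-51.7, -15.1, 15.1, 51.7)

#' Ideal instrument model
#'
#' Builds the built-in ideal polarimeter: `PSG` is the 4x4 matrix whose
#' columns are the generated Stokes states (polarizer at 0 degrees followed
#' by a quarter-wave plate at -51.7, -15.1, 15.1, 51.7 degrees -- the
#' condition-number-optimal set for a rotating-retarder generator); `PSA` is
#' the 8x4 matrix whose rows are the analyzer vectors, ordered slider-out
#' (micropolarizers 0, 45, 90, 135 degrees) then slider-in (quarter-wave
#' plate at 0 degrees ahead of the same four micropolarizers). Calibrated
#' instruments can be supplied instead as plain matrices.
#'
#' @return Object of class `instrument_model`: list with `PSG` (4x4), `PSA`
#'   (8x4), and their condition numbers.
#' @export
ideal_instrument <- function() {
  unpol <- c(1, 0, 0, 0)
  psg_cols <- sapply(.psg_angles_deg * pi / 180, function(th) {
    mm_linear_retarder(pi / 2, th) %*% mm_polarizer(0) %*% unpol
  })
  psa_rows <- NULL
  for (slider in c(FALSE, TRUE)) {
    for (phi in c(0, 45, 90, 135) * pi / 180) {
      a <- 0.5 * c(1, cos(2 * phi), sin(2 * phi), 0)
      if (slider) a <- as.numeric(t(a) %*% mm_linear_retarder(pi / 2, 0))
      psa_rows <- rbind(psa_rows, a)
    }
  }
  rownames(psa_rows) <- NULL
  instrument_model(psg_cols, psa_rows)
}

#' @rdname ideal_instrument
#' @param PSG 4x4 matrix of generated Stokes states (columns).
#' @param PSA K x 4 matrix of analyzer vectors (rows), `K >= 4`, rank 4.
#' @export
instrument_model <- function(PSG, PSA) {
  stopifnot(is.matrix(PSG), identical(dim(PSG), c(4L, 4L)))
  stopifnot(is.matrix(PSA), ncol(PSA) == 4L, nrow(PSA) >= 4L)
  sv_g <- svd(PSG, nu = 0, nv = 0)$d
  sv_a <- svd(PSA, nu = 0, nv = 0)$d
  if (max(sv_g) == 0 || min(sv_g) < 1e-10 * max(sv_g)) {
    stop("instrument configuration error: PSG is not invertible", call. = FALSE)
  }
  if (max(sv_a) == 0 || min(sv_a) < 1e-10 * max(sv_a)) {
    stop("instrument configuration error: PSA is rank-deficient", call. = FALSE)
  }
  structure(
    list(
      PSG = PSG, PSA = PSA,
      cond_PSG = max(sv_g) / min(sv_g),
      cond_PSA = max(sv_a) / min(sv_a)
    ),
    class = "instrument_model"
  )
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf(
    "<instrument_model> PSG 4x4 (cond %.2f), PSA %dx4 (cond %.2f); %d frames per measurement\n",
    x$cond_PSG, nrow(x$PSA), x$cond_PSA, nrow(x$PSA) * ncol(x$PSG)
  ))
  invisible(x)
}

#' Acquisition plan arithmetic
#'
#' Frame bookkeeping for the measurement protocol: each Mueller measurement
#' needs (PSG states) x (slider positions) x (micropolarizer orientations)
#' frames -- 4 x 2 x 4 = 32 for the built-in instrument -- and a study with
#' `n_filters` spectral filters and `n_regions` measured regions yields
#' `n_filters * n_regions` Mueller matrices.
#'
#' @param n_filters Number of spectral filters (>= 1).
#' @param n_regions Number of measured regions/views (>= 1).
#' @param instrument An [instrument_model()]; default ideal.
#' @return A list with `frames_per_measurement`, `total_frames`,
#'   `total_mueller_matrices`.
#' @examples
#' plan_acquisition(6, 20) # 3840 frames, 120 Mueller matrices
#' @export
plan_acquisition <- function(n_filters = 1, n_regions = 1,
                             instrument = ideal_instrument()) {
  if (n_filters < 1 || n_regions < 1) {
    stop("n_filters and n_regions must be >= 1", call. = FALSE)
  }
  fpm <- nrow(instrument$PSA) * ncol(instrument$PSG)
  list(
    frames_per_measurement = fpm,
    total_frames = fpm * n_filters * n_regions,
    total_mueller_matrices = n_filters * n_regions
  )
}

#' Forward measurement: Mueller image to intensity frame stack
#'
#' Per pixel, the noiseless intensity for analyzer row `a` and generator
#' state `g` is `PSA[a, ] %*% M %*% PSG[, g]`. Negative noiseless intensities
#' (unphysical matrix/instrument combinations grazing zero) are clamped at 0
#' with a warning and a reported count.
#'
#' @param img A [mueller_image()].
#' @param instrument An [instrument_model()].
#' @return Object of class `frame_stack`: array `K_psa x N_psg x H x W` of
#'   non-negative intensities plus the instrument and wavelength; attribute
#'   `"clamped"` counts clamped values.
#' @export
forward_measure <- function(img, instrument = ideal_instrument()) {
  stopifnot(inherits(img, "mueller_image"), inherits(instrument, "instrument_model"))
  d <- dim(img$data)
  K <- nrow(instrument$PSA)
  Ng <- ncol(instrument$PSG)
  px <- flatten_cube(img) # n x 16
  n <- nrow(px)
  # intensity for pixel p: PSA %*% M_p %*% PSG, flattened to K*Ng values
  # vectorized: I[a,g,p] = sum_ij PSA[a,i] M_p[i,j] PSG[j,g]
  W <- matrix(0, K * Ng, 16L)
  for (a in 1:K) {
    for (g in 1:Ng) {
      W[(g - 1L) * K + a, ] <- as.numeric(outer(instrument$PSA[a, ], instrument$PSG[, g]))
    }
  }
  I <- px %*% t(W) # n x (K*Ng)
  n_clamp <- sum(I < -1e-12)
  if (n_clamp > 0) {
    warning(sprintf("%d negative noiseless intensities clamped to 0", n_clamp))
  }
  I[I < 0] <- 0
  frames <- array(t(I), dim = c(K, Ng, d[1], d[2]))
  structure(
    list(
      frames = frames, instrument = instrument,
      wavelength = img$wavelength, specimen = img$specimen, region = img$region
    ),
    class = "frame_stack", clamped = n_clamp
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d analyzer x %d generator frames of %d x %d px @ %g nm\n",
    d[1], d[2], d[3], d[4], x$wavelength
  ))
  invisible(x)
}

#' Least-squares Mueller reconstruction from a frame stack
#'
#' Per pixel, solves `I = PSA %*% M %*% PSG` for `M` as
#' `M = pinv(PSA) %*% I %*% inv(PSG)`; with `K > 4` analyzer rows this is the
#' least-squares solution over all frames, and for `K = 4` it coincides with
#' the direct two-sided inversion. Reconstruction is linear in the
#' intensities.
#'
#' @param stack A [forward_measure()] frame stack (possibly noise-corrupted).
#' @param instrument Optional [instrument_model()] overriding the one stored
#'   in the stack.
#' @return A [mueller_image()] with an all-`TRUE` mask (screen afterwards).
#' @export
reconstruct_mueller <- function(stack, instrument = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  instr <- if (is.null(instrument)) stack$instrument else instrument
  stopifnot(inherits(instr, "instrument_model"))
  d <- dim(stack$frames)
  K <- d[1]
  Ng <- d[2]
  sv <- svd(instr$PSA)
  pinvA <- sv$v %*% diag(1 / sv$d) %*% t(sv$u) # 4 x K
  Ginv <- solve(instr$PSG)
  # M_p = pinvA %*% I_p %*% Ginv; I_p is K x Ng
  # flatten: vec(M_p) = (t(Ginv) kron pinvA) vec(I_p)
  Tmat <- kronecker(t(Ginv), pinvA) # 16 x (K*Ng)
  I <- matrix(stack$frames, K * Ng, d[3] * d[4]) # (K*Ng) x n
  px <- t(Tmat %*% I) # n x 16
  data <- array(px, dim = c(d[3], d[4], 4L, 4L))
  mueller_image(data, stack$wavelength,
    specimen = stack$specimen, region = stack$region
  )
}
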