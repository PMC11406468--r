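# Core Mueller/Stokes objects and canonical element factories.
#
# Conventions fixed repo-wide:
#   * Stokes components (I, Q, U, V), Q = horizontal - vertical.
#   * Equation-style "(i, j)" element references are 0-based; R storage is
#     1-based, so element (i, j) lives at M[i + 1, j + 1].
#   * Angles are radians everywhere in the API; retarder/diattenuator axes are
#     measured from the horizontal fast axis and folded into (-pi/2, pi/2].

#' Validate and tag a 4x4 Mueller matrix
#'
#' A Mueller matrix is stored as a plain 4x4 numeric matrix; this helper
#' checks shape and finiteness and is used by every factory.
#'
#' @param M A 4x4 numeric matrix.
#' @return The matrix, unchanged.
#' @keywords internal
assert_mueller <- function(M) {
  if (!is.matrix(M) || !identical(dim(M), c(4L, 4L)) || !is.numeric(M)) {
    stop("expected a 4x4 numeric Mueller matrix", call. = FALSE)
  }
  if (!all(is.finite(M))) {
    stop("Mueller matrix contains non-finite entries", call. = FALSE)
  }
  invisible(M)
}

#' Normalize a Mueller matrix by its first element
#'
#' Splits a Mueller matrix into its unnormalized intensity transmittance
#' `M00 = M[1, 1]` and the normalized matrix `m = M / M00` (so `m[1, 1] = 1`).
#' The diattenuation vector is the first row of `m` (elements 1..3, 0-based)
#' and the polarizance vector is the first column.
#'
#' @param M A 4x4 numeric Mueller matrix with positive `M00`.
#' @return A list with elements `M00` (scalar) and `m` (normalized 4x4 matrix).
#' @examples
#' mm_normalize(2.5 * diag(4))
#' @export
mm_normalize <- function(M) {
  assert_mueller(M)
  M00 <- M[1, 1]
  if (!(M00 > 0)) {
    stop("degenerate pixel: M00 must be positive to normalize", call. = FALSE)
  }
  list(M00 = M00, m = M / M00)
}

#' Diattenuation and polarizance vectors of a normalized Mueller matrix
#'
#' @param m A normalized 4x4 Mueller matrix (`m[1, 1] == 1`).
#' @return Length-3 numeric vector.
#' @export
mm_diattenuation <- function(m) {
  assert_mueller(m)
  as.numeric(m[1, 2:4])
}

#' @rdname mm_diattenuation
#' @export
mm_polarizance <- function(m) {
  assert_mueller(m)
  as.numeric(m[2:4, 1])
}

fold_axis <- function(theta) {
  # fold an axis angle into (-pi/2, pi/2]
  th <- (theta + pi / 2) %% pi - pi / 2
  ifelse(th <= -pi / 2 + 1e-15, th + pi, th)
}

rot3 <- function(phi) {
  # Stokes-space rotation of the (Q, U) plane by 2*phi (axis rotation by phi)
  c2 <- cos(2 * phi)
  s2 <- sin(2 * phi)
  matrix(c(
    1, 0, 0, 0,
    0, c2, -s2, 0,
    0, s2, c2, 0,
    0, 0, 0, 1
  ), 4, 4, byrow = TRUE)
}

#' Canonical Mueller element factories
#'
#' Textbook non-depolarizing (and diagonal-depolarizing) Mueller elements used
#' as building blocks for phantoms, oracles, and decompositions:
#'
#' * `mm_depolarizer(a, b, c)`: `diag(1, a, b, c)`. `mm_depolarizer(0, 0, 0)`
#'   is the ideal depolarizer.
#' * `mm_linear_retarder(delta, theta)`: linear retarder of retardance `delta`
#'   (radians, in `[0, pi]`) with fast axis at `theta`.
#' * `mm_rotator(psi)`: optical rotator by `psi` (rotates the Q-U plane by
#'   `2 * psi`).
#' * `mm_linear_diattenuator(D, axis)`: linear diattenuator of diattenuation
#'   `D` in `[0, 1]` along `axis`, normalized so `M00 = 1`.
#' * `mm_polarizer(axis)`: ideal linear polarizer (`D = 1`) at `axis`, with
#'   the conventional overall transmittance factor 1/2.
#'
#' All elements follow the Lu-Chipman sign conventions, so the retardance-axis
#' estimator [retardance_axis()] recovers `theta` exactly.
#'
#' @param a,b,c Diagonal depolarizer entries, each in `[-1, 1]`.
#' @param delta Retardance in radians, in `[0, pi]`.
#' @param theta,axis Element axis in radians.
#' @param psi Rotation angle in radians.
#' @param D Diattenuation in `[0, 1]`.
#' @return A 4x4 numeric Mueller matrix.
#' @examples
#' mm_linear_retarder(pi, 0) # half-wave plate: diag(1, 1, -1, -1)
#' @export
mm_depolarizer <- function(a, b = a, c = a) {
  vals <- c(a, b, c)
  if (any(!is.finite(vals)) || any(abs(vals) > 1)) {
    stop("depolarizer diagonal entries must lie in [-1, 1]", call. = FALSE)
  }
  diag(c(1, a, b, c))
}

#' @rdname mm_depolarizer
#' @export
mm_linear_retarder <- function(delta, theta = 0) {
  if (!is.finite(delta) || delta < 0 || delta > pi) {
    stop("retardance delta must lie in [0, pi]", call. = FALSE)
  }
  cd <- cos(delta)
  sdl <- sin(delta)
  base <- matrix(c(
    1, 0, 0, 0,
    0, 1, 0, 0,
    0, 0, cd, sdl,
    0, 0, -sdl, cd
  ), 4, 4, byrow = TRUE)
  rot3(theta) %*% base %*% rot3(-theta)
}

#' @rdname mm_depolarizer
#' @export
mm_rotator <- function(psi) {
  if (!is.finite(psi)) stop("rotation angle must be finite", call. = FALSE)
  rot3(psi)
}

#' @rdname mm_depolarizer
#' @export
mm_linear_diattenuator <- function(D, axis = 0) {
  if (!is.finite(D) || D < 0 || D > 1) {
    stop("diattenuation D must lie in [0, 1]", call. = FALSE)
  }
  s <- sqrt(pmax(0, 1 - D^2))
  base <- matrix(c(
    1, D, 0, 0,
    D, 1, 0, 0,
    0, 0, s, 0,
    0, 0, 0, s
  ), 4, 4, byrow = TRUE)
  rot3(axis) %*% base %*% rot3(-axis)
}

#' @rdname mm_depolarizer
#' @export
mm_polarizer <- function(axis = 0) {
  base <- 0.5 * matrix(c(
    1, 1, 0, 0,
    1, 1, 0, 0,
    0, 0, 0, 0,
    0, 0, 0, 0
  ), 4, 4, byrow = TRUE)
  rot3(axis) %*% base %*% rot3(-axis)
}

# Jones -> Mueller conversion matrix A with M = A (J kron J*) A^-1
.jones_A <- matrix(c(
  1, 0, 0, 1,
  1, 0, 0, -1,
  0, 1, 1, 0,
  0, 1i, -1i, 0
), 4, 4, byrow = TRUE)
.jones_Ainv <- solve(.jones_A)

#' Mueller matrix of a deterministic (Jones) element
#'
#' Converts a 2x2 complex Jones matrix into its equivalent 4x4 Mueller matrix.
#' The result is always non-depolarizing: its coherency matrix has rank 1.
#'
#' @param J A 2x2 complex matrix.
#' @return A 4x4 numeric Mueller matrix.
#' @export
mm_from_jones <- function(J) {
  if (!is.matrix(J) || !identical(dim(J), c(2L, 2L))) {
    stop("expected a 2x2 Jones matrix", call. = FALSE)
  }
  M <- .jones_A %*% kronecker(J, Conj(J)) %*% .jones_Ainv
  Re(M)
}

#' Random physically realizable Mueller matrices
#'
#' Draws a convex combination of `n_components` Mueller matrices derived from
#' random complex Jones matrices, each scaled so its largest transmittance is
#' below one (passivity). By construction the output passes the ensemble
#' criterion (non-negative coherency eigenvalues plus forward and reverse
#' passivity).
#'
#' @param n_components Number of pure components; `1` yields a pure
#'   (non-depolarizing) matrix.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @param m00_max Upper bound on the resulting `M00` (default 0.5, a
#'   tissue-like reflectance scale).
#' @return A 4x4 numeric Mueller matrix (unnormalized, `M00 <= m00_max`).
#' @export
random_physical_mueller <- function(n_components = 3, seed = NULL,
                                    m00_max = 0.5) {
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(0, 4, 4)
  w <- rexp_weights(n_components)
  for (k in seq_len(n_components)) {
    J <- matrix(stats::rnorm(4), 2, 2) + 1i * matrix(stats::rnorm(4), 2, 2)
    smax <- max(svd(J)$d)
    J <- J / (smax * (1 + 1e-9)) # largest transmittance <= 1: passive
    M <- M + w[k] * mm_from_jones(J)
  }
  scl <- stats::runif(1, 0.2, 1)
  if (M[1, 1] > 0) M <- M * min(1, m00_max / M[1, 1]) * scl
  M
}

rexp_weights <- function(n) {
  w <- stats::rexp(n)
  w / sum(w)
}

#' Multispectral Mueller image
#'
#' The central pixel-wise container: an `H x W x 4 x 4` real array of Mueller
#' matrices at a single wavelength, together with a validity mask (pixels that
#' pass the physical-realizability screen) and specimen/region metadata.
#'
#' @param data An `H x W x 4 x 4` numeric array.
#' @param wavelength Wavelength in nm (any positive value).
#' @param mask Optional `H x W` logical matrix; defaults to all-`TRUE`.
#' @param specimen,region Optional identifier tags.
#' @param m00 Optional `H x W` matrix of unnormalized `M00` values (when
#'   `data` stores normalized matrices).
#' @return An object of class `mueller_image`.
#' @export
mueller_image <- function(data, wavelength, mask = NULL, specimen = NA_character_,
                          region = NA_character_, m00 = NULL) {
  d <- dim(data)
  if (length(d) != 4L || d[3] != 4L || d[4] != 4L) {
    stop("data must be an H x W x 4 x 4 array", call. = FALSE)
  }
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop("wavelength must be positive", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2])) {
    stop("mask shape must match image shape", call. = FALSE)
  }
  structure(
    list(
      data = data, wavelength = wavelength, mask = mask,
      specimen = specimen, region = region, m00 = m00
    ),
    class = "mueller_image"
  )
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<mueller_image> %d x %d pixels @ %g nm (specimen %s, region %s); %.1f%% valid\n",
    d[1], d[2], x$wavelength, x$specimen, x$region, 100 * mean(x$mask)
  ))
  invisible(x)
}

#' @export
dim.mueller_image <- function(x) dim(x$data)[1:2]

#' Extract the Mueller matrix at one pixel
#'
#' @param img A [mueller_image()].
#' @param i,j Pixel row and column (1-based).
#' @return A 4x4 numeric matrix.
#' @export
pixel_matrix <- function(img, i, j) {
  matrix(img$data[i, j, , ], 4, 4)
}

#' Stokes vector helpers
#'
#' `stokes()` builds a length-4 Stokes vector `(I, Q, U, V)`;
#' `degree_of_polarization()` returns `sqrt(Q^2 + U^2 + V^2) / I`.
#'
#' @param I,Q,U,V Stokes components.
#' @return `stokes()`: a numeric length-4 vector; `degree_of_polarization()`:
#'   a scalar.
#' @export
stokes <- function(I, Q = 0, U = 0, V = 0) {
  s <- c(I, Q, U, V)
  if (any(!is.finite(s))) stop("Stokes components must be finite", call. = FALSE)
  s
}

#' @rdname stokes
#' @param s A length-4 Stokes vector.
#' @export
degree_of_polarization <- function(s) {
  if (s[1] <= 0) stop("Stokes intensity must be positive", call. = FALSE)
  sqrt(sum(s[2:4]^2)) / s[1]
}

# Flatten an image cube into an n_pixels x 16 matrix (row-major over pixels,
# column-major over the 4x4 elements) for the compiled kernels.
flatten_cube <- function(img) {
  d <- dim(img$data)
  matrix(img$data, d[1] * d[2], 16L)
}
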