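# Five-layer symmetric decomposition M = MD2 . MR2 . MDelta_d . MR1^T . MD1
# with all depolarization confined to a diagonal depolarizer.

#' Diagonalizability precondition for the symmetric decomposition
#'
#' The symmetric decomposition requires `N = G M^T G M` (with
#' `G = diag(1, -1, -1, -1)`) to be diagonalizable with real, non-negative
#' eigenvalues. Returns `TRUE` when the eigenvalues are real and non-negative
#' within tolerance and the eigenvector matrix is well conditioned.
#'
#' @param M A 4x4 numeric Mueller matrix.
#' @param tol Relative tolerance on eigenvalue imaginary parts/negativity.
#' @return Logical.
#' @export
is_symmetric_diagonalizable <- function(M, tol = 1e-6) {
  assert_mueller(M)
  N <- G_METRIC %*% t(M) %*% G_METRIC %*% M
  ev <- eigen(N)
  scale <- max(abs(ev$values), 1e-12)
  if (max(abs(Im(ev$values))) > tol * scale) {
    return(FALSE)
  }
  if (min(Re(ev$values)) < -tol * scale) {
    return(FALSE)
  }
  V <- ev$vectors
  # defective (Jordan-block) N has a numerically singular eigenvector matrix
  rc <- rcond_cplx(V)
  rc > 1e-8
}

rcond_cplx <- function(V) {
  sv <- svd(V, nu = 0, nv = 0)$d
  if (max(sv) == 0) {
    return(0)
  }
  min(sv) / max(sv)
}

#' Five-layer symmetric decomposition
#'
#' Factors a normalized Mueller matrix as
#' `m = MD2 %*% MR2 %*% MDelta_d %*% t(MR1) %*% MD1`, isolating all
#' depolarization in the diagonal depolarizer
#' `MDelta_d = diag(d0, d1, d2, d3)`. The two diattenuation vectors come from
#' the eigenvector (largest eigenvalue, first component scaled to 1) of
#' `M^T G M G` (for `MD1`) and `M G M^T G` (for `MD2`); the stripped matrix
#' `M' = MD2^{-1} m MD1^{-1}` is then factored by SVD of its 3x3 block into
#' `MR2 MDelta_d MR1^T`. Both SVD frames are forced to proper rotations
#' (determinant +1); any reflection is pushed into the sign of `d3`.
#'
#' When the leading eigenvalue is (near-)degenerate -- e.g. for a pure
#' retarder, where any vector is an eigenvector -- the diattenuation vector is
#' taken as the projection of `(1, 0, 0, 0)` onto the leading eigenspace,
#' which correctly yields zero diattenuation.
#'
#' @param m A normalized, realizable 4x4 Mueller matrix that passes
#'   [is_symmetric_diagonalizable()].
#' @param tol Validity tolerance (diattenuations above `1 + tol` flag the
#'   result invalid).
#' @return Object of class `symmetric_result`: matrices `M_D1`, `M_D2`,
#'   `M_R1`, `M_R2`, `M_delta_d`, diagonal `d` (length 4), scalars `D1`, `D2`,
#'   total retarder `M_R` (`= MR2 MR1^T`, free of the SVD rotation gauge) and
#'   its retardance `R`, depolarization `Delta` (from the diagonal
#'   depolarizer), `residual`, and `valid`.
#' @export
symmetric_decompose <- function(m, tol = 1e-6) {
  assert_mueller(m)
  if (abs(m[1, 1] - 1) > 1e-8) {
    stop("symmetric_decompose expects a normalized matrix", call. = FALSE)
  }
  valid <- TRUE
  D1v <- diatt_vector_from_eigen(t(m) %*% G_METRIC %*% m %*% G_METRIC)
  D2v <- diatt_vector_from_eigen(m %*% G_METRIC %*% t(m) %*% G_METRIC)
  D1 <- sqrt(sum(D1v^2))
  D2 <- sqrt(sum(D2v^2))
  if (is.na(D1) || is.na(D2) || D1 > 1 + tol || D2 > 1 + tol) {
    valid <- FALSE
  }
  clip <- function(v) {
    n <- sqrt(sum(v^2))
    if (n >= 1 - 1e-9) v * ((1 - 1e-9) / n) else v
  }
  D1v <- clip(D1v)
  D2v <- clip(D2v)
  MD1 <- diattenuator_from_vector(D1v)
  MD2 <- diattenuator_from_vector(D2v)
  Mp <- solve(MD2) %*% m %*% solve(MD1)
  d0 <- Mp[1, 1]
  sv <- svd(Mp[2:4, 2:4])
  U <- sv$u
  V <- sv$v
  dd <- sv$d
  if (det(U) < 0) {
    U[, 3] <- -U[, 3]
    dd[3] <- -dd[3]
  }
  if (det(V) < 0) {
    V[, 3] <- -V[, 3]
    dd[3] <- -dd[3]
  }
  MR2 <- diag(4)
  MR2[2:4, 2:4] <- U
  MR1 <- diag(4)
  MR1[2:4, 2:4] <- V
  M_delta_d <- diag(c(d0, dd))
  recon <- MD2 %*% MR2 %*% M_delta_d %*% t(MR1) %*% MD1
  # total retarder in the factor order of m, free of the SVD rotation gauge
  M_R <- MR2 %*% t(MR1)
  R <- acos(min(1, max(-1, sum(diag(M_R)) / 2 - 1)))
  Delta <- 1 - abs(sum(dd)) / (3 * max(d0, .Machine$double.eps))
  structure(
    list(
      M_D1 = MD1, M_D2 = MD2, M_R1 = MR1, M_R2 = MR2,
      M_delta_d = M_delta_d, d = c(d0, dd),
      D1 = D1, D2 = D2, M_R = M_R, R = R, Delta = Delta,
      residual = sqrt(sum((m - recon)^2)), valid = valid
    ),
    class = "symmetric_result"
  )
}

#' @export
print.symmetric_result <- function(x, ...) {
  cat(sprintf(
    "<symmetric_result> d = (%.4f, %.4f, %.4f, %.4f), R = %.4f, D1 = %.4f, D2 = %.4f, residual = %.2e%s\n",
    x$d[1], x$d[2], x$d[3], x$d[4], x$R, x$D1, x$D2, x$residual,
    if (x$valid) "" else " [invalid]"
  ))
  invisible(x)
}

# First-component-to-1 scaled eigenvector of the largest eigenvalue; handles
# degenerate leading eigenspaces by projecting e1 onto them.
diatt_vector_from_eigen <- function(A, degeneracy_tol = 1e-7) {
  ev <- eigen(A)
  vals <- Re(ev$values)
  scale <- max(abs(vals), 1e-12)
  lead <- which(vals >= max(vals) - degeneracy_tol * scale)
  V <- Re(ev$vectors[, lead, drop = FALSE])
  # projection of e1 = (1,0,0,0) onto the leading eigenspace
  qrV <- qr(V)
  Q <- qr.Q(qrV)
  s <- as.numeric(Q %*% crossprod(Q, c(1, 0, 0, 0)))
  if (abs(s[1]) < 1e-9) {
    return(rep(NA_real_, 3))
  }
  s <- s / s[1]
  s[2:4]
}

#' Total retarder of the symmetric decomposition
#'
#' Combines the two retarders into the gauge-invariant total retarder
#' `M_R = MR2 %*% t(MR1)` and its retardance `R`. Multiplying both SVD frames
#' by a common rotation leaves this product unchanged.
#'
#' @param MR1,MR2 4x4 retarder matrices from [symmetric_decompose()].
#' @return List with `M_R` and `R` (radians).
#' @export
total_retarder <- function(MR1, MR2) {
  assert_mueller(MR1)
  assert_mueller(MR2)
  M_R <- MR2 %*% t(MR1)
  R <- acos(min(1, max(-1, sum(diag(M_R)) / 2 - 1)))
  list(M_R = M_R, R = R)
}

#' Symmetric-decomposition maps for a Mueller image
#'
#' Per-pixel `Delta` (from the diagonal depolarizer), total retardance `R`,
#' and the two diattenuations `D1`, `D2`. Pixels outside the mask or failing
#' the diagonalizability precondition are `NA` (their count is reported in
#' the `"invalid_count"` attribute).
#'
#' @param img A screened [mueller_image()] with normalized matrices.
#' @return Object of class `symmetric_maps` (also `map_set`).
#' @export
symmetric_maps <- function(img) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img$data)
  px <- flatten_cube(img)
  out <- symmetric_pixels_cpp(px, as.logical(img$mask))
  nm <- c("Delta", "R", "D1", "D2")
  maps <- stats::setNames(
    lapply(seq_along(nm), function(k) matrix(out[, k], d[1], d[2])), nm
  )
  res <- structure(
    c(maps, list(wavelength = img$wavelength, mask = img$mask)),
    class = c("symmetric_maps", "map_set")
  )
  attr(res, "invalid_count") <- sum(is.na(out[, 1]) & as.logical(img$mask))
  res
}
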