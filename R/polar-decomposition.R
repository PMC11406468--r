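# Forward polar (Lu-Chipman) decomposition M = M_Delta . M_R . M_D and the
# retardance-axis map.

#' Forward polar (Lu-Chipman) decomposition
#'
#' Factors a normalized Mueller matrix as `m = M_Delta %*% M_R %*% M_D`
#' (depolarizer, retarder, diattenuator) and extracts the scalar magnitudes
#'
#' * depolarization `Delta = 1 - |trace(M_Delta) - 1| / 3` in `[0, 1]`,
#' * retardance `R = acos(trace(M_R) / 2 - 1)` in `[0, pi]`,
#' * diattenuation `D = ||D_vec||` in `[0, 1]`.
#'
#' `M_D` is built from the diattenuation vector (first row of `m`) via the
#' standard rank-one plus isotropic form; `M_Delta`'s 3x3 block is the signed
#' symmetric square root of `m' m'^T` (with `m' = m M_D^{-1}` stripped of its
#' first row), the sign branch fixed by `sign(det m')`; `M_R = M_Delta^{-1} m'`.
#'
#' @param m A normalized, physically realizable 4x4 Mueller matrix (screen
#'   first; see [screen_image()]).
#' @param d_clip Diattenuations above `1 - 1e-9` are clipped there and the
#'   result flagged (`MD` would be singular).
#' @return An object of class `polar_result`: list with matrices `M_delta`,
#'   `M_R`, `M_D`, scalars `Delta`, `R`, `D`, the retarder split `M_LR`,
#'   `M_psi`, `delta`, `psi`, axis `theta`, `residual` (Frobenius norm of
#'   `m - M_delta M_R M_D`), and logical `flags` (`d_clipped`,
#'   `depolarizer_singular`, `axis_undefined`).
#' @export
lu_chipman <- function(m, d_clip = 1 - 1e-9) {
  assert_mueller(m)
  if (abs(m[1, 1] - 1) > 1e-8) {
    stop("lu_chipman expects a normalized matrix (m[1,1] == 1)", call. = FALSE)
  }
  flags <- c(d_clipped = FALSE, depolarizer_singular = FALSE, axis_undefined = FALSE)

  Dvec <- m[1, 2:4]
  D <- sqrt(sum(Dvec^2))
  if (D >= d_clip) {
    Dvec <- Dvec * (d_clip / D)
    D <- d_clip
    flags["d_clipped"] <- TRUE
  }
  MD <- diattenuator_from_vector(Dvec)
  Mp <- m %*% solve(MD)
  mp <- Mp[2:4, 2:4]
  Pdel <- Mp[2:4, 1]

  mmT <- mp %*% t(mp)
  ev <- eigen((mmT + t(mmT)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0) # descending
  dets <- det(mp)
  sgn <- if (dets < 0) -1 else 1
  mdelta <- ev$vectors %*% diag(sgn * sqrt(lam)) %*% t(ev$vectors)

  if (min(sqrt(lam)) < 1e-12) {
    flags["depolarizer_singular"] <- TRUE
    mr <- diag(3)
  } else {
    mr <- solve(mdelta, mp)
  }
  M_delta <- diag(4)
  M_delta[2:4, 1] <- Pdel
  M_delta[2:4, 2:4] <- mdelta
  M_R <- diag(4)
  M_R[2:4, 2:4] <- mr

  Delta <- 1 - abs(sum(diag(mdelta))) / 3
  R <- acos(min(1, max(-1, sum(diag(M_R)) / 2 - 1)))
  recon <- M_delta %*% M_R %*% MD
  split <- retarder_split(M_R)
  flags["axis_undefined"] <- !split$defined
  theta <- if (split$defined) retardance_axis(split$M_LR) else NA_real_

  structure(
    list(
      M_delta = M_delta, M_R = M_R, M_D = MD,
      Delta = Delta, R = R, D = D,
      M_LR = split$M_LR, M_psi = split$M_psi,
      delta = split$delta, psi = split$psi, theta = theta,
      residual = sqrt(sum((m - recon)^2)),
      flags = flags
    ),
    class = "polar_result"
  )
}

#' @export
print.polar_result <- function(x, ...) {
  cat(sprintf(
    "<polar_result> Delta = %.4f, R = %.4f rad, D = %.4f, theta = %s, residual = %.2e\n",
    x$Delta, x$R, x$D,
    if (is.na(x$theta)) "NA" else sprintf("%.4f rad", x$theta), x$residual
  ))
  invisible(x)
}

# Canonical diattenuator from its diattenuation vector (normalized, M00 = 1).
diattenuator_from_vector <- function(Dvec) {
  D <- sqrt(sum(Dvec^2))
  MD <- diag(4)
  MD[1, 2:4] <- Dvec
  MD[2:4, 1] <- Dvec
  s <- sqrt(max(0, 1 - D^2))
  mD <- s * diag(3)
  if (D > 0) {
    dh <- Dvec / D
    mD <- mD + (1 - s) * tcrossprod(dh)
  }
  MD[2:4, 2:4] <- mD
  MD
}

#' Split a retarder into linear retarder and rotator
#'
#' Factors a retarder `M_R = M_LR %*% M_psi` into a linear retarder of
#' retardance `delta` and an optical rotation by `psi`. The rotation angle is
#' the one that makes the upper-left 2x2 of `M_LR`'s 3x3 block symmetric.
#' Composing the two factors reproduces `M_R` (checked by `residual`).
#'
#' @param MR A 4x4 retarder Mueller matrix (orthogonal 3x3 block).
#' @param tol Retarders with total retardance within `tol` of 0 have
#'   `delta = psi = 0` by convention; within `tol` of `pi` the split is
#'   returned but flagged (`defined = FALSE`) because the rotation is
#'   ambiguous there.
#' @return List with `M_LR`, `M_psi`, `delta`, `psi`, `residual`, `defined`.
#' @export
retarder_split <- function(MR, tol = 1e-6) {
  assert_mueller(MR)
  b <- MR[2:4, 2:4]
  if (max(abs(crossprod(b) - diag(3))) > 1e-6) {
    stop("retarder_split expects an orthogonal 3x3 retarder block", call. = FALSE)
  }
  R <- acos(min(1, max(-1, (sum(diag(b)) - 1) / 2)))
  if (R < tol) {
    return(list(
      M_LR = diag(4), M_psi = diag(4), delta = 0, psi = 0,
      residual = sqrt(sum((MR - diag(4))^2)), defined = TRUE
    ))
  }
  psi <- 0.5 * atan2(b[2, 1] - b[1, 2], b[1, 1] + b[2, 2])
  M_psi <- mm_rotator(psi)
  M_LR <- MR %*% t(M_psi) # rotator inverse = transpose
  blr <- M_LR[2:4, 2:4]
  delta <- atan2(sqrt(blr[3, 1]^2 + blr[3, 2]^2), blr[3, 3])
  recon <- M_LR %*% M_psi
  list(
    M_LR = M_LR, M_psi = M_psi, delta = delta, psi = psi,
    residual = sqrt(sum((MR - recon)^2)),
    defined = R < pi - tol
  )
}

#' Orientation of the linear-retardance axis
#'
#' Quadrant-correct axis estimator
#' `theta = 0.5 * atan2(M_LR(3,1) - M_LR(1,3), M_LR(2,3) - M_LR(3,2))`
#' (0-based element indices), folded into `(-pi/2, pi/2]`. Recovers the
#' fast-axis angle of [mm_linear_retarder()] exactly.
#'
#' @param MLR A 4x4 linear-retarder Mueller matrix whose retardance is not
#'   congruent to 0 (mod pi).
#' @param tol Below this magnitude of both numerator and denominator the axis
#'   is undefined and `NA` is returned.
#' @return Axis angle in radians, in `(-pi/2, pi/2]`, or `NA`.
#' @export
retardance_axis <- function(MLR, tol = 1e-9) {
  assert_mueller(MLR)
  num <- MLR[4, 2] - MLR[2, 4]
  den <- MLR[3, 4] - MLR[4, 3]
  if (abs(num) < tol && abs(den) < tol) {
    return(NA_real_)
  }
  fold_axis(0.5 * atan2(num, den))
}

#' Lu-Chipman parameter maps for a Mueller image
#'
#' Runs [lu_chipman()] at every masked pixel (compiled kernel) and returns
#' `Delta`, `R`, `D`, `theta` maps. Pixels outside the mask are `NA`;
#' `theta` is additionally `NA` where the retardance is too close to 0 or pi
#' for the axis to be defined.
#'
#' @param img A screened [mueller_image()] holding normalized matrices.
#' @return An object of class `polar_maps` (also `map_set`): list of `H x W`
#'   matrices `Delta`, `R`, `D`, `theta`, plus `wavelength`, `mask`, and a
#'   `residual` summary.
#' @export
polar_maps <- function(img) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img$data)
  px <- flatten_cube(img)
  out <- polar_pixels_cpp(px, as.logical(img$mask))
  nm <- c("Delta", "R", "D", "theta")
  maps <- stats::setNames(
    lapply(seq_along(nm), function(k) matrix(out[, k], d[1], d[2])), nm
  )
  structure(
    c(maps, list(
      wavelength = img$wavelength, mask = img$mask,
      residual = stats::quantile(out[, 5], c(0.5, 1), na.rm = TRUE, names = FALSE)
    )),
    class = c("polar_maps", "map_set")
  )
}
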