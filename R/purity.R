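# Indices of polarimetric purity and anisotropy coefficients.

#' Indices of polarimetric purity
#'
#' From the sorted, trace-normalized coherency eigenvalues
#' `l0 >= l1 >= l2 >= l3` computes
#' `P1 = l0 - l1`, `P2 = l0 + l1 - 2 l2`, `P3 = 1 - 4 l3`, and the degree of
#' polarimetric purity
#' `P_delta = sqrt((1/3) (2 P1^2 + (2/3) P2^2 + (1/3) P3^2))`.
#' The indices satisfy `0 <= P1 <= P2 <= P3 <= 1`; a pure matrix has all four
#' equal to 1 and the ideal depolarizer has all four equal to 0. Eigenvalues
#' within `-tol` of zero are clipped to zero before normalization.
#'
#' @param x A 4x4 Mueller matrix or a [coherency_matrix()] result.
#' @param tol Clipping tolerance for slightly negative eigenvalues.
#' @return A list with `P1`, `P2`, `P3`, `P_delta`.
#' @export
polarimetric_purity <- function(x, tol = 1e-9) {
  ch <- if (inherits(x, "coherency")) x else coherency_matrix(x)
  ev <- ch$eigenvalues
  ev[ev > -tol & ev < 0] <- 0
  tr <- sum(ev)
  if (!(tr > 0)) {
    return(list(P1 = NA_real_, P2 = NA_real_, P3 = NA_real_, P_delta = NA_real_))
  }
  lh <- sort(ev / tr, decreasing = TRUE)
  P1 <- lh[1] - lh[2]
  P2 <- lh[1] + lh[2] - 2 * lh[3]
  P3 <- 1 - 4 * lh[4]
  Pd <- sqrt((2 * P1^2 + (2 / 3) * P2^2 + (1 / 3) * P3^2) / 3)
  list(P1 = P1, P2 = P2, P3 = P3, P_delta = Pd)
}

#' Complementary k, r, q vectors of a normalized Mueller matrix
#'
#' Reads the layout of the lower-right 3x3 block
#' `m3x3 = [[k1, r3, r2], [q3, k2, r1], [q2, q1, k3]]` and returns the vectors
#' k = (k1, k2, k3) / sqrt(3), r = (r1, r2, r3), q = (q1, q2, q3).
#'
#' @param m A normalized 4x4 Mueller matrix (`m[1, 1] == 1`).
#' @return A list with numeric length-3 vectors `k`, `r`, `q`.
#' @export
kqr_vectors <- function(m) {
  assert_mueller(m)
  list(
    k = c(m[2, 2], m[3, 3], m[4, 4]) / sqrt(3),
    r = c(m[3, 4], m[2, 4], m[2, 3]),
    q = c(m[4, 3], m[4, 2], m[3, 2])
  )
}

#' Linear and circular anisotropy coefficients
#'
#' With `D` and `P` the diattenuation and polarizance vectors and `k`, `r`,
#' `q` from [kqr_vectors()], defines
#' `Sigma = 3 (1 - ||k||^2) + 2 D'P - 2 r'q` and
#' \deqn{\alpha_L = [(D_1+P_1)^2 + (r_1-q_1)^2 +
#'   (D_2+P_2)^2 + (r_2-q_2)^2] / \Sigma,}
#' \deqn{\alpha_C = [(D_3+P_3)^2 + (r_3-q_3)^2] / \Sigma,}
#' and the overall degree of anisotropy `P_alpha = sqrt(aL^2 + aC^2)`.
#'
#' With these definitions `Sigma` obeys the identity
#' `Sigma = 3 (1 - P_delta^2) + 2 A^2`, where `A^2` is the squared norm of
#' the G-antisymmetric content of `m` (the numerator sum over all three
#' channels), so every pure anisotropic element saturates `P_alpha = 1` (a
#' polarizer or any linear retarder has `alpha_L = 1`; a rotator has
#' `alpha_C = 1`) and the chain `P_alpha <= P_delta <= 1` holds for every
#' physically realizable matrix.
#'
#' @param m A normalized 4x4 Mueller matrix.
#' @param eps Degeneracy guard: `Sigma <= eps` (a non-depolarizing pixel with
#'   vanishing denominator, e.g. the identity) yields `NA` coefficients with
#'   `defined = FALSE`.
#' @return A list with `alpha_L`, `alpha_C`, `P_alpha`, `Sigma`, `defined`.
#' @export
anisotropy_coefficients <- function(m, eps = 1e-12) {
  assert_mueller(m)
  v <- kqr_vectors(m)
  D <- mm_diattenuation(m)
  P <- mm_polarizance(m)
  Sigma <- 3 * (1 - sum(v$k^2)) + 2 * sum(D * P) - 2 * sum(v$r * v$q)
  if (!is.finite(Sigma) || Sigma <= eps) {
    return(list(
      alpha_L = NA_real_, alpha_C = NA_real_, P_alpha = NA_real_,
      Sigma = Sigma, defined = FALSE
    ))
  }
  aL <- ((D[1] + P[1])^2 + (v$r[1] - v$q[1])^2 +
    (D[2] + P[2])^2 + (v$r[2] - v$q[2])^2) / Sigma
  aC <- ((D[3] + P[3])^2 + (v$r[3] - v$q[3])^2) / Sigma
  list(
    alpha_L = aL, alpha_C = aC, P_alpha = sqrt(aL^2 + aC^2),
    Sigma = Sigma, defined = TRUE
  )
}

#' Purity and anisotropy maps for a Mueller image
#'
#' Computes per-pixel `P1`, `P2`, `P3`, `P_delta`, `alpha_L`, `alpha_C`,
#' `P_alpha`. Pixels outside the realizability mask (or with undefined
#' quantities) are `NA`.
#'
#' @param img A [mueller_image()], ideally screened with [screen_image()].
#' @return An object of class `purity_maps`: a list of `H x W` matrices (one
#'   per quantity) plus `wavelength` and `mask`.
#' @export
purity_maps <- function(img) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img$data)
  px <- flatten_cube(img)
  out <- purity_pixels_cpp(px, as.logical(img$mask))
  nm <- c("P1", "P2", "P3", "P_delta", "alpha_L", "alpha_C", "P_alpha")
  maps <- stats::setNames(
    lapply(seq_along(nm), function(k) matrix(out[, k], d[1], d[2])), nm
  )
  structure(
    c(maps, list(wavelength = img$wavelength, mask = img$mask)),
    class = c("purity_maps", "map_set")
  )
}
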