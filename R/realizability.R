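# Physical-realizability screening: coherency matrix, ensemble criterion,
# and pixel-wise mask generation.

#' Coherency matrix of a Mueller matrix
#'
#' Builds the Hermitian coherency matrix `H = (1/4) sum_ij M_ij sigma_i (x)
#' conj(sigma_j)` in the Pauli basis (sigma_0 = I, sigma_1 = diag(1, -1),
#' sigma_2 = real off-diagonal, sigma_3 = imaginary off-diagonal; the second
#' factor is conjugated so that the identity Mueller matrix maps to a rank-one
#' projector). `trace(H) = M00`; `M` is an ensemble of deterministic optical
#' elements exactly when all eigenvalues of `H` are non-negative.
#'
#' @param M A 4x4 numeric Mueller matrix.
#' @return A list of class `coherency` with elements `H` (4x4 complex
#'   Hermitian), `eigenvalues` (sorted descending), and `eigenvalues_hat`
#'   (trace-normalized, `NA` when the trace is zero).
#' @export
coherency_matrix <- function(M) {
  assert_mueller(M)
  H <- matrix(0 + 0i, 4, 4)
  for (k in 1:16) {
    i <- (k - 1L) %/% 4L + 1L
    j <- (k - 1L) %% 4L + 1L
    H <- H + M[i, j] * .pauli[[k]]
  }
  H <- H / 4
  H <- (H + Conj(t(H))) / 2 # enforce exact Hermiticity against roundoff
  ev <- sort(Re(eigen(H, symmetric = TRUE, only.values = TRUE)$values),
    decreasing = TRUE
  )
  tr <- sum(ev)
  structure(
    list(
      H = H,
      eigenvalues = ev,
      eigenvalues_hat = if (abs(tr) > 0) ev / tr else rep(NA_real_, 4)
    ),
    class = "coherency"
  )
}

#' @export
print.coherency <- function(x, ...) {
  cat("<coherency> eigenvalues:", signif(x$eigenvalues, 6), "\n")
  invisible(x)
}

#' Ensemble criterion for physical realizability
#'
#' A Mueller matrix is accepted as physically realizable when (1) all
#' eigenvalues of its coherency matrix are non-negative (within a tolerance
#' relative to `trace(H)`, since matrices arrive at arbitrary intensity
#' scale), and (2) the forward and reverse passivity conditions
#' `M00 (1 + ||D||) <= 1` and `M00 (1 + ||P||) <= 1` hold within the same
#' tolerance. The default tolerance is `1e-5`.
#'
#' Passivity needs the unnormalized `M00`; when `M` is already normalized
#' (`M[1,1] == 1`), supply the true intensity scale via `m00`.
#'
#' @param M A 4x4 numeric Mueller matrix (unnormalized unless `m00` is given).
#' @param tol Positive tolerance (default `1e-5`).
#' @param m00 Optional intensity scale overriding `M[1, 1]`.
#' @return A list with `pass` (logical), `min_eigenvalue_hat` (smallest
#'   trace-normalized coherency eigenvalue), and `passivity_margins`
#'   (`1 + tol - M00 (1 + ||D||)`, forward then reverse; non-negative means
#'   the condition holds).
#' @export
ensemble_criterion <- function(M, tol = 1e-5, m00 = NULL) {
  assert_mueller(M)
  if (!(tol > 0)) stop("tol must be positive", call. = FALSE)
  ch <- coherency_matrix(M)
  tr <- sum(ch$eigenvalues)
  min_hat <- if (abs(tr) > 0) min(ch$eigenvalues) / tr else min(ch$eigenvalues)
  eig_ok <- min(ch$eigenvalues) >= -tol * max(abs(tr), .Machine$double.eps)
  M00 <- if (is.null(m00)) M[1, 1] else m00
  nm <- if (M[1, 1] != 0) M / M[1, 1] else M
  Dn <- sqrt(sum(nm[1, 2:4]^2))
  Pn <- sqrt(sum(nm[2:4, 1]^2))
  marg_fwd <- 1 + tol - M00 * (1 + Dn)
  marg_rev <- 1 + tol - M00 * (1 + Pn)
  list(
    pass = eig_ok && marg_fwd >= 0 && marg_rev >= 0,
    min_eigenvalue_hat = min_hat,
    passivity_margins = c(forward = marg_fwd, reverse = marg_rev)
  )
}

#' Pixel-wise realizability mask for a Mueller image
#'
#' Applies [ensemble_criterion()] to every pixel and returns the image with
#' its `mask` field replaced: `TRUE` marks pixels that pass. Downstream map
#' and summary functions honor this mask (failing pixels yield `NA`s and are
#' excluded from statistics), mirroring the exclusion policy used for
#' measured data.
#'
#' @param img A [mueller_image()]. If the cube stores normalized matrices, the
#'   per-pixel intensity scale is taken from `img$m00` when present, else from
#'   `m00_scale`.
#' @param tol Tolerance passed to the criterion (default `1e-5`).
#' @param m00_scale Reflectance scale assumed for normalized cubes without
#'   stored `M00` (default 0.4; tissue reflectance is well below the passivity
#'   bound, so the check remains meaningful).
#' @return The image with an updated `mask`, plus attribute `"screen_report"`
#'   (list with `n_pixels`, `n_fail`, `fail_fraction`).
#' @export
screen_image <- function(img, tol = 1e-5, m00_scale = 0.4) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img$data)
  px <- flatten_cube(img)
  m00 <- if (!is.null(img$m00)) {
    as.numeric(img$m00)
  } else {
    # column 1 of px is M00; if the cube is normalized, rescale
    ifelse(abs(px[, 1] - 1) < 1e-12, m00_scale, px[, 1])
  }
  ok <- screen_pixels_cpp(px, m00, tol)
  mask <- matrix(ok, d[1], d[2])
  img$mask <- mask
  attr(img, "screen_report") <- list(
    n_pixels = length(ok),
    n_fail = sum(!ok),
    fail_fraction = mean(!ok),
    tol = tol
  )
  img
}
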