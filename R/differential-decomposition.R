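# Differential (matrix-logarithm) decomposition: L = ln m, split into
# G-antisymmetric (mean spectroscopic properties) and G-symmetric
# (fluctuation variances/covariances) parts. All quantities are per single
# traversal of the medium (path length z = 1).

#' Principal matrix logarithm of a Mueller matrix
#'
#' Computes the real principal logarithm via the complex eigendecomposition:
#' eigenvalues on the closed negative real axis (possible for retardance near
#' pi combined with strong depolarization) have no principal logarithm, and
#' such inputs are flagged rather than branch-shifted, since any branch choice
#' offsets the retardance entries by multiples of 2 pi.
#'
#' @param m A normalized 4x4 Mueller matrix.
#' @param tol Eigenvalues with `|Im| < tol` and `Re <= tol` are treated as
#'   lying on the negative real axis / at zero.
#' @return A list with `L` (4x4 real matrix, or `NA`-filled when undefined)
#'   and `defined` (logical).
#' @export
mueller_log <- function(m, tol = 1e-12) {
  assert_mueller(m)
  ev <- eigen(m)
  vals <- ev$values
  if (any(Re(vals) <= tol & abs(Im(vals)) < tol)) {
    return(list(L = matrix(NA_real_, 4, 4), defined = FALSE))
  }
  V <- ev$vectors
  if (rcond_cplx(V) < 1e-10) {
    # near-defective: fall back to an inverse-scaling-and-squaring log
    L <- log_via_sqrt(m)
    if (is.null(L)) {
      return(list(L = matrix(NA_real_, 4, 4), defined = FALSE))
    }
    return(list(L = L, defined = TRUE))
  }
  L <- V %*% diag(log(vals + 0i)) %*% solve(V)
  list(L = Re(L), defined = TRUE)
}

# Inverse scaling and squaring: repeated principal square roots (Denman-
# Beavers iteration) until close to I, then log via Pade-free series.
log_via_sqrt <- function(m, max_sqrt = 30) {
  A <- m
  k <- 0
  while (max(abs(A - diag(4))) > 0.3 && k < max_sqrt) {
    Y <- A
    Z <- diag(4)
    for (it in 1:60) {
      Yn <- 0.5 * (Y + solve(Z))
      Zn <- 0.5 * (Z + solve(Y))
      if (max(abs(Yn - Y)) < 1e-14) break
      Y <- Yn
      Z <- Zn
    }
    A <- Y
    k <- k + 1
  }
  if (max(abs(A - diag(4))) > 0.5) {
    return(NULL)
  }
  X <- A - diag(4)
  L <- matrix(0, 4, 4)
  P <- diag(4)
  for (n in 1:60) {
    P <- P %*% X
    L <- L + ((-1)^(n + 1) / n) * P
    if (max(abs(P)) < 1e-17) break
  }
  L * 2^k
}

#' G-antisymmetric / G-symmetric split of the matrix logarithm
#'
#' With the Minkowski metric `G = diag(1, -1, -1, -1)` and the G-transpose
#' `A^G = G A^T G`, splits `L = Lm + Lu` where `Lm = (L - G L^T G) / 2` is
#' G-antisymmetric (mean spectroscopic properties) and
#' `Lu = (L + G L^T G) / 2` is G-symmetric (depolarization / fluctuations).
#'
#' @param L A 4x4 real matrix (the Mueller log).
#' @return List with `Lm` and `Lu`; `Lm + Lu == L` exactly.
#' @export
g_split <- function(L) {
  assert_mueller(L)
  LG <- G_METRIC %*% t(L) %*% G_METRIC
  list(Lm = (L - LG) / 2, Lu = (L + LG) / 2)
}

#' Mean spectroscopic properties from the G-antisymmetric log component
#'
#' Reads the six mean properties off the fixed template (0-based indices)
#' `Lm = [[0, -LDH, -LD45, CD], [-LDH, 0, CB, LB45], [-LD45, -CB, 0, -LBH],
#' [CD, -LB45, LBH, 0]]`: linear dichroism along horizontal (`LDH`) and 45
#' degree (`LD45`) axes, circular dichroism `CD`, linear birefringence `LBH`,
#' `LB45`, and circular birefringence `CB`. Dichroic entries are
#' dimensionless per traversal; birefringent entries are radians per
#' traversal.
#'
#' @param Lm A G-antisymmetric 4x4 matrix from [g_split()].
#' @return Named list `LDH`, `LD45`, `CD`, `LBH`, `LB45`, `CB`.
#' @export
spectroscopic_means <- function(Lm) {
  assert_mueller(Lm)
  list(
    LDH = -Lm[1, 2],
    LD45 = -Lm[1, 3],
    CD = Lm[1, 4],
    LBH = -Lm[3, 4],
    LB45 = Lm[2, 4],
    CB = Lm[2, 3]
  )
}

#' Fluctuation variances and covariances from the G-symmetric log component
#'
#' Under the fluctuation interpretation, the G-symmetric part of the log of a
#' depolarizing Mueller matrix equals half the second moment of a zero-mean
#' random G-antisymmetric perturbation `dL` of the elementary properties:
#' `Lu = <dL^2> / 2`. Carrying the Eq.-template generator layout through that
#' identity gives a fixed linear map from `Lu` entries to the three variances
#' of the complex fluctuation channels `dLH = dLDH + i dLBH`,
#' `dL45 = dLD45 + i dLB45`, `dC = dCD + i dCB` and their three complex
#' covariances:
#'
#' * `var_LH  = Lu[0,0] + Lu[1,1] - Lu[2,2] - Lu[3,3]`
#' * `var_L45 = Lu[0,0] - Lu[1,1] + Lu[2,2] - Lu[3,3]`
#' * `var_C   = Lu[0,0] - Lu[1,1] - Lu[2,2] + Lu[3,3]`
#' * `cov(LH, L45*) =  2 Lu[1,2] + 2i Lu[0,3]`
#' * `cov(LH, C*)   = -2 Lu[1,3] + 2i Lu[0,2]`
#' * `cov(L45, C*)  = -2 Lu[2,3] - 2i Lu[0,1]`
#'
#' (0-based indices). Non-depolarizing inputs give all six (near) zero.
#'
#' @param Lu A G-symmetric 4x4 matrix from [g_split()].
#' @param tol Variances in `[-tol, 0)` are clipped to zero; more negative
#'   values are left as computed and flagged via `physical = FALSE`.
#' @return List with `var_LH`, `var_L45`, `var_C` (real), `cov_LH_L45`,
#'   `cov_LH_C`, `cov_L45_C` (complex; the real part is the reported
#'   covariance), and `physical`.
#' @export
fluctuation_stats <- function(Lu, tol = 1e-9) {
  assert_mueller(Lu)
  dg <- diag(Lu)
  v <- c(
    var_LH = dg[1] + dg[2] - dg[3] - dg[4],
    var_L45 = dg[1] - dg[2] + dg[3] - dg[4],
    var_C = dg[1] - dg[2] - dg[3] + dg[4]
  )
  physical <- all(v >= -tol)
  v[v < 0 & v >= -tol] <- 0
  list(
    var_LH = v[["var_LH"]], var_L45 = v[["var_L45"]], var_C = v[["var_C"]],
    cov_LH_L45 = complex(real = 2 * Lu[2, 3], imaginary = 2 * Lu[1, 4]),
    cov_LH_C = complex(real = -2 * Lu[2, 4], imaginary = 2 * Lu[1, 3]),
    cov_L45_C = complex(real = -2 * Lu[3, 4], imaginary = -2 * Lu[1, 2]),
    physical = physical
  )
}

#' Applicability of the differential decomposition
#'
#' The differential model applies when the fluctuation (reduced coherency)
#' matrix associated with the trace-removed G-symmetric component is positive
#' semi-definite. That matrix is the 3x3 Hermitian covariance of the complex
#' fluctuation channels assembled by [fluctuation_stats()] -- an exact
#' reparameterization of the G-symmetric part once the isotropic-absorption
#' entry `Lu[0,0]` is set aside.
#'
#' @param L A 4x4 real Mueller log (or a list as returned by [mueller_log()]).
#' @param tol Eigenvalue tolerance, relative to the matrix scale.
#' @return Logical: `TRUE` when the fluctuation covariance is PSD.
#' @export
differential_applicable <- function(L, tol = 1e-9) {
  if (is.list(L)) {
    if (!isTRUE(L$defined)) {
      return(FALSE)
    }
    L <- L$L
  }
  Lu <- g_split(L)$Lu
  fs <- fluctuation_stats(Lu, tol = 0) # raw variances, no clipping
  C <- matrix(c(
    complex(real = fs$var_LH), fs$cov_LH_L45, fs$cov_LH_C,
    Conj(fs$cov_LH_L45), complex(real = fs$var_L45), fs$cov_L45_C,
    Conj(fs$cov_LH_C), Conj(fs$cov_L45_C), complex(real = fs$var_C)
  ), 3, 3, byrow = TRUE)
  ev <- Re(eigen((C + Conj(t(C))) / 2, symmetric = TRUE, only.values = TRUE)$values)
  scale <- max(abs(ev), 1)
  min(ev) >= -tol * scale
}

#' Full differential decomposition of one Mueller matrix
#'
#' Convenience wrapper: log, G-split, six means, three variances, three
#' covariances, applicability.
#'
#' @param m A normalized 4x4 Mueller matrix.
#' @return Object of class `differential_result` with `L`, `Lm`, `Lu`,
#'   `means` (list of 6), `fluctuations` (list from [fluctuation_stats()]),
#'   `applicable`, `defined`.
#' @export
differential_decompose <- function(m) {
  lg <- mueller_log(m)
  if (!lg$defined) {
    return(structure(
      list(
        L = lg$L, Lm = NULL, Lu = NULL, means = NULL,
        fluctuations = NULL, applicable = FALSE, defined = FALSE
      ),
      class = "differential_result"
    ))
  }
  sp <- g_split(lg$L)
  structure(
    list(
      L = lg$L, Lm = sp$Lm, Lu = sp$Lu,
      means = spectroscopic_means(sp$Lm),
      fluctuations = fluctuation_stats(sp$Lu),
      applicable = differential_applicable(lg$L),
      defined = TRUE
    ),
    class = "differential_result"
  )
}

#' @export
print.differential_result <- function(x, ...) {
  if (!x$defined) {
    cat("<differential_result> log undefined\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<differential_result> LBH = %.4f, LB45 = %.4f, CB = %.4f; var_LH = %.4f%s\n",
    x$means$LBH, x$means$LB45, x$means$CB, x$fluctuations$var_LH,
    if (x$applicable) "" else " [not applicable]"
  ))
  invisible(x)
}

# Row order of the per-wavelength differential summary table.
.differential_rows <- c(
  "LBH", "LB45", "CB", "LDH", "LD45", "CD",
  "var_LH", "var_L45", "var_C",
  "cov_LH_L45", "cov_LH_C", "cov_L45_C"
)

#' Differential-decomposition maps for a Mueller image
#'
#' Per-pixel maps of the six mean spectroscopic properties and the six
#' fluctuation statistics (real parts of the covariances). Pixels outside the
#' mask or whose log is undefined are `NA`; the count of log-undefined pixels
#' is reported in the `"log_undefined_count"` attribute.
#'
#' @param img A screened [mueller_image()] with normalized matrices.
#' @return Object of class `differential_maps` (also `map_set`) with one
#'   `H x W` matrix per quantity (names as in the summary row order), plus
#'   `wavelength` and `mask`.
#' @export
differential_maps <- function(img) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img$data)
  px <- flatten_cube(img)
  out <- differential_pixels_cpp(px, as.logical(img$mask))
  maps <- stats::setNames(
    lapply(seq_along(.differential_rows), function(k) matrix(out[, k], d[1], d[2])),
    .differential_rows
  )
  res <- structure(
    c(maps, list(wavelength = img$wavelength, mask = img$mask)),
    class = c("differential_maps", "map_set")
  )
  attr(res, "log_undefined_count") <- sum(is.na(out[, 1]) & as.logical(img$mask))
  res
}

#' Per-wavelength differential summary (12-quantity table)
#'
#' Aggregates [differential_maps()] over the realizability mask (mean over
#' valid pixels by default) into one row per quantity, in the fixed order
#' LBH, LB45, CB, LDH, LD45, CD, then the three variances, then the three
#' covariances.
#'
#' @param maps A `differential_maps` object (or a list of them across
#'   wavelengths).
#' @param stat Aggregation: `"mean"` (default) or `"median"`.
#' @return A tibble with columns `quantity`, `wavelength`, `value`.
#' @export
differential_summary <- function(maps, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") function(v) mean(v, na.rm = TRUE) else function(v) stats::median(v, na.rm = TRUE)
  one <- function(mp) {
    tibble::tibble(
      quantity = factor(.differential_rows, levels = .differential_rows),
      wavelength = mp$wavelength,
      value = vapply(.differential_rows, function(q) f(mp[[q]]), numeric(1))
    )
  }
  if (inherits(maps, "differential_maps")) {
    return(one(maps))
  }
  dplyr::bind_rows(lapply(maps, one))
}

#' Simulate a Gaussian-fluctuating depolarizing medium
#'
#' Draws `n` realizations `exp(Lm + dL)` where `dL` is a zero-mean Gaussian
#' G-antisymmetric perturbation with the given standard deviations on the six
#' elementary generators (order LDH, LD45, CD, LBH, LB45, CB), and averages
#' them. The ensemble mean is a depolarizing Mueller matrix whose
#' differential decomposition recovers `Lm` and the configured variances --
#' the independent oracle for [fluctuation_stats()].
#'
#' @param Lm Mean G-antisymmetric generator (4x4); e.g. built by
#'   [generator_matrix()].
#' @param sd Length-6 non-negative standard deviations of the generator
#'   coefficients.
#' @param n Number of Monte-Carlo draws.
#' @param seed Optional integer seed.
#' @return The averaged 4x4 Mueller matrix.
#' @export
simulate_fluctuating_medium <- function(Lm, sd, n = 1e4, seed = NULL) {
  assert_mueller(Lm)
  stopifnot(length(sd) == 6, all(sd >= 0))
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::rnorm(n * 6), n, 6) %*% diag(sd)
  fluctuation_mc_cpp(Lm, X)
}

#' Elementary G-antisymmetric generator
#'
#' Builds `sum(coef[k] * G_k)` over the six elementary spectroscopic
#' generators, laid out per the mean-property template of
#' [spectroscopic_means()]: coefficient order LDH, LD45, CD, LBH, LB45, CB.
#'
#' @param LDH,LD45,CD,LBH,LB45,CB Generator coefficients.
#' @return A G-antisymmetric 4x4 matrix.
#' @export
generator_matrix <- function(LDH = 0, LD45 = 0, CD = 0, LBH = 0, LB45 = 0, CB = 0) {
  matrix(c(
    0, -LDH, -LD45, CD,
    -LDH, 0, CB, LB45,
    -LD45, -CB, 0, -LBH,
    CD, -LB45, LBH, 0
  ), 4, 4, byrow = TRUE)
}
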