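# Grey/white-matter discrimination: feature assembly, class balancing,
# leave-one-specimen-out KNN cross-validation, permutation feature
# importance, sequential floating feature selection, and the rank-sum
# distribution comparison.

#' Feature column names
#'
#' Feature columns follow the grammar `<property>_<wavelength>`, with
#' properties `delta` (depolarization), `R` (retardance, radians), and `D`
#' (diattenuation), e.g. `delta_450`, `R_680`.
#'
#' @param wavelengths Numeric wavelengths (nm).
#' @param properties Character subset of `c("delta", "R", "D")`.
#' @return Character vector, property-major within wavelength.
#' @export
feature_names <- function(wavelengths = .wavelengths_default,
                          properties = c("delta", "R", "D")) {
  unlist(lapply(wavelengths, function(w) paste0(properties, "_", w)))
}

#' Assemble the pixel feature table from a phantom study
#'
#' Screens each cube, computes Lu-Chipman maps, and collects one row per
#' labeled pixel with its specimen, region, class, and the
#' depolarization/retardance/diattenuation features at every wavelength.
#' Pixels with any undefined feature (masked at any wavelength) are dropped.
#'
#' @param study A [generate_study()] result.
#' @param classes Label classes to keep (default GM and WM).
#' @param screen Apply the realizability screen before decomposition
#'   (default `TRUE`).
#' @param max_per_cell Optional cap on pixels per (specimen, class) cell,
#'   subsampled uniformly; keeps downstream KNN workloads bounded. `Inf`
#'   keeps everything.
#' @param seed Seed for the subsampling.
#' @return A tibble: `specimen`, `region`, `class`, then feature columns per
#'   [feature_names()].
#' @export
build_feature_table <- function(study, classes = c("GM", "WM"), screen = TRUE,
                                max_per_cell = Inf, seed = 1L) {
  stopifnot(inherits(study, "phantom_study"))
  wl <- study$config$wavelengths
  rows <- lapply(study$regions, function(rg) {
    keep <- which(matrix(rg$labels %in% .label_codes[classes],
      nrow(rg$labels), ncol(rg$labels)
    ))
    if (!length(keep)) {
      return(NULL)
    }
    cls <- names(.label_codes)[match(rg$labels[keep], .label_codes)]
    feats <- matrix(NA_real_, length(keep), 3L * length(wl))
    colnames(feats) <- feature_names(wl)
    for (w in seq_along(wl)) {
      img <- rg$images[[w]]
      if (screen) img <- screen_image(img)
      mp <- polar_maps(img)
      feats[, paste0("delta_", wl[w])] <- mp$Delta[keep]
      feats[, paste0("R_", wl[w])] <- mp$R[keep]
      feats[, paste0("D_", wl[w])] <- mp$D[keep]
    }
    dplyr::bind_cols(
      tibble::tibble(
        specimen = rg$specimen, region = rg$region, class = cls
      ),
      tibble::as_tibble(feats)
    )
  })
  tbl <- dplyr::bind_rows(rows)
  tbl <- tidyr::drop_na(tbl)
  if (is.finite(max_per_cell)) {
    set.seed(seed)
    tbl <- tbl |>
      dplyr::group_by(.data$specimen, .data$class) |>
      dplyr::slice_sample(n = max_per_cell, replace = FALSE) |>
      dplyr::ungroup()
  }
  tbl
}

#' Balance classes within specimens
#'
#' Randomly removes rows so that every (specimen, class) cell has the same
#' number of samples: the global minimum cell count. Specimens lacking one of
#' the classes are dropped with a warning. Balanced input is returned
#' unchanged up to row order.
#'
#' @param table A feature tibble with `specimen` and `class` columns.
#' @param seed Integer seed controlling the random removal.
#' @return The balanced tibble.
#' @export
balance_classes <- function(table, seed = 1L) {
  stopifnot(all(c("specimen", "class") %in% names(table)))
  counts <- dplyr::count(table, .data$specimen, .data$class)
  by_spec <- dplyr::count(counts, .data$specimen)
  n_classes <- length(unique(table$class))
  bad <- by_spec$specimen[by_spec$n < n_classes]
  if (length(bad)) {
    warning(sprintf(
      "dropping specimen(s) lacking a class: %s",
      paste(bad, collapse = ", ")
    ))
    table <- dplyr::filter(table, !(.data$specimen %in% bad))
    counts <- dplyr::count(table, .data$specimen, .data$class)
  }
  n_min <- min(counts$n)
  set.seed(seed)
  table |>
    dplyr::group_by(.data$specimen, .data$class) |>
    dplyr::slice_sample(n = n_min, replace = FALSE) |>
    dplyr::ungroup()
}

#' Metrics from a 2x2 confusion matrix
#'
#' For the confusion matrix with rows = predicted (GM, WM) and columns =
#' expected (GM, WM):
#' true GM rate = True GM / (True GM + False WM) (sensitivity),
#' true WM rate = True WM / (True WM + False GM) (specificity),
#' accuracy = (True GM + True WM) / total. All returned as percentages.
#'
#' @param confusion 2x2 numeric matrix `[predicted x expected]` with classes
#'   ordered (GM, WM).
#' @return List with `accuracy`, `true_gm_rate`, `true_wm_rate` (percent;
#'   `NaN` when a denominator is zero).
#' @export
confusion_metrics <- function(confusion) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == 2), all(confusion >= 0))
  tg <- confusion[1, 1]
  fg <- confusion[1, 2]
  fw <- confusion[2, 1]
  tw <- confusion[2, 2]
  total <- tg + fg + fw + tw
  list(
    accuracy = if (total > 0) 100 * (tg + tw) / total else NaN,
    true_gm_rate = if (tg + fw > 0) 100 * tg / (tg + fw) else NaN,
    true_wm_rate = if (tw + fg > 0) 100 * tw / (tw + fg) else NaN
  )
}

# Deterministic sub-rounding dither: breaks exact distance ties (clipped
# parameter values can pile up on a single value, which the exact-tie
# handling in the KNN backend refuses); 1e-8 on z-scored features is far
# below any meaningful scale.
dither <- function(X) {
  X + 1e-8 * sin(seq_along(X))
}

knn_confusion <- function(train_x, train_y, test_x, test_y, k) {
  pred <- class::knn(dither(train_x), dither(test_x),
    factor(train_y, levels = c("GM", "WM")),
    k = k
  )
  tab <- table(
    predicted = factor(pred, levels = c("GM", "WM")),
    expected = factor(test_y, levels = c("GM", "WM"))
  )
  matrix(as.numeric(tab), 2, 2, dimnames = dimnames(tab))
}

zscore_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

zscore_apply <- function(X, fit) {
  sweep(sweep(X, 2, fit$mu, "-"), 2, fit$sd, "/")
}

#' Leave-one-specimen-out KNN cross-validation
#'
#' One fold per specimen: the classifier trains on all other specimens'
#' pixels and is tested on the held-out specimen, so the training fraction is
#' (k - 1)/k for k specimens (83% for six). Features are z-scored with the
#' training split's statistics (depolarization in \\[0,1\\] and retardance in
#' radians are otherwise incommensurate); set `scale = FALSE` to classify on
#' raw features.
#'
#' @param table A (typically balanced) feature tibble.
#' @param features Character vector of feature columns to use.
#' @param k Number of neighbors `Kn` (defaults: 50 for single-wavelength
#'   models, 8 for the all-features model, 48 for the selected-features
#'   model; see [default_kn()]).
#' @param scale Z-score features per fold (default `TRUE`).
#' @param model Optional label stored in the report.
#' @return Object of class `cv_report`: `folds` (tibble with per-fold train
#'   and test metrics), `summary` (mean and SD across folds), `confusions`,
#'   `model`, `k`, `features`, `train_fraction`.
#' @export
losocv_knn <- function(table, features, k = 50, scale = TRUE, model = "knn") {
  stopifnot(all(features %in% names(table)))
  specs <- sort(unique(table$specimen))
  if (length(specs) < 2) stop("need >= 2 specimens for leave-one-out", call. = FALSE)
  X <- as.matrix(table[, features])
  y <- table$class
  folds <- vector("list", length(specs))
  confusions <- vector("list", length(specs))
  for (f in seq_along(specs)) {
    te <- table$specimen == specs[f]
    if (k > sum(!te)) stop("Kn exceeds training-set size", call. = FALSE)
    Xtr <- X[!te, , drop = FALSE]
    Xte <- X[te, , drop = FALSE]
    if (scale) {
      fit <- zscore_fit(Xtr)
      Xtr <- zscore_apply(Xtr, fit)
      Xte <- zscore_apply(Xte, fit)
    }
    cm_test <- knn_confusion(Xtr, y[!te], Xte, y[te], k)
    cm_train <- knn_confusion(Xtr, y[!te], Xtr, y[!te], k)
    mt <- confusion_metrics(cm_test)
    mr <- confusion_metrics(cm_train)
    folds[[f]] <- tibble::tibble(
      fold = f, specimen = specs[f],
      accuracy_train = mr$accuracy, accuracy_test = mt$accuracy,
      true_gm_train = mr$true_gm_rate, true_wm_train = mr$true_wm_rate,
      true_gm_test = mt$true_gm_rate, true_wm_test = mt$true_wm_rate
    )
    confusions[[f]] <- list(train = cm_train, test = cm_test)
  }
  folds <- dplyr::bind_rows(folds)
  summary <- folds |>
    tidyr::pivot_longer(-c("fold", "specimen"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop"
    )
  structure(
    list(
      folds = folds, summary = summary, confusions = confusions,
      model = model, k = k, features = features,
      train_fraction = (length(specs) - 1) / length(specs)
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  acc <- x$summary[x$summary$metric == "accuracy_test", ]
  cat(sprintf(
    "<cv_report> %s (Kn = %d, %d features, %d folds): test accuracy %.1f +/- %.1f %%\n",
    x$model, x$k, length(x$features), nrow(x$folds), acc$mean, acc$sd
  ))
  invisible(x)
}

#' Default neighbor counts per model type
#'
#' Neighbor numbers adopted from the cross-validated Kn sweep: 50 for
#' single-wavelength models, 8 for the all-features model, 48 for the
#' selected-features model.
#'
#' @param model One of `"single"`, `"all"`, `"selected"`.
#' @return Integer Kn.
#' @export
default_kn <- function(model = c("single", "all", "selected")) {
  switch(match.arg(model), single = 50L, all = 8L, selected = 48L)
}

#' Permutation feature importance
#'
#' Mean accuracy decrease when one feature's values are randomly shuffled:
#' for each feature, fold, and shuffle repetition, the feature column of the
#' evaluation split is permuted and the drop in accuracy relative to the
#' unshuffled baseline recorded; the importance is the mean over folds and
#' the `s` repetitions.
#'
#' @param table Balanced feature tibble.
#' @param features Features in the model.
#' @param k Neighbors.
#' @param s Shuffle repetitions per feature and fold (default 10).
#' @param on Evaluate on the `"test"` (default) or `"train"` split.
#' @param seed Seed for the shuffles.
#' @param scale Z-score per fold as in [losocv_knn()].
#' @return A tibble: `feature`, `importance` (mean accuracy decrease,
#'   percentage points), `sd`.
#' @export
permutation_importance <- function(table, features, k = default_kn("all"),
                                   s = 10, on = c("test", "train"),
                                   seed = 1L, scale = TRUE) {
  on <- match.arg(on)
  stopifnot(s >= 1)
  specs <- sort(unique(table$specimen))
  X <- as.matrix(table[, features])
  y <- table$class
  set.seed(seed)
  drops <- array(NA_real_, c(length(features), length(specs), s))
  for (f in seq_along(specs)) {
    te <- table$specimen == specs[f]
    Xtr <- X[!te, , drop = FALSE]
    Xev <- if (on == "test") X[te, , drop = FALSE] else Xtr
    yev <- if (on == "test") y[te] else y[!te]
    if (scale) {
      fit <- zscore_fit(Xtr)
      Xtr <- zscore_apply(Xtr, fit)
      Xev <- zscore_apply(Xev, fit)
    }
    base <- confusion_metrics(knn_confusion(Xtr, y[!te], Xev, yev, k))$accuracy
    for (j in seq_along(features)) {
      for (rep in seq_len(s)) {
        Xp <- Xev
        Xp[, j] <- sample(Xp[, j])
        acc <- confusion_metrics(knn_confusion(Xtr, y[!te], Xp, yev, k))$accuracy
        drops[j, f, rep] <- base - acc
      }
    }
  }
  tibble::tibble(
    feature = features,
    importance = apply(drops, 1, mean),
    sd = apply(drops, 1, stats::sd)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Sequential floating feature selection
#'
#' Fold-wise floating selection of `n` features for the KNN classifier, with
#' the held-out specimen's accuracy as the objective. Forward selection
#' (SFFS) grows the set, then conditionally excludes features; backward
#' selection (SBFS) shrinks from the full set with conditional inclusion.
#' Once a feature is excluded it is never revisited. Returns the selection
#' per fold plus the features most often selected overall.
#'
#' @param table Balanced feature tibble.
#' @param features Candidate features.
#' @param n Target number of features (default 3).
#' @param direction `"forward"` or `"backward"`.
#' @param k Neighbors for the objective classifier.
#' @param scale Z-score per fold.
#' @return Object of class `sfs_result`: `per_fold` (list of character
#'   vectors), `selected` (the `n` features with the highest selection
#'   frequency, ties broken by order of first selection), `direction`, `n`.
#' @export
sequential_feature_selection <- function(table, features, n = 3,
                                         direction = c("forward", "backward"),
                                         k = default_kn("all"), scale = TRUE) {
  direction <- match.arg(direction)
  stopifnot(n >= 1, n <= length(features))
  specs <- sort(unique(table$specimen))
  X <- as.matrix(table[, features])
  y <- table$class

  eval_set <- function(fold_idx, set) {
    te <- table$specimen == specs[fold_idx]
    Xtr <- X[!te, set, drop = FALSE]
    Xte <- X[te, set, drop = FALSE]
    if (scale) {
      fit <- zscore_fit(Xtr)
      Xtr <- zscore_apply(Xtr, fit)
      Xte <- zscore_apply(Xte, fit)
    }
    kk <- min(k, nrow(Xtr))
    confusion_metrics(knn_confusion(Xtr, y[!te], Xte, y[te], kk))$accuracy
  }

  per_fold <- vector("list", length(specs))
  for (f in seq_along(specs)) {
    excluded <- character(0)
    if (direction == "forward") {
      sel <- character(0)
      while (length(sel) < n) {
        cand <- setdiff(features, c(sel, excluded))
        accs <- vapply(cand, function(ft) eval_set(f, c(sel, ft)), numeric(1))
        sel <- c(sel, cand[which.max(accs)])
        # floating exclusion: drop a feature if that improves the objective
        while (length(sel) > 2) {
          cur <- eval_set(f, sel)
          accs_rm <- vapply(sel, function(ft) eval_set(f, setdiff(sel, ft)), numeric(1))
          if (max(accs_rm) > cur) {
            worst <- sel[which.max(accs_rm)]
            sel <- setdiff(sel, worst)
            excluded <- c(excluded, worst)
          } else {
            break
          }
        }
      }
    } else {
      sel <- features
      while (length(sel) > n) {
        accs_rm <- vapply(sel, function(ft) eval_set(f, setdiff(sel, ft)), numeric(1))
        worst <- sel[which.max(accs_rm)]
        sel <- setdiff(sel, worst)
        excluded <- c(excluded, worst)
        # floating inclusion among never-excluded features
        while (length(sel) < length(features) - length(excluded)) {
          cur <- eval_set(f, sel)
          cand <- setdiff(features, c(sel, excluded))
          if (!length(cand)) break
          accs_add <- vapply(cand, function(ft) eval_set(f, c(sel, ft)), numeric(1))
          if (max(accs_add) > cur) {
            sel <- c(sel, cand[which.max(accs_add)])
          } else {
            break
          }
        }
      }
    }
    per_fold[[f]] <- sel
  }
  freq <- sort(table(unlist(per_fold)), decreasing = TRUE)
  selected <- names(freq)[seq_len(min(n, length(freq)))]
  structure(
    list(per_fold = per_fold, selected = selected, direction = direction, n = n),
    class = "sfs_result"
  )
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf(
    "<sfs_result> %s floating selection of %d features: %s\n",
    x$direction, x$n, paste(x$selected, collapse = ", ")
  ))
  invisible(x)
}

#' Two-sided Mann-Whitney U comparison of two samples
#'
#' Rank-sum test of overall separability between two value distributions
#' (e.g. GM vs WM depolarization at one wavelength). Uses the
#' normal approximation with tie correction; all-tied inputs give p = 1.
#'
#' @param x,y Numeric samples (non-empty).
#' @return List with `U` (the rank-sum statistic for `x`) and `p_value`.
#' @export
compare_distributions <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  }
  ht <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  list(U = unname(ht$statistic), p_value = ht$p.value)
}
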