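# Tidiers and plotting helpers for map sets, CV reports, and summaries.

#' Turn a map set into a long tibble
#'
#' One row per pixel and quantity, with `row`, `col`, `wavelength`. Masked
#' pixels are kept as `NA` values unless `drop_na = TRUE`.
#'
#' @param x A `map_set` ([polar_maps()], [purity_maps()], [symmetric_maps()],
#'   [differential_maps()]).
#' @param drop_na Drop rows with `NA` values.
#' @param ... Unused.
#' @return A tibble: `row`, `col`, `wavelength`, `quantity`, `value`.
#' @export
tidy.map_set <- function(x, drop_na = FALSE, ...) {
  qty <- names(x)[vapply(x, function(v) is.matrix(v) && is.numeric(v), logical(1))]
  qty <- setdiff(qty, "mask")
  out <- lapply(qty, function(q) {
    m <- x[[q]]
    tibble::tibble(
      row = as.integer(row(m)), col = as.integer(col(m)),
      wavelength = x$wavelength, quantity = q, value = as.numeric(m)
    )
  })
  out <- dplyr::bind_rows(out)
  if (drop_na) out <- tidyr::drop_na(out, "value")
  out
}

#' @export
tidy.polar_maps <- tidy.map_set

#' @export
tidy.purity_maps <- tidy.map_set

#' @export
tidy.symmetric_maps <- tidy.map_set

#' @export
tidy.differential_maps <- tidy.map_set

#' Tidy / glance methods for cross-validation reports
#'
#' `tidy()` returns the per-fold metric table in long form; `glance()` the
#' across-fold mean and SD of each metric plus model metadata.
#'
#' @param x A `cv_report` from [losocv_knn()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cv_report <- function(x, ...) {
  tidyr::pivot_longer(x$folds, -c("fold", "specimen"),
    names_to = "metric", values_to = "value"
  )
}

#' @rdname tidy.cv_report
#' @export
glance.cv_report <- function(x, ...) {
  acc <- function(metric) {
    r <- x$summary[x$summary$metric == metric, ]
    c(r$mean, r$sd)
  }
  at <- acc("accuracy_test")
  ar <- acc("accuracy_train")
  tibble::tibble(
    model = x$model, k = x$k, n_features = length(x$features),
    n_folds = nrow(x$folds), train_fraction = x$train_fraction,
    accuracy_train = ar[1], accuracy_train_sd = ar[2],
    accuracy_test = at[1], accuracy_test_sd = at[2]
  )
}

#' Parameter-map panel plot
#'
#' Raster panel of every quantity in a map set (masked pixels blank),
#' faceted by quantity.
#'
#' @param object A `map_set`.
#' @param quantities Optional subset of quantity names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.map_set <- function(object, quantities = NULL, ...) {
  df <- tidy.map_set(object)
  if (!is.null(quantities)) df <- dplyr::filter(df, .data$quantity %in% quantities)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%g nm", object$wavelength),
      x = NULL, y = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.polar_maps <- autoplot.map_set

#' @export
autoplot.purity_maps <- autoplot.map_set

#' @export
autoplot.symmetric_maps <- autoplot.map_set

#' @export
autoplot.differential_maps <- autoplot.map_set

#' @rdname tidy.cv_report
#' @param object A `cv_report`.
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidy.cv_report(object)
  df <- dplyr::filter(df, .data$metric %in% c("accuracy_train", "accuracy_test"))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$specimen), .data$value,
    fill = .data$metric
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "held-out specimen", y = "accuracy (%)",
      title = sprintf("%s (Kn = %d)", object$model, object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Class-wise boxplots of a map quantity across wavelengths
#'
#' Reproduces the standard presentation of per-class parameter
#' distributions: boxes per class and wavelength with the distribution mean
#' overlaid as a point.
#'
#' @param summaries Long pixel table with columns `class`, `wavelength`, and
#'   the value column `value` (e.g. built from [tidy.map_set()] joined to
#'   labels, or from a feature table via [tidyr::pivot_longer()]).
#' @param quantity Label used for the y axis.
#' @return A ggplot object.
#' @export
plot_class_boxplots <- function(summaries, quantity = "value") {
  ggplot2::ggplot(summaries, ggplot2::aes(
    factor(.data$wavelength), .data$value,
    fill = .data$class
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.3, position = ggplot2::position_dodge(0.8)) +
    ggplot2::stat_summary(
      fun = mean, geom = "point", shape = 21, fill = "white",
      position = ggplot2::position_dodge(0.8)
    ) +
    ggplot2::labs(x = "wavelength (nm)", y = quantity) +
    ggplot2::theme_minimal()
}
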