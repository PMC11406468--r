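# Pipeline orchestration: simulate -> (measure + reconstruct) -> screen ->
# decompose -> summarize -> classify, plus region statistics.

#' Per-label, per-wavelength summary statistics of parameter maps
#'
#' Aggregates one or more map sets over an integer label image, honoring the
#' realizability mask: masked-out pixels never enter any statistic. Labels
#' with no valid pixels are still emitted with `n = 0` and `NA` statistics.
#'
#' @param maps A `map_set` (e.g. [polar_maps()] output) or list of them
#'   (one per wavelength).
#' @param labels Integer label matrix congruent with the maps (codes as in
#'   the phantom: background 0, GM 1, WM 2, vessel 3 -- or any user coding).
#' @param label_names Optional named integer vector mapping names to codes;
#'   defaults to the phantom vocabulary.
#' @return A tibble with columns `label`, `wavelength`, `quantity`, `n`,
#'   `mean`, `median`, `q25`, `q75`.
#' @export
summarize_regions <- function(maps, labels,
                              label_names = .label_codes[-1]) {
  if (inherits(maps, "map_set")) maps <- list(maps)
  rows <- lapply(maps, function(mp) {
    stopifnot(inherits(mp, "map_set"))
    qty <- setdiff(
      names(mp)[vapply(mp, function(x) is.matrix(x) && is.numeric(x), logical(1))],
      c("mask")
    )
    out <- list()
    for (lb in names(label_names)) {
      sel <- labels == label_names[[lb]] & mp$mask
      for (q in qty) {
        v <- mp[[q]][sel]
        v <- v[is.finite(v)]
        out[[length(out) + 1L]] <- tibble::tibble(
          label = lb, wavelength = mp$wavelength, quantity = q,
          n = length(v),
          mean = if (length(v)) mean(v) else NA_real_,
          median = if (length(v)) stats::median(v) else NA_real_,
          q25 = if (length(v)) stats::quantile(v, 0.25, names = FALSE) else NA_real_,
          q75 = if (length(v)) stats::quantile(v, 0.75, names = FALSE) else NA_real_
        )
      }
    }
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' Run the full phantom-to-classification pipeline
#'
#' Sequences the stages of the analysis on synthetic data: phantom study
#' generation, optional instrument-level measurement and reconstruction,
#' realizability screening, the requested decompositions, region summaries,
#' and GM/WM classification. Identical configuration and seed give identical
#' outputs.
#'
#' @param config A [phantom_config()]; its `seed` drives every stage.
#' @param n_specimens,n_regions Study size (defaults 6 and 20).
#' @param through_instrument Push each cube through [forward_measure()] /
#'   [reconstruct_mueller()] with the configured intensity noise instead of
#'   using the noiseless cubes directly.
#' @param screen Apply the realizability screen (`TRUE`; disabling marks the
#'   run report `unscreened`).
#' @param methods Decompositions to run: subset of `c("polar", "symmetric",
#'   "differential", "purity")`.
#' @param classify Run the KNN stage (single-wavelength, all-features, and
#'   selected-features models).
#' @param max_per_cell Pixel cap per (specimen, class) for the feature table.
#' @param tol Realizability tolerance.
#' @return A list of class `pipeline_result`: `study`, `summaries` (tibble),
#'   `feature_table`, `cv` (list of `cv_report`), `importance`, `selection`,
#'   `report` (stage log with masked-pixel counts and timings).
#' @export
run_pipeline <- function(config = phantom_config(),
                         n_specimens = 6, n_regions = 20,
                         through_instrument = FALSE, screen = TRUE,
                         methods = c("polar"),
                         classify = TRUE, max_per_cell = 500, tol = 1e-5) {
  methods <- match.arg(methods, c("polar", "symmetric", "differential", "purity"),
    several.ok = TRUE
  )
  t0 <- proc.time()[["elapsed"]]
  report <- list(unscreened = !screen, stages = list())
  stamp <- function(stage, extra = list()) {
    report$stages[[stage]] <<- c(
      list(elapsed_s = proc.time()[["elapsed"]] - t0), extra
    )
  }

  study <- generate_study(config, n_specimens = n_specimens, n_regions = n_regions)
  stamp("simulate", list(n_cubes = sum(study$manifest$n_cubes)))

  if (through_instrument) {
    instr <- ideal_instrument()
    for (r in seq_along(study$regions)) {
      for (w in seq_along(study$regions[[r]]$images)) {
        img <- study$regions[[r]]$images[[w]]
        fs <- forward_measure(img, instr)
        if (config$noise_sigma > 0) {
          fs <- corrupt_frames(fs,
            sigma_gauss = config$noise_sigma,
            seed = config$seed + 131L * r + w
          )
        }
        rec <- reconstruct_mueller(fs)
        rec$mask <- img$mask
        rec$m00 <- img$m00
        study$regions[[r]]$images[[w]] <- rec
      }
    }
    stamp("reconstruct")
  }

  n_masked <- 0L
  if (screen) {
    for (r in seq_along(study$regions)) {
      for (w in seq_along(study$regions[[r]]$images)) {
        img <- study$regions[[r]]$images[[w]]
        labeled <- study$regions[[r]]$labels != .label_codes[["background"]]
        scr <- screen_image(img, tol = tol)
        scr$mask <- scr$mask & labeled
        n_masked <- n_masked + sum(labeled & !scr$mask)
        study$regions[[r]]$images[[w]] <- scr
      }
    }
    stamp("screen", list(n_masked = n_masked))
  }

  map_fun <- list(
    polar = polar_maps, symmetric = symmetric_maps,
    differential = differential_maps, purity = purity_maps
  )
  summaries <- list()
  for (meth in methods) {
    rows <- lapply(study$regions, function(rg) {
      mps <- lapply(rg$images, map_fun[[meth]])
      dplyr::mutate(
        summarize_regions(mps, rg$labels),
        method = meth, specimen = rg$specimen, region = rg$region
      )
    })
    summaries[[meth]] <- dplyr::bind_rows(rows)
  }
  summaries <- dplyr::bind_rows(summaries)
  stamp("summarize", list(methods = methods))

  feature_table <- NULL
  cv <- importance <- selection <- NULL
  if (classify) {
    feature_table <- build_feature_table(study,
      screen = FALSE, # images already screened above when requested
      max_per_cell = max_per_cell, seed = config$seed
    )
    feature_table <- balance_classes(feature_table, seed = config$seed)
    wl <- config$wavelengths
    cv <- list()
    for (w in wl) {
      cv[[paste0("single_", w)]] <- losocv_knn(
        feature_table, feature_names(w),
        k = default_kn("single"), model = paste0(w, " nm")
      )
    }
    all_feats <- feature_names(wl)
    cv[["all"]] <- losocv_knn(feature_table, all_feats,
      k = default_kn("all"), model = "KNN-All"
    )
    importance <- permutation_importance(feature_table, all_feats,
      k = default_kn("all"), seed = config$seed
    )
    selection <- sequential_feature_selection(feature_table, all_feats,
      n = 3, direction = "forward", k = default_kn("all")
    )
    cv[["selected"]] <- losocv_knn(feature_table, selection$selected,
      k = default_kn("selected"), model = "KNN-SF"
    )
    stamp("classify", list(n_rows = nrow(feature_table)))
  }

  structure(
    list(
      study = study, summaries = summaries, feature_table = feature_table,
      cv = cv, importance = importance, selection = selection,
      report = report
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf(
    "  study: %d regions, %d cubes\n",
    nrow(x$study$manifest), sum(x$study$manifest$n_cubes)
  ))
  if (!is.null(x$cv)) {
    for (nm in names(x$cv)) {
      acc <- x$cv[[nm]]$summary
      a <- acc[acc$metric == "accuracy_test", ]
      cat(sprintf("  %-12s test accuracy %.1f +/- %.1f %%\n", nm, a$mean, a$sd))
    }
  }
  invisible(x)
}
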