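# Serialization: Mueller cubes as 16-page float TIFF stacks with a JSON
# sidecar; masks as single-page TIFF; frame stacks as multi-page TIFF;
# feature tables as CSV.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Read and write Mueller cubes as 16-page TIFF + JSON sidecar
#'
#' Page `k` (0-based) of the TIFF holds element `(k %/% 4, k %% 4)` (0-based
#' row, column) of the per-pixel Mueller matrix as 32-bit float; wavelength,
#' specimen, region, and the validity mask travel in a JSON sidecar next to
#' the TIFF (same stem, `.json` extension). TIFF float pages must lie in
#' `[-1, 1]` after normalization, which holds for normalized cubes; the
#' unnormalized `M00` plane is carried in the sidecar scale field.
#'
#' @param img A [mueller_image()].
#' @param path Output `.tiff` path.
#' @return `write_mueller_cube()`: the path, invisibly;
#'   `read_mueller_cube()`: a [mueller_image()].
#' @export
write_mueller_cube <- function(img, path) {
  stopifnot(inherits(img, "mueller_image"))
  d <- dim(img$data)
  pages <- lapply(0:15, function(k) {
    i <- k %/% 4L + 1L
    j <- k %% 4L + 1L
    img$data[, , i, j]
  })
  scale <- max(abs(unlist(pages)), 1)
  # affine map into [0, 1]: TIFF pages cannot carry signed values
  pages <- lapply(pages, function(p) (p / scale + 1) / 2)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    wavelength_nm = img$wavelength, specimen = img$specimen,
    region = img$region, height = d[1], width = d[2],
    scale = scale,
    mask = as.integer(img$mask),
    m00 = if (!is.null(img$m00)) as.numeric(img$m00) else NULL,
    page_order = "element (k %/% 4, k %% 4), 0-based"
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mueller_cube
#' @export
read_mueller_cube <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  h <- meta$height
  w <- meta$width
  data <- array(0, c(h, w, 4L, 4L))
  for (k in 0:15) {
    data[, , k %/% 4L + 1L, k %% 4L + 1L] <- (2 * pages[[k + 1L]] - 1) * meta$scale
  }
  mueller_image(
    data, meta$wavelength_nm,
    mask = matrix(as.logical(meta$mask), h, w),
    specimen = meta$specimen, region = meta$region,
    m00 = if (!is.null(meta$m00)) matrix(meta$m00, h, w) else NULL
  )
}

#' Read and write realizability masks as single-page TIFF
#'
#' @param mask Logical matrix.
#' @param path `.tiff` path.
#' @return The path / the logical matrix.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
    path,
    bits.per.sample = 8L
  )
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  tiff::readTIFF(path) > 0.5
}

#' Read and write frame stacks as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered analyzer-major: page index (0-based) = `(g * K + a)` for
#' analyzer row `a` and generator state `g`. Instrument matrices, wavelength,
#' and the intensity scale live in the JSON sidecar.
#'
#' @param stack A [forward_measure()] frame stack.
#' @param path `.tiff` path.
#' @return The path / a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  scale <- max(stack$frames, 1e-12)
  pages <- list()
  for (g in seq_len(d[2])) {
    for (a in seq_len(d[1])) {
      pages[[length(pages) + 1L]] <- stack$frames[a, g, , ] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    K_psa = d[1], N_psg = d[2], height = d[3], width = d[4],
    scale = scale, wavelength_nm = stack$wavelength,
    specimen = stack$specimen, region = stack$region,
    PSA = stack$instrument$PSA, PSG = stack$instrument$PSG,
    page_order = "page = g * K_psa + a (0-based)"
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  K <- meta$K_psa
  Ng <- meta$N_psg
  frames <- array(0, c(K, Ng, meta$height, meta$width))
  for (g in seq_len(Ng)) {
    for (a in seq_len(K)) {
      frames[a, g, , ] <- pages[[(g - 1L) * K + a]] * meta$scale
    }
  }
  instr <- instrument_model(
    matrix(unlist(meta$PSG), 4, 4),
    matrix(unlist(meta$PSA), K, 4)
  )
  structure(
    list(
      frames = frames, instrument = instr,
      wavelength = meta$wavelength_nm,
      specimen = meta$specimen, region = meta$region
    ),
    class = "frame_stack"
  )
}

#' Read and write feature tables as CSV
#'
#' Plain CSV with the header grammar of [feature_names()].
#'
#' @param table Feature tibble.
#' @param path `.csv` path.
#' @return The path / a tibble.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
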