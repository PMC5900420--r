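#' Pixel-wise prediction map
#'
#' Transfers a calibration model to every foreground pixel of a
#' hypercube: the model's wavelengths are resolved on the cube axis
#' (nearest band, 1.5 nm tolerance), each masked pixel's reflectance at
#' those bands is pushed through [predict.pls_model()], and background
#' pixels carry `NA`.
#'
#' @param cube a [hypercube()].
#' @param model a `pls_model` whose feature names are wavelengths in nm.
#' @param mask logical foreground matrix; defaults to the cube's mask.
#' @param preprocess optional function `spectrum -> spectrum` applied to
#'   each pixel's full spectrum before band extraction (use the same
#'   chain the calibration spectra received; NULL for none).
#' @return An object of class `prediction_map`: `values` (rows x cols,
#'   `NA` in background), `mask`, `model_id`, `clip_range` (1st-99th
#'   percentile of the foreground values).
#' @export
predict_map <- function(cube, model, mask = cube$mask, preprocess = NULL) {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "pls_model"))
  if (is.null(mask)) stop("no mask supplied and the cube carries none")
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  d <- dim(cube$data)
  wl_model <- suppressWarnings(as.numeric(model$feature_names))
  if (anyNA(wl_model))
    stop("model features are not wavelengths: ",
         paste(model$feature_names[is.na(wl_model)], collapse = ", "))
  idx <- band_index(cube$wavelengths, wl_model)

  values <- matrix(NA_real_, d[1], d[2])
  if (any(mask)) {
    flat <- matrix(cube$data, d[1] * d[2], d[3])
    px <- flat[as.vector(mask), , drop = FALSE]
    if (!is.null(preprocess)) {
      px <- t(apply(px, 1, function(v)
        preprocess(spectrum(cube$wavelengths, v))$values))
    }
    feat <- px[, idx, drop = FALSE]
    colnames(feat) <- model$feature_names
    values[mask] <- predict(model, feat)
  }
  fg <- values[mask]
  clip <- if (length(fg)) stats::quantile(fg, c(0.01, 0.99), names = FALSE)
          else c(0, 1)
  structure(list(values = values, mask = mask,
                 model_id = paste0(model$mode, "_", model$n_lv, "lv"),
                 clip_range = clip),
            class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  fg <- x$values[x$mask]
  cat(sprintf("<prediction_map> %d x %d, %d foreground px, range [%.2f, %.2f]\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              if (length(fg)) min(fg) else NA, if (length(fg)) max(fg) else NA))
  invisible(x)
}

# blue -> cyan -> yellow -> red ramp; cold = low, warm = high concentration
map_palette <- function(n = 256) {
  grDevices::colorRampPalette(c("#0000CC", "#00AAFF", "#FFE000",
                                "#D40000"))(n)
}

#' Render a prediction map to PNG
#'
#' Linear blue-to-red false-color mapping of foreground concentrations
#' over `clip_range` (values outside are clipped), background in neutral
#' grey, with a vertical color bar on the right edge. Rendering is
#' deterministic: identical map and range give byte-identical files.
#'
#' @param map a [predict_map()] result.
#' @param out_path PNG path.
#' @param clip_range display bounds; defaults to the map's stored range.
#' @return `out_path`, invisibly.
#' @export
render_map <- function(map, out_path, clip_range = map$clip_range) {
  stopifnot(inherits(map, "prediction_map"))
  if (!all(is.finite(clip_range)) || diff(clip_range) < 0)
    stop("clip_range must be finite and ordered")
  pal <- map_palette()
  rgb_pal <- grDevices::col2rgb(pal) / 255

  v <- map$values
  rows <- nrow(v); cols <- ncol(v)
  span <- diff(clip_range)
  scaled <- if (span > 0) (v - clip_range[1]) / span else v * 0 + 0.5
  scaled <- pmin(pmax(scaled, 0), 1)
  bin <- pmin(floor(scaled * 255) + 1L, 256L)

  img <- array(0.85, c(rows, cols, 3))   # neutral background
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[map$mask] <- rgb_pal[ch, bin[map$mask]]
    img[, , ch] <- plane
  }

  # color bar: 8 px wide, 2 px gutter, low at bottom
  bar_w <- 8L; gutter <- 2L
  bar <- array(0.85, c(rows, bar_w + gutter, 3))
  bar_bins <- pmin(floor((rev(seq_len(rows)) - 1) / (rows - 1) * 255) + 1L,
                   256L)
  for (ch in 1:3)
    bar[, gutter + seq_len(bar_w), ch] <- matrix(rgb_pal[ch, bar_bins],
                                                 rows, bar_w)
  out <- array(0, c(rows, cols + bar_w + gutter, 3))
  out[, seq_len(cols), ] <- img
  out[, cols + seq_len(bar_w + gutter), ] <- bar
  png::writePNG(out, out_path)
  invisible(out_path)
}

#' Dump a prediction map to CSV
#'
#' @param map a [predict_map()] result.
#' @param path CSV path; background pixels are written as empty cells.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
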