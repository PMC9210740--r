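#' Single-platelet image container
#'
#' A `platelet_image` bundles a 2D non-negative intensity matrix with its
#' physical pixel size and optional labels (protein, category, sample id) and,
#' for simulated images, the planted ground truth.  All image operations in
#' the package accept and return this class.
#'
#' Pixel coordinates are 0-based; a pixel's position is its centre, x runs
#' right along columns, y runs down along rows.  Physical distances are
#' obtained by multiplying by `pixel_size_nm`.
#'
#' @param pixels numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixel_size_nm physical size of one pixel, in nanometres.
#' @param protein optional protein label.
#' @param category optional integer category code.
#' @param sample_id optional sample identifier.
#' @param ground_truth optional data frame with one row per planted cluster
#'   (`center_x_nm`, `center_y_nm`, `radius_nm`), origin at the top-left
#'   pixel centre.
#' @return An object of class `platelet_image`.
#' @examples
#' img <- platelet_image(matrix(runif(64), 8, 8), pixel_size_nm = 20)
#' img
#' @export
platelet_image <- function(pixels, pixel_size_nm, protein = NULL,
                           category = NULL, sample_id = NULL,
                           ground_truth = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("'pixels' must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stopf("pixel intensities must be finite and non-negative")
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  if (!is.null(ground_truth)) {
    need <- c("center_x_nm", "center_y_nm", "radius_nm")
    if (!is.data.frame(ground_truth) || !all(need %in% names(ground_truth)))
      stopf("'ground_truth' must be a data frame with columns %s",
            paste(need, collapse = ", "))
  }
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         protein = protein, category = category, sample_id = sample_id,
         ground_truth = ground_truth),
    class = "platelet_image")
}

#' @export
print.platelet_image <- function(x, ...) {
  cat(sprintf("<platelet_image> %d x %d px, %.3g nm/px",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm))
  if (!is.null(x$protein)) cat(sprintf(", protein %s", x$protein))
  if (!is.null(x$category)) cat(sprintf(", category %s", x$category))
  if (!is.null(x$ground_truth))
    cat(sprintf(", %d planted clusters", nrow(x$ground_truth)))
  cat("\n")
  invisible(x)
}

#' @export
plot.platelet_image <- function(x, ...) {
  graphics::image(t(x$pixels)[, rev(seq_len(nrow(x$pixels))), drop = FALSE],
                  asp = 1, axes = FALSE, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}

as_platelet_image <- function(x, pixel_size_nm = NULL) {
  if (inherits(x, "platelet_image")) return(x)
  if (is.matrix(x)) {
    if (is.null(pixel_size_nm))
      stopf("pixel_size_nm is required when passing a bare matrix")
    return(platelet_image(x, pixel_size_nm))
  }
  stopf("cannot interpret object of class '%s' as a platelet image",
        class(x)[1L])
}

#' Read and write platelet images as TIFF
#'
#' Images are stored as single-channel 32-bit float TIFF.  The pixel size is
#' written into the TIFF X/Y resolution tags (pixels per centimetre); planted
#' ground truth, when present, is written to a JSON sidecar
#' (`<path>.truth.json`) with coordinates in nanometres.
#'
#' @param image a [platelet_image].
#' @param path file path of the TIFF.
#' @param pixel_size_nm pixel size override when the TIFF carries no
#'   resolution tag.
#' @return `write_platelet_tiff` returns `path` invisibly;
#'   `read_platelet_tiff` returns a [platelet_image].
#' @export
write_platelet_tiff <- function(image, path) {
  image <- as_platelet_image(image)
  px_per_cm <- 1e7 / image$pixel_size_nm
  peak <- max(image$pixels)
  scaled <- if (peak > 0) image$pixels / peak else image$pixels
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                  reduce = FALSE, compression = "none")
  meta <- list(pixel_size_nm = image$pixel_size_nm, intensity_scale = peak,
               protein = image$protein, category = image$category,
               sample_id = image$sample_id)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(image$ground_truth))
    jsonlite::write_json(image$ground_truth, paste0(path, ".truth.json"),
                         digits = NA)
  invisible(path)
}

#' @rdname write_platelet_tiff
#' @export
read_platelet_tiff <- function(path, pixel_size_nm = NULL) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  ps <- pixel_size_nm %||% meta$pixel_size_nm
  if (is.null(ps))
    stopf("no pixel size stored with '%s'; pass pixel_size_nm", path)
  scale <- meta$intensity_scale %||% 1
  truth_path <- paste0(path, ".truth.json")
  truth <- if (file.exists(truth_path)) {
    as.data.frame(jsonlite::fromJSON(truth_path))
  } else NULL
  platelet_image(px * scale, as.numeric(ps),
                 protein = meta$protein %||% NULL,
                 category = if (!is.null(meta$category))
                   as.integer(meta$category) else NULL,
                 sample_id = meta$sample_id %||% NULL,
                 ground_truth = truth)
}
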