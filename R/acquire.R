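# Software simulation of the streamlined acquisition logic: find platelets
# in a coarse overview image, refine focus on a small z-stack, emit crops.
# No hardware is touched; the functions operate on plain image containers.

#' Coarse field image container
#'
#' @param pixels 2D non-negative intensity matrix (a confocal overview,
#'   typically covering 50 x 50 um at ~100 nm/px).
#' @param pixel_size_nm pixel size in nm.
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_size_nm) {
  if (!is.matrix(pixels) || any(pixels < 0))
    stopf("'pixels' must be a non-negative matrix")
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm),
            class = "field_image")
}

#' Detect platelets in a coarse field image
#'
#' Thresholds the field, groups supra-threshold pixels by 8-connectivity,
#' filters components by area (rejecting debris below `min_area_px` and
#' aggregates above `max_area_px`) and reports the intensity-weighted centre
#' and a padded bounding box of each platelet.  Detections are ordered by
#' (y, x) of their centres.
#'
#' @param field a [field_image].
#' @param intensity_threshold detection threshold (pixels >= threshold are
#'   candidate platelet pixels).
#' @param min_area_px,max_area_px component area filter, pixels.
#' @param margin_px padding added around each tight bounding box.
#' @return A data frame with one row per detection: `center_x_px`,
#'   `center_y_px` (0-based, intensity-weighted), `x0`, `y0`, `x1`, `y1`
#'   (0-based inclusive bounding box) and `area_px`.
#' @export
detect_platelets <- function(field, intensity_threshold, min_area_px = 20L,
                             max_area_px = 5000L, margin_px = 2L) {
  if (!inherits(field, "field_image")) stopf("'field' must be a field_image")
  check_number(intensity_threshold, "intensity_threshold")
  if (min_area_px > max_area_px) stopf("min_area_px must be <= max_area_px")
  cmap <- label_clusters(field$pixels, intensity_threshold)
  k <- length(cmap$areas_px)
  empty <- data.frame(center_x_px = numeric(0), center_y_px = numeric(0),
                      x0 = integer(0), y0 = integer(0), x1 = integer(0),
                      y1 = integer(0), area_px = integer(0))
  if (k == 0L) return(empty)
  keep <- which(cmap$areas_px >= min_area_px & cmap$areas_px <= max_area_px)
  if (length(keep) == 0L) return(empty)
  nr <- nrow(field$pixels); nc <- ncol(field$pixels)
  rows <- lapply(keep, function(i) {
    sel <- which(cmap$label_grid == i)
    r <- ((sel - 1L) %% nr)       # 0-based row (y)
    cc <- ((sel - 1L) %/% nr)     # 0-based col (x)
    wgt <- field$pixels[sel]
    data.frame(center_x_px = sum(cc * wgt) / sum(wgt),
               center_y_px = sum(r * wgt) / sum(wgt),
               x0 = max(0L, min(cc) - margin_px),
               y0 = max(0L, min(r) - margin_px),
               x1 = min(nc - 1L, max(cc) + margin_px),
               y1 = min(nr - 1L, max(r) + margin_px),
               area_px = cmap$areas_px[i])
  })
  out <- do.call(rbind, rows)
  out[order(out$center_y_px, out$center_x_px), , drop = FALSE]
}

#' Axial image stack
#'
#' @param planes list of >= 3 equally sized 2D intensity matrices, ordered
#'   along the optical axis.
#' @param z_spacing_nm plane spacing in nm (default 200, matching a 600 nm
#'   axial resolution: finer steps only add bleaching, not focus accuracy).
#' @return An object of class `z_stack`.
#' @export
z_stack <- function(planes, z_spacing_nm = 200) {
  if (!is.list(planes) || length(planes) < 3L)
    stopf("need at least 3 planes")
  d <- dim(planes[[1L]])
  for (p in planes)
    if (!identical(dim(p), d)) stopf("all planes must have the same shape")
  check_number(z_spacing_nm, "z_spacing_nm", lower = 1e-9)
  structure(list(planes = planes, z_spacing_nm = z_spacing_nm),
            class = "z_stack")
}

#' Gradient focus score per plane
#'
#' For each plane an axial-gradient image is formed from the absolute
#' differences to its upper and lower neighbour planes; the score is the sum
#' of that gradient image.  The focal plane with the largest score is in
#' best focus.  End planes have a single neighbour, whose difference is
#' doubled so all planes remain comparable.
#'
#' @param stack a [z_stack].
#' @return Numeric vector of per-plane scores.
#' @export
focus_scores <- function(stack) {
  if (!inherits(stack, "z_stack")) stopf("'stack' must be a z_stack")
  n <- length(stack$planes)
  vapply(seq_len(n), function(i) {
    up <- if (i > 1L) abs(stack$planes[[i]] - stack$planes[[i - 1L]]) else NULL
    dn <- if (i < n) abs(stack$planes[[i]] - stack$planes[[i + 1L]]) else NULL
    if (is.null(up)) sum(2 * dn)
    else if (is.null(dn)) sum(2 * up)
    else sum(up + dn)
  }, numeric(1))
}

#' Best-focus plane of a z-stack
#'
#' Index of the plane maximizing [focus_scores()]; ties go to the lower
#' index.
#'
#' @param stack a [z_stack].
#' @return Integer plane index.
#' @export
best_focus <- function(stack) {
  which.max(focus_scores(stack))
}

#' Crop detections out of a field image
#'
#' @param field a [field_image].
#' @param detections data frame from [detect_platelets()].
#' @return A list of [platelet_image] crops, one per detection.
#' @export
crop_detections <- function(field, detections) {
  lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    platelet_image(field$pixels[(d$y0:d$y1) + 1L, (d$x0:d$x1) + 1L,
                                drop = FALSE],
                   field$pixel_size_nm)
  })
}

#' Simulate a coarse field of platelets
#'
#' Renders `n_platelets` Gaussian-blurred platelet-sized discs at random
#' non-overlapping positions in a square field, with optional Poisson noise.
#' Planted centres are returned in the attribute `truth` (0-based pixel
#' units), to validate the detection step.
#'
#' @param n_platelets number of planted platelets.
#' @param field_size_um field side length, um.
#' @param pixel_size_nm coarse pixel size, nm.
#' @param platelet_radius_nm platelet disc radius, nm.
#' @param intensity disc intensity, photons.
#' @param background background level, photons.
#' @param noise add Poisson noise?
#' @param seed integer seed.
#' @return A [field_image] with attribute `truth` (data frame of planted
#'   `center_x_px`, `center_y_px`).
#' @export
simulate_field <- function(n_platelets = 5L, field_size_um = 50,
                           pixel_size_nm = 100, platelet_radius_nm = 1500,
                           intensity = 80, background = 1, noise = TRUE,
                           seed = 1L) {
  n <- as.integer(round(field_size_um * 1000 / pixel_size_nm))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483647))
  rad_px <- platelet_radius_nm / pixel_size_nm
  pad <- ceiling(rad_px) + 4
  cx <- numeric(0); cy <- numeric(0)
  while (length(cx) < n_platelets) {
    x <- stats::runif(1, pad, n - 1 - pad)
    y <- stats::runif(1, pad, n - 1 - pad)
    if (all(sqrt((x - cx)^2 + (y - cy)^2) > 2.5 * rad_px) ||
        length(cx) == 0L) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  img <- matrix(0, n, n)
  xs <- matrix(rep(0:(n - 1L), each = n), n, n)   # column index (x)
  ys <- matrix(rep(0:(n - 1L), times = n), n, n)  # row index (y)
  for (i in seq_len(n_platelets))
    img <- img + intensity *
      ((xs - cx[i])^2 + (ys - cy[i])^2 <= rad_px^2)
  img <- conv2_reflect(img, gaussian_kernel(1.5))
  pixels <- if (noise)
    matrix(stats::rpois(n * n, pmax(img + background, 0)), n, n)
  else img + background
  out <- field_image(pixels, pixel_size_nm)
  attr(out, "truth") <- data.frame(center_x_px = cx, center_y_px = cy)
  out
}

#' Simulate a defocus z-stack of a bead-like object
#'
#' A bright spot rendered in `n_planes` planes, blurred with a Gaussian
#' whose width grows with the distance to the planted focal plane — the
#' standard test object for the gradient autofocus.
#'
#' @param focal_plane index of the in-focus plane.
#' @param n_planes number of planes (default 10, mirroring the fast
#'   ten-frame focus scan).
#' @param size_px image side length, pixels.
#' @param defocus_blur_px blur growth per plane of defocus, pixels.  The
#'   default 0.8 px/plane mirrors a 600 nm axial resolution sampled at
#'   200 nm steps; much faster growth makes the heavily defocused end
#'   planes artificially gradient-rich.
#' @param intensity spot intensity.
#' @param noise add Poisson noise?
#' @param seed integer seed.
#' @return A [z_stack].
#' @export
simulate_zstack <- function(focal_plane, n_planes = 10L, size_px = 32L,
                            defocus_blur_px = 0.8, intensity = 2000,
                            noise = TRUE, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483647))
  base <- matrix(0, size_px, size_px)
  c0 <- (size_px + 1L) %/% 2L
  base[c0, c0] <- intensity
  base[c0 + 1L, c0] <- intensity / 2
  base[c0, c0 + 1L] <- intensity / 2
  planes <- lapply(seq_len(n_planes), function(i) {
    sg <- 0.8 + defocus_blur_px * abs(i - focal_plane)
    p <- conv2_reflect(base, gaussian_kernel(sg))
    if (noise) matrix(stats::rpois(size_px^2, pmax(p, 0) + 1),
                      size_px, size_px)
    else p
  })
  z_stack(planes)
}
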