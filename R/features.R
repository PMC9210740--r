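#' Otsu intensity threshold
#'
#' Computes the automatic threshold that maximizes the between-class variance
#' of the intensity histogram (256 equal-width bins over the observed
#' intensity range).  Pixels at or above the returned threshold are
#' foreground.
#'
#' @param image a [platelet_image] or numeric matrix.
#' @return The threshold intensity (a single number).
#' @export
otsu_threshold <- function(image) {
  x <- if (inherits(image, "platelet_image")) image$pixels else image
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stopf("cannot threshold a constant image")
  nbins <- 256L
  edges <- seq(rng[1L], rng[2L], length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(v, edges, all.inside = TRUE), nbins),
                     nbins)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[nbins]; mu_t <- mu[nbins]
  # between-class variance for split after bin t (exhaustive over all splits)
  t_idx <- seq_len(nbins - 1L)
  w0 <- w[t_idx]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (n * mu[t_idx][valid] - mu_t * w0[valid])^2 /
    (w0[valid] * w1[valid])
  # the maximum is a plateau when the histogram has an empty gap between
  # the classes; take the midpoint of the maximal stretch
  top <- which(bcv >= max(bcv) * (1 - 1e-12))
  mean(edges[range(top) + 1L])
}

#' Label protein clusters by 8-connectivity
#'
#' Binarizes the image at `threshold` (inclusive: intensity >= threshold is
#' foreground) and groups foreground pixels that share an edge or a corner
#' ("square or diagonal" adjacency) into clusters.  Cluster centroids are the
#' unweighted means of member pixel coordinates, in 0-based pixel units
#' (x = column, y = row).
#'
#' @param image a [platelet_image] or numeric matrix.
#' @param threshold intensity threshold, typically from [otsu_threshold()].
#' @return An object of class `cluster_map`: `label_grid` (0 = background,
#'   1..K cluster ids), `areas_px`, `centroids_px` (K x 2 matrix, columns
#'   x, y), `threshold_used`.
#' @export
label_clusters <- function(image, threshold) {
  x <- if (inherits(image, "platelet_image")) image$pixels else image
  check_number(threshold, "threshold")
  mask <- x >= threshold
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0L)
    return(structure(list(label_grid = labels, areas_px = integer(0),
                          centroids_px = matrix(numeric(0), 0L, 2L,
                                                dimnames = list(NULL, c("x", "y"))),
                          threshold_used = threshold),
                     class = "cluster_map"))
  vid <- matrix(0L, nr, nc)
  vid[fg] <- seq_along(fg)
  row_of <- ((fg - 1L) %% nr) + 1L
  col_of <- ((fg - 1L) %/% nr) + 1L
  # edges to 4 of the 8 neighbours (the other 4 are covered symmetrically)
  edges <- NULL
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row_of + d[1L]; c2 <- col_of + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- vid[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    if (any(keep))
      edges <- rbind(edges, cbind(vid[fg][ok][keep], nb[keep]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # contiguous ids 1..K in order of first appearance (column-major scan)
  first_seen <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first_seen]] <- seq_len(sum(first_seen))
  lab <- relab[memb]
  labels[fg] <- lab
  k <- max(lab)
  areas <- tabulate(lab, k)
  cx <- vapply(seq_len(k), function(i) mean(col_of[lab == i]) - 1, numeric(1))
  cy <- vapply(seq_len(k), function(i) mean(row_of[lab == i]) - 1, numeric(1))
  structure(list(label_grid = labels, areas_px = areas,
                 centroids_px = cbind(x = cx, y = cy),
                 threshold_used = threshold),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %d clusters, threshold %.4g\n",
              length(x$areas_px), x$threshold_used))
  invisible(x)
}

#' Cluster number and mean area within the platelet ROI
#'
#' The platelet's reference point is the intensity-independent centre of mass
#' of the cluster mask (the unweighted centroid of all foreground pixels).
#' Only clusters whose centroid lies within `roi_radius_um` (default 1.6 um,
#' chosen to cover the clusters of a whole platelet) of that centre
#' contribute: `n_clusters` counts them and `mean_cluster_area_um2` is their
#' total area divided by their number.
#'
#' @param cmap a `cluster_map` from [label_clusters()].
#' @param pixel_size_nm physical pixel size in nm.
#' @param roi_radius_um radius of the circular region of interest, um.
#' @return A list with `n_clusters`, `mean_cluster_area_um2` (`NA` when no
#'   cluster lies in the ROI), `center_of_mass_px` (x, y) and `empty`
#'   (logical flag).
#' @export
cluster_stats <- function(cmap, pixel_size_nm, roi_radius_um = 1.6) {
  if (!inherits(cmap, "cluster_map")) stopf("'cmap' must be a cluster_map")
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  if (length(cmap$areas_px) == 0L)
    return(list(n_clusters = 0L, mean_cluster_area_um2 = NA_real_,
                center_of_mass_px = c(x = NA_real_, y = NA_real_),
                empty = TRUE))
  fg <- which(cmap$label_grid > 0L)
  nr <- nrow(cmap$label_grid)
  com <- c(x = mean((fg - 1L) %/% nr), y = mean((fg - 1L) %% nr))
  d_um <- sqrt((cmap$centroids_px[, "x"] - com["x"])^2 +
               (cmap$centroids_px[, "y"] - com["y"])^2) *
    pixel_size_nm / 1000
  inside <- d_um <= roi_radius_um
  n_c <- sum(inside)
  a_c <- if (n_c > 0) {
    sum(cmap$areas_px[inside]) * (pixel_size_nm / 1000)^2 / n_c
  } else NA_real_
  list(n_clusters = as.integer(n_c), mean_cluster_area_um2 = a_c,
       center_of_mass_px = com, empty = n_c == 0L)
}

#' Radial distribution of clusters around the platelet centre
#'
#' Divides the plane around `center_px` into `n_zones` concentric zones of
#' equal width (250 nm by default) and counts the clusters whose centroid
#' distance falls in each zone (zone i covers distances in
#' `(r_{i-1}, r_i]`, with distance 0 assigned to zone 1).  Clusters beyond
#' the outermost zone are ignored but counted in `n_outside`.  The profile is
#' normalized so the zone fractions sum to one.
#'
#' @param cmap a `cluster_map`.
#' @param center_px numeric (x, y) centre in 0-based pixel units, typically
#'   the `center_of_mass_px` from [cluster_stats()].
#' @param pixel_size_nm physical pixel size in nm.
#' @param n_zones number of zones (default 10).
#' @param zone_width_um zone width in um (default 0.25).
#' @return An object of class `radial_profile`: `zone_outer_radii_um`,
#'   `counts`, `normalized` (all `NA` when no cluster falls in any zone) and
#'   `n_outside`.
#' @export
radial_profile <- function(cmap, center_px, pixel_size_nm, n_zones = 10L,
                           zone_width_um = 0.25) {
  if (!inherits(cmap, "cluster_map")) stopf("'cmap' must be a cluster_map")
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  check_number(zone_width_um, "zone_width_um", lower = 1e-9)
  n_zones <- as.integer(check_number(n_zones, "n_zones", lower = 1))
  outer_r <- seq_len(n_zones) * zone_width_um
  k <- length(cmap$areas_px)
  if (k == 0L)
    return(structure(list(zone_outer_radii_um = outer_r,
                          counts = integer(n_zones),
                          normalized = rep(NA_real_, n_zones),
                          n_outside = 0L),
                     class = "radial_profile"))
  d_um <- sqrt((cmap$centroids_px[, "x"] - center_px[1L])^2 +
               (cmap$centroids_px[, "y"] - center_px[2L])^2) *
    pixel_size_nm / 1000
  zone <- pmax(ceiling(d_um / zone_width_um), 1L)
  outside <- zone > n_zones
  counts <- tabulate(zone[!outside], n_zones)
  total <- sum(counts)
  normalized <- if (total > 0) counts / total else rep(NA_real_, n_zones)
  structure(list(zone_outer_radii_um = outer_r, counts = counts,
                 normalized = normalized, n_outside = sum(outside)),
            class = "radial_profile")
}

#' First and second radial moments
#'
#' For a normalized radial profile, `m1 = sum_i r_i * Nbar(r_i)` is the
#' average cluster distance from the platelet centre and
#' `m2 = sum_i r_i^2 * Nbar(r_i)` relates to the spread of that distance;
#' `r_i` is the outer radius of zone i.
#'
#' @param profile a `radial_profile` with a valid normalization.
#' @return A list with `m1_um` and `m2_um2`.
#' @export
radial_moments <- function(profile) {
  if (!inherits(profile, "radial_profile"))
    stopf("'profile' must be a radial_profile")
  nb <- profile$normalized
  if (any(is.na(nb)) || abs(sum(nb) - 1) > 1e-9)
    stopf("profile is not normalized (empty or invalid)")
  r <- profile$zone_outer_radii_um
  list(m1_um = sum(r * nb), m2_um2 = sum(r^2 * nb))
}

#' Extract the five per-platelet parameters
#'
#' Runs the full morphometric chain on one image: Otsu threshold,
#' 8-connectivity cluster labeling, cluster count and mean area inside the
#' ROI, radial profile and moments about the cluster centre of mass, and —
#' when a dictionary is supplied — the SSIM score of the sparse dictionary
#' reconstruction.  Images in which no cluster is found (or that are
#' constant) yield a flagged row rather than an error, so batch runs can
#' exclude them from downstream density fitting.
#'
#' @param image a [platelet_image].
#' @param dictionary optional [patch_dictionary] for the SSIM parameter.
#' @param roi_radius_um ROI radius for the cluster statistics, um.
#' @param n_zones,zone_width_um radial zone layout.
#' @param sparsity atoms per patch for the SSIM reconstruction.
#' @param image_id identifier stored in the output row.
#' @return A one-row data frame with columns `image_id`, `protein`,
#'   `category`, `sample_id`, `n_clusters`, `mean_cluster_area_um2`,
#'   `m1_um`, `m2_um2`, `ssim`, `flag` ("" when all parameters are valid).
#' @export
platelet_features <- function(image, dictionary = NULL, roi_radius_um = 1.6,
                              n_zones = 10L, zone_width_um = 0.25,
                              sparsity = 3L, image_id = NA_character_) {
  image <- as_platelet_image(image)
  row <- data.frame(image_id = image_id,
                    protein = image$protein %||% NA_character_,
                    category = image$category %||% NA_integer_,
                    sample_id = image$sample_id %||% NA_character_,
                    n_clusters = NA_integer_,
                    mean_cluster_area_um2 = NA_real_,
                    m1_um = NA_real_, m2_um2 = NA_real_, ssim = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  thr <- tryCatch(otsu_threshold(image), error = function(e) NULL)
  if (is.null(thr)) {
    row$flag <- "constant_image"
    return(row)
  }
  cmap <- label_clusters(image, thr)
  cs <- cluster_stats(cmap, image$pixel_size_nm, roi_radius_um)
  row$n_clusters <- cs$n_clusters
  row$mean_cluster_area_um2 <- cs$mean_cluster_area_um2
  if (cs$empty) {
    row$flag <- "no_clusters"
  } else {
    prof <- radial_profile(cmap, cs$center_of_mass_px, image$pixel_size_nm,
                           n_zones = n_zones, zone_width_um = zone_width_um)
    if (all(prof$counts == 0)) {
      row$flag <- "no_clusters_in_zones"
    } else {
      mom <- radial_moments(prof)
      row$m1_um <- mom$m1_um
      row$m2_um2 <- mom$m2_um2
    }
  }
  if (!is.null(dictionary))
    row$ssim <- ssim_feature(image, dictionary, sparsity = sparsity)
  row
}

#' Feature table for a batch of platelet images
#'
#' @param images list of [platelet_image]s.
#' @param dictionary optional [patch_dictionary]; when present the `ssim`
#'   column is filled.
#' @param ... passed to [platelet_features()].
#' @return A data frame with one row per image (see [platelet_features()]).
#' @export
feature_table <- function(images, dictionary = NULL, ...) {
  rows <- lapply(seq_along(images), function(i)
    platelet_features(images[[i]], dictionary = dictionary,
                      image_id = sprintf("img%04d", i), ...))
  do.call(rbind, rows)
}
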