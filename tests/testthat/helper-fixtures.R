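# Shared fixtures and independent oracles used across the test files.

# small, fast imaging geometry that still contains a full platelet disc
small_imaging <- function(...) {
  imaging_spec(pixel_size_nm = 60, image_size_px = 64, psf_fwhm_nm = 40,
               background = 1, read_noise_sigma = 0.5, ...)
}

# noise-free geometry for planted-truth recovery (clusters inside the ROI)
recovery_pop <- function(n = 8L) {
  cluster_population(n_clusters_mean = n, n_clusters_dispersion = 0,
                     cluster_radius_mean_nm = 80, cluster_radius_sigma = 0,
                     platelet_radius_nm = 1280)
}

recovery_imaging <- function() {
  imaging_spec(pixel_size_nm = 20, image_size_px = 200, psf_fwhm_nm = 40,
               background = 0, read_noise_sigma = 0)
}

# independent queue-based flood fill with 8-connectivity; returns the number
# of components and their sorted areas
floodfill_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  areas <- integer(0)
  for (sr in seq_len(nr)) for (sc in seq_len(nc)) {
    if (!mask[sr, sc] || seen[sr, sc]) next
    queue <- list(c(sr, sc)); seen[sr, sc] <- TRUE; area <- 0L
    while (length(queue) > 0L) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      area <- area + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r >= 1L && r <= nr && c >= 1L && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
    areas <- c(areas, area)
  }
  list(n = length(areas), areas = sort(areas))
}

# exhaustive-search Otsu oracle working on the raw values (no histogram):
# tries 256 candidate thresholds and maximizes between-class variance
otsu_oracle <- function(v) {
  cand <- seq(min(v), max(v), length.out = 256L)
  bcv <- vapply(cand, function(t) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0L || length(hi) == 0L) return(-Inf)
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  cand[which.max(bcv)]
}

# hand-rolled probability-function builder for classifier unit tests
make_pf <- function(bin_edges, bin_probs, name = "x") {
  structure(list(parameter_name = name, bin_edges = bin_edges,
                 bin_probs = bin_probs / sum(bin_probs), bandwidth = NA_real_,
                 degenerate = FALSE), class = "probability_function")
}

make_library <- function(table, categories, parameters, proteins) {
  structure(list(table = table, proteins = proteins,
                 parameters = parameters, categories = categories,
                 M = length(categories)), class = "category_library")
}

# feature table drawn numerically from per-category Gaussians — lets the
# classifier be exercised without rendering any image
synthetic_feature_table <- function(means_by_category, n_per_cat,
                                    protein = "P1", sd_ = 1, seed = 1L) {
  set.seed(seed)
  rows <- lapply(seq_along(means_by_category), function(i) {
    m <- means_by_category[[i]]
    data.frame(image_id = sprintf("%s_c%d_%04d", protein, i,
                                  seq_len(n_per_cat)),
               protein = protein, category = i,
               n_clusters = rnorm(n_per_cat, m[1L], sd_),
               mean_cluster_area_um2 = rnorm(n_per_cat, m[2L], sd_),
               m1_um = rnorm(n_per_cat, m[3L], sd_),
               m2_um2 = rnorm(n_per_cat, m[4L], sd_),
               ssim = NA_real_, flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# tiny patch dictionary for reconstruction tests (trained once per session)
tiny_dictionary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      imgs <- simulate_training_set(cluster_population(),
                                    imaging_spec(pixel_size_nm = 40,
                                                 image_size_px = 100,
                                                 background = 0,
                                                 read_noise_sigma = 0),
                                    n_images = 40, seed = 404)
      cache <<- train_dictionary(imgs, n_atoms = 25L, patch_size = 10L,
                                 sparsity = 3L, n_iter = 5L, seed = 404)
    }
    cache
  }
})
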