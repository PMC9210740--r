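#' Specification of a synthetic platelet cluster population
#'
#' Describes how fluorescent protein clusters are planted inside a simulated
#' platelet: how many (a count distribution), how large (log-normal radii)
#' and where (a one-parameter radial placement family spanning centre- to
#' rim-biased layouts).
#'
#' The cluster count distribution is controlled by `n_clusters_dispersion`,
#' the variance-to-mean ratio of the count: 0 gives a fixed count
#' (`round(n_clusters_mean)`), 1 gives a Poisson count, values above 1 a
#' negative-binomial count, and values in (0, 1) a binomial count with the
#' matching under-dispersion.
#'
#' Cluster centres are drawn at radius r with density proportional to
#' `r * (1 + radial_bias * (2 r / R - 1))` on `[0, R - cluster radius]`
#' (clipped at zero), where R is the platelet radius: `radial_bias = 0` is
#' uniform over the disc area, positive values push clusters to the rim,
#' negative values pull them to the centre.
#'
#' @param n_clusters_mean mean number of planted clusters (>= 0).
#' @param n_clusters_dispersion variance-to-mean ratio of the cluster count.
#' @param cluster_radius_mean_nm mean cluster radius in nm.
#' @param cluster_radius_sigma log-normal shape parameter of the radius
#'   (0 = all clusters identical).
#' @param radial_bias placement bias in \code{[-1, 1]}; see Details.
#' @param platelet_radius_nm radius of the platelet disc in nm.
#' @param peak_intensity expected photon count at the centre of an unblurred
#'   cluster disc.
#' @return An object of class `cluster_population`.
#' @examples
#' cluster_population(n_clusters_mean = 10)
#' @export
cluster_population <- function(n_clusters_mean = 10,
                               n_clusters_dispersion = 1,
                               cluster_radius_mean_nm = 80,
                               cluster_radius_sigma = 0.25,
                               radial_bias = 0,
                               platelet_radius_nm = 1750,
                               peak_intensity = 60) {
  check_number(n_clusters_mean, "n_clusters_mean", lower = 0)
  check_number(n_clusters_dispersion, "n_clusters_dispersion", lower = 0)
  check_number(cluster_radius_mean_nm, "cluster_radius_mean_nm", lower = 1e-9)
  check_number(cluster_radius_sigma, "cluster_radius_sigma", lower = 0)
  check_number(radial_bias, "radial_bias", lower = -1, upper = 1)
  check_number(platelet_radius_nm, "platelet_radius_nm", lower = 1e-9)
  check_number(peak_intensity, "peak_intensity", lower = 0)
  structure(list(n_clusters_mean = n_clusters_mean,
                 n_clusters_dispersion = n_clusters_dispersion,
                 cluster_radius_mean_nm = cluster_radius_mean_nm,
                 cluster_radius_sigma = cluster_radius_sigma,
                 radial_bias = radial_bias,
                 platelet_radius_nm = platelet_radius_nm,
                 peak_intensity = peak_intensity),
            class = "cluster_population")
}

#' Specification of the simulated STED acquisition
#'
#' Defaults emulate the imaging regime of a 40 nm lateral PSF sampled at
#' 20 nm per pixel on a 200 x 200 grid (a 4 x 4 micron field comfortably
#' holding one platelet).
#'
#' @param pixel_size_nm physical pixel size in nm.
#' @param image_size_px image side length in pixels (square image).
#' @param psf_fwhm_nm full width at half maximum of the Gaussian point
#'   spread function, in nm.
#' @param background mean background level, photons per pixel.
#' @param read_noise_sigma standard deviation of additive Gaussian read
#'   noise, photons.
#' @return An object of class `imaging_spec`.
#' @export
imaging_spec <- function(pixel_size_nm = 20, image_size_px = 200,
                         psf_fwhm_nm = 40, background = 2,
                         read_noise_sigma = 1) {
  check_number(pixel_size_nm, "pixel_size_nm", lower = 1e-9)
  check_number(image_size_px, "image_size_px", lower = 8)
  check_number(psf_fwhm_nm, "psf_fwhm_nm", lower = 0)
  check_number(background, "background", lower = 0)
  check_number(read_noise_sigma, "read_noise_sigma", lower = 0)
  structure(list(pixel_size_nm = pixel_size_nm,
                 image_size_px = as.integer(image_size_px),
                 psf_fwhm_nm = psf_fwhm_nm, background = background,
                 read_noise_sigma = read_noise_sigma),
            class = "imaging_spec")
}

draw_cluster_count <- function(pop) {
  mu <- pop$n_clusters_mean
  d <- pop$n_clusters_dispersion
  if (mu == 0) return(0L)
  if (d == 0) return(as.integer(round(mu)))
  if (d == 1) return(stats::rpois(1L, mu))
  if (d > 1) {
    size <- mu / (d - 1)
    return(stats::rnbinom(1L, size = size, mu = mu))
  }
  # under-dispersed: binomial with variance mu * d
  n <- max(1L, as.integer(round(mu / (1 - d))))
  as.integer(stats::rbinom(1L, n, mu / n))
}

# radius density ~ r * (1 + bias * (2 r / R - 1)), clipped >= 0, on [0, rmax]
draw_radius <- function(n, rmax, R, bias) {
  if (n == 0L) return(numeric(0))
  if (rmax <= 0) return(rep(0, n))
  dens <- function(r) pmax(0, r * (1 + bias * (2 * r / R - 1)))
  peak <- max(dens(seq(0, rmax, length.out = 256)))
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out)) + 8L
    r <- stats::runif(m, 0, rmax)
    keep <- stats::runif(m) * peak < dens(r)
    out <- c(out, r[keep])
  }
  out[seq_len(n)]
}

place_clusters <- function(pop, allow_overlap, min_sep_nm = 0,
                           max_tries = 200L) {
  k <- draw_cluster_count(pop)
  if (k == 0L)
    return(data.frame(center_x_nm = numeric(0), center_y_nm = numeric(0),
                      radius_nm = numeric(0)))
  radii <- if (pop$cluster_radius_sigma == 0) {
    rep(pop$cluster_radius_mean_nm, k)
  } else {
    stats::rlnorm(k, meanlog = log(pop$cluster_radius_mean_nm) -
                    pop$cluster_radius_sigma^2 / 2,
                  sdlog = pop$cluster_radius_sigma)
  }
  R <- pop$platelet_radius_nm
  cx <- numeric(k); cy <- numeric(k)
  for (i in seq_len(k)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      rmax <- max(0, R - radii[i])
      r <- draw_radius(1L, rmax, R, pop$radial_bias)
      th <- stats::runif(1L, 0, 2 * pi)
      x <- r * cos(th); y <- r * sin(th)
      if (allow_overlap || i == 1L ||
          all(sqrt((x - cx[seq_len(i - 1L)])^2 +
                   (y - cy[seq_len(i - 1L)])^2) >=
              radii[i] + radii[seq_len(i - 1L)] + min_sep_nm)) {
        cx[i] <- x; cy[i] <- y; ok <- TRUE; break
      }
    }
    if (!ok)
      stopf("could not place %d non-overlapping clusters in the platelet disc",
            k)
  }
  data.frame(center_x_nm = cx, center_y_nm = cy, radius_nm = radii)
}

render_clusters <- function(truth, img, intensity) {
  n <- img$image_size_px
  ps <- img$pixel_size_nm
  signal <- matrix(0, n, n)
  if (nrow(truth) > 0L) {
    # pixel centres in nm, origin at the top-left pixel centre
    coords <- (seq_len(n) - 1L) * ps
    centre <- (n - 1) * ps / 2
    for (i in seq_len(nrow(truth))) {
      x0 <- truth$center_x_nm[i] + centre
      y0 <- truth$center_y_nm[i] + centre
      rad <- truth$radius_nm[i]
      xi <- which(abs(coords - x0) <= rad + ps)
      yi <- which(abs(coords - y0) <= rad + ps)
      if (length(xi) == 0L || length(yi) == 0L) next
      d2 <- outer((coords[yi] - y0)^2, (coords[xi] - x0)^2, "+")
      signal[yi, xi] <- signal[yi, xi] + intensity * (d2 <= rad^2)
    }
  }
  if (img$psf_fwhm_nm > 0) {
    sigma_px <- fwhm_to_sigma(img$psf_fwhm_nm) / ps
    signal <- conv2_reflect(signal, gaussian_kernel(sigma_px))
  }
  signal
}

#' Simulate a STED-like image of a single platelet
#'
#' Plants fluorescent clusters inside a platelet-sized disc according to a
#' [cluster_population], blurs the resulting photon signal with the Gaussian
#' point spread function of an [imaging_spec], and adds Poisson shot noise,
#' a constant background and Gaussian read noise.  Every planted cluster is
#' recorded in the returned image's `ground_truth`.
#'
#' Identical `(pop, img, seed)` give bit-identical images.
#'
#' @param pop a [cluster_population].
#' @param img an [imaging_spec].
#' @param seed integer seed for this image.
#' @param noise if `FALSE`, return the noise-free expected image
#'   (background + blurred signal) — useful for ground-truth recovery tests.
#' @param allow_overlap if `FALSE`, cluster positions are rejection-sampled
#'   so no two planted discs overlap; discs additionally keep an
#'   edge-to-edge distance of `min_separation_nm` so that the PSF blur
#'   cannot bridge neighbouring clusters into one connected component.
#' @param min_separation_nm edge-to-edge separation enforced when
#'   `allow_overlap = FALSE`; defaults to twice the PSF FWHM.
#' @param protein,category,sample_id optional labels stored on the image.
#' @return A [platelet_image] with `ground_truth` attached.
#' @examples
#' im <- simulate_platelet(cluster_population(8), imaging_spec(), seed = 1)
#' nrow(im$ground_truth)
#' @export
simulate_platelet <- function(pop, img = imaging_spec(), seed = 1L,
                              noise = TRUE, allow_overlap = TRUE,
                              min_separation_nm = NULL,
                              protein = NULL, category = NULL,
                              sample_id = NULL) {
  if (!inherits(pop, "cluster_population"))
    stopf("'pop' must be a cluster_population")
  if (!inherits(img, "imaging_spec"))
    stopf("'img' must be an imaging_spec")
  if (img$image_size_px * img$pixel_size_nm < 2 * pop$platelet_radius_nm)
    stopf("image (%g nm across) cannot contain the platelet disc (%g nm)",
          img$image_size_px * img$pixel_size_nm, 2 * pop$platelet_radius_nm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483647))
  min_sep <- if (allow_overlap) 0 else
    (min_separation_nm %||% (2 * img$psf_fwhm_nm))
  truth <- place_clusters(pop, allow_overlap, min_sep_nm = min_sep)
  signal <- render_clusters(truth, img, pop$peak_intensity)
  pixels <- if (noise) {
    n <- img$image_size_px
    shot <- matrix(stats::rpois(n * n, pmax(signal, 0)), n, n)
    read <- if (img$read_noise_sigma > 0)
      matrix(stats::rnorm(n * n, 0, img$read_noise_sigma), n, n) else 0
    pmax(img$background + shot + read, 0)
  } else {
    img$background + pmax(signal, 0)
  }
  platelet_image(pixels, img$pixel_size_nm, protein = protein,
                 category = category, sample_id = sample_id,
                 ground_truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate an independent set of platelet images
#'
#' Produces `n_images` independent draws from the same population; the seed
#' of image i is derived deterministically from the master seed, so the whole
#' set is reproducible and individual images can be regenerated in isolation.
#'
#' @inheritParams simulate_platelet
#' @param n_images number of images (>= 1).
#' @return A list of [platelet_image]s.
#' @export
simulate_training_set <- function(pop, img = imaging_spec(), n_images,
                                  seed = 1L, noise = TRUE,
                                  allow_overlap = TRUE, protein = NULL,
                                  category = NULL, sample_id = NULL) {
  check_number(n_images, "n_images", lower = 1)
  lapply(seq_len(n_images), function(i)
    simulate_platelet(pop, img, seed = derive_seed(seed, i), noise = noise,
                      allow_overlap = allow_overlap, protein = protein,
                      category = category, sample_id = sample_id))
}

#' Simulate a labeled multi-category platelet ensemble
#'
#' Generates `n_per_category` images for each entry of `category_specs`, a
#' named list mapping integer category codes to `list(pop =, img =)` pairs
#' (a bare [cluster_population] is also accepted and paired with the default
#' [imaging_spec]).  Each returned image carries its category code; within a
#' category images are exchangeable.
#'
#' @param category_specs named list; names are distinct integer category
#'   codes.
#' @param n_per_category images per category (>= 1).
#' @param seed master seed.
#' @param protein,noise,allow_overlap passed through to the generator.
#' @return A flat list of labeled [platelet_image]s,
#'   `n_per_category * length(category_specs)` long.
#' @export
simulate_category_ensemble <- function(category_specs, n_per_category,
                                       seed = 1L, protein = NULL,
                                       noise = TRUE, allow_overlap = TRUE) {
  if (length(category_specs) < 2L)
    stopf("need at least 2 categories")
  codes <- suppressWarnings(as.integer(names(category_specs)))
  if (any(is.na(codes)) || anyDuplicated(codes))
    stopf("category_specs must be named by distinct integer codes")
  out <- vector("list", 0L)
  for (j in seq_along(category_specs)) {
    spec <- category_specs[[j]]
    if (inherits(spec, "cluster_population"))
      spec <- list(pop = spec, img = imaging_spec())
    imgs <- simulate_training_set(
      spec$pop, spec$img %||% imaging_spec(), n_per_category,
      seed = derive_seed(seed, 1000L + j), noise = noise,
      allow_overlap = allow_overlap, protein = protein,
      category = codes[j])
    out <- c(out, imgs)
  }
  out
}
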