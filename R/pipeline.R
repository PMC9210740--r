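#' Study configuration
#'
#' Collects every tunable of the image-to-classification workflow in one
#' validated object so a whole study can be rerun bit-identically from its
#' configuration and seed.
#'
#' @param pixel_size_nm pixel size of the input images, nm.
#' @param lowpass_sigma_px Gaussian low-pass sigma, pixels (0 disables).
#' @param psf_fwhm_nm deconvolution PSF FWHM, nm.
#' @param max_iterations Richardson-Lucy iteration cap (0 disables
#'   deconvolution).
#' @param roi_radius_um cluster-statistics ROI radius, um.
#' @param n_zones,zone_width_um radial zone layout.
#' @param dict_n_images simulated images for dictionary training.
#' @param dict_atoms,dict_patch,dict_sparsity dictionary geometry and
#'   sparsity level.
#' @param kde_bins,kde_grid,kde_folds,kde_trim_sigma KDE settings.
#' @param set_size,n_rounds classification settings.
#' @param holdout split-sample evaluation flag.
#' @param seed master seed.
#' @param category_codes named integer vector mapping category labels to
#'   codes (default [coculture_codes]).
#' @return An object of class `study_config`.
#' @export
study_config <- function(pixel_size_nm = 20, lowpass_sigma_px = 1,
                         psf_fwhm_nm = 40, max_iterations = 10,
                         roi_radius_um = 1.6, n_zones = 10L,
                         zone_width_um = 0.25, dict_n_images = 2000L,
                         dict_atoms = 81L, dict_patch = 30L,
                         dict_sparsity = 3L, kde_bins = 100L,
                         kde_grid = 30L, kde_folds = 5L, kde_trim_sigma = 5,
                         set_size = 10L, n_rounds = 1000L, holdout = FALSE,
                         seed = 1L, category_codes = coculture_codes) {
  cfg <- list(pixel_size_nm = pixel_size_nm,
              lowpass_sigma_px = lowpass_sigma_px,
              psf_fwhm_nm = psf_fwhm_nm, max_iterations = max_iterations,
              roi_radius_um = roi_radius_um, n_zones = as.integer(n_zones),
              zone_width_um = zone_width_um,
              dict_n_images = as.integer(dict_n_images),
              dict_atoms = as.integer(dict_atoms),
              dict_patch = as.integer(dict_patch),
              dict_sparsity = as.integer(dict_sparsity),
              kde_bins = as.integer(kde_bins),
              kde_grid = as.integer(kde_grid),
              kde_folds = as.integer(kde_folds),
              kde_trim_sigma = kde_trim_sigma,
              set_size = as.integer(set_size),
              n_rounds = as.integer(n_rounds), holdout = isTRUE(holdout),
              seed = as.integer(seed), category_codes = category_codes)
  for (nm in c("pixel_size_nm", "zone_width_um"))
    check_number(cfg[[nm]], nm, lower = 1e-9)
  for (nm in c("lowpass_sigma_px", "psf_fwhm_nm", "max_iterations",
               "kde_trim_sigma"))
    check_number(cfg[[nm]], nm, lower = 0)
  for (nm in c("roi_radius_um", "n_zones", "dict_n_images", "dict_atoms",
               "dict_patch", "dict_sparsity", "kde_bins", "kde_grid",
               "kde_folds", "set_size", "n_rounds"))
    check_number(cfg[[nm]], nm, lower = 1)
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(flat))
    cat(sprintf("  %-18s %s\n", nm, paste(flat[[nm]], collapse = " ")))
  invisible(x)
}

preprocess_image <- function(image, config) {
  if (config$lowpass_sigma_px > 0)
    image <- gaussian_lowpass(image, config$lowpass_sigma_px)
  if (config$max_iterations > 0 && config$psf_fwhm_nm > 0)
    image <- deconvolve(image, psf_model(config$psf_fwhm_nm),
                        config$max_iterations)
  image
}

#' Run the full image-to-classification study
#'
#' Orchestrates the whole workflow on a set of labeled platelet images:
#' identical preprocessing for every image (low-pass then Richardson-Lucy),
#' dictionary training on simulated platelet images, extraction of the five
#' per-platelet parameters, the KDE probability library, per-protein
#' bootstrap classification matrices, the combined matrix, and — optionally
#' — protein-subset rankings.  All randomness derives from `config$seed`,
#' so a rerun with the same inputs is bit-identical.
#'
#' Images can be given either as an in-memory list of labeled
#' [platelet_image]s or as a manifest data frame with columns `path`,
#' `protein`, `category`, `sample_id` pointing at TIFF files
#' ([read_platelet_tiff()]).  Every (protein, category) cell must contain at
#' least `config$set_size` images; gaps are reported as an error before any
#' computation starts.
#'
#' @param config a [study_config].
#' @param images list of labeled [platelet_image]s (alternative to
#'   `manifest`).
#' @param manifest data frame with columns `path`, `protein`, `category`
#'   and optionally `sample_id`.
#' @param subset_sizes integer vector; for each entry n, rank all size-n
#'   protein subsets (skipped when empty or only one protein is present).
#' @param subset_rounds bootstrap rounds per subset during the search.
#' @return An object of class `study_bundle`: `features`, `dictionary`,
#'   `classifier` (a [platelet_classifier]), `subset_rankings`, `config`,
#'   `log` (character vector of the seeds and decisions taken).
#' @export
run_study <- function(config, images = NULL, manifest = NULL,
                      subset_sizes = integer(0), subset_rounds = 200L) {
  if (!inherits(config, "study_config"))
    stopf("'config' must be a study_config")
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  if (is.null(images)) {
    if (is.null(manifest)) stopf("supply either 'images' or 'manifest'")
    need <- c("path", "protein", "category")
    if (!all(need %in% names(manifest)))
      stopf("manifest needs columns %s", paste(need, collapse = ", "))
    missing <- !file.exists(manifest$path)
    if (any(missing))
      stopf("manifest paths do not exist: %s",
            paste(utils::head(manifest$path[missing], 5), collapse = ", "))
    images <- lapply(seq_len(nrow(manifest)), function(i) {
      im <- read_platelet_tiff(manifest$path[i],
                               pixel_size_nm = config$pixel_size_nm)
      im$protein <- as.character(manifest$protein[i])
      im$category <- as.integer(manifest$category[i])
      im$sample_id <- if ("sample_id" %in% names(manifest))
        as.character(manifest$sample_id[i]) else NULL
      im
    })
    note("loaded %d images from manifest", length(images))
  }
  prot <- vapply(images, function(im) im$protein %||% NA_character_,
                 character(1))
  cat_ <- vapply(images, function(im) as.integer(im$category %||% NA),
                 integer(1))
  if (any(is.na(prot)) || any(is.na(cat_)))
    stopf("every image must carry protein and category labels")
  cells <- table(factor(prot), factor(cat_))
  short <- which(cells < config$set_size, arr.ind = TRUE)
  if (nrow(short) > 0L)
    stopf("too few images (< set_size) for: %s",
          paste(sprintf("(%s, %s)", rownames(cells)[short[, 1L]],
                        colnames(cells)[short[, 2L]]), collapse = ", "))
  # 1. identical preprocessing for every image of the study
  images <- lapply(images, preprocess_image, config = config)
  note("preprocessing: lowpass sigma %g px, RL %d iterations, PSF %g nm",
       config$lowpass_sigma_px, config$max_iterations, config$psf_fwhm_nm)
  # 2. dictionary trained on simulated platelet images
  dict_seed <- derive_seed(config$seed, 101L)
  train <- simulate_training_set(cluster_population(),
                                 imaging_spec(pixel_size_nm =
                                                config$pixel_size_nm),
                                 n_images = config$dict_n_images,
                                 seed = dict_seed)
  dict <- train_dictionary(train, n_atoms = config$dict_atoms,
                           patch_size = config$dict_patch,
                           sparsity = config$dict_sparsity,
                           seed = derive_seed(config$seed, 102L))
  note("dictionary: %d atoms, %d x %d px, %d simulated training images, seed %d",
       config$dict_atoms, config$dict_patch, config$dict_patch,
       config$dict_n_images, dict_seed)
  # 3. five parameters per platelet
  feats <- feature_table(images, dictionary = dict,
                         roi_radius_um = config$roi_radius_um,
                         n_zones = config$n_zones,
                         zone_width_um = config$zone_width_um,
                         sparsity = config$dict_sparsity)
  n_flag <- sum(feats$flag != "")
  if (n_flag > 0)
    note("%d image(s) flagged and excluded from density fitting", n_flag)
  # 4-5. KDE library + bootstrap matrices (+ combined)
  fit <- platelet_classifier(feats, set_size = config$set_size,
                             n_rounds = config$n_rounds,
                             seed = derive_seed(config$seed, 103L),
                             holdout = config$holdout,
                             n_bins = config$kde_bins,
                             n_grid = config$kde_grid,
                             n_folds = config$kde_folds,
                             trim_sigma = config$kde_trim_sigma)
  note("classifier: sets of %d, %d rounds, holdout %s", config$set_size,
       config$n_rounds, config$holdout)
  rankings <- list()
  if (length(fit$library$proteins) > 1L)
    for (n in subset_sizes) {
      rankings[[as.character(n)]] <-
        protein_subset_search(fit$features, fit$library, fit$matrices, n,
                              set_size = config$set_size,
                              n_rounds = subset_rounds,
                              seed = derive_seed(config$seed, 104L + n))
      note("subset search n=%d at %d rounds", n, subset_rounds)
    }
  structure(list(features = feats, dictionary = dict, classifier = fit,
                 subset_rankings = rankings, config = config, log = log),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d platelets\n", nrow(x$features)))
  print(x$classifier)
  invisible(x)
}

#' Write the outputs of a study bundle to a directory
#'
#' Emits `features.csv`, `dictionary.json`, `library.json`,
#' `matrix_<protein>.csv`, `combined_matrix.csv`, `subsets_<n>.csv` and
#' `run.log`.
#'
#' @param bundle a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  write_dictionary(bundle$dictionary, file.path(dir, "dictionary.json"))
  write_category_library(bundle$classifier$library,
                         file.path(dir, "library.json"))
  for (pr in names(bundle$classifier$matrices))
    utils::write.csv(bundle$classifier$matrices[[pr]]$P,
                     file.path(dir, sprintf("matrix_%s.csv", pr)))
  if (!is.null(bundle$classifier$combined_matrix))
    utils::write.csv(bundle$classifier$combined_matrix$P,
                     file.path(dir, "combined_matrix.csv"))
  for (n in names(bundle$subset_rankings)) {
    rk <- bundle$subset_rankings[[n]]
    df <- data.frame(rank = seq_along(rk),
                     proteins = vapply(rk, function(r)
                       paste(r$proteins, collapse = "+"), character(1)),
                     diag_sum = vapply(rk, `[[`, numeric(1), "diag_sum"))
    utils::write.csv(df, file.path(dir, sprintf("subsets_%s.csv", n)),
                     row.names = FALSE)
  }
  writeLines(bundle$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Serialize / restore a category library as JSON
#'
#' @param library a `category_library`.
#' @param path file path.
#' @return `write_category_library` returns `path` invisibly;
#'   `read_category_library` the restored library.
#' @export
write_category_library <- function(library, path) {
  obj <- list(proteins = library$proteins, parameters = library$parameters,
              categories = library$categories, table = library$table)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname write_category_library
#' @export
read_category_library <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  tab <- obj$table
  for (pr in names(tab)) for (pa in names(tab[[pr]]))
    for (m in names(tab[[pr]][[pa]])) {
      pf <- tab[[pr]][[pa]][[m]]
      tab[[pr]][[pa]][[m]] <-
        structure(list(parameter_name = pf$parameter_name,
                       bin_edges = as.numeric(unlist(pf$bin_edges)),
                       bin_probs = as.numeric(unlist(pf$bin_probs)),
                       bandwidth = as.numeric(pf$bandwidth),
                       degenerate = isTRUE(pf$degenerate)),
                  class = "probability_function")
    }
  structure(list(table = tab, proteins = unlist(obj$proteins),
                 parameters = unlist(obj$parameters),
                 categories = as.integer(unlist(obj$categories)),
                 M = length(unlist(obj$categories))),
            class = "category_library")
}
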