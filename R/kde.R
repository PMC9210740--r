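#' Binned KDE probability function for one parameter
#'
#' Fits a Gaussian kernel density estimate to a set of parameter values,
#' choosing the bandwidth by k-fold cross-validated grid search on the
#' held-out log likelihood.  Before the bandwidth search, points above a
#' five-sigma cutoff are removed (parameters such as the mean cluster area
#' can have very large outliers that would inflate the bandwidth); all
#' values re-enter the final density evaluation.  The fitted density is then
#' integrated over `n_bins` equal-width bins spanning the 1st to 99th
#' percentile of the fitted density (avoiding the asymptotic tails) and
#' normalized to sum 1.
#'
#' @param values numeric parameter values (at least 10).
#' @param seed integer seed for the cross-validation fold assignment.
#' @param n_bins number of probability bins.
#' @param n_grid number of candidate bandwidths (log-spaced over
#'   `[0.01, 1] * sd`).
#' @param n_folds cross-validation folds.
#' @param trim_sigma outlier cutoff (in standard deviations above the mean)
#'   applied during bandwidth selection only.
#' @param bin_range optional common `c(lo, hi)` range for the bins.  When
#'   probability functions of several categories are compared (as in the
#'   p-score), they must share one bin grid — [fit_category_library()]
#'   passes the union of the per-category supports here.  `NULL` uses this
#'   sample's own 1st-99th percentile support.
#' @param bandwidth optional fixed kernel bandwidth, skipping the
#'   cross-validated search.
#' @param parameter_name label stored with the function.
#' @return An object of class `probability_function`: `bin_edges`
#'   (`n_bins + 1` increasing values), `bin_probs` (summing to 1),
#'   `bandwidth`, `parameter_name`, `degenerate` flag.
#' @export
fit_probability_function <- function(values, seed = 1L, n_bins = 100L,
                                     n_grid = 30L, n_folds = 5L,
                                     trim_sigma = 5, bin_range = NULL,
                                     bandwidth = NULL,
                                     parameter_name = NA_character_) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 10L)
    stopf("need at least 10 finite values to fit a probability function, got %d",
          length(values))
  s <- stats::sd(values)
  if (s < 1e-8 * max(1, abs(mean(values)))) {
    # numerically zero spread: the KDE degenerates to a point mass
    # zero-variance fallback: all mass in one narrow bin around the value
    v <- mean(values)
    h <- max(abs(v) * 1e-6, 1e-9)
    return(structure(list(parameter_name = parameter_name,
                          bin_edges = c(v - h, v + h), bin_probs = 1,
                          bandwidth = h, degenerate = TRUE),
                     class = "probability_function"))
  }
  v_bw <- values[values <= mean(values) + trim_sigma * s]
  if (length(v_bw) < 10L) v_bw <- values
  bw <- bandwidth %||%
    cv_bandwidth(v_bw, seed = seed, n_grid = n_grid, n_folds = n_folds)
  # exact Gaussian-mixture CDF makes the per-bin integrals exact
  kde_cdf <- function(q) vapply(q, function(qq)
    mean(stats::pnorm(qq, mean = values, sd = bw)), numeric(1))
  rng <- bin_range %||% kde_support(values, bw)
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  mass <- diff(kde_cdf(edges))
  mass[mass < 0] <- 0
  probs <- mass / sum(mass)
  structure(list(parameter_name = parameter_name, bin_edges = edges,
                 bin_probs = probs, bandwidth = bw, degenerate = FALSE),
            class = "probability_function")
}

# 1st-99th percentile of the fitted Gaussian-mixture density (trimming the
# asymptotic tails).
kde_support <- function(values, bw) {
  lo <- min(values) - 4 * bw
  hi <- max(values) + 4 * bw
  grid <- seq(lo, hi, length.out = 1024L)
  cdf <- vapply(grid, function(qq)
    mean(stats::pnorm(qq, mean = values, sd = bw)), numeric(1))
  q01 <- grid[which(cdf >= 0.01)[1L]]
  q99 <- grid[which(cdf >= 0.99)[1L]]
  if (!is.finite(q99) || q99 <= q01) c(lo, hi) else c(q01, q99)
}

# k-fold cross-validated held-out log-likelihood over a log-spaced
# bandwidth grid.
cv_bandwidth <- function(v, seed, n_grid = 30L, n_folds = 5L) {
  s <- stats::sd(v)
  # lower bound 0.1 sd: discrete-valued parameters (the cluster count) make
  # the held-out likelihood degenerate for near-zero bandwidths
  grid <- exp(seq(log(0.1 * s), log(1.0 * s), length.out = n_grid))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483647))
  n <- length(v)
  folds <- sample(rep_len(seq_len(n_folds), n))
  score <- vapply(grid, function(bw) {
    ll <- 0
    for (f in seq_len(n_folds)) {
      train <- v[folds != f]; test <- v[folds == f]
      if (length(train) == 0L || length(test) == 0L) next
      dens <- vapply(test, function(x)
        mean(stats::dnorm(x, mean = train, sd = bw)), numeric(1))
      ll <- ll + sum(log(pmax(dens, 1e-300)))
    }
    ll
  }, numeric(1))
  grid[which.max(score)]
}

#' @export
print.probability_function <- function(x, ...) {
  cat(sprintf("<probability_function> %s: %d bins on [%.4g, %.4g], bw %.4g%s\n",
              x$parameter_name, length(x$bin_probs), min(x$bin_edges),
              max(x$bin_edges), x$bandwidth,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Look up the binned probability of a parameter value
#'
#' Returns the probability of the bin containing each value; values outside
#' the binned range receive the floor probability `1e-12`.
#'
#' @param pf a `probability_function`.
#' @param value numeric vector of parameter values.
#' @return Probabilities, same length as `value`.
#' @export
lookup_probability <- function(pf, value) {
  if (!inherits(pf, "probability_function"))
    stopf("'pf' must be a probability_function")
  idx <- findInterval(value, pf$bin_edges, rightmost.closed = TRUE)
  out <- rep(1e-12, length(value))
  inside <- idx >= 1L & idx <= length(pf$bin_probs)
  out[inside] <- pf$bin_probs[idx[inside]]
  out
}

#' The five classification parameters
#'
#' Column names of the per-platelet parameters used throughout the
#' classification: cluster count, mean cluster area, the two radial moments
#' and the dictionary-reconstruction SSIM.
#' @export
platelet_parameters <- c("n_clusters", "mean_cluster_area_um2", "m1_um",
                         "m2_um2", "ssim")

#' Category code map of the co-culturing study design
#'
#' The five co-culturing categories and their integer codes: resting
#' platelets (R = 1), platelets co-cultured with non-cancer MCF-10A cells
#' (2), with MCF-7 (3), MDA-MB-231 (4) or EFO-21 (5) tumor cells.  Synthetic
#' studies may use any other set of integer codes.
#' @export
coculture_codes <- c(R = 1L, "10A" = 2L, MCF7 = 3L, "231" = 4L,
                     EFO21 = 5L)

usable_rows <- function(features, parameters) {
  ok <- features$flag == "" | is.na(features$flag)
  for (p in parameters) ok <- ok & is.finite(features[[p]])
  ok
}

#' Fit the library of KDE probability functions
#'
#' Fits one [fit_probability_function()] per (protein, parameter, category)
#' cell of a feature table.  Rows flagged during feature extraction (e.g.
#' zero-cluster images) are excluded.
#'
#' @param features feature table from [feature_table()] with `protein` and
#'   `category` columns filled.
#' @param parameters parameter columns to model (default the standard five;
#'   columns that are entirely `NA` — e.g. `ssim` when no dictionary was
#'   used — are dropped with a message).
#' @param seed integer seed (cross-validation folds).
#' @param ... passed to [fit_probability_function()].
#' @return An object of class `category_library` with fields `table`
#'   (nested protein -> parameter -> category list), `proteins`,
#'   `parameters`, `categories`, `M`.
#' @export
fit_category_library <- function(features, parameters = platelet_parameters,
                                 seed = 1L, ...) {
  if (!all(c("protein", "category") %in% names(features)))
    stopf("'features' needs protein and category columns")
  keep_par <- vapply(parameters, function(p)
    any(is.finite(features[[p]])), logical(1))
  if (!all(keep_par))
    message("dropping all-NA parameter(s): ",
            paste(parameters[!keep_par], collapse = ", "))
  parameters <- parameters[keep_par]
  ok <- usable_rows(features, parameters)
  feats <- features[ok, , drop = FALSE]
  proteins <- sort(unique(as.character(feats$protein)))
  categories <- sort(unique(as.integer(feats$category)))
  if (length(categories) < 2L) stopf("need at least 2 categories")
  tab <- list()
  for (pr in proteins) {
    tab[[pr]] <- list()
    for (pa in parameters) {
      tab[[pr]][[pa]] <- list()
      cell_values <- lapply(categories, function(m) {
        vals <- feats[[pa]][feats$protein == pr & feats$category == m]
        if (length(vals) < 10L)
          stopf("fewer than 10 usable values for (%s, %s, category %d)",
                pr, pa, m)
        vals
      })
      cell_seeds <- vapply(categories, function(m)
        derive_seed(seed, 100L * m + match(pa, parameters)), integer(1))
      # pass 1: per-category cross-validated bandwidths and density
      # supports.  The final functions share one bandwidth (geometric mean
      # of the per-category choices) and one bin grid (union of supports):
      # the p-score compares binned probabilities across categories, which
      # is only fair when all categories are smoothed and binned alike.
      fits <- mapply(function(vals, sd_) {
        pf <- fit_probability_function(vals, seed = sd_,
                                       parameter_name = pa, ...)
        list(bw = pf$bandwidth, degenerate = pf$degenerate,
             rng = range(pf$bin_edges))
      }, cell_values, cell_seeds, SIMPLIFY = FALSE)
      ok_fit <- !vapply(fits, `[[`, logical(1), "degenerate")
      bw_common <- exp(mean(log(vapply(fits[ok_fit], `[[`, numeric(1),
                                       "bw"))))
      rng <- c(min(vapply(fits, function(f) f$rng[1L], numeric(1))),
               max(vapply(fits, function(f) f$rng[2L], numeric(1))))
      for (i in seq_along(categories)) {
        tab[[pr]][[pa]][[as.character(categories[i])]] <-
          if (fits[[i]]$degenerate) {
            fit_probability_function(cell_values[[i]], seed = cell_seeds[i],
                                     parameter_name = pa, ...)
          } else {
            fit_probability_function(cell_values[[i]], seed = cell_seeds[i],
                                     bin_range = rng,
                                     bandwidth = bw_common,
                                     parameter_name = pa, ...)
          }
      }
    }
  }
  structure(list(table = tab, proteins = proteins, parameters = parameters,
                 categories = categories, M = length(categories)),
            class = "category_library")
}

#' @export
print.category_library <- function(x, ...) {
  cat(sprintf("<category_library> %d proteins x %d parameters x %d categories\n",
              length(x$proteins), length(x$parameters), x$M))
  invisible(x)
}

library_pf <- function(library, protein, parameter, category) {
  pf <- library$table[[protein]][[parameter]][[as.character(category)]]
  if (is.null(pf))
    stopf("library has no probability function for (%s, %s, category %s)",
          protein, parameter, category)
  pf
}
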