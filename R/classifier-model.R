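#' Fit the set-level platelet classifier
#'
#' The central fitting function of the package: from a per-platelet feature
#' table it builds (i) the library of KDE probability functions for every
#' (protein, parameter, category) combination and (ii) the bootstrap
#' classification matrix of every protein, and — when several proteins are
#' present — (iii) the combined multi-protein classification matrix.  The
#' result is a classed model object with `print`, `summary`, `predict` and
#' `plot` methods.
#'
#' As in the underlying study design, the probability library and the
#' matrices are estimated from the same pool of platelets that is later
#' resampled for classification; pass `holdout = TRUE` to fit the library on
#' one half of each (protein, category) cell and the matrices on the other
#' half for a stricter split-sample evaluation.
#'
#' @param features per-platelet feature table (see [feature_table()]) with
#'   `protein` and `category` columns filled.
#' @param set_size platelets per classified set (default 10).
#' @param n_rounds bootstrap rounds per matrix column (default 1000).
#' @param seed integer master seed; every stochastic stage derives its own
#'   seed from it.
#' @param parameters parameter columns to use.
#' @param holdout logical; split-sample fitting (see Details).
#' @param combined logical; also fit the all-protein combined matrix.
#' @param ... passed to [fit_probability_function()] (binning, bandwidth
#'   grid, folds).
#' @return An object of class `platelet_classifier` with components
#'   `library`, `matrices` (named per-protein list), `combined_matrix`
#'   (or `NULL`), `features`, and the call settings.
#' @examples
#' \donttest{
#' specs <- list("1" = cluster_population(5), "2" = cluster_population(15))
#' imgs <- simulate_category_ensemble(specs, 40, seed = 3, protein = "SIM")
#' feats <- feature_table(imgs)
#' fit <- platelet_classifier(feats, n_rounds = 50, seed = 3)
#' fit
#' }
#' @export
platelet_classifier <- function(features, set_size = 10L, n_rounds = 1000L,
                                seed = 1L, parameters = platelet_parameters,
                                holdout = FALSE, combined = TRUE, ...) {
  features$protein <- as.character(features$protein)
  features$category <- as.integer(features$category)
  fit_pool <- features
  eval_pool <- features
  if (holdout) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, 3L))
    half <- rep(FALSE, nrow(features))
    for (pr in unique(features$protein))
      for (m in unique(features$category)) {
        idx <- which(features$protein == pr & features$category == m)
        half[sample(idx, floor(length(idx) / 2))] <- TRUE
      }
    fit_pool <- features[half, , drop = FALSE]
    eval_pool <- features[!half, , drop = FALSE]
  }
  lib <- fit_category_library(fit_pool, parameters = parameters,
                              seed = derive_seed(seed, 1L), ...)
  mats <- list()
  for (pr in lib$proteins)
    mats[[pr]] <- bootstrap_matrix(eval_pool, lib, pr, set_size = set_size,
                                   n_rounds = n_rounds,
                                   seed = derive_seed(seed,
                                     10L + match(pr, lib$proteins)))
  comb <- NULL
  if (combined && length(lib$proteins) > 1L)
    comb <- bootstrap_combined_matrix(eval_pool, lib, mats, lib$proteins,
                                      set_size = set_size,
                                      n_rounds = n_rounds,
                                      seed = derive_seed(seed, 99L))
  structure(list(library = lib, matrices = mats, combined_matrix = comb,
                 features = eval_pool, set_size = set_size,
                 n_rounds = n_rounds, seed = seed, holdout = holdout),
            class = "platelet_classifier")
}

#' @export
print.platelet_classifier <- function(x, ...) {
  lib <- x$library
  cat(sprintf("Platelet set classifier (sets of %d, %d bootstrap rounds)\n",
              x$set_size, x$n_rounds))
  cat(sprintf("  proteins:   %s\n", paste(lib$proteins, collapse = ", ")))
  cat(sprintf("  categories: %s\n", paste(lib$categories, collapse = ", ")))
  cat(sprintf("  parameters: %s\n", paste(lib$parameters, collapse = ", ")))
  diag_of <- function(m) mean(diag(m$P))
  for (pr in names(x$matrices))
    cat(sprintf("  %-10s mean diagonal %.3f\n", pr, diag_of(x$matrices[[pr]])))
  if (!is.null(x$combined_matrix))
    cat(sprintf("  combined   mean diagonal %.3f\n",
                diag_of(x$combined_matrix)))
  invisible(x)
}

#' @export
summary.platelet_classifier <- function(object, ...) {
  out <- list(per_protein = lapply(object$matrices, `[[`, "P"),
              combined = if (!is.null(object$combined_matrix))
                object$combined_matrix$P else NULL,
              bandwidths = sapply(object$library$proteins, function(pr)
                sapply(object$library$parameters, function(pa)
                  sapply(as.character(object$library$categories), function(m)
                    library_pf(object$library, pr, pa, m)$bandwidth))),
              set_size = object$set_size, n_rounds = object$n_rounds)
  class(out) <- "summary.platelet_classifier"
  out
}

#' @export
print.summary.platelet_classifier <- function(x, digits = 3, ...) {
  for (pr in names(x$per_protein)) {
    cat(sprintf("Classification matrix — %s (columns: true category):\n", pr))
    print(round(x$per_protein[[pr]], digits))
  }
  if (!is.null(x$combined)) {
    cat("Combined classification matrix:\n")
    print(round(x$combined, digits))
  }
  invisible(x)
}

#' Classify new platelet sets with a fitted classifier
#'
#' `newdata` is a feature table of one platelet set per protein (grouped by
#' the `protein` column).  A single-protein table is classified by its
#' p-score; a multi-protein table via the combined probability.
#'
#' @param object a fitted [platelet_classifier].
#' @param newdata feature rows of the set(s) to classify.
#' @param type `"category"` for the decided code, `"prob"` for the full
#'   per-category probability vector.
#' @param ... unused.
#' @return Decided category code, or a named probability vector.
#' @export
predict.platelet_classifier <- function(object, newdata,
                                        type = c("category", "prob"), ...) {
  type <- match.arg(type)
  prots <- unique(as.character(newdata$protein))
  if (length(prots) == 1L) {
    ps <- p_score(newdata, object$library, prots)
    if (type == "category") return(ps$category)
    return(ps$p)
  }
  sets <- split(newdata, as.character(newdata$protein))
  res <- classify_combined(sets, object$library, object$matrices,
                           proteins_used = prots)
  if (type == "category") res$decided_category else res$psi
}

#' Plot a fitted platelet classifier
#'
#' Draws the per-protein (and combined) classification matrices as shaded
#' probability grids, diagonal = correct classification.
#'
#' @param x a [platelet_classifier].
#' @param which `"matrices"` (default) or a protein name.
#' @param ... unused.
#' @export
plot.platelet_classifier <- function(x, which = "matrices", ...) {
  mats <- x$matrices
  if (!is.null(x$combined_matrix)) mats$combined <- x$combined_matrix
  if (which != "matrices") mats <- mats[which]
  old_par <- graphics::par(mfrow = c(1, length(mats)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old_par))
  for (nm in names(mats)) {
    P <- mats[[nm]]$P
    M <- ncol(P)
    graphics::image(seq_len(M), seq_len(M), t(P[rev(seq_len(M)), ]),
                    zlim = c(0, 1), col = grDevices::hcl.colors(32, "Blues",
                                                                rev = TRUE),
                    xlab = "true category", ylab = "assigned category",
                    main = nm, axes = FALSE)
    graphics::axis(1, at = seq_len(M), labels = mats[[nm]]$categories)
    graphics::axis(2, at = seq_len(M), labels = rev(mats[[nm]]$categories))
    for (i in seq_len(M)) for (j in seq_len(M))
      graphics::text(j, M + 1 - i, sprintf("%.2f", P[i, j]), cex = 0.8)
  }
  invisible(x)
}
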