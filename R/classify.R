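#' Probability score of a platelet set for each category
#'
#' For a set of platelets imaged for one protein, sums the KDE bin
#' probabilities of all five parameters over all platelets of the set, per
#' candidate category, and normalizes the per-category sums across
#' categories into a probability-like score p.  The set is classified into
#' the category with the highest p-score (ties, which are improbable with
#' continuous scores, go to the lowest category code).
#'
#' @param features_set data frame of platelet feature rows (typically 10)
#'   from a single protein.
#' @param library a [fit_category_library()] result.
#' @param protein protein label to score under.
#' @return A list with `p` (named per-category scores summing to 1), `raw`
#'   (unnormalized sums) and `category` (the decided code).
#' @export
p_score <- function(features_set, library, protein) {
  if (!inherits(library, "category_library"))
    stopf("'library' must be a category_library")
  if (!protein %in% library$proteins)
    stopf("library has no protein '%s'", protein)
  raw <- vapply(library$categories, function(m) {
    tot <- 0
    for (pa in library$parameters) {
      pf <- library_pf(library, protein, pa, m)
      tot <- tot + sum(lookup_probability(pf, features_set[[pa]]))
    }
    tot
  }, numeric(1))
  names(raw) <- library$categories
  p <- raw / sum(raw)
  k <- library$categories[argmax_random_ties(p)]
  list(p = p, raw = raw, category = k)
}

# argmax with exact ties resolved uniformly at random (using the caller's
# RNG stream).  Ties cannot occur between distinct continuous scores, but
# they do occur exactly when several categories share identical probability
# functions; a deterministic tie-break would then fabricate a perfect
# classification of the lowest code out of indistinguishable categories.
argmax_random_ties <- function(x) {
  tol <- max(abs(x)) * 1e-12
  tied <- which(x >= max(x) - tol)
  if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
}

new_classification_matrix <- function(P, protein, categories, n_rounds,
                                      set_size) {
  dimnames(P) <- list(assigned = categories, true = categories)
  structure(list(P = P, protein = protein, categories = categories,
                 n_rounds = n_rounds, set_size = set_size),
            class = "classification_matrix")
}

#' @export
print.classification_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<classification_matrix> %s (%d rounds, sets of %d)\n",
              paste(x$protein, collapse = "+"), x$n_rounds, x$set_size))
  print(round(x$P, digits))
  invisible(x)
}

draw_set <- function(pool_idx, set_size) {
  pool_idx[sample.int(length(pool_idx), set_size)]
}

#' Bootstrap classification matrix for one protein
#'
#' Repeatedly draws random sets of `set_size` platelets of a known category
#' (without replacement within a round, independently across rounds),
#' classifies each set by its [p_score()], and tallies the decisions: entry
#' `P[k, m]` is the probability that a set of true category m is classified
#' as k.  Columns sum to 1.
#'
#' @param features feature table (pooled platelets with `protein` and
#'   `category` columns).
#' @param library a [fit_category_library()] result.
#' @param protein protein whose images are used.
#' @param set_size platelets per set (default 10).
#' @param n_rounds bootstrap rounds per true category (default 1000).
#' @param seed integer seed.
#' @return A `classification_matrix`.
#' @export
bootstrap_matrix <- function(features, library, protein, set_size = 10L,
                             n_rounds = 1000L, seed = 1L) {
  feats <- features[features$protein == protein &
                      usable_rows(features, library$parameters), ,
                    drop = FALSE]
  cats <- library$categories
  M <- length(cats)
  P <- matrix(0, M, M)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 7L))
  for (mi in seq_len(M)) {
    idx <- which(feats$category == cats[mi])
    if (length(idx) < set_size)
      stopf("category %d has only %d usable '%s' records (need %d)",
            cats[mi], length(idx), protein, set_size)
    for (r in seq_len(n_rounds)) {
      sel <- draw_set(idx, set_size)
      k <- p_score(feats[sel, , drop = FALSE], library, protein)$category
      ki <- match(k, cats)
      P[ki, mi] <- P[ki, mi] + 1
    }
  }
  new_classification_matrix(P / n_rounds, protein, cats, n_rounds, set_size)
}

matrix_entries <- function(matrices) {
  lapply(matrices, function(m) {
    if (inherits(m, "classification_matrix")) m else
      structure(list(P = m, n_rounds = NA_integer_,
                     categories = seq_len(ncol(m))),
                class = "classification_matrix")
  })
}

#' Combined multi-protein category probability
#'
#' Given the per-protein classifications `k_vector` of one multi-protein
#' platelet set and the per-protein classification matrices, the probability
#' that the set stems from category m is
#' `Psi_N(m | k) = prod_prot P[k_prot, m] / sum_m' prod_prot P[k_prot, m']`.
#' When every per-category product vanishes (a zero matrix cell annihilating
#' all candidates), zero entries are floored at `1/(2 n_rounds)` and the
#' ratio is recomputed, so a single empty bootstrap cell cannot erase the
#' evidence of the remaining proteins.
#'
#' @param k_vector integer vector of per-protein decided categories, in the
#'   same order as `matrices`.
#' @param matrices list of `classification_matrix` objects (or bare M x M
#'   matrices), one per protein.
#' @return Named numeric vector `Psi` over categories, summing to 1.
#' @export
combined_probability <- function(k_vector, matrices) {
  mats <- matrix_entries(matrices)
  if (length(k_vector) != length(mats))
    stopf("need one matrix per entry of k_vector")
  cats <- mats[[1L]]$categories
  M <- length(cats)
  for (m in mats)
    if (!identical(dim(m$P), c(M, M)))
      stopf("all matrices must be %d x %d", M, M)
  prod_for <- function(floor_zero) {
    out <- rep(1, M)
    for (i in seq_along(mats)) {
      ki <- match(k_vector[i], cats)
      if (is.na(ki)) stopf("k_vector entry %s is not a known category code",
                           k_vector[i])
      row <- mats[[i]]$P[ki, ]
      if (floor_zero) {
        fl <- if (is.finite(mats[[i]]$n_rounds) && mats[[i]]$n_rounds > 0)
          1 / (2 * mats[[i]]$n_rounds) else 1e-6
        row[row == 0] <- fl
      }
      out <- out * row
    }
    out
  }
  num <- prod_for(FALSE)
  if (sum(num) == 0) num <- prod_for(TRUE)
  psi <- num / sum(num)
  names(psi) <- cats
  psi
}

#' Classify a multi-protein platelet set
#'
#' Each protein's set of platelets is classified by its [p_score()], giving
#' the classification vector k; the combined probability
#' [combined_probability()] then decides the category.
#'
#' @param per_protein_sets named list mapping protein -> feature rows of its
#'   set.
#' @param library a [fit_category_library()] result.
#' @param matrices named list of per-protein `classification_matrix`
#'   objects.
#' @param proteins_used proteins to combine (default: names of
#'   `per_protein_sets`).
#' @return An object of class `combined_result`: `k_vector`, `psi`,
#'   `decided_category`.
#' @export
classify_combined <- function(per_protein_sets, library, matrices,
                              proteins_used = names(per_protein_sets)) {
  k_vec <- vapply(proteins_used, function(pr)
    p_score(per_protein_sets[[pr]], library, pr)$category, numeric(1))
  psi <- combined_probability(k_vec, matrices[proteins_used])
  cats <- library$categories
  structure(list(k_vector = k_vec, psi = psi,
                 decided_category = cats[argmax_random_ties(psi)]),
            class = "combined_result")
}

#' @export
print.combined_result <- function(x, ...) {
  cat("<combined_result> k = (", paste(x$k_vector, collapse = ", "),
      "), decided category ", x$decided_category, "\n", sep = "")
  invisible(x)
}

#' Bootstrap classification matrix for a protein combination
#'
#' As [bootstrap_matrix()], but each round draws one set of `set_size`
#' platelets per protein (so `N x set_size` platelets in total) and decides
#' via the combined probability.
#'
#' @inheritParams bootstrap_matrix
#' @param matrices named per-protein `classification_matrix` list.
#' @param proteins_used proteins to combine.
#' @return A `classification_matrix` whose `protein` field lists the
#'   combined proteins.
#' @export
bootstrap_combined_matrix <- function(features, library, matrices,
                                      proteins_used, set_size = 10L,
                                      n_rounds = 1000L, seed = 1L) {
  cats <- library$categories
  M <- length(cats)
  pools <- list()
  for (pr in proteins_used) {
    feats <- features[features$protein == pr &
                        usable_rows(features, library$parameters), ,
                      drop = FALSE]
    for (m in cats)
      if (sum(feats$category == m) < set_size)
        stopf("category %d has only %d usable '%s' records (need %d)",
              m, sum(feats$category == m), pr, set_size)
    pools[[pr]] <- feats
  }
  P <- matrix(0, M, M)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 13L))
  for (mi in seq_len(M)) {
    for (r in seq_len(n_rounds)) {
      k_vec <- vapply(proteins_used, function(pr) {
        feats <- pools[[pr]]
        idx <- which(feats$category == cats[mi])
        sel <- draw_set(idx, set_size)
        p_score(feats[sel, , drop = FALSE], library, pr)$category
      }, numeric(1))
      psi <- combined_probability(k_vec, matrices[proteins_used])
      ki <- argmax_random_ties(psi)
      P[ki, mi] <- P[ki, mi] + 1
    }
  }
  new_classification_matrix(P / n_rounds, proteins_used, cats, n_rounds,
                            set_size)
}

#' Search protein subsets by combined classification strength
#'
#' Evaluates [bootstrap_combined_matrix()] for every size-`n` subset of the
#' available proteins and ranks subsets by the sum of the diagonal elements
#' (total correct-classification probability).
#'
#' @inheritParams bootstrap_combined_matrix
#' @param n subset size.
#' @param n_rounds bootstrap rounds per subset (a reduced number keeps the
#'   exhaustive search tractable).
#' @return A list of results sorted best-first, each with `proteins`,
#'   `diag_sum` and `matrix`.
#' @export
protein_subset_search <- function(features, library, matrices, n,
                                  set_size = 10L, n_rounds = 200L,
                                  seed = 1L) {
  prots <- library$proteins
  if (n < 1L || n > length(prots))
    stopf("'n' must be between 1 and %d", length(prots))
  subsets <- utils::combn(prots, n, simplify = FALSE)
  res <- lapply(seq_along(subsets), function(i) {
    cm <- bootstrap_combined_matrix(features, library, matrices,
                                    subsets[[i]], set_size = set_size,
                                    n_rounds = n_rounds,
                                    seed = derive_seed(seed, i))
    list(proteins = subsets[[i]], diag_sum = sum(diag(cm$P)), matrix = cm)
  })
  res[order(vapply(res, `[[`, numeric(1), "diag_sum"), decreasing = TRUE)]
}
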