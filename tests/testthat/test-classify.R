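params4 <- c("n_clusters", "mean_cluster_area_um2", "m1_um", "m2_um2")

# library whose categories share identical entries: p-scores must tie at 1/M
identical_library <- function(M = 3L) {
  pf <- make_pf(seq(0, 10, length.out = 11), rep(0.1, 10))
  tab <- list(P1 = lapply(setNames(params4, params4), function(pa)
    setNames(rep(list(pf), M), as.character(seq_len(M)))))
  make_library(tab, seq_len(M), params4, "P1")
}

# category `hot` holds all its mass where the set's values live; the others
# put their mass elsewhere
dominant_library <- function(hot = 2L, M = 3L) {
  inside <- make_pf(c(0, 1), 1)
  outside <- make_pf(c(100, 101), 1)
  tab <- list(P1 = lapply(setNames(params4, params4), function(pa)
    setNames(lapply(seq_len(M), function(m)
      if (m == hot) inside else outside), as.character(seq_len(M)))))
  make_library(tab, seq_len(M), params4, "P1")
}

set_at <- function(value, n = 10L) {
  df <- synthetic_feature_table(list(c(0, 0, 0, 0)), n_per_cat = n)
  for (pa in params4) df[[pa]] <- rep(value, n)
  df
}

test_that("p-score is uniform for identical libraries and follows dominance", {
  lib <- identical_library()
  ps <- p_score(set_at(5), lib, "P1")
  expect_equal(unname(ps$p), rep(1 / 3, 3), tolerance = 1e-12)
  lib2 <- dominant_library(hot = 2L)
  ps2 <- p_score(set_at(0.5), lib2, "P1")
  expect_gt(ps2$p[["2"]], 0.99)
  expect_equal(ps2$category, 2L)
})

test_that("p-score equals a hand-enumerated double-sum oracle", {
  # M = 3 categories, 2 bins per function, fixed small set
  probs <- list("1" = c(0.3, 0.7), "2" = c(0.9, 0.1), "3" = c(0.5, 0.5))
  tab <- list(P1 = lapply(setNames(params4, params4), function(pa)
    lapply(probs, function(p) make_pf(c(0, 1, 2), p))))
  lib <- make_library(tab, 1:3, params4, "P1")
  df <- set_at(0, n = 4L)
  vals <- c(0.5, 1.5, 0.5, 0.5)  # bins 1, 2, 1, 1
  for (pa in params4) df[[pa]] <- vals
  ps <- p_score(df, lib, "P1")
  raw_oracle <- vapply(probs, function(p)
    length(params4) * (3 * p[1L] + 1 * p[2L]), numeric(1))
  expect_lt(max(abs(ps$raw - raw_oracle)), 1e-12)
  expect_lt(max(abs(ps$p - raw_oracle / sum(raw_oracle))), 1e-12)
})

test_that("bootstrap matrices are column-stochastic, deterministic and separate perfectly separable categories", {
  feats <- synthetic_feature_table(list(c(0, 0, 0, 0), c(50, 50, 50, 50),
                                        c(-50, -50, -50, -50)),
                                   n_per_cat = 20, sd_ = 0.5, seed = 9)
  lib <- suppressMessages(fit_category_library(feats, seed = 2))
  M1 <- bootstrap_matrix(feats, lib, "P1", n_rounds = 100, seed = 5)
  M2 <- bootstrap_matrix(feats, lib, "P1", n_rounds = 100, seed = 5)
  expect_identical(M1$P, M2$P)
  expect_equal(colSums(M1$P), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(diag(M1$P)), rep(1, 3))
  expect_error(bootstrap_matrix(feats[1:25, ], lib, "P1", n_rounds = 10,
                                seed = 1), "usable")
})

test_that("indistinguishable categories with shared library entries give uniform columns", {
  feats <- synthetic_feature_table(list(c(5, 5, 5, 5), c(5, 5, 5, 5),
                                        c(5, 5, 5, 5)),
                                   n_per_cat = 40, seed = 10)
  lib <- suppressMessages(fit_category_library(feats, seed = 3))
  for (pa in lib$parameters) for (m in c("2", "3"))
    lib$table$P1[[pa]][[m]] <- lib$table$P1[[pa]][["1"]]
  M <- bootstrap_matrix(feats, lib, "P1", n_rounds = 1000, seed = 6)
  expect_lt(max(abs(M$P - 1 / 3)), 0.08)
})

test_that("the combined probability reproduces closed forms and the hand example", {
  I3 <- diag(3)
  psi <- combined_probability(2, list(I3))
  expect_equal(unname(psi), c(0, 1, 0))
  U <- matrix(1 / 3, 3, 3)
  psi_u <- combined_probability(c(1, 2), list(U, U))
  expect_equal(unname(psi_u), rep(1 / 3, 3), tolerance = 1e-12)
  P1 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2)
  P2 <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2)
  psi_h <- combined_probability(c(1, 1), list(P1, P2))
  expect_equal(unname(psi_h[1L]), (0.9 * 0.7) / (0.9 * 0.7 + 0.2 * 0.4),
               tolerance = 1e-12)
})

test_that("the combined probability matches a direct-formula oracle and sums to one", {
  for (s in 1:200) {
    set.seed(s)
    M <- sample(2:4, 1); N <- sample(1:3, 1)
    mats <- lapply(seq_len(N), function(i) {
      P <- matrix(runif(M * M, 0.05, 1), M, M)
      sweep(P, 2L, colSums(P), "/")
    })
    k <- sample(seq_len(M), N, replace = TRUE)
    psi <- combined_probability(k, mats)
    expect_lt(abs(sum(psi) - 1), 1e-12)
    oracle <- numeric(M)
    for (m in seq_len(M)) {
      pr <- 1
      for (i in seq_len(N)) pr <- pr * mats[[i]][k[i], m]
      oracle[m] <- pr
    }
    oracle <- oracle / sum(oracle)
    expect_lt(max(abs(psi - oracle)), 1e-12)
  }
})

test_that("combined probability is equivariant under category relabeling", {
  set.seed(60)
  M <- 3
  mats <- lapply(1:2, function(i) {
    P <- matrix(runif(M * M, 0.05, 1), M, M)
    sweep(P, 2L, colSums(P), "/")
  })
  k <- c(2, 1)
  psi <- combined_probability(k, mats)
  perm <- c(3, 1, 2)  # new = position of old code
  mats_p <- lapply(mats, function(P) P[perm, perm])
  k_p <- match(k, perm)
  psi_p <- combined_probability(k_p, mats_p)
  expect_equal(unname(psi_p), unname(psi[perm]), tolerance = 1e-12)
})

test_that("zero matrix cells cannot annihilate the combined probability", {
  P1 <- diag(3)                      # column 2 has a zero in row 1
  P2 <- matrix(1 / 3, 3, 3)
  # k = (1, 1): without flooring all products vanish except category 1;
  # with k = (2, 1) categories other than 2 are zero via P1 only
  psi <- combined_probability(c(2, 1), list(P1, P2))
  expect_equal(unname(psi), c(0, 1, 0))
  # all products zero: flooring kicks in and yields a proper distribution
  P3 <- matrix(c(0, 1, 1, 0), 2, 2)
  P4 <- matrix(c(1, 0, 0, 1), 2, 2)
  psi2 <- combined_probability(c(1, 1), list(P3, P4))
  expect_lt(abs(sum(psi2) - 1), 1e-12)
  expect_true(all(psi2 > 0))
})

test_that("multi-protein classification follows the informative protein", {
  feats2 <- rbind(
    synthetic_feature_table(list(c(0, 0, 0, 0), c(40, 40, 40, 40)),
                            n_per_cat = 20, protein = "A", sd_ = 0.5,
                            seed = 11),
    synthetic_feature_table(list(c(5, 5, 5, 5), c(5, 5, 5, 5)),
                            n_per_cat = 20, protein = "B", seed = 12))
  lib <- suppressMessages(fit_category_library(feats2, seed = 4))
  near_diag <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  uniform <- matrix(0.5, 2, 2)
  mats <- list(A = near_diag, B = uniform)
  sets <- list(A = feats2[feats2$protein == "A" & feats2$category == 2, ][1:10, ],
               B = feats2[feats2$protein == "B" & feats2$category == 1, ][1:10, ])
  res <- classify_combined(sets, lib, mats)
  expect_equal(res$k_vector[["A"]], 2)
  expect_equal(res$decided_category, 2L)
  # single protein: reduction to the p-score decision
  res1 <- classify_combined(sets["A"], lib, mats["A"])
  expect_equal(res1$decided_category,
               p_score(sets$A, lib, "A")$category)
})

test_that("combined bootstrap matrices and subset search behave on planted informativeness", {
  feats <- rbind(
    synthetic_feature_table(list(c(0, 0, 0, 0), c(30, 30, 30, 30)),
                            n_per_cat = 20, protein = "A", sd_ = 1, seed = 13),
    synthetic_feature_table(list(c(0, 0, 0, 0), c(30, 30, 30, 30)),
                            n_per_cat = 20, protein = "B", sd_ = 1, seed = 14),
    synthetic_feature_table(list(c(5, 5, 5, 5), c(5, 5, 5, 5)),
                            n_per_cat = 20, protein = "C", seed = 15))
  lib <- suppressMessages(fit_category_library(feats, seed = 5))
  mats <- lapply(setNames(lib$proteins, lib$proteins), function(pr)
    bootstrap_matrix(feats, lib, pr, n_rounds = 50, seed = 16))
  cm1 <- bootstrap_combined_matrix(feats, lib, mats, c("A", "B"),
                                   n_rounds = 50, seed = 17)
  cm2 <- bootstrap_combined_matrix(feats, lib, mats, c("A", "B"),
                                   n_rounds = 50, seed = 17)
  expect_identical(cm1$P, cm2$P)
  expect_equal(colSums(cm1$P), rep(1, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(diag(cm1$P)), rep(1, 2))
  rk <- protein_subset_search(feats, lib, mats, n = 2, n_rounds = 30,
                              seed = 18)
  expect_length(rk, 3L)
  expect_equal(sort(rk[[1L]]$proteins), c("A", "B"))
  # n = 1 ranking reproduces the single-protein diagonal ordering
  rk1 <- protein_subset_search(feats, lib, mats, n = 1, n_rounds = 30,
                               seed = 19)
  expect_equal(rk1[[1L]]$proteins %in% c("A", "B"), TRUE)
  expect_error(protein_subset_search(feats, lib, mats, n = 9), "between")
})

test_that("the fitted classifier model exposes methods and predicts new sets", {
  feats <- synthetic_feature_table(list(c(0, 0, 0, 0), c(30, 30, 30, 30)),
                                   n_per_cat = 25, sd_ = 1, seed = 20)
  fit <- suppressMessages(platelet_classifier(feats, n_rounds = 40,
                                              seed = 21))
  expect_s3_class(fit, "platelet_classifier")
  expect_output(print(fit), "Platelet set classifier")
  sm <- summary(fit)
  expect_equal(dim(sm$per_protein$P1), c(2L, 2L))
  newset <- synthetic_feature_table(list(c(30, 30, 30, 30)), n_per_cat = 10,
                                    sd_ = 1, seed = 22)
  newset$category <- NA_integer_
  expect_equal(predict(fit, newset), 2L)
  pr <- predict(fit, newset, type = "prob")
  expect_lt(abs(sum(pr) - 1), 1e-9)
  # holdout mode fits and evaluates on disjoint halves
  fit2 <- suppressMessages(platelet_classifier(feats, n_rounds = 20,
                                               seed = 23, holdout = TRUE))
  expect_equal(nrow(fit2$features), 26L)
})
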