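test_that("zero-cluster populations give background-only images with empty truth", {
  pop <- cluster_population(n_clusters_mean = 0)
  img <- small_imaging()
  im <- simulate_platelet(pop, img, seed = 1, noise = FALSE)
  expect_equal(nrow(im$ground_truth), 0L)
  expect_true(all(im$pixels == img$background))
})

test_that("identical specs and seed give bit-identical images", {
  pop <- cluster_population(n_clusters_mean = 12)
  img <- small_imaging()
  a <- simulate_platelet(pop, img, seed = 77)
  b <- simulate_platelet(pop, img, seed = 77)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("planted clusters are recovered by thresholding and labeling", {
  im <- simulate_platelet(recovery_pop(8L), recovery_imaging(), seed = 3,
                          noise = FALSE, allow_overlap = FALSE)
  cmap <- label_clusters(im, otsu_threshold(im))
  expect_equal(length(cmap$areas_px), 8L)
  # brute-force nearest matching of centroids to planted truth, within 1 px
  centre_nm <- (recovery_imaging()$image_size_px - 1) * 20 / 2
  tx <- (im$ground_truth$center_x_nm + centre_nm) / 20
  ty <- (im$ground_truth$center_y_nm + centre_nm) / 20
  for (i in seq_len(8L)) {
    d <- sqrt((cmap$centroids_px[, "x"] - tx[i])^2 +
              (cmap$centroids_px[, "y"] - ty[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("cluster centres always lie inside the platelet disc", {
  for (s in 1:20) {
    pop <- cluster_population(n_clusters_mean = 15, radial_bias = 0.8,
                              platelet_radius_nm = 1500)
    im <- simulate_platelet(pop, small_imaging(), seed = s, noise = FALSE)
    tr <- im$ground_truth
    if (nrow(tr) == 0L) next
    expect_true(all(sqrt(tr$center_x_nm^2 + tr$center_y_nm^2) <= 1500))
  }
})

test_that("training sets derive child seeds deterministically", {
  pop <- cluster_population(n_clusters_mean = 6)
  img <- small_imaging()
  one <- simulate_training_set(pop, img, n_images = 1, seed = 9)
  expect_identical(one[[1L]]$pixels,
                   simulate_platelet(pop, img,
                                     seed = plateletNano:::derive_seed(9, 1))$pixels)
  a <- simulate_training_set(pop, img, n_images = 20, seed = 5)
  b <- simulate_training_set(pop, img, n_images = 20, seed = 5)
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
  expect_error(simulate_training_set(pop, img, n_images = 0, seed = 1),
               "n_images")
})

test_that("planted cluster counts follow the requested Poisson mean", {
  pop <- cluster_population(n_clusters_mean = 10, n_clusters_dispersion = 1)
  imgs <- simulate_training_set(pop, small_imaging(), n_images = 1000,
                                seed = 123, noise = FALSE)
  counts <- vapply(imgs, function(im) nrow(im$ground_truth), numeric(1))
  expect_lt(abs(mean(counts) - 10), 0.3)
})

test_that("category ensembles carry labels and balanced sizes", {
  specs <- list("1" = cluster_population(5), "2" = cluster_population(10),
                "3" = cluster_population(20))
  specs <- lapply(specs, function(p) list(pop = p, img = small_imaging()))
  ens <- simulate_category_ensemble(specs, n_per_category = 50, seed = 2,
                                    protein = "SIM")
  expect_length(ens, 150L)
  cats <- vapply(ens, `[[`, integer(1), "category")
  expect_equal(as.vector(table(cats)), rep(50L, 3L))
  expect_error(simulate_category_ensemble(specs[1L], 10, seed = 1),
               "2 categories")
})

test_that("increasing radial bias shifts planted clusters outward", {
  mean_r <- vapply(c(-0.8, 0, 0.8), function(bias) {
    pop <- cluster_population(n_clusters_mean = 10, radial_bias = bias)
    imgs <- simulate_training_set(pop, small_imaging(), n_images = 500,
                                  seed = 11, noise = FALSE)
    r <- unlist(lapply(imgs, function(im)
      sqrt(im$ground_truth$center_x_nm^2 + im$ground_truth$center_y_nm^2)))
    mean(r)
  }, numeric(1))
  expect_lt(mean_r[1L], mean_r[2L])
  expect_lt(mean_r[2L], mean_r[3L])
})

test_that("well-separated cluster-count categories give separable N_C distributions", {
  img <- recovery_imaging()
  specs <- list("1" = list(pop = cluster_population(5, platelet_radius_nm = 1300),
                           img = img),
                "2" = list(pop = cluster_population(20, platelet_radius_nm = 1300),
                           img = img))
  ens <- simulate_category_ensemble(specs, n_per_category = 30, seed = 8,
                                    protein = "SIM", noise = FALSE)
  feats <- feature_table(ens)
  lib <- suppressMessages(fit_category_library(feats, seed = 1))
  pf1 <- lib$table$SIM$n_clusters[["1"]]
  pf2 <- lib$table$SIM$n_clusters[["2"]]
  overlap <- sum(pmin(pf1$bin_probs, pf2$bin_probs))
  expect_lt(overlap, 0.2)
})

test_that("invalid generator specs are rejected", {
  expect_error(cluster_population(n_clusters_mean = -1), "n_clusters_mean")
  expect_error(cluster_population(radial_bias = 2), "radial_bias")
  expect_error(imaging_spec(pixel_size_nm = 0), "pixel_size_nm")
  expect_error(simulate_platelet(cluster_population(platelet_radius_nm = 4000),
                                 small_imaging(), seed = 1),
               "cannot contain")
})

test_that("TIFF round trip preserves pixels, pixel size and ground truth", {
  im <- simulate_platelet(recovery_pop(4L), recovery_imaging(), seed = 2,
                          noise = FALSE, protein = "VAMP8", category = 3L)
  path <- file.path(tempdir(), "platelet-roundtrip.tif")
  write_platelet_tiff(im, path)
  back <- read_platelet_tiff(path)
  expect_equal(back$pixels, im$pixels, tolerance = 1e-6)
  expect_equal(back$pixel_size_nm, 20)
  expect_equal(back$protein, "VAMP8")
  expect_equal(back$category, 3L)
  expect_equal(back$ground_truth$radius_nm, im$ground_truth$radius_nm,
               tolerance = 1e-9)
  unlink(paste0(path, c("", ".meta.json", ".truth.json")))
})
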