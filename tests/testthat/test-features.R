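test_that("Otsu threshold separates bimodal intensities", {
  x <- matrix(c(rep(0, 60), rep(100, 40)), 10, 10)
  thr <- otsu_threshold(x)
  expect_gt(thr, 0); expect_lt(thr, 100)
  set.seed(1)
  v <- c(rnorm(500, 20, 5), rnorm(500, 200, 5))
  thr2 <- otsu_threshold(matrix(v, 25, 40))
  expect_gt(thr2, 60); expect_lt(thr2, 160)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

test_that("Otsu threshold attains the exhaustive-search between-class variance", {
  bcv_of <- function(v, t) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (length(lo) == 0L || length(hi) == 0L) return(-Inf)
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }
  for (s in 1:10) {
    set.seed(s)
    v <- c(rlnorm(300, 0, 0.4), rnorm(120, 30, 4))
    ours <- otsu_threshold(matrix(v, 20, 21))
    oracle <- otsu_oracle(v)
    expect_gte(bcv_of(v, ours), bcv_of(v, oracle) * (1 - 1e-3))
  }
})

test_that("labeling uses 8-connectivity (corner-touching squares merge)", {
  m <- matrix(0, 8, 8)
  m[2:4, 2:4] <- 1; m[5:7, 5:7] <- 1
  cmap <- label_clusters(m, 0.5)
  expect_equal(length(cmap$areas_px), 1L)
  expect_equal(cmap$areas_px, 18L)
  empty <- label_clusters(matrix(0, 5, 5), 0.5)
  expect_equal(length(empty$areas_px), 0L)
})

test_that("labeling agrees with an independent flood-fill oracle", {
  for (s in 1:100) {
    set.seed(s)
    mask <- matrix(runif(400) < 0.35, 20, 20)
    cmap <- label_clusters(mask * 1, 0.5)
    oracle <- floodfill_components(mask)
    expect_equal(length(cmap$areas_px), oracle$n)
    expect_equal(sort(cmap$areas_px), oracle$areas)
  }
})

test_that("cluster statistics follow the ROI definition", {
  # single 10x10 cluster at image centre, 20 nm pixels
  x <- matrix(0, 100, 100); x[46:55, 46:55] <- 10
  cs <- cluster_stats(label_clusters(x, 5), pixel_size_nm = 20)
  expect_equal(cs$n_clusters, 1L)
  expect_equal(cs$mean_cluster_area_um2, 100 * 0.02^2)
  # a dominant central cluster and a tiny one ~2.5 um from the mask
  # centroid: only the inner one lies within the 1.6 um ROI
  y <- matrix(0, 300, 300)
  y[146:155, 146:155] <- 10              # 100 px cluster pinning the centroid
  y[151, 276] <- 10                      # 1 px cluster ~2.5 um away
  cs2 <- cluster_stats(label_clusters(y, 5), pixel_size_nm = 20)
  expect_equal(cs2$n_clusters, 1L)
  expect_equal(cs2$mean_cluster_area_um2, 100 * 0.02^2)
  # empty map: flagged sentinel
  cs3 <- cluster_stats(label_clusters(matrix(0, 5, 5), 1), 20)
  expect_true(cs3$empty)
  expect_equal(cs3$n_clusters, 0L)
  expect_true(is.na(cs3$mean_cluster_area_um2))
})

test_that("radial profiles bin cluster centroids by distance", {
  x <- matrix(0, 60, 60); x[30:31, 34:35] <- 10   # ~0.1 um from (29.5,29.5) at 20nm
  cmap <- label_clusters(x, 5)
  prof <- radial_profile(cmap, c(29.5, 29.5), 20)
  expect_equal(prof$counts[1L], 1L)
  expect_equal(sum(prof$counts), 1L)
  expect_equal(prof$normalized[1L], 1)
  # zero clusters: sentinel profile, moments refuse
  p0 <- radial_profile(label_clusters(matrix(0, 5, 5), 1), c(2, 2), 20)
  expect_true(all(is.na(p0$normalized)))
  expect_error(radial_moments(p0), "normalized")
})

test_that("radial profile matches a brute-force distance binning oracle", {
  for (s in 1:50) {
    set.seed(s)
    k <- sample(3:25, 1)
    # place k tiny clusters at random positions on a 150x150 20nm grid
    x <- matrix(0, 150, 150)
    px <- sample(5:145, k); py <- sample(5:145, k)
    # reject coincident/adjacent placements for a clean count
    if (any(dist(cbind(px, py)) < 3)) next
    for (i in seq_len(k)) x[py[i] + 1L, px[i] + 1L] <- 10
    cmap <- label_clusters(x, 5)
    centre <- c(75, 75)
    prof <- radial_profile(cmap, centre, 20)
    d_um <- sqrt((px - centre[1L])^2 + (py - centre[2L])^2) * 0.02
    zone <- pmax(ceiling(d_um / 0.25), 1)
    oracle <- tabulate(zone[zone <= 10], 10)
    expect_equal(prof$counts, oracle)
    expect_equal(prof$n_outside, sum(zone > 10))
  }
})

test_that("radial moments reproduce closed-form and direct-summation values", {
  prof1 <- structure(list(zone_outer_radii_um = seq(0.25, 2.5, by = 0.25),
                          counts = c(5L, rep(0L, 9L)),
                          normalized = c(1, rep(0, 9)), n_outside = 0L),
                     class = "radial_profile")
  m <- radial_moments(prof1)
  expect_identical(m$m1_um, 0.25)
  expect_identical(m$m2_um2, 0.0625)
  prof2 <- prof1
  prof2$normalized <- c(0.5, 0, 0.5, rep(0, 7))
  m2 <- radial_moments(prof2)
  expect_equal(m2$m1_um, 0.5)
  expect_equal(m2$m2_um2, 0.3125)
  # random normalized profiles vs independent summation, and m2 >= m1^2
  r <- seq(0.25, 2.5, by = 0.25)
  for (s in 1:200) {
    set.seed(s)
    w <- rexp(10); w <- w / sum(w)
    p <- prof1; p$normalized <- w
    mm <- radial_moments(p)
    expect_lt(abs(mm$m1_um - sum(r * w)), 1e-12)
    expect_lt(abs(mm$m2_um2 - sum(r^2 * w)), 1e-12)
    expect_gte(mm$m2_um2, mm$m1_um^2 - 1e-12)
  }
})

test_that("feature extraction flags degenerate images instead of failing", {
  flat <- platelet_image(matrix(2, 64, 64), 20)
  row <- platelet_features(flat)
  expect_equal(row$flag, "constant_image")
  noise_only <- simulate_platelet(cluster_population(0), recovery_imaging(),
                                  seed = 1, noise = FALSE)
  # zero-signal noise-free image is constant -> flagged, not an error
  expect_true(platelet_features(noise_only)$flag != "")
})

test_that("features are deterministic and invariant to shifts and rotations", {
  im <- simulate_platelet(recovery_pop(6L), recovery_imaging(), seed = 12,
                          noise = FALSE, allow_overlap = FALSE)
  f1 <- platelet_features(im)
  f2 <- platelet_features(im)
  expect_identical(f1[platelet_parameters], f2[platelet_parameters])
  # whole-pixel translation (clusters stay in bounds and in ROI)
  shifted <- matrix(0, 200, 200)
  shifted[11:200, 11:200] <- im$pixels[1:190, 1:190]
  fs <- platelet_features(platelet_image(shifted, 20))
  # 90 degree rotation
  rot <- t(im$pixels)[, rev(seq_len(200))]
  fr <- platelet_features(platelet_image(rot, 20))
  for (col in c("n_clusters", "mean_cluster_area_um2", "m1_um", "m2_um2")) {
    expect_equal(fs[[col]], f1[[col]], tolerance = 1e-9)
    expect_equal(fr[[col]], f1[[col]], tolerance = 1e-9)
  }
})
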