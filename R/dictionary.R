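# Sparse patch dictionary: MOD-style alternating minimisation with batch
# orthogonal matching pursuit for the sparse-coding step.  The dictionary is
# trained on simulated platelet images only; its purpose is not a good
# generic image model but a *limited* one, whose varying inability to
# reconstruct images of different platelet categories is itself the signal.

# --- batch OMP ---------------------------------------------------------------
# X: d x n matrix of (mean-subtracted) patch columns; D: d x k unit-norm
# atoms.  Returns a k x n coefficient matrix with <= sparsity nonzeros per
# column.  Greedy selection on the Gram matrix; per-column least squares on
# the selected support after each selection, so residual norms are
# non-increasing in the sparsity level.
omp_encode <- function(X, D, sparsity) {
  d <- nrow(D); k <- ncol(D); n <- ncol(X)
  sparsity <- min(sparsity, k)
  G <- crossprod(D)                 # k x k
  B <- crossprod(D, X)              # k x n, atom-signal correlations
  A <- matrix(0, k, n)
  support <- matrix(0L, sparsity, n)
  coef <- matrix(0, sparsity, n)
  corr <- B
  active <- rep(TRUE, n)
  for (t in seq_len(sparsity)) {
    if (!any(active)) break
    sel <- max.col(t(abs(corr[, active, drop = FALSE])), ties.method = "first")
    support[t, active] <- sel
    idx_active <- which(active)
    for (jj in seq_along(idx_active)) {
      j <- idx_active[jj]
      s <- support[seq_len(t), j]
      Gs <- G[s, s, drop = FALSE]
      cf <- tryCatch(solve(Gs, B[s, j]),
                     error = function(e) qr.solve(Gs, B[s, j]))
      coef[seq_len(t), j] <- cf
      corr[, j] <- B[, j] - G[, s, drop = FALSE] %*% cf
      corr[s, j] <- 0
      if (sum(corr[, j]^2) < 1e-24) active[j] <- FALSE
    }
  }
  for (j in seq_len(n)) {
    s <- support[, j]
    nz <- s > 0L
    if (any(nz)) A[s[nz], j] <- coef[nz, j]
  }
  A
}

extract_patches <- function(images, patch_size) {
  out <- list()
  for (im in images) {
    x <- if (inherits(im, "platelet_image")) im$pixels else im
    nr <- nrow(x); nc <- ncol(x)
    if (nr < patch_size || nc < patch_size) next
    for (i0 in seq(1L, nr - patch_size + 1L, by = patch_size))
      for (j0 in seq(1L, nc - patch_size + 1L, by = patch_size))
        out[[length(out) + 1L]] <-
          as.numeric(x[i0 + seq_len(patch_size) - 1L,
                       j0 + seq_len(patch_size) - 1L])
  }
  if (length(out) == 0L) return(matrix(numeric(0), patch_size^2, 0L))
  matrix(unlist(out), nrow = patch_size^2)
}

#' Train a sparse patch dictionary on simulated platelet images
#'
#' Learns `n_atoms` unit-norm image elements of `patch_size x patch_size`
#' pixels (the default 81 atoms of 30 x 30 pixels form a 9 x 9 element
#' dictionary) that reconstruct the training patches well under a sparsity
#' constraint: each patch is approximated by a linear combination of at most
#' `sparsity` atoms.  Training alternates batch orthogonal matching pursuit
#' with a method-of-optimal-directions dictionary update; patches are
#' mean-subtracted before coding (the mean is restored at reconstruction).
#'
#' @param training_images list of [platelet_image]s (typically from
#'   [simulate_training_set()]).
#' @param n_atoms number of dictionary elements.
#' @param patch_size side length of the square image elements, pixels.
#' @param sparsity maximum atoms per patch during training.
#' @param n_iter alternating-update iterations.
#' @param max_patches cap on the number of training patches (subsampled
#'   deterministically from the available tiles when exceeded).
#' @param seed integer seed controlling initialisation and subsampling.
#' @return An object of class `patch_dictionary`: `atoms` (a
#'   `patch_size^2 x n_atoms` matrix of unit-norm columns), `patch_size`,
#'   and `training_meta`.
#' @export
train_dictionary <- function(training_images, n_atoms = 81L,
                             patch_size = 30L, sparsity = 3L, n_iter = 8L,
                             max_patches = 15000L, seed = 1L) {
  n_atoms <- as.integer(check_number(n_atoms, "n_atoms", lower = 1))
  patch_size <- as.integer(check_number(patch_size, "patch_size", lower = 2))
  sparsity <- as.integer(check_number(sparsity, "sparsity", lower = 1))
  X <- extract_patches(training_images, patch_size)
  if (ncol(X) < n_atoms)
    stopf("need at least %d training patches, got %d", n_atoms, ncol(X))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed %% 2147483647))
  if (ncol(X) > max_patches)
    X <- X[, sort(sample.int(ncol(X), max_patches)), drop = FALSE]
  mu <- colMeans(X)
  X <- sweep(X, 2L, mu)
  # drop (numerically) empty patches: they carry no structure to learn from
  energy <- colSums(X^2)
  keep <- energy > 1e-12
  if (sum(keep) >= n_atoms) X <- X[, keep, drop = FALSE]
  # init: atoms = random distinct training patches, unit-normalised
  init <- sample.int(ncol(X), n_atoms)
  D <- X[, init, drop = FALSE]
  D <- normalize_atoms(D, ncol(X))
  loss <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    A <- omp_encode(X, D, sparsity)
    R <- X - D %*% A
    loss[it] <- sum(R^2)
    AAt <- tcrossprod(A)
    D_new <- X %*% t(A) %*% solve(AAt + diag(1e-8, n_atoms))
    # replace unused/degenerate atoms by the worst-reconstructed patches
    D <- normalize_atoms(D_new, ncol(X), X = X, R = R)
  }
  structure(list(atoms = D, patch_size = patch_size,
                 training_meta = list(n_training_images =
                                        length(training_images),
                                      n_patches = ncol(X),
                                      sparsity_level = sparsity,
                                      n_iter = n_iter, seed = seed,
                                      loss = loss,
                                      mean_subtracted = TRUE)),
            class = "patch_dictionary")
}

normalize_atoms <- function(D, n_patches, X = NULL, R = NULL) {
  nrm <- sqrt(colSums(D^2))
  dead <- which(nrm < 1e-10)
  if (length(dead) > 0L && !is.null(X)) {
    worst <- order(colSums(R^2), decreasing = TRUE)
    for (i in seq_along(dead)) {
      D[, dead[i]] <- X[, worst[min(i, length(worst))]]
    }
    nrm <- sqrt(colSums(D^2))
  }
  nrm[nrm < 1e-10] <- 1
  sweep(D, 2L, nrm, "/")
}

#' @export
print.patch_dictionary <- function(x, ...) {
  cat(sprintf("<patch_dictionary> %d atoms of %d x %d px (trained on %d patches)\n",
              ncol(x$atoms), x$patch_size, x$patch_size,
              x$training_meta$n_patches))
  invisible(x)
}

#' Sparse reconstruction of an image from a patch dictionary
#'
#' Tiles the image into non-overlapping `patch_size x patch_size` patches
#' anchored at the top-left (right/bottom margins narrower than a patch are
#' zero-padded for coding and cropped afterwards), replaces each
#' mean-subtracted patch by its best combination of at most `sparsity`
#' dictionary atoms (greedy orthogonal matching pursuit) and restores the
#' patch means.
#'
#' @param image a [platelet_image] or matrix at least `patch_size` in each
#'   dimension.
#' @param dictionary a [patch_dictionary].
#' @param sparsity maximum atoms per patch.
#' @return The reconstructed image, same class and shape as the input.
#' @export
reconstruct_image <- function(image, dictionary, sparsity = 3L) {
  is_pi <- inherits(image, "platelet_image")
  x <- if (is_pi) image$pixels else image
  ps <- dictionary$patch_size
  if (nrow(x) < ps || ncol(x) < ps)
    stopf("image (%d x %d) is smaller than one %d x %d patch",
          nrow(x), ncol(x), ps, ps)
  nr_pad <- ceiling(nrow(x) / ps) * ps
  nc_pad <- ceiling(ncol(x) / ps) * ps
  xp <- matrix(0, nr_pad, nc_pad)
  xp[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  i_starts <- seq(1L, nr_pad - ps + 1L, by = ps)
  j_starts <- seq(1L, nc_pad - ps + 1L, by = ps)
  patches <- matrix(0, ps^2, length(i_starts) * length(j_starts))
  idx <- 0L
  for (j0 in j_starts) for (i0 in i_starts) {
    idx <- idx + 1L
    patches[, idx] <- as.numeric(xp[i0 + seq_len(ps) - 1L,
                                    j0 + seq_len(ps) - 1L])
  }
  mu <- colMeans(patches)
  A <- omp_encode(sweep(patches, 2L, mu), dictionary$atoms, sparsity)
  recon <- dictionary$atoms %*% A
  recon <- sweep(recon, 2L, mu, "+")
  out <- matrix(0, nr_pad, nc_pad)
  idx <- 0L
  for (j0 in j_starts) for (i0 in i_starts) {
    idx <- idx + 1L
    out[i0 + seq_len(ps) - 1L, j0 + seq_len(ps) - 1L] <-
      matrix(recon[, idx], ps, ps)
  }
  out <- out[seq_len(nrow(x)), seq_len(ncol(x)), drop = FALSE]
  if (is_pi) {
    image$pixels <- pmax(out, 0)
    image
  } else out
}

#' Structural similarity index (SSIM)
#'
#' Mean local structural similarity between two images of identical shape,
#' computed over a sliding uniform window:
#' `SSIM_w = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'   ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`
#' with `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` and dynamic range
#' `L = max(x, y) - min(x, y)`.  Symmetric in its arguments, 1 for identical
#' images, clipped to `[0, 1]`.
#'
#' @param x,y [platelet_image]s or numeric matrices of identical shape.
#' @param window_size side of the square local window (default 7).
#' @return SSIM value in `[0, 1]`.
#' @export
ssim <- function(x, y, window_size = 7L) {
  xm <- if (inherits(x, "platelet_image")) x$pixels else x
  ym <- if (inherits(y, "platelet_image")) y$pixels else y
  if (!identical(dim(xm), dim(ym)))
    stopf("images must have identical shape")
  L <- max(xm, ym) - min(xm, ym)
  if (L == 0) return(1)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  w <- matrix(1 / window_size^2, window_size, window_size)
  mu_x <- conv2_reflect(xm, w); mu_y <- conv2_reflect(ym, w)
  sxx <- conv2_reflect(xm * xm, w) - mu_x^2
  syy <- conv2_reflect(ym * ym, w) - mu_y^2
  sxy <- conv2_reflect(xm * ym, w) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + c1) * (2 * sxy + c2)
  den <- (mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2)
  val <- mean(num / den)
  min(max(val, 0), 1)
}

#' SSIM score of the sparse dictionary reconstruction
#'
#' The fifth per-platelet parameter: how faithfully the image can be rebuilt
#' from a limited sparse dictionary.  Values well below 1 are expected and
#' informative — categories differ in how reconstructable their cluster
#' patterns are.
#'
#' @inheritParams reconstruct_image
#' @return SSIM between the image and its reconstruction, in `[0, 1]`.
#' @export
ssim_feature <- function(image, dictionary, sparsity = 3L) {
  ssim(image, reconstruct_image(image, dictionary, sparsity = sparsity))
}

#' Serialize / restore a patch dictionary as JSON
#'
#' Atoms are written row-major with full precision together with the
#' training metadata, so dictionaries are portable text artifacts.
#'
#' @param dictionary a [patch_dictionary].
#' @param path file path.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   the restored [patch_dictionary].
#' @export
write_dictionary <- function(dictionary, path) {
  obj <- list(patch_size = dictionary$patch_size,
              n_atoms = ncol(dictionary$atoms),
              atoms = as.numeric(t(dictionary$atoms)),
              training_meta = dictionary$training_meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  obj <- jsonlite::fromJSON(path)
  # row-major on disk: invert the transpose used at write time
  atoms <- matrix(obj$atoms, ncol = obj$n_atoms, byrow = TRUE)
  structure(list(atoms = atoms, patch_size = obj$patch_size,
                 training_meta = obj$training_meta),
            class = "patch_dictionary")
}
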