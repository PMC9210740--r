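# Internal numerical helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper || (!allow_zero && x == 0))
    stopf("'%s' = %g is outside its valid range [%g, %g]", name, x,
          lower, upper)
  invisible(x)
}

#' @noRd
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Mirror-pad a matrix by `pad` pixels on every side (reflection without
# repeating the edge pixel when possible; falls back to edge replication for
# very small images).
reflect_pad <- function(x, pad) {
  if (pad == 0L) return(x)
  nr <- nrow(x); nc <- ncol(x)
  ridx <- c(rev(seq_len(min(pad, nr))), seq_len(nr),
            nr + 1L - rev(seq_len(min(pad, nr))))
  # if pad exceeds the image size, replicate the mirrored block
  while (length(ridx) < nr + 2L * pad)
    ridx <- c(ridx[1L], ridx, ridx[length(ridx)])
  cidx <- c(rev(seq_len(min(pad, nc))), seq_len(nc),
            nc + 1L - rev(seq_len(min(pad, nc))))
  while (length(cidx) < nc + 2L * pad)
    cidx <- c(cidx[1L], cidx, cidx[length(cidx)])
  x[ridx, cidx, drop = FALSE]
}

# 2D convolution with a small centred kernel, reflective boundary handling,
# computed by FFT on the padded image.  The kernel must have odd dimensions.
conv2_reflect <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2L == 0L || kc %% 2L == 0L)
    stopf("convolution kernel must have odd dimensions")
  if (kr == 1L && kc == 1L) return(x * kernel[1L, 1L])
  pad <- max((kr - 1L) %/% 2L, (kc - 1L) %/% 2L)
  xp <- reflect_pad(x, pad)
  nr <- nrow(xp); nc <- ncol(xp)
  kbig <- matrix(0, nr, nc)
  kbig[seq_len(kr), seq_len(kc)] <- kernel
  # circularly shift so the kernel centre sits at (1,1)
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  kbig <- kbig[c(cr:nr, seq_len(cr - 1L)), c(cc:nc, seq_len(cc - 1L)),
               drop = FALSE]
  out <- Re(stats::fft(stats::fft(xp) * stats::fft(kbig), inverse = TRUE)) /
    (nr * nc)
  out[pad + seq_len(nrow(x)), pad + seq_len(ncol(x)), drop = FALSE]
}

# Sampled, normalised 2D Gaussian kernel (sum 1).  Radius covers 4 sigma.
gaussian_kernel <- function(sigma_px, radius = NULL) {
  if (sigma_px <= 0) return(matrix(1, 1L, 1L))
  r <- radius %||% max(1L, ceiling(4 * sigma_px))
  g <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- outer(g, g)
  k / sum(k)
}

# Deterministic child-seed derivation: a small multiplicative hash of
# (master seed, index) folded into the signed 32-bit range.  Stable across
# platforms because it only uses exact double arithmetic below 2^53.
derive_seed <- function(master_seed, i) {
  h <- (abs(master_seed) %% 2147483647) + 1
  for (v in c(i, 97)) {
    h <- (h * 48271 + v) %% 2147483647
  }
  as.integer(h)
}
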