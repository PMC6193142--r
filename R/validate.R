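# Resolution estimation (Fourier shell correlation) and reference-free
# class-average diagnostics.

#' Fourier shell correlation between two volumes
#'
#' Per concentric Fourier shell of width one Fourier pixel, the normalized
#' (real part of the) complex correlation of the two transforms.
#' `compute_fsc(v, v)` is 1 in every shell and the operation is symmetric
#' in its arguments.
#'
#' @param v1,v2 [em_volume()]s on identical grids with identical voxel
#'   sizes.
#' @return An `fsc_curve`: data.frame with `freq` (shell centre, 1/Angstrom)
#'   and `fsc`; the voxel size and shell count are kept as attributes.
#' @export
compute_fsc <- function(v1, v2) {
  if (!all(dim(v1) == dim(v2)))
    stop("volume grids differ")
  if (abs(voxel_size(v1) - voxel_size(v2)) > 1e-9)
    stop("voxel sizes differ")
  d <- dim(v1)
  f1 <- fft(as_plain_array(v1))
  f2 <- fft(as_plain_array(v2))
  ix <- fft_freq(d[1]) * d[1]
  iy <- fft_freq(d[2]) * d[2]
  iz <- fft_freq(d[3]) * d[3]
  r <- sqrt(outer(outer(ix^2, iy^2, `+`), iz^2, `+`))
  shell <- as.integer(round(r))
  nmax <- floor(min(d) / 2)
  keep <- shell >= 1L & shell <= nmax
  sh <- shell[keep]
  num <- rowsum(Re(f1 * Conj(f2))[keep], sh)[, 1]
  p1 <- rowsum(abs(f1[keep])^2, sh)[, 1]
  p2 <- rowsum(abs(f2[keep])^2, sh)[, 1]
  den <- sqrt(p1 * p2)
  den[den == 0] <- Inf
  fsc <- num / den
  freq <- sort(unique(sh)) / (d[1] * voxel_size(v1))
  structure(data.frame(freq = freq, fsc = fsc),
            class = c("fsc_curve", "data.frame"),
            voxel_size = voxel_size(v1), n_shells = length(freq))
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.5, ...) {
  plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
       ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  abline(h = threshold, lty = 2)
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' Locates the first crossing below the threshold by linear interpolation
#' in frequency between adjacent shells and returns the corresponding
#' wavelength.  If the curve never crosses, the Nyquist wavelength is
#' returned with attribute `"flag" = "not reached"`.
#'
#' @param curve an `fsc_curve`.
#' @param threshold FSC threshold (0.5 by default).
#' @return Resolution in Angstrom, with a `"flag"` attribute (`"ok"`,
#'   `"not reached"`, or `"immediate"` when already below threshold at the
#'   first shell).
#' @export
resolution_at_threshold <- function(curve, threshold = 0.5) {
  if (nrow(curve) == 0) stop("empty FSC curve")
  f <- curve$freq
  y <- curve$fsc
  below <- which(y < threshold)
  if (length(below) == 0) {
    vx <- attr(curve, "voxel_size") %||% (1 / (2 * max(f)))
    return(structure(2 * vx, flag = "not reached"))
  }
  i <- below[1]
  if (i == 1L)
    return(structure(1 / f[1], flag = "immediate"))
  fc <- f[i - 1] + (f[i] - f[i - 1]) * (y[i - 1] - threshold) / (y[i - 1] - y[i])
  structure(1 / fc, flag = "ok")
}

#' Reference-free classification and class averaging
#'
#' A deliberately simple stand-in for multivariate statistical
#' classification: principal components of the (optionally masked) aligned
#' pixels followed by k-means.  Deterministic for a given seed; class
#' averages are the plain means of their members and the classes partition
#' the stack.
#'
#' @param stack aligned [particle_stack()].
#' @param k number of classes (`1 <= k <= n`).
#' @param seed RNG seed for k-means.
#' @param mask optional logical image mask restricting the feature pixels.
#' @param n_components number of principal components retained.
#' @return list with `averages` (`n` x `n` x `k` array), `membership`
#'   (integer vector) and `sizes`.
#' @export
classify_and_average <- function(stack, k, seed = 1, mask = NULL,
                                 n_components = 10) {
  arr <- as_plain_array(stack)
  np <- dim(arr)[3]
  if (k < 1) stop("k must be >= 1")
  if (k > np) stop(sprintf("k = %d exceeds the stack size %d", k, np))
  sel <- if (is.null(mask)) seq_len(dim(arr)[1] * dim(arr)[2]) else which(mask != 0)
  x <- t(apply(arr, 3, function(m) as.numeric(m)[sel]))
  if (k == 1L) {
    membership <- rep(1L, np)
  } else {
    nc <- min(n_components, np - 1, ncol(x))
    pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = nc)
    membership <- with_seed(seed,
      kmeans(pc$x, centers = k, nstart = 10, iter.max = 100)$cluster)
  }
  avgs <- array(0, c(dim(arr)[1], dim(arr)[2], k))
  for (cl in seq_len(k)) {
    idx <- which(membership == cl)
    if (length(idx) > 0)
      avgs[, , cl] <- apply(arr[, , idx, drop = FALSE], c(1, 2), mean)
  }
  list(averages = avgs, membership = as.integer(membership),
       sizes = tabulate(membership, k))
}
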