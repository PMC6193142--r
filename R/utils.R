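# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# FFT sample frequencies in cycles per unit, order matching stats::fft
fft_freq <- function(n, d = 1) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k / (n * d)
}

# run code with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

deg_mod <- function(x) ((x %% 360) + 360) %% 360

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

# radial coordinate grid (in pixels) about the image/volume centre
radius_grid_2d <- function(nx, ny) {
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  dx <- seq_len(nx) - cx
  dy <- seq_len(ny) - cy
  sqrt(outer(dx^2, dy^2, `+`))
}

# Pearson correlation between two numeric arrays (flattened), optional mask
arr_cor <- function(a, b, mask = NULL) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (!is.null(mask)) {
    a <- a[mask]
    b <- b[mask]
  }
  if (sd(a) == 0 || sd(b) == 0) return(0)
  stats::cor(a, b)
}

# parabolic interpolation of a discrete peak position; returns offset in
# [-0.5, 0.5] grid units
parabolic_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
}

# local maxima of a circular series; returns indices
circular_local_maxima <- function(y) {
  n <- length(y)
  ym <- y[c(n, seq_len(n - 1))]
  yp <- y[c(seq_len(n)[-1], 1)]
  which(y > ym & y >= yp)
}
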