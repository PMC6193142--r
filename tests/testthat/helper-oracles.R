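# Independent oracles and fixtures used across the suite.

# direct double-loop masked NCC (oracle for the FFT implementation)
brute_masked_ncc <- function(image, template, mask) {
  h <- nrow(template); w <- ncol(template)
  H <- nrow(image); W <- ncol(image)
  out <- matrix(0, H - h + 1, W - w + 1)
  tm <- template[mask]
  for (i in seq_len(H - h + 1)) {
    for (j in seq_len(W - w + 1)) {
      p <- image[i:(i + h - 1), j:(j + w - 1)][mask]
      out[i, j] <- if (stats::sd(p) == 0 || stats::sd(tm) == 0) 0 else
        stats::cor(p, tm)
    }
  }
  out
}

# closed-form frequencies of CTF zeros: sin(gamma + atan(A / sqrt(1 - A^2)))
# changes sign where gamma = -phi_a - m * pi; solve the quadratic in k^2
ctf_zeros_closed_form <- function(defocus_um, voltage_kv, cs_mm,
                                  amplitude_contrast, n = 3) {
  v <- voltage_kv * 1e3
  lambda <- 12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
  z <- -defocus_um * 1e4
  cs <- cs_mm * 1e7
  phi_a <- atan2(amplitude_contrast, sqrt(1 - amplitude_contrast^2))
  roots <- c()
  for (m in 0:(n + 2)) {
    # -pi lambda z k^2 + (pi/2) cs lambda^3 k^4 = -phi_a - m pi
    a <- (pi / 2) * cs * lambda^3
    b <- -pi * lambda * z
    cc <- phi_a + m * pi
    disc <- b^2 - 4 * a * cc
    if (disc < 0) next
    for (s in c(-1, 1)) {
      k2 <- (-b + s * sqrt(disc)) / (2 * a)
      if (k2 > 0) roots <- c(roots, sqrt(k2))
    }
  }
  sort(roots)[seq_len(n)]
}

# adjusted Rand index between two partitions
rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# compact microfibril phantom for fast refinement tests: 28.8 nm repeat in a
# 64-voxel box at 8 A/voxel (36-voxel period, two beads in the box)
small_phantom_spec <- function(...) {
  microfibril_phantom_spec(periodicity = 28.8, max_diameter = 16,
                           interbead_diameter = 11, ...)
}

small_phantom <- function(...) {
  make_microfibril_phantom(small_phantom_spec(...), box_px = 64,
                           voxel_size = 8)
}

# correlation of two volumes inside a cylindrical mask
masked_volume_cor <- function(a, b, radius = NULL) {
  d <- dim(a)
  radius <- radius %||% (d[1] / 2 - 2)
  rad <- sqrt(outer((seq_len(d[1]) - (d[1] + 1) / 2)^2,
                    (seq_len(d[2]) - (d[2] + 1) / 2)^2, `+`))
  m <- array(rep(rad <= radius, d[3]), d)
  stats::cor(as.numeric(a)[m], as.numeric(b)[m])
}

`%||%` <- function(x, y) if (is.null(x)) y else x
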