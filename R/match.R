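# Masked, locally normalized cross-correlation (the FindEM-style matcher)
# and exhaustive 2D particle alignment.

#' Masked normalized cross-correlation map
#'
#' At each valid offset, the Pearson correlation between the template and
#' the image patch it covers, with both mean and variance computed under
#' the binary mask only.  Evaluated with FFT cross-correlations (the sums
#' under the shifted mask are correlations of the image and its square with
#' the mask), which matches the direct double-loop computation to better
#' than 1e-5.
#'
#' @param image numeric matrix (H x W).
#' @param template numeric matrix, no larger than `image`.
#' @param mask logical (or 0/1) matrix, same size as `template`, at least 16
#'   true pixels.
#' @return Matrix of size `(H - h + 1) x (W - w + 1)` of correlations in
#'   `[-1, 1]`.  Offsets where the local variance under the mask vanishes
#'   are set to 0 and flagged in the `"flagged"` attribute (a logical matrix).
#' @export
masked_ncc_map <- function(image, template, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(template), ncol(template))
  if (!all(dim(template) == dim(mask)))
    stop("mask must match the template size")
  if (nrow(template) > nrow(image) || ncol(template) > ncol(image))
    stop("template larger than image")
  m <- (mask != 0) * 1
  nm <- sum(m)
  if (nm == 0) stop("empty mask")
  if (nm < 16) stop("mask must contain at least 16 true pixels")
  H <- nrow(image); W <- ncol(image)
  h <- nrow(template); w <- ncol(template)

  pad <- function(a) {
    out <- matrix(0, H, W)
    out[seq_len(nrow(a)), seq_len(ncol(a))] <- a
    out
  }
  xcorr <- function(fa, b) {
    # C[u, v] = sum_{x, y} A[x + u, y + v] B[x, y]  (0-based offsets)
    Re(fft(fa * Conj(fft(pad(b))), inverse = TRUE)) / (H * W)
  }
  fI <- fft(image)
  fI2 <- fft(image^2)
  tm <- template * m
  s1 <- xcorr(fI, m)          # sum of image under mask
  s2 <- xcorr(fI2, m)         # sum of image^2 under mask
  st <- xcorr(fI, tm)         # sum of image * template under mask

  iu <- seq_len(H - h + 1)
  jv <- seq_len(W - w + 1)
  s1 <- s1[iu, jv, drop = FALSE]
  s2 <- s2[iu, jv, drop = FALSE]
  st <- st[iu, jv, drop = FALSE]

  tsum <- sum(tm)
  tvar <- sum(m * template^2) - tsum^2 / nm
  covm <- st - s1 * tsum / nm
  varI <- s2 - s1^2 / nm
  eps <- 1e-10 * max(1, max(abs(s2)))
  bad <- varI <= eps | tvar <= 0
  den <- sqrt(pmax(varI, eps) * max(tvar, eps))
  out <- covm / den
  out[bad] <- 0
  out <- pmin(pmax(out, -1), 1)
  attr(out, "flagged") <- bad
  out
}

# default alignment mask radius for a box of n px with a given shift budget
default_align_radii <- function(n, shift_max) {
  rmax <- floor(n / 2) - shift_max - 2
  if (rmax < 4) stop("box too small for the requested shift range")
  c(2L, as.integer(rmax))
}

#' Exhaustively align one particle against a set of references
#'
#' Searches every combination of reference, in-plane rotation on a regular
#' `psi_step` grid and integer shift within `shift_max`, maximizing the
#' masked normalized cross-correlation; ties are broken deterministically
#' (lowest reference index, then smallest psi, then smallest shift).  The
#' best grid point is polished by parabolic interpolation, so noise-free
#' transforms are recovered to a fraction of the grid spacing.
#'
#' Two engines implement the same search: `"polar"` (default when no mask
#' is given) scores on a ring-weighted polar resampling of the disk around
#' each candidate shifted centre, which is exactly the masked NCC for a
#' rotation-invariant disk mask and lets the whole psi grid be scored at
#' once; `"cartesian"` rotates the particle and evaluates [masked_ncc_map()]
#' for every rotation, and accepts arbitrary masks (used for region-masked
#' sub-model refinement).
#'
#' @param particle numeric square matrix.
#' @param references a [particle_stack()], 3D array or single matrix of
#'   reference images (projections of the current model).
#' @param psi_step in-plane rotation grid step in degrees; must divide 360.
#' @param shift_max maximum shift in px (integer grid, both axes).
#' @param mask optional binary mask (template-sized after cropping by
#'   `shift_max`); forces the cartesian engine.
#' @param engine `"auto"`, `"polar"` or `"cartesian"`.
#' @param ring_step radial stride of the polar sampling grid, voxels (polar
#'   engine only; 2 is ample for 20 A band-limited images).
#' @return One-row alignment record: `psi`, `dx`, `dy` (transform that maps
#'   the matched reference onto the particle: rotate by `psi`, then shift),
#'   `phi` (`NA`; filled by callers that know reference azimuths), `ref`
#'   (1-based reference index), `score`, `flagged`.
#' @export
align_particle <- function(particle, references, psi_step = 5, shift_max = 8,
                           mask = NULL, engine = c("auto", "polar", "cartesian"),
                           ring_step = 2) {
  engine <- match.arg(engine)
  if (engine == "auto") engine <- if (is.null(mask)) "polar" else "cartesian"
  refs <- ref_array(references)
  stack <- array(particle, c(dim(particle), 1L))
  if (engine == "polar") {
    rec <- align_stack_polar(stack, refs, psi_step, shift_max,
                             ring_step = ring_step)
  } else {
    rec <- align_stack_cartesian(stack, refs, psi_step, shift_max, mask)
  }
  rec
}

ref_array <- function(references) {
  if (is.matrix(references)) references <- array(references, c(dim(references), 1L))
  if (length(dim(references)) != 3L) stop("references must be a matrix or 3D array")
  as_plain_array(references)
}

align_stack_polar <- function(stack, refs, psi_step, shift_max,
                              rmin = NULL, rmax = NULL, ring_step = 2) {
  if (360 %% psi_step != 0) stop("psi_step must divide 360")
  n <- dim(stack)[1]
  rr <- default_align_radii(n, shift_max)
  rmin <- rmin %||% rr[1]
  rmax <- rmax %||% rr[2]
  ntheta <- as.integer(360 / psi_step)
  res <- cpp_align_polar(as.numeric(stack), dim(stack), as.numeric(refs),
                         dim(refs), ntheta, as.integer(shift_max),
                         as.integer(rmin), as.integer(rmax),
                         as.integer(ring_step))
  np <- dim(stack)[3]
  rec <- new_records(np)
  rec$score <- res[, 1]
  rec$ref <- as.integer(res[, 2]) + 1L
  rec$psi <- deg_mod((res[, 3] + res[, 6]) * psi_step)
  rec$dx <- res[, 4] + res[, 7]
  rec$dy <- res[, 5] + res[, 8]
  rec$phi <- NA_real_
  # flat particles (no finite-variance patch anywhere): identity record
  flat <- res[, 2] < 0
  if (any(flat)) {
    rec$score[flat] <- 0
    rec$psi[flat] <- 0
    rec$dx[flat] <- 0
    rec$dy[flat] <- 0
    rec$ref[flat] <- 1L
  }
  rec$flagged <- flat
  rec
}

align_stack_cartesian <- function(stack, refs, psi_step, shift_max, mask) {
  if (360 %% psi_step != 0) stop("psi_step must divide 360")
  n <- dim(stack)[1]
  m <- as.integer(shift_max)
  if (2 * m >= n - 4) stop("shift_max too large for the box")
  crop <- (m + 1):(n - m)
  if (is.null(mask)) {
    tm_mask <- NULL
  } else {
    if (!all(dim(mask) == c(n, n)) && !all(dim(mask) == c(length(crop), length(crop))))
      stop("mask must match the box or the cropped template")
    tm_mask <- if (all(dim(mask) == c(n, n))) mask[crop, crop] else mask
    tm_mask <- tm_mask != 0
  }
  psis <- seq(0, 360 - psi_step, by = psi_step)
  offs <- expand.grid(dx = -m:m, dy = -m:m)
  ord <- order(offs$dx^2 + offs$dy^2, offs$dy, offs$dx)
  np <- dim(stack)[3]
  nref <- dim(refs)[3]
  rec <- new_records(np)
  for (p in seq_len(np)) {
    img <- stack[, , p]
    if (all(img == 0)) {
      rec$score[p] <- 0; rec$ref[p] <- 1L; rec$flagged[p] <- TRUE
      rec$phi[p] <- NA_real_
      next
    }
    best <- list(score = -2)
    qs <- lapply(psis, function(ps)
      if (ps == 0) img else cpp_rotate_image(img, -ps))
    # loop order implements the tie-break: reference, then psi, then |shift|
    for (rf in seq_len(nref)) {
      tmpl <- refs[crop, crop, rf]
      for (ip in seq_along(psis)) {
        q <- qs[[ip]]
        map <- masked_ncc_map(q, tmpl, tm_mask)
        vals <- map[cbind(offs$dx[ord] + m + 1L, offs$dy[ord] + m + 1L)]
        ibest <- which.max(vals)
        sc <- vals[ibest]
        if (sc > best$score) {
          io <- ord[ibest]
          best <- list(score = sc, ref = rf, psi = psis[ip],
                       ddx = offs$dx[io], ddy = offs$dy[io], map = map)
        }
      }
    }
    rm(qs)
    # sub-pixel polish of the shift on the winning NCC map
    mi <- best$ddx + m + 1L
    mj <- best$ddy + m + 1L
    sx <- sy <- 0
    if (mi > 1 && mi < nrow(best$map))
      sx <- parabolic_offset(best$map[mi - 1, mj], best$map[mi, mj],
                             best$map[mi + 1, mj])
    if (mj > 1 && mj < ncol(best$map))
      sy <- parabolic_offset(best$map[mi, mj - 1], best$map[mi, mj],
                             best$map[mi, mj + 1])
    dpr <- best$psi * pi / 180
    ddx <- best$ddx + sx
    ddy <- best$ddy + sy
    # delta found in the unrotated frame; rotate into the particle frame
    rec$psi[p] <- best$psi
    rec$dx[p] <- cos(dpr) * ddx - sin(dpr) * ddy
    rec$dy[p] <- sin(dpr) * ddx + cos(dpr) * ddy
    rec$ref[p] <- best$ref
    rec$score[p] <- best$score
    rec$phi[p] <- NA_real_
  }
  rec
}

#' Align every particle of a stack against a reference set
#'
#' @inheritParams align_particle
#' @param stack a [particle_stack()].
#' @param ref_azimuths optional numeric vector of reference azimuths
#'   (degrees); when given, the `phi` column is filled from the matched
#'   reference.
#' @return Alignment records, one row per particle (see [align_particle()]).
#' @export
align_stack <- function(stack, references, psi_step = 5, shift_max = 8,
                        mask = NULL, engine = c("auto", "polar", "cartesian"),
                        ref_azimuths = NULL, ring_step = 2) {
  engine <- match.arg(engine)
  if (engine == "auto") engine <- if (is.null(mask)) "polar" else "cartesian"
  refs <- ref_array(references)
  arr <- as_plain_array(stack)
  rec <- if (engine == "polar") {
    align_stack_polar(arr, refs, psi_step, shift_max, ring_step = ring_step)
  } else {
    align_stack_cartesian(arr, refs, psi_step, shift_max, mask)
  }
  if (!is.null(ref_azimuths)) rec$phi <- deg_mod(ref_azimuths[rec$ref])
  rec
}

#' Average a stack under its alignment records
#'
#' Each particle is mapped back onto the reference frame by undoing its
#' recorded shift and rotation in a single resampling pass, then the stack
#' mean is taken.  With identity records this is the plain stack mean (the
#' initial, reference-free template).
#'
#' @param stack a [particle_stack()] or 3D array.
#' @param records alignment records (see [align_particle()]); identity
#'   records when missing.
#' @return The average image (matrix).
#' @export
average_aligned <- function(stack, records = NULL) {
  arr <- as_plain_array(stack)
  np <- dim(arr)[3]
  if (np == 0L) stop("empty stack")
  if (is.null(records)) {
    records <- new_records(np)
    records$ref <- 1L
  }
  check_records(records, np)
  acc <- matrix(0, dim(arr)[1], dim(arr)[2])
  for (i in seq_len(np)) {
    if (records$psi[i] == 0 && records$dx[i] == 0 && records$dy[i] == 0) {
      acc <- acc + arr[, , i]
    } else {
      acc <- acc + cpp_unalign_image(arr[, , i], records$psi[i],
                                     records$dx[i], records$dy[i])
    }
  }
  acc / np
}

#' Rotate an average image so its principal axis is vertical
#'
#' The filament direction of a 2D average is estimated from the second
#' moments of the (positive) intensity about the image centre and the image
#' is rotated so this axis lies along the second (axial) index, as required
#' by [cylindrical_initial_model()].
#'
#' @param image square matrix.
#' @return The rotated image; rotation applied (degrees) in attribute
#'   `"angle"`.
#' @export
align_average_vertical <- function(image) {
  n <- nrow(image)
  c0 <- (n + 1) / 2
  w <- pmax(image, 0)
  if (sum(w) == 0) return(structure(image, angle = 0))
  ix <- matrix(seq_len(n) - c0, n, ncol(image))
  iy <- matrix(seq_len(ncol(image)) - c0, n, ncol(image), byrow = TRUE)
  sxx <- sum(w * ix * ix); syy <- sum(w * iy * iy); sxy <- sum(w * ix * iy)
  # orientation of the major axis; rotate it onto the y (axial) direction
  theta <- 0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi
  ang <- 90 - theta
  out <- cpp_rotate_image(image, ang)
  structure(out, angle = ang)
}

#' Reference-free iterative pre-alignment
#'
#' Starts from the average of the unaligned stack as template and
#' alternates alignment and averaging with the running average as the
#' evolving template.
#'
#' @inheritParams align_stack
#' @param iterations number of align/average rounds.
#' @return list with `average` (final template), `records`, and the mean
#'   score per iteration in `score_log`.
#' @export
reference_free_align <- function(stack, psi_step = 5, shift_max = 8,
                                 iterations = 5) {
  template <- average_aligned(stack)
  log <- numeric(iterations)
  rec <- NULL
  for (it in seq_len(iterations)) {
    rec <- align_stack(stack, template, psi_step = psi_step,
                       shift_max = shift_max)
    template <- average_aligned(stack, rec)
    log[it] <- mean(rec$score)
  }
  list(average = template, records = rec, score_log = log)
}
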