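# Region-masked sub-model refinement and rotational cross-correlation
# detection of (pseudo-)symmetry.

#' Axial region of the repeat
#'
#' @param name region name (`"bead"`, `"arm"`, `"interbead"`, or custom).
#' @param intervals numeric matrix, one `[start, end)` fractional z-interval
#'   of the repeat per row (the arm region has two).
#' @param softness raised-cosine edge width in px (0 = binary).
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(name, intervals, softness = 0) {
  if (is.null(dim(intervals))) intervals <- rbind(intervals)
  if (any(intervals[, 2] <= intervals[, 1]))
    stop("empty axial interval")
  if (any(intervals < 0) || any(intervals > 1))
    stop("intervals must lie within [0, 1]")
  structure(list(name = name, intervals = intervals, softness = softness),
            class = "region_spec")
}

#' Default bead / arm / interbead regions
#' @return Named list of [region_spec()]s matching
#'   [default_region_boundaries()].
#' @export
default_regions <- function() {
  rb <- default_region_boundaries()
  list(bead = region_spec("bead", rb$bead),
       arm = region_spec("arm", rb$arm),
       interbead = region_spec("interbead", rb$interbead))
}

# fractional repeat coordinate of each axial index (interbead centred
# mid-box, same phase convention as make_microfibril_phantom)
axial_phase <- function(n_axial, period_vox, center_phase = 0.65) {
  cz <- (n_axial + 1) / 2
  ((seq_len(n_axial) - cz) / period_vox + center_phase) %% 1
}

in_intervals <- function(t, intervals) {
  hit <- rep(FALSE, length(t))
  for (r in seq_len(nrow(intervals)))
    hit <- hit | (t >= intervals[r, 1] & t < intervals[r, 2])
  hit
}

#' Binary region mask for a box
#'
#' True exactly on the region's fractional axial interval(s) of the repeat
#' (periodically continued over the box).  The 2D mask is the projection
#' support of the 3D mask: both depend on the axial coordinate only.
#'
#' @param box box edge in px/voxels (axial length).
#' @param region a [region_spec()].
#' @param periodicity repeat length in nm.
#' @param voxel_size voxel size in Angstrom.
#' @param ndim 2 for an image mask (`box` x `box`), 3 for a volume mask.
#' @param center_phase fractional position at the box centre (0.65 =
#'   interbead centre, the phantom convention).
#' @return Logical matrix or 3D array (numeric in `[0, 1]` when
#'   `softness > 0`).
#' @export
region_mask <- function(box, region, periodicity = 59.2, voxel_size = 8,
                        ndim = 2, center_phase = 0.65) {
  period_vox <- periodicity * 10 / voxel_size
  t <- axial_phase(box, period_vox, center_phase)
  axial <- in_intervals(t, region$intervals)
  if (!any(axial)) stop("region mask is empty for this box")
  if (region$softness > 0) {
    k <- seq(-ceiling(3 * region$softness), ceiling(3 * region$softness))
    w <- exp(-k^2 / (2 * region$softness^2))
    w <- w / sum(w)
    ax <- as.numeric(axial)
    axn <- sapply(seq_along(ax), function(i) {
      idx <- ((i + k - 1) %% length(ax)) + 1
      sum(ax[idx] * w)
    })
    axial <- axn
  }
  if (ndim == 2) {
    matrix(rep(axial, each = box), box, box)
  } else {
    arr <- array(0, c(box, box, box))
    for (iz in seq_len(box)) arr[, , iz] <- axial[iz]
    if (region$softness == 0) arr <- arr > 0.5
    arr
  }
}

# local cartesian search used by sub-model refinement: psi and reference
# azimuth restricted to a window around the previous assignment
align_stack_local <- function(stack, refs, prev, psi_step, shift_max, mask,
                              psi_window = 2, phi_window = 2) {
  arr <- as_plain_array(stack)
  np <- dim(arr)[3]
  nref <- dim(refs)[3]
  n <- dim(arr)[1]
  m <- as.integer(shift_max)
  crop <- (m + 1):(n - m)
  tm_mask <- if (is.null(mask)) NULL else {
    mk <- if (all(dim(mask) == c(n, n))) mask[crop, crop] else mask
    mk != 0
  }
  offs <- expand.grid(dx = -m:m, dy = -m:m)
  ord <- order(offs$dx^2 + offs$dy^2, offs$dy, offs$dx)
  rec <- new_records(np)
  for (p in seq_len(np)) {
    img <- arr[, , p]
    psi0 <- round(prev$psi[p] / psi_step)
    psis <- deg_mod((psi0 + (-psi_window:psi_window)) * psi_step)
    psis <- unique(psis)
    rset <- unique(((prev$ref[p] - 1 + (-phi_window:phi_window)) %% nref) + 1L)
    rset <- sort(rset)
    best <- list(score = -2)
    for (rf in rset) {
      tmpl <- refs[crop, crop, rf]
      for (ps in psis) {
        q <- if (ps == 0) img else cpp_rotate_image(img, -ps)
        map <- masked_ncc_map(q, tmpl, tm_mask)
        vals <- map[cbind(offs$dx[ord] + m + 1L, offs$dy[ord] + m + 1L)]
        ib <- which.max(vals)
        if (vals[ib] > best$score) {
          io <- ord[ib]
          best <- list(score = vals[ib], ref = rf, psi = ps,
                       ddx = offs$dx[io], ddy = offs$dy[io])
        }
      }
    }
    dpr <- best$psi * pi / 180
    rec$psi[p] <- best$psi
    rec$dx[p] <- cos(dpr) * best$ddx - sin(dpr) * best$ddy
    rec$dy[p] <- sin(dpr) * best$ddx + cos(dpr) * best$ddy
    rec$ref[p] <- best$ref
    rec$score[p] <- best$score
  }
  rec
}

#' Region-masked sub-model refinement
#'
#' Identical to [refine_projection_matching()] except that alignment is
#' scored by masked NCC under the region's 2D mask, localizing the
#' alignment to that region (this is how flexible filaments are handled:
#' each region is aligned and reconstructed on its own).  Because band
#' masks are not rotation invariant, scoring uses the cartesian engine
#' with the in-plane rotation and azimuth searched locally around the
#' incoming full-model alignment.  The returned volume is windowed to the
#' region's axial interval.
#'
#' With a region covering the whole repeat the call reduces to
#' [refine_projection_matching()].
#'
#' @inheritParams refine_projection_matching
#' @param region a [region_spec()].
#' @param periodicity repeat length in nm (locates the region in the box).
#' @param records starting alignment records; when `NULL` a full-model
#'   polar alignment against projections of `init` is run first.
#' @param psi_window,phi_window local search half-width, in grid steps.
#' @return A `pm_refinement` object (see [refine_projection_matching()]);
#'   `model` is windowed to the region.
#' @export
refine_submodel <- function(stack, init, region, cfg = refinement_config(),
                            periodicity = 59.2, records = NULL,
                            psi_window = 2, phi_window = 2) {
  span <- sum(region$intervals[, 2] - region$intervals[, 1])
  if (span >= 1 - 1e-9)
    return(refine_projection_matching(stack, init, cfg))
  arr <- as_plain_array(stack)
  px <- voxel_size(stack)
  n <- dim(arr)[1]
  azgrid <- seq(0, 360 - cfg$azimuth_step, by = cfg$azimuth_step)
  mask2 <- region_mask(n, region, periodicity, px, ndim = 2)
  mask3 <- region_mask(n, region, periodicity, px, ndim = 3)
  model <- init
  if (is.null(records)) {
    refs <- vapply(azgrid, function(a) project_about_axis(model, a),
                   matrix(0, n, n))
    records <- align_stack(stack, refs, psi_step = cfg$psi_step,
                           shift_max = cfg$shift_max, engine = "polar",
                           ref_azimuths = azgrid)
  }
  scores <- changed <- numeric(0)
  prev_ref <- records$ref
  stopped <- "max_iterations"
  for (it in seq_len(cfg$n_iterations)) {
    refs <- vapply(azgrid, function(a) project_about_axis(model, a),
                   matrix(0, n, n))
    rec <- align_stack_local(stack, refs, records, cfg$psi_step,
                             cfg$shift_max, mask2, psi_window, phi_window)
    rec$phi <- deg_mod(azgrid[rec$ref])
    model <- wbp_filament(stack, rec, px)
    if (cfg$symmetry_order > 1) model <- impose_cn(model, cfg$symmetry_order)
    model <- lowpass_volume(model, cfg$lowpass_each_iter)
    scores <- c(scores, mean(rec$score))
    fc <- mean(rec$ref != prev_ref)
    changed <- c(changed, fc)
    prev_ref <- rec$ref
    records <- rec
    if (it > 1 && fc < cfg$min_changed) {
      stopped <- "converged"
      break
    }
  }
  win <- as_plain_array(model) * (mask3 != 0)
  out <- list(model = em_volume(win, voxel_size(model)), records = records,
              log = data.frame(iteration = seq_along(scores),
                               mean_score = scores, frac_changed = changed),
              config = cfg, region = region, stopped = stopped)
  class(out) <- "pm_refinement"
  out
}

#' Extract the sub-volume of a region
#'
#' Windows a volume to a region's axial interval (zero outside).
#'
#' @param volume an [em_volume()].
#' @param region a [region_spec()].
#' @param periodicity repeat length, nm.
#' @return Windowed [em_volume()].
#' @export
region_subvolume <- function(volume, region, periodicity = 59.2) {
  m <- region_mask(dim(volume)[3], region, periodicity, voxel_size(volume),
                   ndim = 3)
  em_volume(as_plain_array(volume) * (m != 0), voxel_size(volume))
}

#' Rotational cross-correlation scan
#'
#' Self mode: the model is projected on the azimuth grid and every
#' projection is correlated with the projection rotated by each angular
#' offset; the curve is the mean correlation per offset.  Data mode: every
#' particle (mapped back to the reference frame with its record) is
#' correlated with the model projection at its assigned azimuth plus each
#' offset.  Peaks at multiples of `360/n` reveal Cn (pseudo-)symmetry.
#'
#' @param model an [em_volume()].
#' @param data optional [particle_stack()] (data mode).
#' @param records alignment records (required in data mode).
#' @param increment angular step in degrees; must divide 360.
#' @param mask optional logical image mask for the correlations (e.g. a
#'   region mask); default disk.
#' @return A `correlation_curve`: data.frame with `angle`, `correlation`.
#' @export
rotational_correlation_scan <- function(model, data = NULL, records = NULL,
                                        increment = 5, mask = NULL) {
  if (360 %% increment != 0) stop("increment must divide 360")
  nang <- as.integer(360 / increment)
  angles <- (seq_len(nang) - 1) * increment
  n <- dim(model)[1]
  if (is.null(mask)) mask <- radius_grid_2d(n, dim(model)[3]) <= n / 2 - 1
  sel <- which(mask != 0)
  projs <- vapply(angles, function(a) project_about_axis(model, a),
                  matrix(0, n, dim(model)[3]))
  pm <- apply(projs, 3, function(m) m[sel])
  pm <- scale(pm, center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(pm^2))
  nrm[nrm == 0] <- 1
  pm <- sweep(pm, 2, nrm, "/")
  if (is.null(data)) {
    cc <- crossprod(pm)               # nang x nang correlation matrix
    curve <- vapply(seq_len(nang), function(k) {
      idx <- ((seq_len(nang) - 1 + (k - 1)) %% nang) + 1
      mean(cc[cbind(seq_len(nang), idx)])
    }, numeric(1))
  } else {
    if (is.null(records)) stop("data mode requires alignment records")
    arr <- as_plain_array(data)
    np <- dim(arr)[3]
    check_records(records, np)
    acc <- numeric(nang)
    for (i in seq_len(np)) {
      al <- cpp_unalign_image(arr[, , i], records$psi[i], records$dx[i],
                              records$dy[i])
      v <- al[sel]
      v <- v - mean(v)
      nv <- sqrt(sum(v^2))
      if (nv == 0) next
      v <- v / nv
      base <- round(deg_mod(records$phi[i]) / increment)
      idx <- ((base + seq_len(nang) - 1) %% nang) + 1
      acc <- acc + as.numeric(crossprod(pm[, idx], v))
    }
    curve <- acc / np
  }
  structure(data.frame(angle = angles, correlation = curve),
            class = c("correlation_curve", "data.frame"),
            increment = increment,
            mode = if (is.null(data)) "self" else "data")
}

#' @export
plot.correlation_curve <- function(x, ...) {
  plot(x$angle, x$correlation, type = "l", xlab = "rotation (degrees)",
       ylab = "mean correlation", ...)
  invisible(x)
}

# circular topographic prominence of local maxima
peak_prominences <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(i) {
    if (y[i] >= max(y)) return(y[i] - min(y))
    # walk each way to the nearest strictly higher point, tracking the min
    key <- -Inf
    for (dir in c(1L, -1L)) {
      j <- i
      lo <- y[i]
      repeat {
        j <- ((j - 1 + dir) %% n) + 1
        if (y[j] > y[i]) break
        lo <- min(lo, y[j])
        if (j == i) break
      }
      key <- max(key, lo)
    }
    y[i] - key
  }, numeric(1))
}

#' Detect candidate rotational symmetry orders from a correlation curve
#'
#' Local maxima with topographic prominence at least
#' `prominence * range(curve)` are located (excluding zero rotation); an
#' order `n` is reported when every multiple of `360/n` lies within one
#' grid step of a detected peak.  Orders are returned in decreasing `n`.
#'
#' @param curve a `correlation_curve`.
#' @param prominence minimum peak prominence as a fraction of the curve
#'   range.
#' @param max_order largest order to consider.
#' @return Integer vector of candidate orders (decreasing); detected peak
#'   angles in the `"peaks"` attribute.  Flat curve: empty.
#' @export
detect_symmetry_orders <- function(curve, prominence = 0.1, max_order = 12) {
  y <- curve$correlation
  ang <- curve$angle
  rng <- diff(range(y))
  if (rng < 1e-12) return(structure(integer(0), peaks = numeric(0)))
  peaks <- circular_local_maxima(y)
  peaks <- peaks[ang[peaks] != 0]
  if (length(peaks) > 0) {
    prom <- peak_prominences(y, peaks)
    peaks <- peaks[prom >= prominence * rng]
  }
  pa <- ang[peaks]
  step <- attr(curve, "increment") %||% min(diff(ang))
  orders <- integer(0)
  for (nn in seq(max_order, 2)) {
    mult <- (seq_len(nn - 1)) * 360 / nn
    ok <- all(vapply(mult, function(m)
      any(abs(((pa - m + 180) %% 360) - 180) <= step + 1e-9), logical(1)))
    if (ok && length(pa) > 0) orders <- c(orders, nn)
  }
  structure(orders, peaks = pa)
}
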