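# Initial model construction, azimuthal projection, weighted back-projection
# (filament geometry and single-axis tilt), symmetry imposition and the
# iterative projection-matching refinement loop.

#' Refinement configuration
#'
#' @param azimuth_step reference projection increment about the filament
#'   axis, degrees (must divide 360).
#' @param n_iterations maximum refinement iterations.
#' @param symmetry_order Cn symmetry imposed about z each iteration.
#' @param lowpass_each_iter low-pass wavelength (Angstrom) applied to the
#'   model each iteration.
#' @param psi_step in-plane rotation search step, degrees.
#' @param shift_max translational search radius, px.
#' @param min_changed stop when the fraction of particles changing azimuth
#'   assignment falls below this.
#' @param halfset_mode also reconstruct two half-set models (even/odd
#'   particle index after shuffling with `halfset_seed`) for FSC.
#' @param halfset_seed seed for the half-set shuffle.
#' @return An object of class `refinement_config`.
#' @export
refinement_config <- function(azimuth_step = 5, n_iterations = 5,
                              symmetry_order = 2, lowpass_each_iter = 20,
                              psi_step = 5, shift_max = 8,
                              min_changed = 0.02, halfset_mode = FALSE,
                              halfset_seed = 42) {
  if (360 %% azimuth_step != 0) stop("azimuth_step must divide 360")
  if (symmetry_order < 1) stop("symmetry_order must be >= 1")
  structure(list(azimuth_step = azimuth_step, n_iterations = n_iterations,
                 symmetry_order = symmetry_order,
                 lowpass_each_iter = lowpass_each_iter, psi_step = psi_step,
                 shift_max = shift_max, min_changed = min_changed,
                 halfset_mode = halfset_mode, halfset_seed = halfset_seed),
            class = "refinement_config")
}

#' Top-hat low-pass filter a volume
#'
#' @param volume an [em_volume()].
#' @param lowpass cut-off wavelength in Angstrom.
#' @return Filtered [em_volume()].
#' @export
lowpass_volume <- function(volume, lowpass) {
  vx <- voxel_size(volume)
  d <- dim(volume)
  fx <- fft_freq(d[1], vx); fy <- fft_freq(d[2], vx); fz <- fft_freq(d[3], vx)
  k2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  keep <- k2 <= (1 / lowpass)^2
  ft <- fft(as_plain_array(volume)) * keep
  em_volume(Re(fft(ft, inverse = TRUE)) / prod(d), vx)
}

# ramp (|k|) filter along the first image dimension
ramp_filter <- function(img) {
  n <- nrow(img)
  w <- abs(fft_freq(n))
  Re(mvfft(mvfft(img) * w, inverse = TRUE)) / n
}

#' Cylindrical initial model from an aligned 2D average
#'
#' For every axial row of the average image the 1D transverse profile is
#' ramp-filtered and back-projected at all azimuths (a filtered
#' back-projection of an axially symmetric section from its single
#' projection), yielding a volume that is exactly cylindrically symmetric
#' about z and whose reprojection reproduces the input.  The result is
#' scaled so its azimuth-0 projection matches the input in least squares
#' and low-pass filtered.
#'
#' @param average_image square matrix, filament axis along the second index.
#' @param voxel_size voxel size in Angstrom.
#' @param lowpass low-pass wavelength in Angstrom (default 20).
#' @return An [em_volume()] of size `n^3`.
#' @export
cylindrical_initial_model <- function(average_image, voxel_size,
                                      lowpass = 20) {
  if (!is.matrix(average_image) || nrow(average_image) != ncol(average_image))
    stop("average image must be square")
  n <- nrow(average_image)
  if (all(average_image == 0))
    return(em_volume(array(0, c(n, n, n)), voxel_size))
  cx <- (n + 1) / 2
  alpha <- seq(0, 2 * pi, length.out = 361)[-361]
  rmax <- ceiling(n / 2)
  rgrid <- seq(0, rmax, by = 0.5)
  rad2d <- radius_grid_2d(n, n)
  vol <- array(0, c(n, n, n))
  for (iz in seq_len(n)) {
    g <- ramp_filter(matrix(average_image[, iz], ncol = 1))[, 1]
    pos <- cx + outer(rgrid, cos(alpha))
    v <- matrix(stats::approx(seq_len(n), g, xout = as.numeric(pos),
                              yleft = 0, yright = 0)$y, nrow = length(rgrid))
    fr <- rowMeans(v)
    slice <- stats::approx(rgrid, fr, xout = as.numeric(rad2d),
                           yleft = fr[1], yright = 0)$y
    vol[, , iz] <- slice
  }
  vol <- em_volume(vol, voxel_size)
  # scalar gain so that reprojection matches the input
  pr <- project_about_axis(vol, 0)
  sc <- sum(pr * average_image) / sum(pr * pr)
  if (!is.finite(sc) || sc == 0) sc <- 1
  lowpass_volume(em_volume(as_plain_array(vol) * sc, voxel_size), lowpass)
}

#' Project a volume about the filament axis
#'
#' Rotates the volume about z by `azimuth` degrees and integrates along y.
#'
#' @param volume an [em_volume()].
#' @param azimuth azimuth in degrees (any real; reduced mod 360).
#' @return Projection image, `nx` x `nz` matrix (transverse, axial).
#' @export
project_about_axis <- function(volume, azimuth) {
  cpp_project_z(as.numeric(volume), dim(volume), deg_mod(azimuth))
}

#' Weighted back-projection of an aligned filament particle set
#'
#' Particles are mapped back to the reference frame using their records
#' (undoing shift and in-plane rotation in one resampling), averaged per
#' assigned azimuth, ramp-filtered along the transverse direction and
#' back-projected about z.
#'
#' @param stack a [particle_stack()] (pre-aligned in plane via `records`).
#' @param records alignment records carrying `phi` azimuth assignments.
#' @param voxel_size voxel size in Angstrom (defaults to the stack pixel
#'   size).
#' @return An [em_volume()] of size `n` x `n` x `n_axial`.
#' @export
wbp_filament <- function(stack, records, voxel_size = NULL) {
  arr <- as_plain_array(stack)
  np <- dim(arr)[3]
  check_records(records, np)
  if (anyNA(records$phi)) stop("records carry no azimuth assignments")
  vx <- voxel_size %||% voxel_size(stack)
  phis <- deg_mod(records$phi)
  uphi <- sort(unique(phis))
  if (length(uphi) < 3)
    warning("fewer than 3 distinct azimuths: reconstruction is severely anisotropic")
  n <- dim(arr)[1]; nz <- dim(arr)[2]
  classes <- array(0, c(n, nz, length(uphi)))
  for (ui in seq_along(uphi)) {
    idx <- which(phis == uphi[ui])
    acc <- matrix(0, n, nz)
    for (i in idx)
      acc <- acc + cpp_unalign_image(arr[, , i], records$psi[i],
                                     records$dx[i], records$dy[i])
    classes[, , ui] <- ramp_filter(acc / length(idx))
  }
  w <- rep(pi / length(uphi), length(uphi))
  vol <- cpp_backproject_z(as.numeric(classes), dim(classes), uphi, w)
  em_volume(array(vol, c(n, n, nz)), vx)
}

#' Impose Cn symmetry about the filament axis
#'
#' Averages the `n` azimuthal rotations of the volume by `360 k / n`; the
#' output is invariant under rotation by `360 / n` and the operation is
#' idempotent and norm-non-increasing.
#'
#' @param volume an [em_volume()].
#' @param n symmetry order (`n = 1` is the identity).
#' @return Symmetrized [em_volume()].
#' @export
impose_cn <- function(volume, n) {
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  if (n == 1L) return(volume)
  vx <- voxel_size(volume)
  d <- dim(volume)
  acc <- as.numeric(volume)
  for (k in seq_len(n - 1))
    acc <- acc + cpp_rotate_volume_z(as.numeric(volume), d, 360 * k / n)
  em_volume(array(acc / n, d), vx)
}

#' Iterative projection-matching refinement
#'
#' Per iteration: project the current model at `azimuth_step` increments,
#' exhaustively align every particle to every reference, reconstruct by
#' weighted back-projection, impose Cn symmetry, and low-pass filter.
#' Stops after `n_iterations`, when fewer than `min_changed` of the
#' particles change azimuth assignment, or when the mean alignment score
#' drops in two consecutive iterations (divergence guard).
#'
#' @param stack preprocessed [particle_stack()].
#' @param init initial model ([em_volume()], e.g. from
#'   [cylindrical_initial_model()]).
#' @param cfg a [refinement_config()].
#' @return An object of class `pm_refinement`: list with `model`, `records`,
#'   `log` (per-iteration mean score and fraction of changed assignments),
#'   `config`, `stopped` (reason) and, in half-set mode, `half1`/`half2`.
#' @export
refine_projection_matching <- function(stack, init, cfg = refinement_config()) {
  arr <- as_plain_array(stack)
  px <- voxel_size(stack)
  if (dim(init)[1] != dim(arr)[1] || dim(init)[3] != dim(arr)[2])
    stop("initial model does not match the particle box")
  # with Cn imposed, projections repeat every 360/n degrees: searching one
  # sector is the same exhaustive search over distinct references
  sector <- if (360 %% (cfg$symmetry_order * cfg$azimuth_step) == 0)
    360 / cfg$symmetry_order else 360
  azgrid <- seq(0, sector - cfg$azimuth_step, by = cfg$azimuth_step)
  model <- init
  prev_ref <- NULL
  scores <- changed <- numeric(0)
  stopped <- "max_iterations"
  records <- NULL
  for (it in seq_len(cfg$n_iterations)) {
    refs <- vapply(azgrid, function(a) project_about_axis(model, a),
                   matrix(0, dim(arr)[1], dim(arr)[2]))
    rec <- align_stack(stack, refs, psi_step = cfg$psi_step,
                       shift_max = cfg$shift_max, engine = "polar",
                       ref_azimuths = azgrid)
    if (it == 1L && length(azgrid) > 1) {
      # A cylindrically symmetric start makes every reference identical, so
      # azimuth assignments would be decided by the deterministic tie-break
      # and collapse onto a single view.  When the iteration-1 references
      # are azimuthally degenerate, spread the assignments uniformly over
      # the azimuth grid instead (in-plane rotations and shifts keep their
      # aligned values).  Relative azimuths about a single axis are a gauge
      # freedom of coaxial projection geometry (all Fourier slices share
      # only the meridian), so no data-driven assignment is available at
      # this point; a uniform spread gives an isotropic reconstruction.
      s0 <- sd(refs[, , 1])
      rv <- max(vapply(seq_len(dim(refs)[3])[-1], function(j)
        sd(refs[, , j] - refs[, , 1]), numeric(1)))
      if (s0 == 0 || rv < 0.1 * s0) {
        idx <- ((seq_len(nrow(rec)) - 1L) %% length(azgrid)) + 1L
        rec$ref <- idx
        rec$phi <- azgrid[idx]
      }
    }
    model <- wbp_filament(stack, rec, px)
    if (cfg$symmetry_order > 1) model <- impose_cn(model, cfg$symmetry_order)
    model <- lowpass_volume(model, cfg$lowpass_each_iter)
    scores <- c(scores, mean(rec$score))
    fc <- if (is.null(prev_ref)) 1 else mean(rec$ref != prev_ref)
    changed <- c(changed, fc)
    prev_ref <- rec$ref
    records <- rec
    if (it > 1 && fc < cfg$min_changed) {
      stopped <- "converged"
      break
    }
    if (it > 2 && scores[it] < scores[it - 1] && scores[it - 1] < scores[it - 2]) {
      stopped <- "diverging"
      break
    }
  }
  out <- list(model = model, records = records,
              log = data.frame(iteration = seq_along(scores),
                               mean_score = scores, frac_changed = changed),
              config = cfg, stopped = stopped)
  if (isTRUE(cfg$halfset_mode)) {
    idx <- with_seed(cfg$halfset_seed, sample(dim(arr)[3]))
    for (h in 1:2) {
      sel <- idx[seq_along(idx) %% 2 == (h - 1)]
      hv <- wbp_filament(particle_stack(arr[, , sel, drop = FALSE], px),
                         records[sel, ], px)
      if (cfg$symmetry_order > 1) hv <- impose_cn(hv, cfg$symmetry_order)
      hv <- lowpass_volume(hv, cfg$lowpass_each_iter)
      out[[paste0("half", h)]] <- hv
    }
  }
  class(out) <- "pm_refinement"
  out
}

#' @export
print.pm_refinement <- function(x, ...) {
  cat("<pm_refinement>\n")
  cat(sprintf("  %d particles, C%d, azimuth step %g deg, stopped: %s\n",
              nrow(x$records), x$config$symmetry_order,
              x$config$azimuth_step, x$stopped))
  print(x$log, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pm_refinement <- function(x, ...) {
  plot(x$log$iteration, x$log$mean_score, type = "b", xlab = "iteration",
       ylab = "mean alignment score", ...)
  invisible(x)
}

#' Weighted back-projection of a single-axis tilt series
#'
#' Ramp-filters every tilt image along the direction perpendicular to the
#' tilt axis (y) and back-projects along the recorded tilt angles.  With a
#' limited tilt range the unsampled missing wedge makes the reconstruction
#' anisotropic (worst along the beam direction).
#'
#' @param series a `tilt_series` (see [make_tilt_series()]).
#' @param voxel_size voxel size (defaults to the series pixel size).
#' @return An [em_volume()].
#' @export
wbp_tilt <- function(series, voxel_size = NULL) {
  imgs <- series$images
  if (length(dim(imgs)) != 3L) stop("tilt series images must be a 3D array")
  k <- dim(imgs)[3]
  if (k != length(series$angles))
    stop("angle list does not match the number of images")
  if (k < 3) warning("fewer than 3 tilt images: severe anisotropy")
  vx <- voxel_size %||% series$pixel_size
  filt <- imgs
  for (i in seq_len(k)) filt[, , i] <- ramp_filter(imgs[, , i])
  nz <- dim(imgs)[1]
  w <- rep(pi / k, k)
  vol <- cpp_backproject_tilt(as.numeric(filt), dim(filt), series$angles, w,
                              nz)
  em_volume(array(vol, c(dim(imgs)[1], dim(imgs)[2], nz)), vx)
}

#' Density level enclosing a target volume fraction
#'
#' Returns the iso-level whose superlevel set occupies
#' `fraction * reference_volume`, exact to one voxel (order statistic of
#' the sorted densities, the fixed point of the monotone bisection).
#'
#' @param volume an [em_volume()].
#' @param fraction fraction of the reference volume to enclose, in (0, 1].
#' @param reference_volume reference molecular volume in nm^3 (e.g. from
#'   [mass_to_volume()]).
#' @return The density level.
#' @export
iso_level_for_volume_fraction <- function(volume, fraction, reference_volume) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  vx <- voxel_size(volume)
  voxel_nm3 <- (vx / 10)^3
  target <- fraction * reference_volume / voxel_nm3
  nvox <- length(volume)
  if (target > nvox)
    stop(sprintf("target volume (%.3g nm^3) exceeds the box (%.3g nm^3)",
                 fraction * reference_volume, nvox * voxel_nm3))
  k <- max(1L, round(target))
  sort(as.numeric(volume), decreasing = TRUE)[k]
}

#' Convert protein mass to molecular volume (and back)
#'
#' Uses the standard protein partial specific volume of 1.21 A^3/Da
#' (density 1.35 g/cm^3): `volume[nm^3] = mass[kDa] * 1.21`.
#'
#' @param mass_kda protein mass in kDa.
#' @param specific_volume specific volume in A^3/Da.
#' @return Volume in nm^3 (`mass_to_volume`) or mass in kDa
#'   (`volume_to_mass`).
#' @export
mass_to_volume <- function(mass_kda, specific_volume = 1.21) {
  if (any(mass_kda <= 0)) stop("mass must be positive")
  mass_kda * specific_volume
}

#' @rdname mass_to_volume
#' @param volume_nm3 molecular volume in nm^3.
#' @export
volume_to_mass <- function(volume_nm3, specific_volume = 1.21) {
  if (any(volume_nm3 <= 0)) stop("volume must be positive")
  volume_nm3 / specific_volume
}
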