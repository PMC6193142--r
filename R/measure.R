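# Direct measurements on volumes: radial/axial density profiles, repeat
# distance from axial autocorrelation, maximum transverse FWHM diameter.

#' Azimuthally averaged radial density profile per axial position
#'
#' @param volume an [em_volume()].
#' @param dr radial bin width in voxels.
#' @return list with `r` (bin centres, voxels) and `profile`
#'   (`length(r)` x `nz` matrix of mean densities).
#' @export
radial_density_profile <- function(volume, dr = 0.5) {
  d <- dim(volume)
  rad <- as.numeric(radius_grid_2d(d[1], d[2]))
  rmax <- floor(min(d[1], d[2]) / 2) - 1
  bins <- seq(0, rmax, by = dr)
  bi <- findInterval(rad, bins)
  keep <- bi >= 1 & bi <= length(bins) & rad <= rmax
  bif <- factor(bi[keep], levels = seq_along(bins))
  counts <- tabulate(bi[keep], nbins = length(bins))
  nonempty <- counts > 0
  v <- as_plain_array(volume)
  prof <- matrix(NA_real_, length(bins), d[3])
  for (iz in seq_len(d[3])) {
    sl <- as.numeric(v[, , iz])[keep]
    sums <- vapply(split(sl, bif), sum, numeric(1))
    prof[nonempty, iz] <- sums[nonempty] / counts[nonempty]
  }
  list(r = (bins + dr / 2)[nonempty],
       profile = prof[nonempty, , drop = FALSE])
}

# outer half-maximum crossing radius of a 1D radial profile (linear interp)
outer_half_max_radius <- function(r, p) {
  pm <- max(p)
  if (pm <= 0) return(NA_real_)
  half <- pm / 2
  above <- which(p >= half)
  if (length(above) == 0) return(NA_real_)
  i <- max(above)
  if (i == length(p)) return(r[i])
  # linear interpolation between the last bin above half and the next below
  r[i] + (r[i + 1] - r[i]) * (p[i] - half) / (p[i] - p[i + 1])
}

#' Maximum transverse diameter of a filament model (FWHM)
#'
#' At every axial position the azimuthally averaged radial density profile
#' is computed; the diameter is twice the outer half-maximum crossing
#' radius (the full width at half maximum of the transverse profile).  The
#' maximum over axial positions is returned.
#'
#' @param volume an [em_volume()], filament along z.
#' @param dr radial bin width (voxels).
#' @param min_rel_max only slices whose profile maximum reaches this
#'   fraction of the global profile maximum are measured (excludes
#'   signal-free slices whose half-maximum is noise-defined).
#' @return Diameter in nm (attribute `"per_z"` holds the per-slice values).
#' @export
max_transverse_diameter <- function(volume, dr = 1, min_rel_max = 0.5) {
  rp <- radial_density_profile(volume, dr)
  gmax <- max(rp$profile)
  perz <- vapply(seq_len(ncol(rp$profile)), function(iz) {
    p <- rp$profile[, iz]
    if (max(p) < min_rel_max * gmax) return(NA_real_)
    outer_half_max_radius(rp$r, p)
  }, numeric(1))
  dia_nm <- 2 * perz * voxel_size(volume) / 10
  out <- max(dia_nm, na.rm = TRUE)
  attr(out, "per_z") <- dia_nm
  out
}

#' Mean axial density profile
#'
#' Mean density per z over the in-plane disk of radius `n/2 - 1` voxels.
#'
#' @param volume an [em_volume()].
#' @return Numeric vector of length `nz`.
#' @export
axial_density_profile <- function(volume) {
  d <- dim(volume)
  rad <- radius_grid_2d(d[1], d[2])
  disk <- rad <= min(d[1], d[2]) / 2 - 1
  v <- as_plain_array(volume)
  vapply(seq_len(d[3]), function(iz) mean(v[, , iz][disk]), numeric(1))
}

# first genuine peak of the (linear, demeaned, bias-normalized)
# autocorrelation of a 1D profile: the highest local maximum past the
# central lobe, with parabolic sub-sample interpolation.  Returns the lag
# in samples, or NA when no peak exists (unbeaded profile).
profile_period <- function(p, min_lag = 2L) {
  n <- length(p)
  p <- p - mean(p)
  if (sd(p) == 0) return(NA_real_)
  maxlag <- n - 3L
  ac <- vapply(0:maxlag, function(l)
    sum(p[1:(n - l)] * p[(1 + l):n]) / (n - l), numeric(1))
  ac <- ac / ac[1]
  lags <- 0:maxlag
  locmax <- which(diff(sign(diff(ac))) < 0) + 1L   # interior local maxima
  # skip the central lobe: require the autocorrelation to have dipped first
  dips <- which(ac < 0.5 * ac[1])
  if (length(dips) == 0) return(NA_real_)
  locmax <- locmax[lags[locmax] >= max(min_lag, lags[dips[1]])]
  if (length(locmax) == 0) return(NA_real_)
  # first peak that is comparable to the strongest one (skips weak
  # sub-structure peaks without jumping to a later harmonic repeat)
  strong <- locmax[ac[locmax] >= 0.8 * max(ac[locmax])]
  i <- strong[1]
  off <- if (i > 1 && i < length(ac))
    parabolic_offset(ac[i - 1], ac[i], ac[i + 1]) else 0
  lags[i] + off
}

#' Axial repeat distance of a filament model
#'
#' The bead-to-bead repeat, measured as the first genuine peak of the
#' autocorrelation of the mean axial density profile.
#'
#' @param volume an [em_volume()], filament along z.
#' @return Repeat distance in nm (`NA` if the profile shows no repeat).
#' @export
axial_repeat_distance <- function(volume) {
  lag <- profile_period(axial_density_profile(volume))
  lag * voxel_size(volume) / 10
}
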