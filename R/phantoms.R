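# Synthetic phantom generators.  Every input the analysis pipeline consumes
# can be emulated here, with ground truth recorded so downstream statistics
# can be checked by parameter recovery.  Defaults encode the measured values
# of the beaded microfibril system the package targets: a 59.2 nm axial
# repeat, 20.8 nm maximum bead diameter, four interbead arms, eight chains
# with 2-fold axial symmetry; tomogram bundles with 30 nm centre spacing,
# 11.4 nm filament diameter and 60 nm beading; serial-section fiber stacks
# with 2.06 +/- 1.40 um diameters at 14 nm/px and 100 nm slices.

#' Microfibril repeat phantom specification
#'
#' Geometry of the synthetic beaded repeat: a bead (outer ring plus central
#' core), arms that bow out from the bead, and an interbead region where
#' `n_strands` strand bundles run at a smaller radius.  Strand amplitudes
#' are modulated with period `n_strands / axial_symmetry_order` so the
#' volume has *exact* Cn symmetry of the requested order while retaining
#' higher-order pseudo-symmetry from the uniformly spaced strands
#' (e.g. 4 strands with C2 give a strong 180 degree and a weaker 90 degree
#' rotational correlation).
#'
#' @param periodicity bead-to-bead repeat, nm.
#' @param max_diameter widest (bead) diameter, nm: the transverse FWHM of
#'   the generated volume equals this by construction.
#' @param interbead_diameter transverse FWHM in the interbead, nm.
#' @param n_strands number of strand bundles (arms) in the interbead.
#' @param n_chains chains per repeat (multiple of `axial_symmetry_order`).
#' @param axial_symmetry_order exact Cn about the filament axis.
#' @param region_boundaries named list of fractional z-intervals
#'   (`bead`, `arm`, `interbead`) partitioning the repeat.
#' @param density_amplitude overall density scale (arbitrary units).
#' @return An object of class `phantom_spec`.
#' @export
microfibril_phantom_spec <- function(periodicity = 59.2, max_diameter = 20.8,
                                     interbead_diameter = 14,
                                     n_strands = 4, n_chains = 8,
                                     axial_symmetry_order = 2,
                                     region_boundaries = default_region_boundaries(),
                                     density_amplitude = 1) {
  if (any(c(periodicity, max_diameter, interbead_diameter) <= 0))
    stop("all lengths must be positive")
  if (n_chains %% axial_symmetry_order != 0)
    stop("n_chains must be a multiple of axial_symmetry_order")
  if (n_strands %% axial_symmetry_order != 0)
    stop("n_strands must be a multiple of axial_symmetry_order for exact Cn")
  check_region_boundaries(region_boundaries)
  structure(list(periodicity = periodicity, max_diameter = max_diameter,
                 interbead_diameter = interbead_diameter,
                 n_strands = n_strands, n_chains = n_chains,
                 axial_symmetry_order = axial_symmetry_order,
                 region_boundaries = region_boundaries,
                 density_amplitude = density_amplitude),
            class = "phantom_spec")
}

#' Default fractional region boundaries of the repeat
#'
#' Bead 0-0.30, arms 0.30-0.45 and 0.85-1.0, interbead 0.45-0.85; the bead
#' is centred at fractional position 0.15.
#' @return Named list of interval matrices (rows are `[start, end)`).
#' @export
default_region_boundaries <- function() {
  list(bead = rbind(c(0, 0.30)),
       arm = rbind(c(0.30, 0.45), c(0.85, 1)),
       interbead = rbind(c(0.45, 0.85)))
}

check_region_boundaries <- function(rb) {
  iv <- do.call(rbind, rb)
  if (any(iv[, 1] < 0) || any(iv[, 2] > 1) || any(iv[, 2] <= iv[, 1]))
    stop("region boundaries must be increasing intervals within [0, 1)")
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (any(iv[-1, 1] < iv[-nrow(iv), 2] - 1e-9))
    stop("region boundaries overlap")
  if (abs(sum(iv[, 2] - iv[, 1]) - 1) > 1e-9)
    stop("region boundaries must partition [0, 1)")
  invisible(rb)
}

# circular distance on the fractional repeat coordinate
frac_dist <- function(t, t0) {
  d <- abs(t - t0)
  pmin(d, 1 - d)
}

#' Generate a beaded microfibril repeat phantom
#'
#' Evaluates the analytic density of [microfibril_phantom_spec()] on a
#' cubic grid.  The axial profile is periodic with the spec periodicity, a
#' bead is centred mid-box, and the result has exact Cn symmetry about z.
#' The volume is hollow: in the interbead the on-axis density is far below
#' the strand density.
#'
#' @param spec a [microfibril_phantom_spec()].
#' @param box_px cube edge, voxels; the box must hold at least one repeat.
#' @param voxel_size voxel size in Angstrom.
#' @return An [em_volume()] with the spec attached as attribute
#'   `"phantom_spec"`.
#' @export
make_microfibril_phantom <- function(spec = microfibril_phantom_spec(),
                                     box_px = 128, voxel_size = 8) {
  p_ang <- spec$periodicity * 10
  if (box_px * voxel_size < p_ang)
    stop(sprintf("box too small for one repeat: %g A box < %g A periodicity",
                 box_px * voxel_size, p_ang))
  n <- as.integer(box_px)
  cx <- (n + 1) / 2
  d1 <- (seq_len(n) - cx) * voxel_size          # Angstrom offsets
  xg <- matrix(d1, n, n)
  yg <- matrix(d1, n, n, byrow = TRUE)

  sigma_ring <- 20
  sigma_core <- 12
  sigma_strand <- 9
  hm <- sqrt(2 * log(2))                        # half-max sigma multiplier
  r_ring <- spec$max_diameter * 10 / 2 - hm * sigma_ring
  r_ib <- spec$interbead_diameter * 10 / 2 - hm * sigma_strand
  if (r_ring <= 0 || r_ib <= 0) stop("diameters too small for the bead model")

  r2 <- xg^2 + yg^2
  # the bead ring carries a mild Cn azimuthal modulation (n = the exact
  # symmetry order) so the bead region is orientable in projections
  beta <- atan2(yg, xg)
  ring_base <- exp(-(sqrt(r2) - r_ring)^2 / (2 * sigma_ring^2))
  core <- 0.6 * exp(-r2 / (2 * sigma_core^2))

  ns <- spec$n_strands
  period_amp <- ns %/% spec$axial_symmetry_order
  amp <- ifelse((seq_len(ns) - 1) %% period_amp == 0, 1, 0.8)
  alpha <- (seq_len(ns) - 1) * 2 * pi / ns

  bead <- spec$region_boundaries$bead[1, ]
  t_bead <- mean(bead)
  hw <- (bead[2] - bead[1]) / 2

  # Interbead centred mid-box (fractional phase 0.65 at the box centre), so
  # a 128-voxel box holds two full beads at +/- half a period from centre.
  # The axial structure is deliberately polar (asymmetric banding): the
  # bead envelope falls off faster on one side, and the arm bow and strand
  # amplitude carry odd harmonics, so the two ends of the repeat are
  # distinguishable in projections (no psi/psi+180 degeneracy).
  vol <- array(0, c(n, n, n))
  hw_lo <- 0.65 * hw
  hw_hi <- 1.35 * hw
  for (iz in seq_len(n)) {
    zc <- (iz - cx) * voxel_size
    t <- (zc / p_ang + 0.65) %% 1
    tau <- (t - t_bead + 0.5) %% 1 - 0.5      # signed offset from bead centre
    hws <- if (tau < 0) hw_lo else hw_hi
    env_b <- if (abs(tau) < hws) 0.5 * (1 + cos(pi * tau / hws)) else 0
    w_s <- 1 - env_b
    # gentle periodic twist of the whole azimuthal pattern: the filament is
    # chiral (as protein assemblies are), so projections at azimuth phi and
    # -phi are genuinely different and orientations are not mirror-degenerate
    gam <- (20 * pi / 180) * sin(2 * pi * tau)
    slice <- env_b * (ring_base *
      (1 + 0.15 * cos(spec$axial_symmetry_order * (beta - gam))) + core)
    if (w_s > 0) {
      bow <- 0.5 + 0.3 * cos(2 * pi * tau) + 0.25 * sin(4 * pi * tau)
      bow <- max(0, min(1, bow))
      r_s <- r_ib + (r_ring - r_ib) * bow
      gain <- 1 + 0.2 * sin(2 * pi * tau)
      sl <- 0
      for (k in seq_len(ns)) {
        dx <- xg - r_s * cos(alpha[k] + gam)
        dy <- yg - r_s * sin(alpha[k] + gam)
        sl <- sl + amp[k] * exp(-(dx^2 + dy^2) / (2 * sigma_strand^2))
      }
      slice <- slice + 0.9 * w_s * gain * sl
    }
    vol[, , iz] <- spec$density_amplitude * slice
  }
  out <- em_volume(vol, voxel_size)
  attr(out, "phantom_spec") <- spec
  out
}

#' Simulate a projection dataset from a volume
#'
#' Each particle is a projection of the volume at a uniform random azimuth,
#' rotated in plane by a uniform random psi, shifted by uniform sub-pixel
#' shifts up to `shift_max`, optionally multiplied by a CTF in Fourier
#' space, with additive zero-mean Gaussian noise of variance
#' `signal variance / snr`.  Identical seeds give bit-identical stacks.
#'
#' @param volume an [em_volume()].
#' @param n number of particles.
#' @param snr signal-to-noise variance ratio (`Inf` disables noise).
#' @param shift_max maximum shift, px.
#' @param seed RNG seed.
#' @param ctf optional [ctf_params()] applied (with its sign) to each clean
#'   projection; the pixel size is taken from the volume.
#' @return list with `stack` (a [particle_stack()]) and `truth` alignment
#'   records (`psi`, `dx`, `dy`, `phi`).
#' @export
make_projection_dataset <- function(volume, n, snr = 0.3, shift_max = 8,
                                    seed = 1, ctf = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.numeric(snr) || snr <= 0) stop("snr must be positive")
  vx <- voxel_size(volume)
  d <- dim(volume)
  ctf_mult <- NULL
  if (!is.null(ctf)) {
    ctf$pixel_size <- vx
    fx <- fft_freq(d[1], vx)
    fz <- fft_freq(d[3], vx)
    k <- sqrt(outer(fx^2, fz^2, `+`))
    ctf_mult <- ctf_eval(ctf, k)
    ctf_mult[1, 1] <- 1
  }
  with_seed(seed, {
    phi <- runif(n, 0, 360)
    psi <- runif(n, 0, 360)
    dx <- runif(n, -shift_max, shift_max)
    dy <- runif(n, -shift_max, shift_max)
    stack <- array(0, c(d[1], d[3], n))
    for (i in seq_len(n)) {
      img <- project_about_axis(volume, phi[i])
      if (!is.null(ctf_mult))
        img <- Re(fft(fft(img) * ctf_mult, inverse = TRUE)) / length(img)
      img <- cpp_apply_inplane(img, psi[i], dx[i], dy[i])
      if (is.finite(snr)) {
        sig_sd <- sd(as.numeric(img))
        img <- img + rnorm(length(img), 0, sig_sd / sqrt(snr))
      }
      stack[, , i] <- img
    }
    truth <- new_records(n)
    truth$psi <- psi; truth$dx <- dx; truth$dy <- dy; truth$phi <- phi
    truth$ref <- NA_integer_; truth$score <- NA_real_
    list(stack = particle_stack(stack, vx), truth = truth)
  })
}

#' Single-axis tilt series of a volume
#'
#' One projection per tilt angle about the y axis (beam along z), angles
#' stored with the images.  The default range reproduces a +/-65 degree,
#' 1 degree-step acquisition (131 images), leaving a missing wedge.
#'
#' @param volume an [em_volume()].
#' @param angle_min,angle_max tilt range in degrees (`angle_min < angle_max`).
#' @param step tilt step in degrees (> 0).
#' @return An object of class `tilt_series`: list of `images`
#'   (`nx` x `ny` x `k`), `angles`, `pixel_size`.
#' @export
make_tilt_series <- function(volume, angle_min = -65, angle_max = 65,
                             step = 1) {
  if (!(angle_min < angle_max)) stop("empty angle range: need angle_min < angle_max")
  if (step <= 0) stop("step must be positive")
  angles <- seq(angle_min, angle_max, by = step)
  d <- dim(volume)
  imgs <- array(0, c(d[1], d[2], length(angles)))
  for (i in seq_along(angles))
    imgs[, , i] <- cpp_project_tilt(as.numeric(volume), d, angles[i])
  structure(list(images = imgs, angles = angles,
                 pixel_size = voxel_size(volume)),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  cat(sprintf("<tilt_series> %d images %d x %d px, %g..%g deg\n",
              length(x$angles), dim(x$images)[1], dim(x$images)[2],
              min(x$angles), max(x$angles)))
  invisible(x)
}

#' Packed-filament tomogram phantom specification
#'
#' @param n_filaments number of filaments, or `NULL` to fill the box.
#' @param mean_spacing nearest-neighbour centre-to-centre distance, nm.
#' @param filament_diameter transverse FWHM of each filament, nm.
#' @param orientation_mode `"parallel"` (aligned bundle) or `"meshwork"`.
#' @param orientation_dispersion SD of the tangent tilt about the bundle
#'   axis, degrees (defaults: 2 for parallel, 30 for meshwork).
#' @param repeat_period axial beading period, nm.
#' @param position_jitter SD of the lattice jitter, nm.
#' @param modulation_depth relative amplitude of the axial beading.
#' @return An object of class `tomogram_phantom_spec`.
#' @export
tomogram_phantom_spec <- function(n_filaments = NULL, mean_spacing = 30,
                                  filament_diameter = 11.4,
                                  orientation_mode = c("parallel", "meshwork"),
                                  orientation_dispersion = NULL,
                                  repeat_period = 60, position_jitter = 0.3,
                                  modulation_depth = 0.3) {
  orientation_mode <- match.arg(orientation_mode)
  if (mean_spacing <= filament_diameter)
    stop("mean_spacing must exceed filament_diameter")
  disp <- orientation_dispersion %||%
    if (orientation_mode == "parallel") 2 else 30
  if (disp < 0) stop("orientation_dispersion must be >= 0")
  structure(list(n_filaments = n_filaments, mean_spacing = mean_spacing,
                 filament_diameter = filament_diameter,
                 orientation_mode = orientation_mode,
                 orientation_dispersion = disp,
                 repeat_period = repeat_period,
                 position_jitter = position_jitter,
                 modulation_depth = modulation_depth),
            class = "tomogram_phantom_spec")
}

#' Generate a packed-filament tomogram phantom
#'
#' Filament centrelines are placed on a jittered hexagonal packing with the
#' requested mean nearest-neighbour spacing, tilted per the orientation
#' mode (tilt angles drawn N(0, dispersion), random tilt azimuths, lines
#' pinned at mid-height), and rendered as Gaussian tubes whose transverse
#' FWHM equals the filament diameter, with raised-cosine axial beading of
#' the requested period and random per-filament phase.
#'
#' @param spec a [tomogram_phantom_spec()].
#' @param box cube edge in voxels.
#' @param voxel_size voxel size in nm.
#' @param seed RNG seed.
#' @return list with `volume` (an [em_volume()]), `traces` (truth
#'   centrelines: `trace`, `idx`, `x`, `y`, `z` in voxels), `tangents`
#'   (truth unit tangents with tilt angles) and `spec`.
#' @export
make_tomogram_phantom <- function(spec = tomogram_phantom_spec(), box = 220,
                                  voxel_size = 1, seed = 1) {
  s_vox <- spec$mean_spacing / voxel_size
  margin <- s_vox / 2 + 4
  if (box - 2 * margin < s_vox)
    stop("infeasible packing: box too small for two filaments at mean_spacing")
  # hexagonal packing
  xs <- seq(margin, box - margin, by = s_vox)
  ys <- seq(margin, box - margin, by = s_vox * sqrt(3) / 2)
  cen <- do.call(rbind, lapply(seq_along(ys), function(j) {
    xo <- xs + if (j %% 2 == 0) s_vox / 2 else 0
    xo <- xo[xo <= box - margin + 1e-9]
    cbind(xo, ys[j])
  }))
  if (!is.null(spec$n_filaments)) {
    if (spec$n_filaments > nrow(cen))
      stop(sprintf("infeasible packing: %d filaments requested, %d fit",
                   spec$n_filaments, nrow(cen)))
    cen <- cen[seq_len(spec$n_filaments), , drop = FALSE]
  }
  nf <- nrow(cen)
  if (nf < 2) stop("infeasible packing: fewer than 2 filaments fit")

  sigma <- (spec$filament_diameter / voxel_size) / (2 * sqrt(2 * log(2)))
  per_vox <- spec$repeat_period / voxel_size
  zmid <- (box + 1) / 2

  with_seed(seed, {
    cen <- cen + matrix(rnorm(2 * nf, 0, spec$position_jitter / voxel_size),
                        nf, 2)
    tilt <- rnorm(nf, 0, spec$orientation_dispersion)
    beta <- runif(nf, 0, 2 * pi)
    phase <- runif(nf, 0, 2 * pi)
    tg <- cbind(sin(tilt * pi / 180) * cos(beta),
                sin(tilt * pi / 180) * sin(beta),
                cos(tilt * pi / 180))

    vol <- array(0, c(box, box, box))
    win <- ceiling(4 * sigma)
    xs_idx <- seq_len(box)
    traces <- vector("list", nf)
    for (f in seq_len(nf)) {
      d <- tg[f, ]
      for (iz in xs_idx) {
        # line point at this z
        lz <- (iz - zmid) / d[3]
        px <- cen[f, 1] + lz * d[1]
        py <- cen[f, 2] + lz * d[2]
        i0 <- max(1, floor(px - win - 2)); i1 <- min(box, ceiling(px + win + 2))
        j0 <- max(1, floor(py - win - 2)); j1 <- min(box, ceiling(py + win + 2))
        if (i0 > i1 || j0 > j1) next
        ii <- i0:i1; jj <- j0:j1
        # offsets from the line's mid-height anchor point
        vx <- matrix(ii - cen[f, 1], length(ii), length(jj))
        vy <- matrix(jj - cen[f, 2], length(ii), length(jj), byrow = TRUE)
        vz <- iz - zmid
        # exact 3D perpendicular distance to the line
        ell <- vx * d[1] + vy * d[2] + vz * d[3]
        perp2 <- pmax(vx^2 + vy^2 + vz^2 - ell^2, 0)
        a <- 1 + spec$modulation_depth *
          cos(2 * pi * ell / per_vox + phase[f])
        vol[ii, jj, iz] <- vol[ii, jj, iz] +
          a * exp(-perp2 / (2 * sigma^2))
      }
      zt <- seq(1, box, by = 2)
      lzt <- (zt - zmid) / d[3]
      traces[[f]] <- data.frame(trace = f, idx = seq_along(zt),
                                x = cen[f, 1] + lzt * d[1],
                                y = cen[f, 2] + lzt * d[2], z = zt)
    }
    traces <- do.call(rbind, traces)
    keep <- traces$x >= 1 & traces$x <= box & traces$y >= 1 & traces$y <= box
    traces <- traces[keep, ]
    tangents <- data.frame(trace = seq_len(nf), tx = tg[, 1], ty = tg[, 2],
                           tz = tg[, 3], tilt_deg = tilt)
    list(volume = em_volume(vol, voxel_size * 10),
         traces = structure(traces, voxel_size_nm = voxel_size),
         tangents = tangents, spec = spec, seed = seed)
  })
}

#' Serial-section fiber stack specification
#'
#' Diameters are drawn from a normal distribution truncated at 0.1 um whose
#' post-truncation mean and SD equal `diameter_mean` / `diameter_sd` (the
#' parent parameters are solved for internally).
#'
#' @param n_fibers number of fibers.
#' @param diameter_mean,diameter_sd target mean and SD of the true
#'   diameters, um.
#' @param n_slices number of serial sections.
#' @param pixel_size image pixel size, nm/px.
#' @param slice_thickness section thickness, nm.
#' @param section_obliquity angle between the fiber axis and the section
#'   normal, degrees (< 90); ellipse major axes are inflated by
#'   `1 / cos(obliquity)` while minor axes equal the true diameters.
#' @return An object of class `fiber_stack_spec`.
#' @export
fiber_stack_spec <- function(n_fibers = 300, diameter_mean = 2.06,
                             diameter_sd = 1.40, n_slices = 1500,
                             pixel_size = 14, slice_thickness = 100,
                             section_obliquity = 30) {
  if (n_fibers < 1) stop("n_fibers must be >= 1")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (section_obliquity >= 90 || section_obliquity < 0)
    stop("section_obliquity must be in [0, 90)")
  structure(list(n_fibers = n_fibers, diameter_mean = diameter_mean,
                 diameter_sd = diameter_sd, n_slices = n_slices,
                 pixel_size = pixel_size, slice_thickness = slice_thickness,
                 section_obliquity = section_obliquity),
            class = "fiber_stack_spec")
}

# parent normal parameters whose truncation at `lo` has the target moments
truncnorm_parent <- function(mean_t, sd_t, lo = 0.1) {
  moments <- function(mu, sig) {
    a <- (lo - mu) / sig
    lam <- dnorm(a) / (1 - pnorm(a))
    m <- mu + sig * lam
    v <- sig^2 * (1 + a * lam - lam^2)
    c(m, sqrt(v))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    (mm[1] - mean_t)^2 + (mm[2] - sd_t)^2
  }
  fit <- optim(c(mean_t, log(sd_t)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# exact inverse-CDF sampler for the lower-truncated normal (one uniform
# per draw, so the draw count is deterministic)
rtruncnorm_lo <- function(n, mu, sigma, lo = 0.1) {
  p0 <- pnorm((lo - mu) / sigma)
  qnorm(p0 + runif(n) * (1 - p0)) * sigma + mu
}

#' Generate serial-section fiber cross-section contours
#'
#' Each fiber is an obliquely sectioned cylinder: its contour in every
#' slice is an ellipse whose minor axis equals the true fiber diameter and
#' whose major axis is inflated by `1/cos(section_obliquity)`, at a random
#' in-plane orientation per fiber, with small radial contour noise.
#'
#' @param spec a [fiber_stack_spec()].
#' @param seed RNG seed.
#' @param slices slice indices to render (default: all `n_slices`; pass a
#'   stride to economize on contour volume).
#' @param points_per_contour contour points per fiber per slice.
#' @param contour_noise radial contour noise as a fraction of the radius.
#' @return list with `contours` (`slice`, `fiber`, `x`, `y` in px), `truth`
#'   (`fiber`, `diameter_um`) and `spec`.
#' @export
make_fiber_sections <- function(spec = fiber_stack_spec(), seed = 3,
                                slices = NULL,
                                points_per_contour = 40,
                                contour_noise = 0.005) {
  slices <- slices %||% seq_len(spec$n_slices)
  if (any(slices < 1 | slices > spec$n_slices))
    stop("slice indices out of range")
  par <- truncnorm_parent(spec$diameter_mean, spec$diameter_sd)
  obl <- spec$section_obliquity * pi / 180
  with_seed(seed, {
    d_um <- rtruncnorm_lo(spec$n_fibers, par["mu"], par["sigma"])
    field <- 4096
    cx <- runif(spec$n_fibers, 0, field)
    cy <- runif(spec$n_fibers, 0, field)
    ang <- runif(spec$n_fibers, 0, pi)
    u <- 2 * pi * (seq_len(points_per_contour) - 1) / points_per_contour
    res <- vector("list", length(slices) * spec$n_fibers)
    idx <- 1L
    for (s in slices) {
      for (f in seq_len(spec$n_fibers)) {
        b <- d_um[f] * 1000 / 2 / spec$pixel_size      # minor semi-axis, px
        a <- b / cos(obl)
        noise <- 1 + rnorm(points_per_contour, 0, contour_noise)
        ex <- a * cos(u) * noise
        ey <- b * sin(u) * noise
        res[[idx]] <- data.frame(
          slice = s, fiber = f,
          x = cx[f] + cos(ang[f]) * ex - sin(ang[f]) * ey,
          y = cy[f] + sin(ang[f]) * ex + cos(ang[f]) * ey)
        idx <- idx + 1L
      }
    }
    list(contours = do.call(rbind, res),
         truth = data.frame(fiber = seq_len(spec$n_fibers),
                            diameter_um = d_um),
         spec = spec, seed = seed)
  })
}
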