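# Volume/tomogram filament statistics and serial-section fiber diameter
# measurement.

# structure tensor ridge direction at a point: eigenvector of the smallest
# eigenvalue of the summed gradient outer products in a local cube
ridge_direction <- function(vol, dim, p, half = 2) {
  g <- expand.grid(dx = -half:half, dy = -half:half, dz = -half:half)
  px <- p[1] + g$dx; py <- p[2] + g$dy; pz <- p[3] + g$dz
  s <- function(ox, oy, oz)
    cpp_interp3(vol, dim, px + ox, py + oy, pz + oz)
  gx <- (s(1, 0, 0) - s(-1, 0, 0)) / 2
  gy <- (s(0, 1, 0) - s(0, -1, 0)) / 2
  gz <- (s(0, 0, 1) - s(0, 0, -1)) / 2
  J <- matrix(c(sum(gx * gx), sum(gx * gy), sum(gx * gz),
                sum(gx * gy), sum(gy * gy), sum(gy * gz),
                sum(gx * gz), sum(gy * gz), sum(gz * gz)), 3, 3)
  ev <- eigen(J, symmetric = TRUE)
  ev$vectors[, 3]
}

# orthonormal basis perpendicular to a unit vector
perp_basis <- function(d) {
  a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- a - sum(a * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# intensity centroid in the plane perpendicular to d within search_radius
recenter_point <- function(vol, dim, p, d, search_radius) {
  b <- perp_basis(d)
  g <- expand.grid(u = seq(-search_radius, search_radius, by = 1),
                   v = seq(-search_radius, search_radius, by = 1))
  g <- g[g$u^2 + g$v^2 <= search_radius^2, ]
  px <- p[1] + g$u * b$e1[1] + g$v * b$e2[1]
  py <- p[2] + g$u * b$e1[2] + g$v * b$e2[2]
  pz <- p[3] + g$u * b$e1[3] + g$v * b$e2[3]
  w <- pmax(cpp_interp3(vol, dim, px, py, pz), 0)
  if (sum(w) <= 0) return(list(p = p, peak = 0))
  cu <- sum(w * g$u) / sum(w)
  cv <- sum(w * g$v) / sum(w)
  list(p = p + cu * b$e1 + cv * b$e2, peak = max(w))
}

#' Trace filaments through a volume from seed points
#'
#' From each seed the tracer steps along the local intensity-ridge
#' direction (the eigenvector of the smallest eigenvalue of the local
#' structure tensor), re-centring on the perpendicular intensity centroid
#' within `search_radius` at every step, in both directions.  Tracing
#' stops at the volume edge or when the local ridge intensity falls below
#' `contrast_floor` times the volume maximum.  Seeds in background give an
#' empty, flagged trace.
#'
#' @param volume an [em_volume()] (voxel size attribute in Angstrom).
#' @param seeds data.frame with voxel coordinates `x`, `y`, `z` (1-based).
#' @param step step length in voxels.
#' @param search_radius re-centring radius in voxels.
#' @param contrast_floor termination threshold, fraction of the volume
#'   maximum.
#' @return data.frame of centreline points (`trace`, `idx`, `x`, `y`, `z`)
#'   with the per-seed flags in attribute `"empty"`; voxel size (nm) in
#'   attribute `"voxel_size_nm"`.
#' @export
trace_filaments <- function(volume, seeds, step = 2, search_radius = 4,
                            contrast_floor = 0.2) {
  v <- as.numeric(volume)
  d <- dim(volume)
  floor_abs <- contrast_floor * max(v)
  # keep the structure-tensor cube and re-centring disk inside the volume
  margin <- search_radius + 3
  inside <- function(p) all(p > margin) && all(p < d - margin + 1)
  traces <- vector("list", nrow(seeds))
  empty <- logical(nrow(seeds))
  for (s in seq_len(nrow(seeds))) {
    p0 <- as.numeric(seeds[s, c("x", "y", "z")])
    if (!inside(p0)) { empty[s] <- TRUE; next }
    d0 <- ridge_direction(v, d, p0)
    if (d0[3] < 0) d0 <- -d0
    rc <- recenter_point(v, d, p0, d0, search_radius)
    if (rc$peak < floor_abs) { empty[s] <- TRUE; next }
    p0 <- rc$p
    run <- function(dirsign) {
      pts <- list()
      p <- p0
      dirv <- d0 * dirsign
      for (i in seq_len(ceiling(1.2 * max(d) / step))) {
        rd <- ridge_direction(v, d, p)
        dt <- sum(rd * dirv)
        if (abs(dt) < 0.5) break          # ridge direction ambiguous
        if (dt < 0) rd <- -rd
        dirv <- rd
        pn <- p + step * dirv
        if (!inside(pn)) break
        rc <- recenter_point(v, d, pn, dirv, search_radius)
        if (rc$peak < floor_abs) break
        p <- rc$p
        pts[[i]] <- p
      }
      pts
    }
    fwd <- run(1)
    bwd <- run(-1)
    pts <- c(rev(bwd), list(p0), fwd)
    m <- do.call(rbind, pts)
    traces[[s]] <- data.frame(trace = s, idx = seq_len(nrow(m)),
                              x = m[, 1], y = m[, 2], z = m[, 3])
  }
  out <- do.call(rbind, traces[!vapply(traces, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(trace = integer(0), idx = integer(0), x = numeric(0),
                      y = numeric(0), z = numeric(0))
  structure(out, empty = empty, voxel_size_nm = voxel_size(volume) / 10)
}

# unit tangents of one trace by central differences
trace_tangents <- function(tr) {
  n <- nrow(tr)
  P <- as.matrix(tr[, c("x", "y", "z")])
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  Tm <- rbind(P[2, ] - P[1, ],
              if (n > 2) P[3:n, , drop = FALSE] - P[1:(n - 2), , drop = FALSE],
              P[n, ] - P[n - 1, ])
  Tm / sqrt(rowSums(Tm^2))
}

#' Relative orientation and nearest-neighbour spacing of filament traces
#'
#' The bundle direction is the principal eigenvector of the summed tangent
#' outer products over all traces.  Each filament's relative angle is
#' `acos(|mean tangent . bundle|)` in `[0, 90]` degrees.  Spacing is the
#' per-filament minimum, over neighbouring traces, of the mean
#' perpendicular distance between matched axial samples.
#'
#' @param traces trace table (`trace`, `idx`, `x`, `y`, `z`), e.g. from
#'   [trace_filaments()] or phantom truth; voxel size (nm) read from the
#'   `"voxel_size_nm"` attribute (default 1).
#' @return list with `per_filament` (data.frame: `trace`,
#'   `rel_angle_deg`, `nn_dist_nm`), `bundle_direction`, and `summary`
#'   (means, SDs, angle RMS about the bundle axis, histogram of spacings).
#'   With a single trace the spacing is `NA`, flagged.
#' @export
orientation_and_spacing <- function(traces) {
  ids <- unique(traces$trace)
  if (length(ids) < 1) stop("no traces")
  vs <- attr(traces, "voxel_size_nm") %||% 1
  trs <- lapply(ids, function(i) traces[traces$trace == i, , drop = FALSE])
  tans <- lapply(trs, trace_tangents)
  J <- matrix(0, 3, 3)
  for (tm in tans) J <- J + crossprod(tm)
  bundle <- eigen(J, symmetric = TRUE)$vectors[, 1]
  mean_tan <- t(vapply(tans, function(tm) {
    mt <- colMeans(tm)
    mt / sqrt(sum(mt^2))
  }, numeric(3)))
  rel <- acos(pmin(abs(as.numeric(mean_tan %*% bundle)), 1)) * 180 / pi

  nn <- rep(NA_real_, length(ids))
  if (length(ids) >= 2) {
    # mean perpendicular distance from trace i's samples to trace j's line
    # at matched z
    for (a in seq_along(ids)) {
      pa <- trs[[a]]
      best <- Inf
      for (b in seq_along(ids)) {
        if (b == a) next
        pb <- trs[[b]]
        zr <- range(pb$z)
        sel <- pa$z >= zr[1] & pa$z <= zr[2]
        if (sum(sel) < 2) next
        xb <- stats::approx(pb$z, pb$x, xout = pa$z[sel])$y
        yb <- stats::approx(pb$z, pb$y, xout = pa$z[sel])$y
        tb <- colMeans(trace_tangents(pb))
        tb <- tb / sqrt(sum(tb^2))
        dxv <- pa$x[sel] - xb
        dyv <- pa$y[sel] - yb
        # remove the component along the neighbour's tangent
        dot <- dxv * tb[1] + dyv * tb[2]
        d2 <- pmax(dxv^2 + dyv^2 - dot^2, 0)
        m <- mean(sqrt(d2))
        if (m < best) best <- m
      }
      if (is.finite(best)) nn[a] <- best * vs
    }
  }
  per <- data.frame(trace = ids, rel_angle_deg = rel, nn_dist_nm = nn)
  h <- if (any(is.finite(nn)))
    graphics::hist(nn[is.finite(nn)], breaks = "Sturges", plot = FALSE) else NULL
  list(per_filament = per, bundle_direction = bundle,
       summary = list(mean_angle_deg = mean(rel),
                      sd_angle_deg = sd(rel),
                      rms_angle_deg = sqrt(mean(rel^2)),
                      mean_spacing_nm = mean(nn, na.rm = TRUE),
                      sd_spacing_nm = sd(nn[is.finite(nn)]),
                      spacing_flagged = !any(is.finite(nn)),
                      spacing_hist = h))
}

#' Diameter and axial periodicity of a traced filament
#'
#' The diameter is the full width at half maximum of the mean radial
#' intensity profile perpendicular to the trace; the periodicity is the
#' first genuine peak of the autocorrelation of the intensity sampled
#' along the centreline.  Both are returned in nm.
#'
#' @param volume the [em_volume()] the trace runs through.
#' @param trace one trace (rows of a trace table with a single trace id).
#' @param r_max radial profile extent in voxels.
#' @param dr radial step in voxels.
#' @param n_angles azimuthal samples per radius.
#' @return list with `diameter_nm`, `periodicity_nm` (`NA` with
#'   `periodicity_flag` when the profile shows no repeat or the trace is
#'   too short) and `n_samples`.
#' @export
filament_geometry <- function(volume, trace, r_max = 12, dr = 0.5,
                              n_angles = 12) {
  v <- as.numeric(volume)
  d <- dim(volume)
  vs <- voxel_size(volume) / 10       # nm per voxel
  tr <- trace[order(trace$idx), , drop = FALSE]
  if (nrow(tr) < 2) stop("trace needs at least 2 points")
  tans <- trace_tangents(tr)
  radii <- seq(0, r_max, by = dr)
  ang <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  prof <- matrix(0, length(radii), nrow(tr))
  axial <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    p <- as.numeric(tr[i, c("x", "y", "z")])
    b <- perp_basis(tans[i, ])
    dirs <- outer(cos(ang), b$e1) + outer(sin(ang), b$e2)   # n_angles x 3
    px <- outer(radii, dirs[, 1]) + p[1]
    py <- outer(radii, dirs[, 2]) + p[2]
    pz <- outer(radii, dirs[, 3]) + p[3]
    vals <- matrix(cpp_interp3(v, d, as.numeric(px), as.numeric(py),
                               as.numeric(pz)), length(radii))
    prof[, i] <- rowMeans(vals)
    axial[i] <- vals[1, 1]
  }
  pr <- rowMeans(prof)
  dia <- 2 * outer_half_max_radius(radii, pr) * vs
  # arc-length sample spacing (voxels)
  P <- as.matrix(tr[, c("x", "y", "z")])
  seg <- sqrt(rowSums(diff(P)^2))
  ds <- stats::median(seg)
  lag <- profile_period(axial)
  per <- lag * ds * vs
  flag <- if (is.na(per)) "no repeat detected" else "ok"
  list(diameter_nm = dia, periodicity_nm = per, periodicity_flag = flag,
       n_samples = nrow(tr))
}

#' Direct least-squares ellipse fit and minor diameter
#'
#' Fits a conic constrained to an ellipse (the direct least-squares method
#' with the 4ac - b^2 = 1 constraint) to contour points, after isotropic
#' normalization for conditioning.  For an obliquely sectioned circular
#' cylinder the minor axis equals the true cylinder diameter, which is why
#' fiber diameters are measured as `2 * minor semi-axis * pixel_size`.
#' The fit is exactly invariant to rotation and translation of the contour.
#'
#' @param points data.frame or matrix of contour points (`x`, `y` in px),
#'   at least 6, not collinear.
#' @param pixel_size pixel size in nm/px.
#' @return list with `center`, `major`, `minor` (semi-axes, px),
#'   `angle_deg`, `minor_diameter_um` and `residual` (rms algebraic
#'   distance).
#' @export
fit_ellipse_minor_diameter <- function(points, pixel_size = 14) {
  pts <- as.matrix(points[, c("x", "y")])
  if (nrow(pts) < 6) stop("need at least 6 contour points")
  mu <- colMeans(pts)
  ctr <- sweep(pts, 2, mu)
  sc <- sqrt(mean(rowSums(ctr^2)))
  if (sc == 0) stop("degenerate contour")
  z <- ctr / sc
  x <- z[, 1]; y <- z[, 2]
  if (abs(stats::cor(x, y)) > 1 - 1e-12 || sd(x) < 1e-12 || sd(y) < 1e-12)
    stop("collinear contour points")
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no ellipse fits these points (hyperbolic fit)")
  a1 <- Re(ev$vectors[, ok[1]])
  coefs <- c(a1, as.numeric(Tm %*% a1))   # a b c d e f in normalized frame
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- B^2 - 4 * A * C
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s1 <- num * ((A + C) + sqrt((A - C)^2 + B^2))
  s2 <- num * ((A + C) - sqrt((A - C)^2 + B^2))
  ax1 <- -sqrt(s1) / den
  ax2 <- -sqrt(s2) / den
  semi <- sort(c(ax1, ax2), decreasing = TRUE) * sc   # back to px
  angle <- 0.5 * atan2(B, A - C) * 180 / pi
  # rms algebraic residual on the normalized frame
  res <- sqrt(mean((D1 %*% coefs[1:3] + D2 %*% coefs[4:6])^2))
  center <- c(x0, y0) * sc + mu
  list(center = center, major = semi[1], minor = semi[2],
       angle_deg = angle, minor_diameter_um = 2 * semi[2] * pixel_size / 1000,
       residual = res)
}

#' Fit ellipses to all contours of a fiber-section set
#'
#' @param contours data.frame (`slice`, `fiber`, `x`, `y`).
#' @param pixel_size nm/px.
#' @return data.frame with one row per (slice, fiber): minor/major semi-axes
#'   and `minor_diameter_um`.
#' @export
fit_fiber_contours <- function(contours, pixel_size = 14) {
  keys <- unique(contours[, c("slice", "fiber")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- contours$slice == keys$slice[i] & contours$fiber == keys$fiber[i]
    fit <- fit_ellipse_minor_diameter(contours[sel, ], pixel_size)
    out[[i]] <- data.frame(slice = keys$slice[i], fiber = keys$fiber[i],
                           minor = fit$minor, major = fit$major,
                           minor_diameter_um = fit$minor_diameter_um)
  }
  do.call(rbind, out)
}

#' Summarize fiber diameters with sparse axial sampling
#'
#' Retains one measurement per fiber per `sampling_interval` slices (the
#' first available in each window), then reports mean, SD, N and a
#' histogram with fixed bin width.
#'
#' @param fits data.frame with `slice`, `fiber`, `minor_diameter_um`.
#' @param sampling_interval keep one measurement per fiber per this many
#'   slices.
#' @param bin_width histogram bin width in um.
#' @return list with `mean_um`, `sd_um`, `n`, `hist` and the retained
#'   `measurements`.
#' @export
fiber_diameter_summary <- function(fits, sampling_interval = 100,
                                   bin_width = 0.5) {
  if (nrow(fits) == 0) stop("empty fit table")
  win <- (fits$slice - 1) %/% sampling_interval
  key <- paste(fits$fiber, win)
  keep <- !duplicated(key)
  m <- fits[keep, ]
  d <- m$minor_diameter_um
  breaks <- seq(0, ceiling(max(d) / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(mean_um = mean(d), sd_um = sd(d), n = length(d), hist = h,
       measurements = m)
}
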