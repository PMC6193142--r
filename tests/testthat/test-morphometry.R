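# straight Gaussian tube along z, optional tilt, in a cubic volume
straight_tube <- function(n = 80, x0 = 40, y0 = 40, sigma = 3, tilt = 0,
                          beta = 0, beading = 0, period = 20) {
  v <- array(0, c(n, n, n))
  zmid <- (n + 1) / 2
  d <- c(sin(tilt * pi / 180) * cos(beta), sin(tilt * pi / 180) * sin(beta),
         cos(tilt * pi / 180))
  for (iz in 1:n) {
    lz <- (iz - zmid) / d[3]
    px <- x0 + lz * d[1]; py <- y0 + lz * d[2]
    ii <- pmax(1, floor(px - 12)):pmin(n, ceiling(px + 12))
    jj <- pmax(1, floor(py - 12)):pmin(n, ceiling(py + 12))
    vx <- matrix(ii - x0, length(ii), length(jj))
    vy <- matrix(jj - y0, length(ii), length(jj), byrow = TRUE)
    vz <- iz - zmid
    ell <- vx * d[1] + vy * d[2] + vz * d[3]
    perp2 <- pmax(vx^2 + vy^2 + vz^2 - ell^2, 0)
    a <- 1 + beading * cos(2 * pi * ell / period)
    v[ii, jj, iz] <- v[ii, jj, iz] + a * exp(-perp2 / (2 * sigma^2))
  }
  em_volume(v, 10)
}

test_that("tracing follows a straight filament to sub-voxel accuracy", {
  tube <- straight_tube()
  tr <- trace_filaments(tube, data.frame(x = 40.4, y = 39.7, z = 40))
  expect_gt(nrow(tr), 20)
  err <- sqrt((tr$x - 40)^2 + (tr$y - 40)^2)
  expect_lt(sqrt(mean(err^2)), 1)
})

test_that("tracing does not jump between parallel filaments", {
  v <- fibrilEM:::as_plain_array(straight_tube(x0 = 25)) +
    fibrilEM:::as_plain_array(straight_tube(x0 = 55))
  two <- em_volume(v, 10)
  tr <- trace_filaments(two, data.frame(x = c(25, 55), y = c(40, 40),
                                        z = c(40, 40)))
  t1 <- tr[tr$trace == 1, ]
  expect_lt(max(abs(t1$x - 25)), 15)
  expect_lt(max(abs(t1$x - 25)), 2)
})

test_that("a seed in empty background gives a flagged empty trace", {
  tube <- straight_tube()
  tr <- trace_filaments(tube, data.frame(x = c(40, 10), y = c(40, 10),
                                         z = c(40, 40)))
  expect_true(attr(tr, "empty")[2])
  expect_false(1 %in% tr$trace[tr$trace == 2])
})

test_that("orientation and spacing are exact for parallel straight traces", {
  z <- seq(5, 75, 2)
  tr <- rbind(data.frame(trace = 1, idx = seq_along(z), x = 20, y = 40, z = z),
              data.frame(trace = 2, idx = seq_along(z), x = 50, y = 40, z = z))
  attr(tr, "voxel_size_nm") <- 1
  os <- orientation_and_spacing(tr)
  expect_equal(os$per_filament$rel_angle_deg, c(0, 0), tolerance = 1e-9)
  expect_equal(os$per_filament$nn_dist_nm, c(30, 30), tolerance = 1e-9)
  # single trace: angles defined, spacing flagged
  os1 <- orientation_and_spacing(tr[tr$trace == 1, ])
  expect_true(os1$summary$spacing_flagged)
})

test_that("meshwork bundles show broader relative angles than parallel ones", {
  mesh <- make_tomogram_phantom(
    tomogram_phantom_spec(orientation_mode = "meshwork",
                          orientation_dispersion = 30),
    box = 200, voxel_size = 2, seed = 3)
  par <- make_tomogram_phantom(
    tomogram_phantom_spec(orientation_dispersion = 3),
    box = 200, voxel_size = 2, seed = 3)
  om <- orientation_and_spacing(mesh$traces)
  op <- orientation_and_spacing(par$traces)
  expect_gt(om$summary$sd_angle_deg, op$summary$sd_angle_deg)
  expect_gt(om$summary$rms_angle_deg, 3 * op$summary$rms_angle_deg)
})

test_that("filament geometry measures FWHM diameter and beading period", {
  # FWHM of a sigma=3 Gaussian tube: 2 sqrt(2 log 2) * 3 = 7.06 voxels
  tube <- straight_tube(sigma = 3, beading = 0.3, period = 20)
  tr <- trace_filaments(tube, data.frame(x = 40, y = 40, z = 40))
  geo <- filament_geometry(tube, tr)
  expect_equal(geo$diameter_nm, 2 * sqrt(2 * log(2)) * 3, tolerance = 1 / 7)
  expect_equal(geo$periodicity_nm, 20, tolerance = 0.05)
  expect_identical(geo$periodicity_flag, "ok")
  # unbeaded tube: no repeat detected
  flat <- straight_tube(sigma = 3, beading = 0)
  trf <- trace_filaments(flat, data.frame(x = 40, y = 40, z = 40))
  geof <- filament_geometry(flat, trf)
  expect_true(is.na(geof$periodicity_nm))
  expect_identical(geof$periodicity_flag, "no repeat detected")
})

test_that("ellipse fits are exact and rigid-motion invariant", {
  u <- seq(0, 2 * pi, length.out = 33)[-33]
  for (ang in c(0, 0.4, 1.2)) {
    pts <- data.frame(
      x = 120 + 80 * cos(u) * cos(ang) - 50 * sin(u) * sin(ang),
      y = -40 + 80 * cos(u) * sin(ang) + 50 * sin(u) * cos(ang))
    f <- fit_ellipse_minor_diameter(pts, 14)
    expect_equal(f$major, 80, tolerance = 1e-3)
    expect_equal(f$minor, 50, tolerance = 1e-3)
  }
  circ <- data.frame(x = 50 * cos(u), y = 50 * sin(u))
  fc <- fit_ellipse_minor_diameter(circ, 14)
  expect_equal(fc$minor_diameter_um, 1.4, tolerance = 1e-6)
  expect_error(fit_ellipse_minor_diameter(
    data.frame(x = 1:10, y = 2 * (1:10) + 3), 14), "collinear")
})

test_that("noisy circle contours still give the diameter within 1%", {
  set.seed(71)
  u <- seq(0, 2 * pi, length.out = 61)[-61]
  errs <- sapply(1:20, function(i) {
    r <- 50 * (1 + rnorm(60, 0, 0.01))
    f <- fit_ellipse_minor_diameter(
      data.frame(x = r * cos(u), y = r * sin(u)), 14)
    abs(f$minor_diameter_um - 1.4) / 1.4
  })
  expect_lt(max(errs), 0.01)
})

test_that("fiber summaries subsample per fiber and recover the target mean", {
  # single fiber, constant diameter
  fits <- data.frame(slice = seq(1, 1401, 100), fiber = 1,
                     minor_diameter_um = 2.5)
  s <- fiber_diameter_summary(fits, 100)
  expect_equal(s$mean_um, 2.5)
  expect_equal(s$sd_um, 0)
  expect_lte(s$n, 15)
  # defaults-shaped recovery from generated sections
  spec <- fiber_stack_spec(n_fibers = 120, n_slices = 500)
  secs <- make_fiber_sections(spec, seed = 3, slices = seq(1, 500, 100))
  ft <- fit_fiber_contours(secs$contours, spec$pixel_size)
  su <- fiber_diameter_summary(ft, 100)
  expect_equal(su$mean_um, mean(secs$truth$diameter_um), tolerance = 0.02)
  expect_error(fiber_diameter_summary(ft[0, ], 100), "empty")
})
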