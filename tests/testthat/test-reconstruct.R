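test_that("cylindrical initial models are rotationally symmetric and self-consistent", {
  # input: projection of a genuine cylinder
  n <- 64
  rad <- fibrilEM:::radius_grid_2d(n, n)
  cylvol <- em_volume(array(rep(exp(-(rad - 10)^2 / 18), n), c(n, n, n)), 8)
  pr <- project_about_axis(cylvol, 0)
  m <- cylindrical_initial_model(pr, 8)
  expect_gt(cor(as.numeric(project_about_axis(m, 0)), as.numeric(pr)), 0.99)
  r90 <- fibrilEM:::cpp_rotate_volume_z(as.numeric(m), dim(m), 90)
  expect_lt(sqrt(mean((as.numeric(m) - r90)^2)) / sd(as.numeric(m)), 1e-3)
  z <- cylindrical_initial_model(matrix(0, 32, 32), 8)
  expect_true(all(z == 0))
  expect_error(cylindrical_initial_model(matrix(0, 16, 18), 8), "square")
})

test_that("projection is periodic in azimuth and respects C2", {
  vol <- small_phantom()
  expect_equal(project_about_axis(vol, 0), project_about_axis(vol, 360),
               tolerance = 1e-12)
  p0 <- project_about_axis(vol, 33)
  p180 <- project_about_axis(vol, 213)
  expect_gt(cor(as.numeric(p0), as.numeric(p180)), 0.999)
})

test_that("the projection of a unit ball matches the chord-length integral", {
  n <- 64; r0 <- 20; c0 <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  r <- sqrt((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2)
  ball <- em_volume(array(as.numeric(r <= r0), c(n, n, n)), 8)
  prof <- project_about_axis(ball, 17)[, round(c0)]
  d <- (1:n) - c0
  anal <- ifelse(abs(d) <= r0, 2 * sqrt(pmax(r0^2 - d^2, 0)), 0)
  expect_lt(sqrt(mean((prof - anal)^2)) / sqrt(mean(anal^2)), 0.02)
})

test_that("filament WBP is linear and zero on a zero stack", {
  vol <- small_phantom()
  stack <- vapply(seq(0, 150, 30), function(a) project_about_axis(vol, a),
                  matrix(0, 64, 64))
  rr <- fibrilEM:::new_records(6)
  rr$phi <- seq(0, 150, 30); rr$ref <- 1L
  st <- particle_stack(stack, 8)
  w1 <- wbp_filament(st, rr)
  w2 <- wbp_filament(particle_stack(2 * stack, 8), rr)
  expect_equal(as.numeric(w2), 2 * as.numeric(w1), tolerance = 1e-9)
  z <- wbp_filament(particle_stack(array(0, dim(stack)), 8), rr)
  expect_true(all(z == 0))
})

test_that("project then WBP round-trips the phantom", {
  vol <- small_phantom()
  az <- seq(0, 355, 5)
  stack <- vapply(az, function(a) project_about_axis(vol, a),
                  matrix(0, 64, 64))
  rr <- fibrilEM:::new_records(length(az))
  rr$phi <- az; rr$ref <- 1L
  wb <- lowpass_volume(wbp_filament(particle_stack(stack, 8), rr), 20)
  expect_gt(masked_volume_cor(wb, vol), 0.95)
})

test_that("impose_cn is the identity for n=1, idempotent, and definitional", {
  set.seed(41)
  v <- em_volume(array(rnorm(32^3), c(32, 32, 32)), 8)
  expect_identical(impose_cn(v, 1), v)
  s2 <- impose_cn(v, 2)
  s22 <- impose_cn(s2, 2)
  expect_lt(sqrt(mean((as.numeric(s2) - as.numeric(s22))^2)) /
              sd(as.numeric(s2)), 1e-3)
  s4 <- impose_cn(v, 4)
  r90 <- fibrilEM:::cpp_rotate_volume_z(as.numeric(s4), dim(s4), 90)
  expect_lt(sqrt(mean((as.numeric(s4) - r90)^2)) / sd(as.numeric(s4)), 1e-3)
  # norm-non-increasing
  expect_lte(sum(as.numeric(s2)^2), sum(as.numeric(v)^2))
})

test_that("refinement recovers periodicity and diameter from scratch", {
  vol <- small_phantom()
  ds <- make_projection_dataset(vol, 90, snr = Inf, shift_max = 4, seed = 5)
  init <- cylindrical_initial_model(
    align_average_vertical(average_aligned(ds$stack)), 8)
  fit <- suppressWarnings(
    refine_projection_matching(ds$stack, init,
                               refinement_config(n_iterations = 4,
                                                 shift_max = 4)))
  expect_s3_class(fit, "pm_refinement")
  expect_equal(axial_repeat_distance(fit$model), 28.8, tolerance = 0.05)
  expect_equal(as.numeric(max_transverse_diameter(fit$model)), 16,
               tolerance = 0.05)
  # net improvement of the mean alignment score
  sc <- fit$log$mean_score
  expect_gte(sc[length(sc)], sc[1])
  expect_true(all(diff(sc) > -0.05))
})

test_that("a refinement pass from a correct model keeps it (stability)", {
  vol <- small_phantom()
  lp <- lowpass_volume(vol, 20)
  ds <- make_projection_dataset(vol, 60, snr = Inf, shift_max = 4, seed = 6)
  fit <- refine_projection_matching(ds$stack, lp,
                                    refinement_config(n_iterations = 1,
                                                      shift_max = 4))
  expect_gt(masked_volume_cor(fit$model, vol), 0.9)
})

test_that("single-axis WBP handles degenerate and paired-range cases", {
  n <- 64; c0 <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  r <- sqrt((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2)
  ball <- em_volume(array(pmax(pmin(12.5 - r, 1), 0), c(n, n, n)), 10)
  # single image: back-projection constant along the beam (z at 0 tilt)
  ts1 <- make_tilt_series(ball, -0.5, 0.5, 1)
  ts1$images <- ts1$images[, , 1, drop = FALSE]
  ts1$angles <- 0
  v1 <- suppressWarnings(wbp_tilt(ts1))
  a <- fibrilEM:::as_plain_array(v1)
  expect_lt(max(abs(sweep(a, c(1, 2), a[, , 1]))), 1e-9)
  # missing wedge: +/-65 worse than +/-90, both decent over the sphere + rim
  roi <- r <= 1.3 * 12
  t65 <- wbp_tilt(make_tilt_series(ball, -65, 65, 1))
  t90 <- wbp_tilt(make_tilt_series(ball, -90, 89, 1))
  c65 <- cor(as.numeric(t65)[roi], as.numeric(ball)[roi])
  c90 <- cor(as.numeric(t90)[roi], as.numeric(ball)[roi])
  expect_gt(c90, c65)
  expect_gt(c65, 0.9)
  # inconsistent image sizes rejected
  bad <- list(images = array(0, c(16, 16, 3)), angles = c(-1, 0, 1, 2),
              pixel_size = 10)
  class(bad) <- "tilt_series"
  expect_error(wbp_tilt(bad), "angle list")
})

test_that("iso-levels are order statistics with monotone behaviour", {
  set.seed(42)
  v <- em_volume(array(runif(20^3), c(20, 20, 20)), 10)
  voxel_nm3 <- 1
  # target = half the box: level at the median density
  ref_half <- length(v) * voxel_nm3 / 2
  lv <- iso_level_for_volume_fraction(v, 1, ref_half)
  expect_equal(mean(as.numeric(v) >= lv), 0.5, tolerance = 2 / length(v))
  l1 <- iso_level_for_volume_fraction(v, 0.2, ref_half)
  l2 <- iso_level_for_volume_fraction(v, 0.6, ref_half)
  expect_gte(l1, l2)
  expect_error(iso_level_for_volume_fraction(v, 1, 1e9), "exceeds")
})

test_that("the 40% iso-level of the phantom is connected in the bead", {
  vol <- make_microfibril_phantom()
  ref <- mass_to_volume(8 * 350)          # eight chains of ~350 kDa
  lv <- iso_level_for_volume_fraction(vol, 0.4, ref)
  sup <- fibrilEM:::as_plain_array(vol) >= lv
  lab <- fibrilEM:::cpp_label3d(as.logical(sup), dim(vol))
  main <- which.max(tabulate(lab[lab > 0]))
  # the dominant component contains most of the superlevel set and sits in
  # the bead region
  expect_gt(sum(lab == main) / sum(sup), 0.45)
  bead3 <- region_mask(dim(vol)[3], default_regions()$bead, ndim = 3)
  expect_gt(sum(lab == main & bead3) / sum(lab == main), 0.9)
})

test_that("mass and molecular volume convert with the protein constant", {
  expect_equal(mass_to_volume(2500), 3025, tolerance = 0.01)
  expect_equal(volume_to_mass(mass_to_volume(1400)), 1400, tolerance = 1e-12)
  expect_error(mass_to_volume(0), "positive")
})
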