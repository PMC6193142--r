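test_that("the default repeat phantom has exact C2 and the printed dimensions", {
  vol <- make_microfibril_phantom()
  r180 <- fibrilEM:::cpp_rotate_volume_z(as.numeric(vol), dim(vol), 180)
  expect_lt(max(abs(as.numeric(vol) - r180)), 1e-12)
  # first autocorrelation peak of the axial profile: 74 voxels = 59.2 nm
  lag <- fibrilEM:::profile_period(axial_density_profile(vol))
  expect_equal(round(lag), 74)
  expect_equal(axial_repeat_distance(vol), 59.2, tolerance = 0.01)
  expect_equal(as.numeric(max_transverse_diameter(vol)), 20.8,
               tolerance = 0.01)
})

test_that("the phantom is hollow in the interbead", {
  vol <- make_microfibril_phantom()
  rp <- radial_density_profile(vol)
  ib <- region_mask(dim(vol)[3], default_regions()$interbead,
                    ndim = 2)[1, ]
  for (iz in which(ib)[c(1, 5, 9)]) {
    p <- rp$profile[, iz]
    expect_lt(p[1], 0.5 * max(p))
  }
})

test_that("strand count and interbead pseudo-symmetry follow the spec fields", {
  s8 <- microfibril_phantom_spec(n_strands = 8, axial_symmetry_order = 8)
  v8 <- make_microfibril_phantom(s8)
  r45 <- fibrilEM:::cpp_rotate_volume_z(as.numeric(v8), dim(v8), 45)
  expect_gt(cor(as.numeric(v8), r45), 0.995)
  expect_error(microfibril_phantom_spec(n_chains = 6, axial_symmetry_order = 4),
               "multiple")
})

test_that("a box smaller than one repeat is rejected", {
  expect_error(make_microfibril_phantom(box_px = 64, voxel_size = 8),
               "too small")
})

test_that("projection datasets are seed-deterministic and contract-checked", {
  vol <- small_phantom()
  a <- make_projection_dataset(vol, 5, snr = 1, shift_max = 4, seed = 7)
  b <- make_projection_dataset(vol, 5, snr = 1, shift_max = 4, seed = 7)
  expect_identical(as.numeric(a$stack), as.numeric(b$stack))
  expect_identical(a$truth, b$truth)
  expect_error(make_projection_dataset(vol, 5, snr = 0), "snr")
  expect_error(make_projection_dataset(vol, 0), "n must")
})

test_that("the identity configuration reproduces the plain projection", {
  vol <- small_phantom()
  ds <- make_projection_dataset(vol, 1, snr = Inf, shift_max = 0, seed = 1)
  want <- project_about_axis(vol, ds$truth$phi[1])
  got <- fibrilEM:::cpp_apply_inplane(want, ds$truth$psi[1], 0, 0)
  expect_equal(ds$stack[, , 1], got, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the realized noise level matches the requested SNR", {
  vol <- small_phantom()
  ds <- make_projection_dataset(vol, 100, snr = 1, shift_max = 4, seed = 9)
  clean <- make_projection_dataset(vol, 100, snr = Inf, shift_max = 4, seed = 9)
  noise_var <- sig_var <- numeric(100)
  for (i in 1:100) {
    sig_var[i] <- var(as.numeric(clean$stack[, , i]))
    noise_var[i] <- var(as.numeric(ds$stack[, , i] - clean$stack[, , i]))
  }
  expect_equal(mean(sig_var / noise_var), 1, tolerance = 0.1)
})

test_that("tilt series have one image per angle and reject empty ranges", {
  vol <- em_volume(array(rnorm(16^3), c(16, 16, 16)), 10)
  ts <- make_tilt_series(vol, -65, 65, 1)
  expect_equal(length(ts$angles), 131)
  expect_equal(dim(ts$images)[3], 131)
  expect_error(make_tilt_series(vol, 0, 0), "empty angle range")
})

test_that("projections of a uniform sphere are tilt-invariant", {
  n <- 48; c0 <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  r <- sqrt((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2)
  ball <- em_volume(array(pmax(pmin((14.5 - r) / 2, 1), 0), c(n, n, n)), 10)
  ts <- make_tilt_series(ball, -60, 60, 20)
  mid <- ts$images[, , 4]
  rel <- apply(ts$images, 3, function(im)
    sqrt(mean((im - mid)^2)) / sqrt(mean(mid^2)))
  expect_lt(max(rel), 0.01)
})

test_that("tomogram phantoms hit the packing and orientation targets", {
  tomo <- make_tomogram_phantom(seed = 1)
  expect_gte(nrow(tomo$tangents), 50)
  os <- orientation_and_spacing(tomo$traces)
  expect_equal(os$summary$mean_spacing_nm, 30, tolerance = 0.05)
  # parallel mode, zero dispersion: all truth tangents equal
  t0 <- make_tomogram_phantom(tomogram_phantom_spec(orientation_dispersion = 0),
                              box = 120, seed = 2)
  expect_lt(max(abs(t0$tangents$tilt_deg)), 1e-9)
  os0 <- orientation_and_spacing(t0$traces)
  expect_lt(max(os0$per_filament$rel_angle_deg), 1e-6)
})

test_that("meshwork dispersion is recovered from truth tangents", {
  tomo <- make_tomogram_phantom(
    tomogram_phantom_spec(orientation_mode = "meshwork",
                          orientation_dispersion = 30),
    box = 300, voxel_size = 2, seed = 4)
  expect_gte(nrow(tomo$tangents), 50)
  rms <- sqrt(mean(tomo$tangents$tilt_deg^2))
  expect_gt(rms, 25)
  expect_lt(rms, 35)
})

test_that("infeasible packings are rejected", {
  expect_error(make_tomogram_phantom(box = 40, seed = 1), "infeasible")
  expect_error(make_tomogram_phantom(tomogram_phantom_spec(n_filaments = 1000),
                                     box = 120, seed = 1), "infeasible")
})

test_that("fiber sections encode obliquity and the diameter distribution", {
  # obliquity 0: circles
  s0 <- fiber_stack_spec(n_fibers = 5, n_slices = 10, section_obliquity = 0)
  g0 <- make_fiber_sections(s0, seed = 2, slices = 1)
  f0 <- fit_fiber_contours(g0$contours, s0$pixel_size)
  expect_equal(f0$major / f0$minor, rep(1, 5), tolerance = 0.03)
  # obliquity 60: axis ratio 2
  s60 <- fiber_stack_spec(n_fibers = 5, n_slices = 10, section_obliquity = 60)
  g60 <- make_fiber_sections(s60, seed = 2, slices = 1)
  f60 <- fit_fiber_contours(g60$contours, s60$pixel_size)
  expect_equal(f60$major / f60$minor, rep(2, 5), tolerance = 0.03)
  # defaults, 300 fibers, seed 3: truth mean within 0.1 um of 2.06
  g <- make_fiber_sections(fiber_stack_spec(), seed = 3, slices = 1)
  expect_lt(abs(mean(g$truth$diameter_um) - 2.06), 0.1)
  expect_error(fiber_stack_spec(section_obliquity = 95), "obliquity")
})

test_that("fiber section generation is seed-deterministic", {
  s <- fiber_stack_spec(n_fibers = 10, n_slices = 20)
  a <- make_fiber_sections(s, seed = 5, slices = c(1, 11))
  b <- make_fiber_sections(s, seed = 5, slices = c(1, 11))
  expect_identical(a$contours, b$contours)
  expect_identical(a$truth, b$truth)
})
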