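test_that("region masks cover their axial intervals and nothing else", {
  full <- region_spec("all", c(0, 1))
  m <- region_mask(74, full, periodicity = 59.2, voxel_size = 8)
  expect_true(all(m))
  # one exact period in the box: fractions are exact to one row
  bead <- default_regions()$bead
  mb <- region_mask(74, bead, periodicity = 59.2, voxel_size = 8)
  expect_equal(mean(mb), 0.30, tolerance = 1.5 / 74)
  regions <- default_regions()
  ms <- lapply(regions, function(r)
    region_mask(74, r, periodicity = 59.2, voxel_size = 8))
  expect_false(any(ms$bead & ms$arm))
  expect_false(any(ms$bead & ms$interbead))
  expect_false(any(ms$arm & ms$interbead))
  expect_true(all(ms$bead | ms$arm | ms$interbead))
  expect_error(region_spec("x", c(0.5, 0.5)), "empty")
})

test_that("2D masks are the projection support of the 3D masks", {
  r <- default_regions()$interbead
  m2 <- region_mask(64, r, periodicity = 28.8, voxel_size = 8, ndim = 2)
  m3 <- region_mask(64, r, periodicity = 28.8, voxel_size = 8, ndim = 3)
  expect_equal(m2[1, ], apply(m3, 3, any), ignore_attr = TRUE)
})

test_that("self-mode scans find the imposed symmetry exactly on the grid", {
  vol <- make_microfibril_phantom()
  cv <- rotational_correlation_scan(impose_cn(vol, 2), increment = 5)
  nz <- cv$angle != 0
  expect_equal(cv$angle[nz][which.max(cv$correlation[nz])], 180)
  # a cylindrically symmetric volume gives a flat curve
  n <- 48
  rad <- fibrilEM:::radius_grid_2d(n, n)
  cyl <- em_volume(array(rep(exp(-(rad - 8)^2 / 8), n), c(n, n, n)), 8)
  cc <- rotational_correlation_scan(cyl, increment = 10)
  expect_lt(diff(range(cc$correlation)), 1e-3)
})

test_that("an eight-fold interbead shows peaks at every 45 degrees", {
  s8 <- microfibril_phantom_spec(n_strands = 8, axial_symmetry_order = 8)
  v8 <- make_microfibril_phantom(s8)
  sub <- region_subvolume(v8, default_regions()$interbead)
  cv <- rotational_correlation_scan(sub, increment = 5)
  pk <- cv$angle[fibrilEM:::circular_local_maxima(cv$correlation)]
  expect_true(all(seq(45, 315, 45) %in% pk))
  expect_equal(min(pk[pk > 0]), 45)
  orders <- detect_symmetry_orders(cv)
  expect_true(8 %in% orders)
})

test_that("data-mode scans peak at zero offset on converged alignments", {
  vol <- small_phantom()
  az <- seq(0, 355, 5)
  stack <- vapply(az[seq(1, 72, 3)], function(a) project_about_axis(vol, a),
                  matrix(0, 64, 64))
  rr <- fibrilEM:::new_records(24)
  rr$phi <- az[seq(1, 72, 3)]; rr$ref <- 1L
  cv <- rotational_correlation_scan(vol, data = particle_stack(stack, 8),
                                    records = rr, increment = 5)
  # on a C2 model the 180-degree offset ties with 0; zero must be maximal
  expect_equal(cv$correlation[cv$angle == 0], max(cv$correlation),
               tolerance = 1e-6)
  # peak locations agree with the self-mode scan
  cs <- rotational_correlation_scan(vol, increment = 5)
  nz <- cv$angle != 0
  expect_equal(cv$angle[nz][which.max(cv$correlation[nz])],
               cs$angle[nz][which.max(cs$correlation[nz])])
  expect_error(rotational_correlation_scan(vol, data = particle_stack(stack, 8),
                                           increment = 5), "records")
})

test_that("symmetry orders are detected from constructed curves", {
  th <- seq(0, 355, 5)
  mk <- function(y) structure(data.frame(angle = th, correlation = y),
                              class = c("correlation_curve", "data.frame"),
                              increment = 5)
  expect_equal(as.integer(detect_symmetry_orders(mk(cos(2 * th * pi / 180)))),
               2L)
  mix <- 0.6 * cos(2 * th * pi / 180) + 0.3 * cos(8 * th * pi / 180)
  expect_equal(as.integer(detect_symmetry_orders(mk(mix))), c(8L, 4L, 2L))
  set.seed(51)
  noise <- rnorm(length(th), 0, 0.02)
  expect_length(detect_symmetry_orders(mk(noise), prominence = 0.2), 0)
  flat <- rep(0.5, length(th))
  expect_length(detect_symmetry_orders(mk(flat)), 0)
})

test_that("full-repeat sub-model refinement reduces to the parent refinement", {
  vol <- small_phantom()
  ds <- make_projection_dataset(vol, 30, snr = Inf, shift_max = 4, seed = 8)
  cfg <- refinement_config(n_iterations = 1, shift_max = 4)
  init <- lowpass_volume(vol, 20)
  full <- region_spec("all", c(0, 1))
  a <- refine_submodel(ds$stack, init, full, cfg, periodicity = 28.8)
  b <- refine_projection_matching(ds$stack, init, cfg)
  expect_equal(as.numeric(a$model), as.numeric(b$model), tolerance = 1e-12)
})

test_that("region-masked refinement localizes alignment to the region", {
  vol <- small_phantom()
  # flexible dataset: per-particle axial stretch of +/- 5%
  set.seed(52)
  n <- 64
  az <- runif(40, 0, 360)
  stack <- array(0, c(n, n, 40))
  for (i in 1:40) {
    img <- project_about_axis(vol, az[i])
    s <- 1 + runif(1, -0.05, 0.05)
    zc <- (n + 1) / 2
    stretched <- t(apply(img, 1, function(col)
      approx((seq_len(n) - zc) * s + zc, col, xout = seq_len(n), rule = 2)$y))
    stack[, , i] <- stretched
  }
  st <- particle_stack(stack, 8)
  cfg <- refinement_config(n_iterations = 2, shift_max = 4)
  init <- lowpass_volume(vol, 20)
  ib <- default_regions()$interbead
  sub <- refine_submodel(st, init, ib, cfg, periodicity = 28.8)
  fullfit <- refine_projection_matching(st, init, cfg)
  truth_sub <- region_subvolume(vol, ib, periodicity = 28.8)
  m3 <- region_mask(n, ib, periodicity = 28.8, voxel_size = 8, ndim = 3)
  cor_sub <- cor(as.numeric(sub$model)[m3], as.numeric(truth_sub)[m3])
  cor_full <- cor(as.numeric(fullfit$model)[m3], as.numeric(truth_sub)[m3])
  expect_gt(cor_sub, cor_full)
  # windowing: nothing outside the region
  expect_true(all(as.numeric(sub$model)[!m3] == 0))
})
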