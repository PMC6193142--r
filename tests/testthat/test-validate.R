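test_that("FSC of a volume with itself is 1 in every shell, symmetrically", {
  set.seed(61)
  v <- em_volume(array(rnorm(32^3), c(32, 32, 32)), 8)
  w <- em_volume(array(rnorm(32^3), c(32, 32, 32)), 8)
  self <- compute_fsc(v, v)
  expect_true(all(abs(self$fsc - 1) < 1e-9))
  ab <- compute_fsc(v, w)
  ba <- compute_fsc(w, v)
  expect_equal(ab$fsc, ba$fsc, tolerance = 1e-12)
  expect_error(compute_fsc(v, em_volume(array(0, c(16, 16, 16)), 8)), "grids")
})

test_that("independent noise volumes give near-zero FSC in every shell", {
  set.seed(62)
  v <- em_volume(array(rnorm(48^3), c(48, 48, 48)), 8)
  w <- em_volume(array(rnorm(48^3), c(48, 48, 48)), 8)
  curve <- compute_fsc(v, w)
  # shell counts: ~ 4 pi r^2 Fourier voxels per unit-width shell
  shells <- as.integer(round(curve$freq * 48 * 8))
  nshell <- 4 * pi * shells^2
  expect_true(all(abs(curve$fsc) < 3 / sqrt(nshell) + 0.01))
})

test_that("high-frequency noise pulls the FSC down only at high frequency", {
  set.seed(63)
  base <- array(0, c(32, 32, 32))
  # smooth signal
  g <- expand.grid(x = 1:32, y = 1:32, z = 1:32)
  base[] <- sin(g$x / 4) + cos(g$y / 5) + sin(g$z / 4.5)
  v1 <- em_volume(base, 8)
  v2 <- em_volume(base + array(rnorm(32^3, 0, 0.8), c(32, 32, 32)), 8)
  curve <- compute_fsc(v1, v2)
  k <- nrow(curve)
  expect_gt(mean(curve$fsc[1:3]), 0.8)
  expect_lt(mean(curve$fsc[(k - 3):k]), 0.5)
})

test_that("resolution crossings are linearly interpolated in frequency", {
  curve <- structure(data.frame(freq = c(1 / 45, 1 / 40),
                                fsc = c(0.6, 0.4)),
                     class = c("fsc_curve", "data.frame"), voxel_size = 8)
  res <- resolution_at_threshold(curve, 0.5)
  expect_equal(as.numeric(res), 1 / mean(c(1 / 45, 1 / 40)), tolerance = 1e-9)
  expect_equal(round(as.numeric(res), 1), 42.4)
  expect_identical(attr(res, "flag"), "ok")
  allhigh <- structure(data.frame(freq = c(0.01, 0.02), fsc = c(1, 1)),
                       class = c("fsc_curve", "data.frame"), voxel_size = 8)
  r2 <- resolution_at_threshold(allhigh, 0.5)
  expect_identical(attr(r2, "flag"), "not reached")
  expect_equal(as.numeric(r2), 16)    # Nyquist wavelength at 8 A voxels
  r3 <- resolution_at_threshold(curve, 1.1)
  expect_identical(attr(r3, "flag"), "immediate")
})

test_that("half-set resolution improves with particle count", {
  vol <- small_phantom()
  res <- sapply(c(24, 96), function(N) {
    ds <- make_projection_dataset(vol, N, snr = 0.5, shift_max = 2, seed = 13)
    cfg <- refinement_config(n_iterations = 1, shift_max = 2,
                             halfset_mode = TRUE)
    fit <- refine_projection_matching(ds$stack, lowpass_volume(vol, 20), cfg)
    as.numeric(resolution_at_threshold(compute_fsc(fit$half1, fit$half2)))
  })
  expect_lte(res[2], res[1])
})

test_that("classification partitions the stack deterministically", {
  vol <- small_phantom()
  a <- project_about_axis(vol, 0)
  b <- fibrilEM:::cpp_rotate_image(project_about_axis(vol, 45), 90)
  set.seed(64)
  st <- array(0, c(64, 64, 20))
  truth <- rep(1:2, each = 10)
  for (i in 1:20) st[, , i] <- if (truth[i] == 1) a else b
  stack <- particle_stack(st, 8)
  cl <- classify_and_average(stack, 2, seed = 3)
  expect_equal(rand_index_adjusted(cl$membership, truth), 1)
  expect_equal(sum(cl$sizes), 20)
  # class averages are the member means
  for (k in 1:2) {
    idx <- cl$membership == k
    expect_equal(cl$averages[, , k],
                 apply(st[, , idx, drop = FALSE], c(1, 2), mean),
                 tolerance = 1e-12)
  }
  cl2 <- classify_and_average(stack, 2, seed = 3)
  expect_identical(cl$membership, cl2$membership)
  one <- classify_and_average(stack, 1, seed = 1)
  expect_equal(one$averages[, , 1], apply(st, c(1, 2), mean),
               tolerance = 1e-12)
  expect_error(classify_and_average(stack, 21, seed = 1), "exceeds")
})
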