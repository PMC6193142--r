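test_that("FFT masked NCC equals the direct double-loop computation", {
  set.seed(31)
  worst <- 0
  for (i in 1:25) {
    img <- matrix(rnorm(32 * 32), 32)
    tmp <- matrix(rnorm(9 * 9), 9)
    msk <- matrix(runif(81) > 0.3, 9)
    while (sum(msk) < 16) msk <- matrix(runif(81) > 0.3, 9)
    got <- masked_ncc_map(img, tmp, msk)
    want <- brute_masked_ncc(img, tmp, msk)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-5)
})

test_that("masked NCC peaks at 1 on an exact patch, and is affine invariant", {
  set.seed(32)
  img <- matrix(rnorm(64 * 64), 64)
  tmp <- img[11:30, 21:40]
  map <- masked_ncc_map(img, tmp)
  pk <- which(map == max(map), arr.ind = TRUE)
  expect_equal(max(map), 1, tolerance = 1e-9)
  expect_equal(as.numeric(pk), c(11, 21))
  map2 <- masked_ncc_map(3 * img + 7, tmp)
  expect_equal(max(map2), 1, tolerance = 1e-9)
  expect_equal(which(map2 == max(map2), arr.ind = TRUE), pk)
})

test_that("masked NCC rejects bad masks and flags zero-variance offsets", {
  img <- matrix(rnorm(32 * 32), 32)
  tmp <- matrix(rnorm(64), 8)
  expect_error(masked_ncc_map(img, tmp, matrix(FALSE, 8, 8)), "mask")
  expect_error(masked_ncc_map(img, tmp, matrix(c(rep(TRUE, 8), rep(FALSE, 56)), 8)),
               "16")
  flat <- matrix(0, 24, 24)
  flat[1:8, 1:8] <- matrix(rnorm(64), 8)
  map <- masked_ncc_map(flat, tmp)
  expect_true(any(attr(map, "flagged")))
  expect_true(all(map[attr(map, "flagged")] == 0))
})

test_that("both engines recover a planted rotation and shift", {
  vol <- small_phantom()
  ref <- project_about_axis(vol, 40)
  part <- fibrilEM:::cpp_apply_inplane(ref, 37, 3, -2)
  for (eng in c("polar", "cartesian")) {
    rec <- align_particle(part, ref, psi_step = 1, shift_max = 4,
                          engine = eng)
    expect_lt(abs(rec$psi - 37), 0.5)
    expect_lt(abs(rec$dx - 3), 0.5)
    expect_lt(abs(rec$dy - (-2)), 0.5)
    expect_gt(rec$score, 0.99)
  }
})

test_that("a particle identical to reference 0 gives the identity record", {
  vol <- small_phantom()
  ref <- project_about_axis(vol, 10)
  rec <- align_particle(ref, ref, psi_step = 5, shift_max = 4)
  expect_equal(rec$psi, 0)
  expect_lt(abs(rec$dx), 0.01)
  expect_lt(abs(rec$dy), 0.01)
  expect_equal(rec$ref, 1L)
  expect_equal(rec$score, 1, tolerance = 1e-6)
})

test_that("ties break to the lowest reference index", {
  vol <- small_phantom()
  ref <- project_about_axis(vol, 0)
  refs <- array(c(ref, ref), c(dim(ref), 2))   # two identical references
  for (eng in c("polar", "cartesian")) {
    rec <- align_particle(ref, refs, psi_step = 45, shift_max = 2,
                          engine = eng)
    expect_equal(rec$ref, 1L)
  }
})

test_that("an all-zero particle yields a flagged zero-score record", {
  vol <- small_phantom()
  ref <- project_about_axis(vol, 0)
  rec <- align_particle(matrix(0, nrow(ref), ncol(ref)), ref,
                        psi_step = 45, shift_max = 2)
  expect_equal(rec$score, 0)
  expect_true(rec$flagged)
})

test_that("averaging with identity records is the plain stack mean", {
  set.seed(33)
  st <- array(rnorm(24 * 24 * 6), c(24, 24, 6))
  expect_equal(average_aligned(particle_stack(st, 4)),
               apply(st, c(1, 2), mean), tolerance = 1e-12)
  expect_error(average_aligned(particle_stack(array(0, c(4, 4, 0)), 4)),
               "empty")
})

test_that("aligned averaging suppresses noise in proportion to stack size", {
  vol <- small_phantom()
  clean <- project_about_axis(vol, 25)
  set.seed(34)
  cors <- sapply(c(4, 16, 64), function(N) {
    psis <- runif(N, 0, 360)
    dxs <- runif(N, -3, 3)
    dys <- runif(N, -3, 3)
    st <- array(0, c(dim(clean), N))
    for (i in 1:N)
      st[, , i] <- fibrilEM:::cpp_apply_inplane(clean, psis[i], dxs[i], dys[i]) +
        rnorm(length(clean), 0, 2 * sd(clean))
    rec <- fibrilEM:::new_records(N)
    rec$psi <- psis; rec$dx <- dxs; rec$dy <- dys; rec$ref <- 1L
    avg <- average_aligned(particle_stack(st, 8), rec)
    cor(as.numeric(avg), as.numeric(clean))
  })
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.9)
})

test_that("the principal axis of an average is rotated to vertical", {
  vol <- small_phantom()
  pr <- project_about_axis(vol, 0)
  tilted <- fibrilEM:::cpp_rotate_image(pr, 25)
  fixed <- align_average_vertical(tilted)
  # the correction should undo the 25 degree tilt (mod 180)
  e <- (attr(fixed, "angle") + 25) %% 180
  expect_lt(min(e, 180 - e), 3)
})
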