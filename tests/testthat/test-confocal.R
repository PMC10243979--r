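test_that("stack constructor validates geometry", {
  p <- list(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_s3_class(confocal_stack(p, 15, 45, 5), "confocal_stack")
  expect_error(confocal_stack(list(matrix(0, 8, 8), matrix(0, 7, 8)), 15),
               "same shape")
  expect_error(confocal_stack(p, -1), "depth_step_um")
  expect_error(confocal_stack(p, 15, geometry_angle_deg = 90),
               "geometry_angle_deg")
})

test_that("zero depth step leaves the stack unchanged", {
  set.seed(4)
  p <- lapply(1:3, function(k) matrix(runif(64), 8, 8))
  st <- confocal_stack(p, depth_step_um = 0, pixel_size_um = 5)
  expect_identical(shift_correct(st)$planes, p)
})

test_that("a skewed rod realigns to < 0.5 px centroid drift", {
  # rod: one particle persisting through all planes, skew applied by the
  # generator exactly as the 45-degree geometry dictates
  cp <- make_confocal_phantom(n_planes = 5, n_particles = 1,
                              diameter_logmean = log(30),
                              diameter_logsd = 0.01, persistence = 10,
                              noise = FALSE, seed = 5)
  expect_identical(cp$truth$particles$depth_span, 5L)
  corrected <- shift_correct(cp$stack)
  cent <- vapply(corrected$planes, function(m) {
    on <- which(m > cp$truth$level / 2, arr.ind = TRUE)
    mean(on[, 1])
  }, numeric(1))
  expect_lt(max(cent) - min(cent), 0.5)
  # before correction the drift equals the geometric skew
  cent0 <- vapply(cp$stack$planes, function(m) {
    on <- which(m > cp$truth$level / 2, arr.ind = TRUE)
    mean(on[, 1])
  }, numeric(1))
  expect_gt(max(cent0) - min(cent0), 2 * cp$truth$skew_px_per_plane)
})

test_that("shift correction is invertible and conserves intensity", {
  set.seed(11)
  base <- matrix(0, 24, 24)
  base[8:14, 10:15] <- runif(42, 50, 100)
  # integer shift (3 px/plane): forward then backward is exact
  sti <- confocal_stack(lapply(1:3, function(k) base), depth_step_um = 15,
                        geometry_angle_deg = 45, pixel_size_um = 5)
  fwd_i <- shift_correct(sti, direction = 1)
  back_i <- shift_correct(fwd_i, direction = -1)
  interior <- 8:16
  expect_equal(back_i$planes[[2]][interior, ], base[interior, ],
               tolerance = 1e-12)
  # fractional shift (1.5 px/plane): linear interpolation conserves the
  # total valid-pixel intensity within 0.1%
  st <- confocal_stack(lapply(1:3, function(k) base), depth_step_um = 7.5,
                       geometry_angle_deg = 45, pixel_size_um = 5)
  fwd <- shift_correct(st, direction = 1)
  for (k in 2:3) {
    s0 <- sum(base)
    s1 <- sum(fwd$planes[[k]], na.rm = TRUE)
    expect_lt(abs(s1 - s0) / s0, 1e-3)
  }
  # vacated margins are invalid, not zero
  expect_true(anyNA(fwd$planes[[3]]))
  # shift beyond the image extent errors
  big <- confocal_stack(lapply(1:30, function(k) base), depth_step_um = 15,
                        pixel_size_um = 5)
  expect_error(shift_correct(big), "exceeds image extent")
})

test_that("background estimation matches its contracts", {
  expect_equal(estimate_background(matrix(7, 10, 10)), 7)
  m <- matrix(0, 10, 10); m[c(3, 50, 90)] <- 1000
  expect_equal(estimate_background(m), 0)
  # masked: median of off-tissue pixels
  set.seed(21)
  m2 <- matrix(rpois(2500, 6), 50, 50)
  mask <- matrix(FALSE, 50, 50); mask[20:30, 20:30] <- TRUE
  m2[mask] <- 500
  expect_equal(estimate_background(m2, mask), 6, tolerance = 1e-9)
  expect_error(estimate_background(m2, matrix(TRUE, 50, 50)),
               "off-tissue")
  # phantom oracle: masked estimate within 10% of the true background mean
  cp <- make_confocal_phantom(seed = 14, background = 4)
  plane <- shift_correct(cp$stack)$planes[[1]]
  particle_mask <- !is.na(plane) & plane > cp$truth$level / 2
  est <- estimate_background(plane, particle_mask)
  expect_lt(abs(est - cp$truth$background) / cp$truth$background, 0.10)
})

test_that("thresholding is idempotent and separates phantom classes", {
  m <- matrix(5, 6, 6)
  expect_true(all(threshold_map(m, background = 5) == 0))
  expect_error(threshold_map(m, background = -1), ">= 0")
  expect_error(threshold_map(m, background = 5, factor = 0), "factor")
  # factor 1 on a noiseless positive map keeps everything
  m2 <- matrix(10:45, 6, 6)
  expect_equal(threshold_map(m2, background = 10, factor = 1), m2,
               ignore_attr = FALSE)
  # idempotence
  set.seed(3)
  m3 <- matrix(rpois(400, 3), 20, 20); m3[5:7, 5:7] <- 200
  t1 <- threshold_map(m3, background = 3)
  expect_identical(threshold_map(t1, background = 3), t1)
  # phantom: all true particle pixels survive, < 1% of background does
  cp <- make_confocal_phantom(seed = 31)
  st <- shift_correct(cp$stack)
  bg <- estimate_background(st$planes[[1]])
  part <- bgkeep <- 0; parttot <- bgtot <- 0
  for (p in st$planes) {
    truth_particle <- !is.na(p) & p > cp$truth$level / 2
    th <- threshold_map(p, bg)
    part <- part + sum(th[truth_particle] > 0)
    parttot <- parttot + sum(truth_particle)
    bgkeep <- bgkeep + sum(th[!truth_particle & !is.na(p)] > 0)
    bgtot <- bgtot + sum(!truth_particle & !is.na(p))
  }
  expect_identical(part, parttot)
  expect_lt(bgkeep / bgtot, 0.01)
})

test_that("log display is the documented monotone transform", {
  m <- matrix(c(0, 9, 99, 999), 2, 2)
  out <- log_display(m)
  expect_equal(out, matrix(c(0, 1, 2, 3), 2, 2))
  expect_error(log_display(matrix(-1, 1, 1)), ">= 0")
  m2 <- matrix(c(NA, 5), 1, 2)
  expect_true(is.na(log_display(m2)[1]))
  set.seed(6)
  v <- matrix(runif(100, 0, 1e4), 10, 10)
  expect_identical(order(log_display(v)), order(v))
})

test_that("particle features are counted, sized and depth-spanned", {
  # single bright voxel
  p <- lapply(1:3, function(k) matrix(0, 6, 6))
  p[[2]][3, 4] <- 50
  st <- confocal_stack(p, 15, pixel_size_um = 5)
  f <- particle_features(st)
  expect_identical(nrow(f), 1L)
  expect_identical(f$volume_voxels, 1L)
  expect_identical(f$depth_span, 1L)
  expect_equal(f$extent_um, 5)
  # empty stack -> empty table
  st0 <- confocal_stack(lapply(1:2, function(k) matrix(0, 4, 4)), 15)
  expect_identical(nrow(particle_features(st0)), 0L)
  # noiseless phantom: exactly k features with matching volumes
  cp <- make_confocal_phantom(n_particles = 6, noise = FALSE, seed = 77,
                              background = 0)
  st <- shift_correct(cp$stack)
  f <- particle_features(st)
  expect_identical(nrow(f), 6L)
  expect_equal(sum(f$volume_voxels),
               sum(vapply(st$planes, function(m)
                 sum(m > 0, na.rm = TRUE), numeric(1))))
  # depth persistence increases with extent (generator contract + recovery)
  cp2 <- make_confocal_phantom(n_particles = 12, image_size = c(128, 128),
                               noise = FALSE, seed = 13, background = 0)
  f2 <- particle_features(shift_correct(cp2$stack))
  expect_gt(cor(f2$extent_um, f2$depth_span, method = "spearman"), 0)
  # feature count invariant under plane-order reversal
  strev <- shift_correct(cp2$stack)
  strev$planes <- rev(strev$planes)
  expect_identical(nrow(particle_features(strev)), nrow(f2))
})
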