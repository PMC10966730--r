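test_that("forward projection of a uniform disc matches the chord closed form", {
  f <- softDisc(128, 50, mu = 0.7)
  p <- forwardProject(f, 0, 128, 1)
  expect_equal(max(p), 2 * 50 * 0.7, tolerance = 0.01)
  # off-centre ray at offset b: chord 2 sqrt(r^2 - b^2)
  j <- 64.5 + 30
  expect_equal(p[64 + 30] + (p[65 + 30] - p[64 + 30]) * 0,
               2 * sqrt(50^2 - 30^2) * 0.7, tolerance = 0.02)
  # zero field projects to zero at every angle
  z <- matrix(0, 64, 64)
  for (a in c(0, 33.3, 181)) expect_identical(forwardProject(z, a), rep(0, 64))
})

test_that("projection is linear in the field and symmetric under 180-degree flips", {
  f <- softDisc(96, 30) + 0.3 * softDisc(96, 12)
  expect_equal(forwardProject(3 * f, 25), 3 * forwardProject(f, 25))
  for (a in c(0, 37, 122.4)) {
    p1 <- forwardProject(f, a)
    p2 <- forwardProject(f, a + 180)
    expect_equal(p1, rev(p2), tolerance = 1e-12)
  }
})

test_that("fields outside the reconstruction circle are refused", {
  f <- matrix(0, 64, 64)
  f[2, 2] <- 1  # corner voxel, radius > 32
  expect_error(forwardProject(f, 10), "reconstruction circle")
})

test_that("static noiseless frames repeat at full turns and match the detector model", {
  stack <- fxStackStaticClean()
  geom <- stackGeometry(stack)
  per_turn <- nProjectionsForRange(geom, 360) - 1L  # 1200 frames per 360 deg
  f <- frames(stack)
  expect_identical(f[, , 1], f[, , 1 + per_turn])
  expect_identical(f[, , 7], f[, , 7 + 2L * per_turn])
  # frame equals dark offset + flux * sensitivity * exp(-path integral)
  cfg <- testConfig()
  static <- cfg@phantom
  static@dissolution@front_speed_um_per_s <- 0
  p <- forwardProject(attenuationAt(static, 0), angles(stack)[8], 96, 1)
  sens <- flytomo:::.sensitivityMap(cfg@detector, c(1L, 96L))
  expected <- cfg@detector@dark_level + cfg@detector@flux * as.vector(sens) * exp(-p)
  expect_equal(as.vector(f[1, , 8]), expected, tolerance = 1e-12)
  # noiseless darks/flats are the deterministic detector response
  expect_equal(as.vector(darks(stack)[1, , 3]), rep(cfg@detector@dark_level, 96))
  expect_equal(as.vector(flats(stack)[1, , 3]),
               cfg@detector@dark_level + cfg@detector@flux * as.vector(sens))
})

test_that("a transparent sample leaves every frame at flat-plus-dark level", {
  geom <- scanGeometry(angular_step_deg = 10, n_projections = 19L,
                       detector_shape = c(1L, 48L), pixel_size_um = 1)
  ph <- phantomState(grid_shape = c(48L, 48L), mu_enamel = 1e-14,
                     mu_liquid = 0, texture_amplitude = 0)
  det <- detectorModel(noise = FALSE)
  stack <- simulateFlyscan(ph, geom, det, noise = FALSE)
  sens <- flytomo:::.sensitivityMap(det, c(1L, 48L))
  blank <- det@dark_level + det@flux * as.vector(sens)
  for (i in c(1, 10, 19))
    expect_equal(as.vector(frames(stack)[1, , i]), blank, tolerance = 1e-10)
})

test_that("a detector narrower than the phantom is an explicit truncation error", {
  geom <- scanGeometry(angular_step_deg = 10, n_projections = 19L,
                       detector_shape = c(1L, 64L))
  ph <- phantomState(grid_shape = c(96L, 96L))
  expect_error(simulateFlyscan(ph, geom, detectorModel(), noise = FALSE),
               "truncate")
})

test_that("equal seeds reproduce the stack bit-identically; seeds differ otherwise", {
  geom <- scanGeometry(angular_step_deg = 4.5, n_projections = 41L,
                       detector_shape = c(1L, 64L), n_dark = 5L, n_flat = 5L)
  ph <- phantomState(grid_shape = c(64L, 64L))
  det <- detectorModel()
  s1 <- simulateFlyscan(ph, geom, det, seed = 33)
  s2 <- simulateFlyscan(ph, geom, det, seed = 33)
  s3 <- simulateFlyscan(ph, geom, det, seed = 34)
  expect_identical(frames(s1), frames(s2))
  expect_identical(darks(s1), darks(s2))
  expect_false(identical(frames(s1), frames(s3)))
})

test_that("noise is unbiased: many-seed mean matches the noiseless frame", {
  geom <- scanGeometry(angular_step_deg = 90, n_projections = 2L,
                       detector_shape = c(1L, 32L), n_dark = 1L, n_flat = 1L)
  ph <- phantomState(grid_shape = c(32L, 32L), rod_period_um = 3)
  det <- detectorModel(flux = 2000)
  clean <- frames(simulateFlyscan(ph, geom, det, noise = FALSE))[1, , 1]
  n_rep <- 300
  acc <- 0
  for (k in seq_len(n_rep))
    acc <- acc + frames(simulateFlyscan(ph, geom, det, seed = k))[1, , 1]
  m <- acc / n_rep
  # grand mean within 3 standard errors (Poisson variance = expectation)
  sem <- sqrt(sum(clean - det@dark_level)) / (32 * sqrt(n_rep))
  expect_lt(abs(mean(m) - mean(clean)), 3 * sem)
})

test_that("adding material along a ray never increases detected intensity", {
  geom <- scanGeometry(angular_step_deg = 30, n_projections = 7L,
                       detector_shape = c(1L, 64L))
  base <- phantomState(grid_shape = c(64L, 64L), mu_enamel = 0.01)
  denser <- phantomState(grid_shape = c(64L, 64L), mu_enamel = 0.02)
  det <- detectorModel()
  f1 <- frames(simulateFlyscan(base, geom, det, noise = FALSE))
  f2 <- frames(simulateFlyscan(denser, geom, det, noise = FALSE))
  expect_true(all(f2 <= f1 + 1e-9))
})

test_that("projection stacks round-trip through the TIFF+JSON container", {
  geom <- scanGeometry(angular_step_deg = 12, n_projections = 16L,
                       detector_shape = c(1L, 48L), n_dark = 3L, n_flat = 3L,
                       overhead_s = 0.01)
  ph <- phantomState(grid_shape = c(48L, 48L))
  stack <- simulateFlyscan(ph, geom, detectorModel(), seed = 5)
  dir <- withr::local_tempdir()
  writeProjectionStack(stack, dir)
  back <- readProjectionStack(dir)
  expect_identical(stackGeometry(back), geom)
  expect_equal(angles(back), angles(stack))
  expect_equal(frameTimes(back), frameTimes(stack))
  # 32-bit container quantization
  expect_lt(max(abs(frames(back) - frames(stack))) / max(frames(stack)), 1e-8)
  expect_lt(max(abs(flats(back) - flats(stack))) / max(flats(stack)), 1e-8)
})

test_that("intra-frame angular blur averages sub-angle renders", {
  geom <- scanGeometry(angular_step_deg = 15, n_projections = 5L,
                       detector_shape = c(1L, 64L))
  ph <- phantomState(grid_shape = c(64L, 64L))
  det <- detectorModel()
  sharp <- frames(simulateFlyscan(ph, geom, det, noise = FALSE))
  blurred <- frames(simulateFlyscan(ph, geom, det, noise = FALSE,
                                    blur_substeps = 5L))
  expect_false(identical(sharp, blurred))
  expect_equal(mean(blurred), mean(sharp), tolerance = 1e-3)
})
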