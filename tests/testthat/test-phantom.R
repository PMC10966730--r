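test_that("pre-onset phantom has no dissolved voxels and the expected peak", {
  ph <- phantomState()
  f0 <- attenuationAt(ph, 0)
  expect_false(any(dissolvedMask(ph, 0)))
  expect_false(any(dissolvedMask(ph, ph@dissolution@onset_s)))
  # the softly-thresholded texture saturates somewhere on the default grid,
  # so the voxelwise max hits the nominal peak exactly
  expect_identical(max(f0), ph@mu_enamel * (1 + ph@texture_amplitude))
  expect_true(all(f0 >= 0))
  expect_identical(demineralizedVolume(ph, ph@dissolution@onset_s), 0)
})

test_that("front depth advances linearly and matches a brute-force distance test", {
  diss <- dissolutionModel(anisotropy_gain = 1, onset_s = 100,
                           front_speed_um_per_s = 0.02)
  ph <- phantomState(grid_shape = c(128L, 128L), dissolution = diss)
  r_en <- enamelRadius(ph)
  for (d in c(3, 8, 15)) {
    t <- 100 + d / 0.02
    expect_equal(frontDepth(ph, t), d)
    mask <- dissolvedMask(ph, t)
    co <- expand.grid(row = 1:128, col = 1:128)
    x <- (co$col - 64.5) * ph@voxel_size_um
    y <- (co$row - 64.5) * ph@voxel_size_um
    depth <- r_en - sqrt(x^2 + y^2)
    # deepest affected voxel sits at the front, within one voxel
    expect_lt(abs(max(depth[c(mask)]) - d), 1.5 * ph@voxel_size_um)
  }
})

test_that("dissolution with unit residual fraction leaves the field unchanged", {
  diss <- dissolutionModel(mu_dissolved_frac = 1)
  ph <- phantomState(dissolution = diss)
  expect_identical(attenuationAt(ph, 5000), attenuationAt(ph, 0))
  expect_identical(demineralizedVolume(ph, 5000), 0)
})

test_that("attenuation is voxelwise non-increasing in time", {
  ph <- phantomState()
  times <- c(0, 200, 400, 800, 1500, 3000)
  prev <- attenuationAt(ph, times[1])
  for (t in times[-1]) {
    cur <- attenuationAt(ph, t)
    expect_true(all(cur <= prev + 1e-15))
    prev <- cur
  }
  vols <- vapply(times, function(t) demineralizedVolume(ph, t), numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("dissolved voxels stay inside the exposed-window sector (brute force)", {
  ph <- phantomState()
  dm <- ph@dissolution
  mask <- dissolvedMask(ph, 2000)
  expect_true(any(mask))
  idx <- which(mask, arr.ind = TRUE)
  x <- (idx[, 2] - 48.5) * ph@voxel_size_um
  y <- (idx[, 1] - 48.5) * ph@voxel_size_um
  r_en <- enamelRadius(ph)
  # inside the enamel disc
  expect_true(all(sqrt(x^2 + y^2) <= r_en + 1e-12))
  # inside the angular sector of the window arc
  half_arc <- (dm@window_width_um / 2) / r_en * 180 / pi
  dphi <- ((atan2(y, x) * 180 / pi - dm@window_center_deg + 180) %% 360) - 180
  expect_true(all(abs(dphi) <= half_arc + 1e-9))
  # no deeper than the anisotropy-boosted front depth
  expect_true(all(r_en - sqrt(x^2 + y^2) <=
                    frontDepth(ph, 2000) * dm@anisotropy_gain + 1e-9))
})

test_that("phantom evaluation is deterministic", {
  ph <- phantomState()
  expect_identical(attenuationAt(ph, 1234.5), attenuationAt(ph, 1234.5))
})

test_that("fully dissolved half-disc window recovers the analytic area", {
  r_frac <- 0.75 * 0.95
  n <- 128L
  r_en <- r_frac * n / 2          # um at 1 um voxels
  diss <- dissolutionModel(window_width_um = pi * r_en,  # half the boundary
                           front_speed_um_per_s = 1, onset_s = 0,
                           anisotropy_gain = 1, mu_dissolved_frac = 0)
  ph <- phantomState(grid_shape = c(n, n), dissolution = diss)
  t <- 2 * r_en                   # front depth beyond the disc radius
  area <- demineralizedVolume(ph, t)
  analytic <- pi * r_en^2 / 2
  # agreement within a one-voxel shell around the half-disc perimeter
  shell <- (pi * r_en + 2 * r_en) * ph@voxel_size_um
  expect_lt(abs(area - analytic), shell)
})

test_that("anisotropic dissolution grows at least as fast as isotropic", {
  iso <- phantomState(dissolution = dissolutionModel(anisotropy_gain = 1))
  ani <- phantomState(dissolution = dissolutionModel(anisotropy_gain = 1.6))
  for (t in c(500, 1000, 2000))
    expect_gte(demineralizedVolume(ani, t), demineralizedVolume(iso, t))
})

test_that("3D phantoms extrude the slice with identical dissolution geometry", {
  ph3 <- phantomState(grid_shape = c(4L, 64L, 64L))
  f <- attenuationAt(ph3, 1000)
  expect_identical(dim(f), c(4L, 64L, 64L))
  ph2 <- phantomState(grid_shape = c(64L, 64L))
  expect_identical(f[1, , ], attenuationAt(ph2, 1000))
  expect_false(identical(f[1, , ], f[3, , ]))  # axial texture drift
  expect_equal(demineralizedVolume(ph3, 1000),
               4 * demineralizedVolume(ph2, 1000))
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantomState(mu_liquid = 0.03), "mu_liquid < mu_enamel")
  expect_error(phantomState(texture_amplitude = 1), "texture_amplitude")
  expect_error(phantomState(support_radius_frac = 1.2), "support_radius_frac")
  expect_error(dissolutionModel(anisotropy_gain = 0.5), ">= 1")
  expect_error(dissolutionModel(mu_dissolved_frac = 2), "0, 1")
})
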