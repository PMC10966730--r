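test_that("FBP recovers a uniform disc quantitatively", {
  f <- softDisc(128, 50, mu = 0.8)
  ang <- (0:400) * 0.45
  tomo <- fbpReconstruct(mkSino(f, ang))
  img <- tomogramImage(tomo)
  x <- seq_len(128) - 64.5
  R <- sqrt(outer(x^2, x^2, `+`))
  expect_equal(mean(img[R <= 45]), 0.8, tolerance = 0.05)
  expect_lt(abs(mean(img[R > 56 & R <= 63])), 0.05 * 0.8)
})

test_that("reconstruction is linear and maps zero to zero", {
  f <- softDisc(64, 20)
  ang <- (0:180) * 1
  sino <- mkSino(f, ang)
  r1 <- tomogramImage(fbpReconstruct(sino))
  sino3 <- sino; sino3@values <- 3 * sino@values
  expect_equal(tomogramImage(fbpReconstruct(sino3)), 3 * r1, tolerance = 1e-12)
  sino0 <- sino; sino0@values <- 0 * sino@values
  expect_identical(max(abs(tomogramImage(fbpReconstruct(sino0)))), 0)
})

test_that("angular coverage and spacing preconditions are enforced", {
  f <- softDisc(64, 20)
  expect_error(fbpReconstruct(mkSino(f, (0:100) * 1)), "insufficient angular coverage")
  ang <- c((0:100) * 2, 203, (102:110) * 2 + 2)
  expect_error(fbpReconstruct(mkSino(f, ang)), "non-uniform")
})

test_that("FBP matches an independent direct-summation oracle", {
  ph <- phantomState(grid_shape = c(48L, 48L), rod_period_um = 8)
  f <- attenuationAt(ph, 600)
  ang <- (0:100) * 1.8
  for (off in c(0, 1.5)) {
    sino <- mkSino(f, ang, center_offset = off)
    img <- tomogramImage(fbpReconstruct(sino))
    oracle <- fbpOracle(sino@values, ang, center_offset_px = off)
    expect_lt(max(abs(img - oracle)), 1e-6 * diff(range(oracle)))
  }
})

test_that("apodized filters attenuate high frequencies but preserve the disc mean", {
  f <- softDisc(96, 36)
  ang <- (0:300) * 0.6
  sino <- mkSino(f, ang)
  x <- seq_len(96) - 48.5
  R <- sqrt(outer(x^2, x^2, `+`))
  ramp <- tomogramImage(fbpReconstruct(sino, "ramp"))
  for (flt in c("shepp-logan", "hann")) {
    img <- tomogramImage(fbpReconstruct(sino, flt))
    expect_equal(mean(img[R <= 30]), mean(ramp[R <= 30]), tolerance = 0.02)
    # smoother output: less high-frequency energy along the centre row
    expect_lt(sum(diff(img[48, ])^2), sum(diff(ramp[48, ])^2))
  }
  expect_error(fbpReconstruct(sino, "butterworth"), "unknown filter")
})

test_that("round-trip fidelity improves with angular sampling on a smooth phantom", {
  n <- 96
  f <- softDisc(n, 34, 0.5)
  x <- seq_len(n) - (n + 1) / 2
  R2 <- outer(x^2, x^2, `+`)
  f <- f + 0.3 * exp(-R2 / (2 * 8^2)) * (sqrt(R2) <= 44)
  errs <- vapply(c(61, 181, 601), function(n_ang) {
    step <- 180 / (n_ang - 1)
    nrmse(tomogramImage(fbpReconstruct(mkSino(f, (0:(n_ang - 1)) * step))), f)
  }, numeric(1))
  expect_lt(errs[3], 0.05)
  expect_true(all(diff(errs) < 0))
})

test_that("reconstructions fold 180-degree-shifted windows onto each other", {
  ph <- phantomState()
  f <- attenuationAt(ph, 0)
  ang <- (0:600) * 0.3
  r0 <- tomogramImage(fbpReconstruct(mkSino(f, ang)))
  r180 <- tomogramImage(fbpReconstruct(mkSino(f, ang + 180)))
  r900 <- tomogramImage(fbpReconstruct(mkSino(f, ang + 900)))
  expect_lt(nrmse(r180, r0), 1e-12)
  expect_lt(nrmse(r900, r0), 1e-12)
  # arbitrary (non-multiple-of-180) starts agree to reconstruction tolerance
  r144 <- tomogramImage(fbpReconstruct(mkSino(f, ang + 144)))
  expect_lt(nrmse(r144, r0), 1e-2)
})

test_that("window reconstruction attaches time labels and provenance", {
  stack <- fxStackStaticClean()
  w <- fxWindows()[[2]]
  tomo <- reconstructWindow(stack, w)
  expect_s4_class(tomo, "Tomogram")
  expect_equal(tomogramTime(tomo), w@t_mid_s)
  expect_equal(tomo@voxel_size_um, stackGeometry(stack)@pixel_size_um)
  expect_match(tomo@provenance[1], "fbp filter=ramp")
  # bare WindowSpec derives its labels from the stack tables
  tomo2 <- reconstructWindow(stack, w@spec)
  expect_equal(tomogramTime(tomo2), w@t_mid_s)
  expect_identical(tomogramImage(tomo2), tomogramImage(tomo))
})

test_that("tomograms round-trip through the TIFF+JSON container", {
  stack <- fxStackStaticClean()
  tomo <- reconstructWindow(stack, fxWindows()[[1]])
  path <- withr::local_tempfile(fileext = ".tif")
  writeTomogram(tomo, path)
  back <- readTomogram(path)
  rng <- diff(range(tomogramImage(tomo)))
  expect_lt(max(abs(tomogramImage(back) - tomogramImage(tomo))) / rng, 1e-8)
  expect_identical(back@filter_name, tomo@filter_name)
  expect_equal(back@window@t_mid_s, tomo@window@t_mid_s)
  expect_identical(back@window@spec@start_index, tomo@window@spec@start_index)
})
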