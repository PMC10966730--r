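test_that("a tomogram differenced against itself is identically zero", {
  tomo <- fxTomosEvolving()[[1]]
  d <- differenceMap(tomo, tomo)
  expect_identical(max(abs(d)), 0)
})

test_that("shape and voxel mismatches are rejected", {
  a <- matrix(0, 10, 10)
  expect_error(differenceMap(a, matrix(0, 12, 12)), "shape")
  t1 <- new("Tomogram", image = a, voxel_size_um = 1, window = NULL,
            filter_name = "ramp", center_offset_px = 0, provenance = "x")
  t2 <- t1; t2@voxel_size_um <- 2
  expect_error(differenceMap(t1, t2), "voxel")
})

test_that("material loss concentrates inside the true cavity", {
  tomos <- fxTomosEvolving()
  d <- differenceMap(tomos[[length(tomos)]], tomos[[1]])
  cfg <- testConfig()
  truth <- dissolvedMask(cfg@phantom, tomos[[length(tomos)]]@window@t_mid_s)
  dil <- EBImage::dilate(EBImage::Image(truth * 1),
                         EBImage::makeBrush(7, "disc")) > 0
  inside <- flytomo:::.circleMask(nrow(d))
  # the strongest cavity-sized cohort of changes lies (almost) entirely
  # within the dilated true cavity
  n_top <- sum(truth)
  cutoff <- sort(d[inside], decreasing = TRUE)[n_top]
  top <- d >= cutoff & inside
  expect_gte(mean(dil[top]), 0.9)
})

test_that("noise-only difference maps have zero mean within uncertainty", {
  tomos <- fxTomosStaticNoisy()
  d <- differenceMap(tomos[[4]], tomos[[1]])
  inside <- flytomo:::.circleMask(nrow(d))
  # FBP noise is spatially correlated; estimate the standard error of the
  # mean from independent coarse blocks
  blocks <- tapply(d[inside],
                   interaction(ceiling(row(d)[inside] / 16),
                               ceiling(col(d)[inside] / 16), drop = TRUE),
                   mean)
  sem <- stats::sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(mean(d[inside])), 3 * sem)
})

test_that("cavity segmentation behaves at its limits", {
  z <- matrix(0, 64, 64)
  expect_identical(segmentCavity(z, threshold = 0.1)$volume, 0)
  expect_identical(segmentCavity(z)$volume, 0)  # Otsu on a constant map
  # volume is non-increasing in the threshold
  tomos <- fxTomosEvolving()
  d <- differenceMap(tomos[[6]], tomos[[1]])
  taus <- seq(0, max(d), length.out = 12)
  vols <- vapply(taus, function(tau)
    segmentCavity(d, threshold = tau)$volume, numeric(1))
  expect_true(all(diff(vols) <= 0))
  expect_identical(vols[12], 0)
  # largest-component suppression can only shrink the mask
  s_all <- segmentCavity(d, threshold = 0.002)
  s_lcc <- segmentCavity(d, threshold = 0.002, largest_component = TRUE)
  expect_lte(s_lcc$volume, s_all$volume)
  expect_true(all(s_all$mask[s_lcc$mask]))
})

test_that("Otsu segmentation of the final difference map recovers the cavity area", {
  tomos <- fxTomosEvolving()
  d <- differenceMap(tomos[[6]], tomos[[1]])
  seg <- segmentCavity(d, threshold = "otsu")
  expect_identical(seg$rule, "otsu")
  cfg <- testConfig()
  truth <- demineralizedVolume(cfg@phantom, tomos[[6]]@window@t_mid_s)
  expect_lt(abs(seg$volume - truth) / truth, 0.15)
})

test_that("static phantoms yield flat progression curves", {
  curve <- fxCurveNull()
  inside_area <- sum(flytomo:::.circleMask(96))
  expect_identical(curve@cavity_volume[1], 0)
  expect_lt(max(curve@cavity_volume), 0.005 * inside_area)
  # mean grey constant within noise
  expect_lt(diff(range(curve@mean_grey_in_roi)) /
              mean(curve@mean_grey_in_roi), 0.01)
})

test_that("the cavity growth rate matches the phantom's ground-truth rate", {
  curve <- fxCurveEvolving()
  cfg <- testConfig()
  truth <- vapply(curve@times_s, function(t)
    demineralizedVolume(cfg@phantom, t), numeric(1))
  post <- curve@times_s > cfg@phantom@dissolution@onset_s
  fit_m <- stats::lm(v ~ t, data.frame(t = curve@times_s[post],
                                       v = curve@cavity_volume[post]))
  fit_g <- stats::lm(v ~ t, data.frame(t = curve@times_s[post],
                                       v = truth[post]))
  expect_equal(unname(stats::coef(fit_m)[2]), unname(stats::coef(fit_g)[2]),
               tolerance = 0.15)
})

test_that("overlapping-window curves refine the disjoint curve consistently", {
  stack <- fxStackEvolving()
  cfg <- testConfig()
  owins <- enumerateWindows(cfg@geometry, cfg@n_window, 300L)
  otomos <- fixture("tomos_overlap", function()
    lapply(owins, function(w) reconstructWindow(stack, w)))
  curve <- fxCurveEvolving()
  ocurve <- progressionCurve(otomos, threshold = curve@threshold_used)
  m <- match(vapply(fxWindows(), function(w) w@spec@start_index, integer(1)),
             vapply(owins, function(w) w@spec@start_index, integer(1)))
  expect_false(anyNA(m))
  expect_identical(ocurve@cavity_volume[m], curve@cavity_volume)
  expect_identical(ocurve@times_s[m], curve@times_s)
  # the refined curve is denser in time
  expect_gt(length(ocurve@times_s), length(curve@times_s))
})

test_that("progression analysis is deterministic and rejects degenerate input", {
  tomos <- fxTomosEvolving()
  c1 <- progressionCurve(tomos)
  c2 <- progressionCurve(tomos)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(c1@threshold_used, c2@threshold_used)
  expect_error(progressionCurve(tomos[1]), "at least 2")
})

test_that("onset estimation interprets the null band correctly", {
  curve <- fxCurveEvolving()
  expect_identical(estimateOnset(curve, Inf), NA_real_)
  expect_identical(estimateOnset(curve, -1),  curve@times_s[1])
})

test_that("motion blur during a window is quantified as a small QC metric", {
  tomo <- fxTomosEvolving()[[4]]
  cfg <- testConfig()
  qc <- motionBlurQC(tomo, cfg@phantom, cfg@geometry, cfg@detector)
  expect_true(is.finite(qc))
  expect_gt(qc, 0)
  expect_lt(qc, 0.1)  # front moves ~1.5 um during a 300 s window
})
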