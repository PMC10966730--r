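#' TimeSeriesResult: temporal quantification across a tomogram sequence
#'
#' Per-tomogram nominal times, segmented cavity volumes (areas for 2D
#' slices), mean grey values in a fixed region of interest, the voxelwise
#' difference maps against the first (reference) tomogram, and the
#' segmentation threshold with the rule that produced it.
#'
#' @slot times_s nominal (mid-window) time per tomogram, seconds.
#' @slot cavity_volume segmented demineralized area/volume per tomogram
#'   (um^2 per slice, um^3 for volumes).
#' @slot mean_grey_in_roi mean reconstructed attenuation in the ROI.
#' @slot diff_maps list of difference maps vs the first tomogram (the first
#'   entry, tomogram vs itself, is identically zero).
#' @slot threshold_used the segmentation threshold applied to every map.
#' @slot threshold_rule how the threshold was chosen.
#' @slot monotone_fraction fraction of consecutive volume steps that are
#'   non-decreasing.
#' @export
setClass("TimeSeriesResult",
  representation(times_s = "numeric", cavity_volume = "numeric",
                 mean_grey_in_roi = "numeric", diff_maps = "list",
                 threshold_used = "numeric", threshold_rule = "character",
                 monotone_fraction = "numeric"))

setValidity("TimeSeriesResult", function(object) {
  n <- length(object@times_s)
  if (length(object@cavity_volume) != n || length(object@mean_grey_in_roi) != n ||
      length(object@diff_maps) != n)
    return("all per-tomogram series must have equal length")
  TRUE
})

setMethod("show", "TimeSeriesResult", function(object) {
  n <- length(object@times_s)
  cat(sprintf("TimeSeriesResult  %d tomograms, t = %.6g .. %.6g s\n",
              n, object@times_s[1], object@times_s[n]))
  cat(sprintf("  cavity volume %.6g -> %.6g (threshold %.4g, rule %s)\n",
              object@cavity_volume[1], object@cavity_volume[n],
              object@threshold_used, object@threshold_rule))
  cat(sprintf("  monotone fraction %.3g\n", object@monotone_fraction))
})

#' Coerce a TimeSeriesResult to a data.frame
#' @param x a [TimeSeriesResult-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return `data.frame(time_s, volume, mean_grey)`.
#' @export
as.data.frame.TimeSeriesResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(time_s = x@times_s, volume = x@cavity_volume,
             mean_grey = x@mean_grey_in_roi)
}

.circleMask <- function(n) {
  x <- (seq_len(n) - (n + 1) / 2)
  sqrt(outer(x^2, x^2, `+`)) <= n / 2
}

#' Voxelwise change map between two co-registered tomograms
#'
#' `reference - current`, so positive values mean loss of attenuating
#' material relative to the initial state. Both tomograms must share shape
#' and voxel size; no registration is performed (simulated sequences are
#' co-registered by construction). Pixels outside the reconstruction circle
#' are zero.
#'
#' @param tomo_t the later [Tomogram-class] (or matrix).
#' @param tomo_0 the reference [Tomogram-class] (or matrix).
#' @return Signed change matrix.
#' @export
differenceMap <- function(tomo_t, tomo_0) {
  vt <- if (is(tomo_t, "Tomogram")) tomo_t@voxel_size_um else NA_real_
  v0 <- if (is(tomo_0, "Tomogram")) tomo_0@voxel_size_um else NA_real_
  if (!is.na(vt) && !is.na(v0) && abs(vt - v0) > 1e-12)
    stop("voxel size mismatch between tomograms", call. = FALSE)
  a <- if (is(tomo_t, "Tomogram")) tomo_t@image else tomo_t
  b <- if (is(tomo_0, "Tomogram")) tomo_0@image else tomo_0
  if (!identical(dim(a), dim(b)))
    stop("shape mismatch between tomograms", call. = FALSE)
  d <- b - a
  d[!.circleMask(nrow(d))] <- 0
  d
}

# Otsu threshold of the in-circle values of a difference map
.otsuThreshold <- function(diff_map) {
  inside <- .circleMask(nrow(diff_map))
  v <- diff_map[inside]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  img <- EBImage::Image((diff_map - rng[1]) / diff(rng))
  EBImage::otsu(img, range = c(0, 1)) * diff(rng) + rng[1]
}

#' Segment the demineralized cavity in a difference map
#'
#' Thresholds the (positive = material loss) difference map inside the
#' reconstruction circle. The threshold is either a fixed value or chosen by
#' Otsu's method on the map's in-circle histogram; optionally only the
#' largest connected component is kept, suppressing noise speckle. An empty
#' mask is a valid result.
#'
#' @param diff_map matrix from [differenceMap()].
#' @param threshold `"otsu"` (default) or a fixed numeric threshold.
#' @param voxel_size_um voxel size used to convert counts to area/volume.
#' @param largest_component keep only the largest connected component.
#' @return List: `mask` (logical matrix), `volume` (um^2 for a slice),
#'   `threshold` (value used), `rule` (`"otsu"` or `"fixed"`).
#' @export
segmentCavity <- function(diff_map, threshold = "otsu", voxel_size_um = 1,
                          largest_component = FALSE) {
  stopifnot(is.matrix(diff_map))
  if (identical(threshold, "otsu")) {
    tau <- .otsuThreshold(diff_map); rule <- "otsu"
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    tau <- threshold; rule <- "fixed"
  }
  mask <- diff_map > tau & .circleMask(nrow(diff_map))
  if (largest_component && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- tabulate(as.integer(lab[lab > 0]))
    mask <- matrix(as.integer(lab) == which.max(sizes), nrow(mask))
  }
  list(mask = mask, volume = sum(mask) * voxel_size_um^2,
       threshold = tau, rule = rule)
}

#' Progression curve of demineralization across a tomogram sequence
#'
#' Takes an ordered list of co-registered tomograms (first = reference),
#' forms each one's difference map against the reference, segments the
#' cavity with a single threshold applied to the whole series, and reports
#' cavity volume and mean grey value against the mid-window times.
#'
#' Threshold rules:
#' \describe{
#'   \item{`"mad"` (default)}{`k` times the robust noise scale (median
#'     absolute deviation, scaled to sigma) of the *last* difference map's
#'     in-circle background. Signal-free series then segment essentially
#'     nothing, which keeps the static-phantom null band tight.}
#'   \item{`"otsu"`}{Otsu on the last (largest-change) difference map,
#'     applied to all maps. Appropriate once a clear cavity exists.}
#'   \item{numeric}{a fixed threshold, for exactly reproducible analyses.}
#' }
#'
#' @param tomograms list of [Tomogram-class] (>= 2), ordered by time.
#' @param threshold `"mad"`, `"otsu"` or a numeric threshold.
#' @param k multiplier for the `"mad"` rule.
#' @param roi_mask optional logical matrix: region for the mean grey value
#'   (default: the whole reconstruction circle).
#' @param largest_component passed to [segmentCavity()].
#' @return A [TimeSeriesResult-class].
#' @export
progressionCurve <- function(tomograms, threshold = "mad", k = 4,
                             roi_mask = NULL, largest_component = FALSE) {
  if (length(tomograms) < 2)
    stop("need at least 2 tomograms to measure progression", call. = FALSE)
  imgs <- lapply(tomograms, function(t) if (is(t, "Tomogram")) t@image else t)
  times <- vapply(seq_along(tomograms), function(i) {
    t <- tomograms[[i]]
    if (is(t, "Tomogram") && !is.null(t@window)) t@window@t_mid_s else as.numeric(i)
  }, numeric(1))
  vox <- if (is(tomograms[[1]], "Tomogram")) tomograms[[1]]@voxel_size_um else 1
  n <- nrow(imgs[[1]])
  inside <- .circleMask(n)
  if (is.null(roi_mask)) roi_mask <- inside

  diffs <- lapply(imgs, function(im) differenceMap(im, imgs[[1]]))
  last <- diffs[[length(diffs)]]
  if (identical(threshold, "mad")) {
    sigma <- stats::mad(last[inside])
    tau <- k * sigma; rule <- sprintf("mad(k=%g)", k)
  } else if (identical(threshold, "otsu")) {
    tau <- .otsuThreshold(last); rule <- "otsu"
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    tau <- threshold; rule <- "fixed"
  }
  seg <- lapply(diffs, segmentCavity, threshold = tau,
                voxel_size_um = vox, largest_component = largest_component)
  vols <- vapply(seg, `[[`, numeric(1), "volume")
  greys <- vapply(imgs, function(im) mean(im[roi_mask]), numeric(1))
  dv <- diff(vols)
  mono <- if (length(dv)) mean(dv >= 0) else 1
  new("TimeSeriesResult", times_s = times, cavity_volume = vols,
      mean_grey_in_roi = greys, diff_maps = diffs,
      threshold_used = tau, threshold_rule = rule,
      monotone_fraction = mono)
}

#' Estimate the dissolution onset time from a progression curve
#'
#' The onset is the mid-window time of the first tomogram whose segmented
#' cavity volume exceeds the null band (e.g. the 3-sigma excursion of a
#' static-phantom run under the same noise model).
#'
#' @param result a [TimeSeriesResult-class].
#' @param null_band volume threshold separating noise from signal.
#' @return Estimated onset time in seconds, or `NA` if never exceeded.
#' @export
estimateOnset <- function(result, null_band) {
  stopifnot(is(result, "TimeSeriesResult"))
  i <- which(result@cavity_volume > null_band)
  if (!length(i)) return(NA_real_)
  result@times_s[i[1]]
}

#' Motion-consistency QC of a window reconstruction
#'
#' Material dissolving *during* a window violates the static-object
#' assumption of filtered back-projection. This metric quantifies the effect
#' as the normalized RMSE between the window's reconstruction and an ideal
#' reconstruction of the phantom frozen at the window's mid-time (simulated
#' noiselessly over the same angles). Reported as QC, not corrected.
#'
#' @param tomo a [Tomogram-class] reconstructed from an evolving phantom.
#' @param state the [PhantomState-class] that generated the data.
#' @param geom the [ScanGeometry-class] of the parent scan.
#' @param detector the [DetectorModel-class] (noise is disabled here).
#' @return Normalized RMSE between the two reconstructions.
#' @export
motionBlurQC <- function(tomo, state, geom, detector = detectorModel()) {
  stopifnot(is(tomo, "Tomogram"), !is.null(tomo@window))
  win <- tomo@window
  frozen <- state
  # freeze: dissolution front held at the window's mid-time
  d <- frontDepth(state, win@t_mid_s)
  dm <- frozen@dissolution
  dm@onset_s <- 0
  dm@front_speed_um_per_s <- if (win@t_mid_s > 0) d / win@t_mid_s else 0
  frozen@dissolution <- dm
  sub_geom <- scanGeometry(
    angular_step_deg = geom@angular_step_deg, exposure_s = geom@exposure_s,
    overhead_s = geom@overhead_s, n_projections = win@spec@n_window,
    start_angle_deg = win@angles_deg[1],
    detector_shape = geom@detector_shape, pixel_size_um = geom@pixel_size_um,
    magnification = geom@magnification, n_dark = geom@n_dark,
    n_flat = geom@n_flat)
  # render the frozen phantom over the same angles, noise off
  frozen_static <- frozen
  frozen_static@dissolution@front_speed_um_per_s <- 0
  field <- attenuationAt(frozen, win@t_mid_s)
  if (length(dim(field)) == 3) field <- field[1, , ]
  det_cols <- geom@detector_shape[2]
  vals <- t(vapply(win@angles_deg, function(a)
    forwardProject(field, a, det_cols, state@voxel_size_um),
    numeric(det_cols)))
  sino <- new("Sinogram", values = vals, angles_deg = win@angles_deg,
              times_s = rep(win@t_mid_s, length(win@angles_deg)) +
                seq_along(win@angles_deg) * 1e-9,
              slice_index = 1L, center_offset_px = tomo@center_offset_px,
              qc = list())
  ideal <- fbpReconstruct(sino, filter_name = tomo@filter_name,
                          center_offset_px = tomo@center_offset_px,
                          pixel_size_um = tomo@voxel_size_um)
  nrmse(tomo, ideal)
}

#' Write a progression curve to CSV
#' @param result a [TimeSeriesResult-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
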