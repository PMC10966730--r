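#' @import methods
NULL

#' ScanGeometry: parameterization of a continuous-rotation (fly-scan) acquisition
#'
#' A `ScanGeometry` is the single source of truth for the index/angle/time
#' bookkeeping of a continuous-rotation scan: the rotation stage moves at
#' constant angular speed while the detector records frames at a fixed period,
#' so the projection index maps linearly to both rotation angle and wall-clock
#' time. Angles are kept *unwrapped* (cumulative, they may exceed 360 degrees);
#' use [wrapAngle()] where a wrapped angle is needed.
#'
#' Projection indices are **zero-based** throughout the package, matching the
#' numbering of frames in beamline scan files (a scan of `n_projections = N`
#' frames has indices `0 ... N-1`).
#'
#' @slot angular_step_deg degrees of rotation per projection.
#' @slot exposure_s exposure time per frame, seconds.
#' @slot overhead_s dead time (readout etc.) per frame, seconds; frame period
#'   is `exposure_s + overhead_s`.
#' @slot n_projections number of frames in the scan file.
#' @slot start_angle_deg unwrapped angle of projection index 0.
#' @slot detector_shape integer `(rows, cols)` of the detector in pixels.
#' @slot pixel_size_um effective pixel size at the sample plane, micrometres.
#' @slot magnification objective magnification that produced `pixel_size_um`.
#' @slot n_dark number of dark-field frames recorded with the scan.
#' @slot n_flat number of flat-field frames recorded with the scan.
#'
#' @seealso [scanGeometry()], [angleOfIndex()], [timeOfIndex()],
#'   [nProjectionsForRange()]
#' @export
setClass("ScanGeometry",
  representation(
    angular_step_deg = "numeric",
    exposure_s       = "numeric",
    overhead_s       = "numeric",
    n_projections    = "integer",
    start_angle_deg  = "numeric",
    detector_shape   = "integer",
    pixel_size_um    = "numeric",
    magnification    = "numeric",
    n_dark           = "integer",
    n_flat           = "integer"
  )
)

setValidity("ScanGeometry", function(object) {
  msgs <- character()
  if (length(object@angular_step_deg) != 1 || !is.finite(object@angular_step_deg) ||
      object@angular_step_deg <= 0)
    msgs <- c(msgs, "angular_step_deg must be a single positive number")
  if (length(object@exposure_s) != 1 || !is.finite(object@exposure_s) ||
      object@exposure_s <= 0)
    msgs <- c(msgs, "exposure_s must be a single positive number")
  if (length(object@overhead_s) != 1 || !is.finite(object@overhead_s) ||
      object@overhead_s < 0)
    msgs <- c(msgs, "overhead_s must be a single non-negative number")
  if (length(object@n_projections) != 1 || is.na(object@n_projections) ||
      object@n_projections < 2L)
    msgs <- c(msgs, "n_projections must be >= 2")
  if (length(object@detector_shape) != 2 || any(object@detector_shape < 1L))
    msgs <- c(msgs, "detector_shape must be two positive integers (rows, cols)")
  if (object@pixel_size_um <= 0) msgs <- c(msgs, "pixel_size_um must be positive")
  if (object@magnification <= 0) msgs <- c(msgs, "magnification must be positive")
  if (object@n_dark < 0L || object@n_flat < 0L)
    msgs <- c(msgs, "n_dark and n_flat must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScanGeometry
#'
#' Defaults describe the reference continuous-rotation acquisition: 15 001
#' frames at an angular step of 0.072 degrees (a 0 to 1080 degree scan, i.e.
#' six consecutive 180 degree tomograms) with 0.5 s exposure, a 10x objective
#' giving 0.325 um pixels at the sample plane, and 20 dark- plus 20 flat-field
#' frames recorded at the start of the scan.
#'
#' @param angular_step_deg degrees per projection.
#' @param exposure_s exposure per frame, seconds.
#' @param overhead_s per-frame dead time, seconds (default 0; the frame period
#'   is `exposure_s + overhead_s`).
#' @param n_projections frame count of the scan file.
#' @param start_angle_deg angle of projection index 0 (default 0).
#' @param detector_shape integer `(rows, cols)` in pixels.
#' @param pixel_size_um effective pixel size at the sample plane, micrometres.
#' @param magnification objective magnification.
#' @param n_dark,n_flat dark-/flat-field frame counts.
#' @return A [ScanGeometry-class] object.
#' @examples
#' geom <- scanGeometry()
#' angleOfIndex(geom, 2500)   # 180 degrees
#' nProjectionsForRange(geom, 180)
#' @export
scanGeometry <- function(angular_step_deg = 0.072, exposure_s = 0.5,
                         overhead_s = 0, n_projections = 15001L,
                         start_angle_deg = 0,
                         detector_shape = c(2160L, 2560L),
                         pixel_size_um = 0.325, magnification = 10,
                         n_dark = 20L, n_flat = 20L) {
  new("ScanGeometry",
      angular_step_deg = as.numeric(angular_step_deg),
      exposure_s = as.numeric(exposure_s),
      overhead_s = as.numeric(overhead_s),
      n_projections = as.integer(n_projections),
      start_angle_deg = as.numeric(start_angle_deg),
      detector_shape = as.integer(detector_shape),
      pixel_size_um = as.numeric(pixel_size_um),
      magnification = as.numeric(magnification),
      n_dark = as.integer(n_dark), n_flat = as.integer(n_flat))
}

#' The reference full-scale acquisition geometry
#'
#' Convenience constructor for the full-scale continuous scan used for the
#' scan-arithmetic checks: 15 001 projections, 0.072 degree step, 0.5 s
#' exposure, 10x objective, 0.325 um pixels.
#' @return A [ScanGeometry-class].
#' @export
referenceGeometry <- function() scanGeometry()

.checkIndex <- function(geom, i) {
  n <- geom@n_projections
  bad <- !is.finite(i) | i < 0 | i > n - 1L | (i != floor(i))
  if (any(bad))
    stop(sprintf(
      "projection index out of range: valid indices are 0 .. %d (got %s)",
      n - 1L, paste(utils::head(i[bad], 3L), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Unwrapped rotation angle of a projection index
#'
#' Computed multiplicatively from the index (`start + i * step`), never by
#' accumulation, so there is no floating-point drift along the scan.
#'
#' @param geom a [ScanGeometry-class].
#' @param i zero-based projection index (vectorized).
#' @return Angle(s) in degrees, unwrapped (may exceed 360).
#' @export
angleOfIndex <- function(geom, i) {
  stopifnot(is(geom, "ScanGeometry"))
  .checkIndex(geom, i)
  geom@start_angle_deg + i * geom@angular_step_deg
}

#' Acquisition start time of a projection index
#'
#' Timestamps refer to the *start* of the frame's exposure; index 0 is time 0.
#'
#' @inheritParams angleOfIndex
#' @return Time(s) in seconds: `i * (exposure_s + overhead_s)`.
#' @export
timeOfIndex <- function(geom, i) {
  stopifnot(is(geom, "ScanGeometry"))
  .checkIndex(geom, i)
  i * (geom@exposure_s + geom@overhead_s)
}

#' Number of projections spanning an angular range
#'
#' Fence-post inclusive: a range of 180 degrees at a 0.072 degree step
#' contains `180/0.072 + 1 = 2501` projections (both endpoints present).
#' The range must be an integer multiple of the angular step to within
#' 1e-9 degrees; otherwise an error reports the nearest commensurate ranges.
#'
#' @param geom a [ScanGeometry-class].
#' @param range_deg angular range in degrees (> 0).
#' @return Integer projection count.
#' @export
nProjectionsForRange <- function(geom, range_deg) {
  stopifnot(is(geom, "ScanGeometry"), length(range_deg) == 1, range_deg > 0)
  step <- geom@angular_step_deg
  k <- range_deg / step
  if (abs(range_deg - round(k) * step) > 1e-9) {
    lo <- floor(k) * step; hi <- ceiling(k) * step
    stop(sprintf(
      "range %.9g deg is not a multiple of the angular step %.9g deg; nearest commensurate ranges are %.9g and %.9g deg",
      range_deg, step, lo, hi), call. = FALSE)
  }
  as.integer(round(k)) + 1L
}

#' Total angular range of a scan
#'
#' `(n_projections - 1) * angular_step_deg`, consistent with the fence-post
#' convention of [nProjectionsForRange()].
#' @param geom a [ScanGeometry-class].
#' @return Range in degrees.
#' @export
angularRange <- function(geom) {
  stopifnot(is(geom, "ScanGeometry"))
  (geom@n_projections - 1L) * geom@angular_step_deg
}

#' Wrap an unwrapped angle into `[0, period)` degrees
#'
#' Pure helper used by the reconstructor; the bookkeeping itself always keeps
#' angles cumulative so that time ordering is preserved.
#' @param angle_deg angle(s) in degrees.
#' @param period wrap period, 360 by default (180 folds parallel-beam pairs).
#' @return Wrapped angle(s) in `[0, period)`.
#' @export
wrapAngle <- function(angle_deg, period = 360) {
  a <- angle_deg %% period
  # guard against -1e-16 %% 360 == 360 style artefacts
  a[a >= period] <- a[a >= period] - period
  a
}

#' Frame period of the acquisition
#' @param geom a [ScanGeometry-class].
#' @return Seconds per frame (`exposure_s + overhead_s`).
#' @export
framePeriod <- function(geom) {
  stopifnot(is(geom, "ScanGeometry"))
  geom@exposure_s + geom@overhead_s
}

#' Number of projections in a scan geometry
#' @param geom a [ScanGeometry-class].
#' @return Integer frame count.
#' @export
nProjections <- function(geom) {
  stopifnot(is(geom, "ScanGeometry"))
  geom@n_projections
}

#' Angular step of a scan geometry
#' @param geom a [ScanGeometry-class].
#' @return Degrees per projection.
#' @export
angularStep <- function(geom) {
  stopifnot(is(geom, "ScanGeometry"))
  geom@angular_step_deg
}

#' Detector shape of a scan geometry
#' @param geom a [ScanGeometry-class].
#' @return Integer `(rows, cols)`.
#' @export
detectorShape <- function(geom) {
  stopifnot(is(geom, "ScanGeometry"))
  geom@detector_shape
}

#' Effective pixel size at the sample plane
#' @param geom a [ScanGeometry-class].
#' @return Micrometres per pixel.
#' @export
pixelSize <- function(geom) {
  stopifnot(is(geom, "ScanGeometry"))
  geom@pixel_size_um
}

#' Voxel size implied by a different objective magnification
#'
#' The product `pixel_size_um * magnification` is a property of the detector
#' and is constant across objectives, so the voxel size at magnification `m`
#' is `pixel_size_um * magnification / m`. For the reference geometry
#' (0.325 um at 10x) the 4x objective gives 0.8125 um.
#'
#' @param geom a [ScanGeometry-class].
#' @param magnification the other objective's magnification.
#' @return Voxel size in micrometres.
#' @export
voxelSizeFor <- function(geom, magnification) {
  stopifnot(is(geom, "ScanGeometry"), magnification > 0)
  geom@pixel_size_um * geom@magnification / magnification
}

#' Serialize a ScanGeometry to a flat named list
#'
#' Keys are the slot names verbatim; the list round-trips through YAML/JSON
#' and through [geometryFromList()].
#' @param geom a [ScanGeometry-class].
#' @return Named list of geometry fields.
#' @export
geometryToList <- function(geom) {
  stopifnot(is(geom, "ScanGeometry"))
  list(
    angular_step_deg = geom@angular_step_deg,
    exposure_s       = geom@exposure_s,
    overhead_s       = geom@overhead_s,
    n_projections    = geom@n_projections,
    start_angle_deg  = geom@start_angle_deg,
    detector_shape   = geom@detector_shape,
    pixel_size_um    = geom@pixel_size_um,
    magnification    = geom@magnification,
    n_dark           = geom@n_dark,
    n_flat           = geom@n_flat)
}

#' Rebuild a ScanGeometry from its serialized list
#' @param lst a list as produced by [geometryToList()] (extra keys are an error).
#' @return A [ScanGeometry-class].
#' @export
geometryFromList <- function(lst) {
  known <- names(formals(scanGeometry))
  extra <- setdiff(names(lst), known)
  if (length(extra))
    stop("unknown geometry keys: ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(scanGeometry, lst)
}

#' Format seconds as hh:mm:ss
#'
#' Used when reporting the time difference between the first-projection start
#' times of two tomograms.
#' @param seconds non-negative duration(s) in seconds.
#' @return Character vector "hh:mm:ss" (seconds rounded to nearest integer).
#' @export
formatHMS <- function(seconds) {
  s <- round(seconds)
  sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
}

setMethod("show", "ScanGeometry", function(object) {
  cat("ScanGeometry\n")
  cat(sprintf("  %d projections, step %.4g deg  (range %.6g deg, %s)\n",
              object@n_projections, object@angular_step_deg,
              angularRange(object),
              formatHMS((object@n_projections - 1L) * framePeriod(object))))
  cat(sprintf("  exposure %.3g s + overhead %.3g s per frame\n",
              object@exposure_s, object@overhead_s))
  cat(sprintf("  detector %d x %d px, %.4g um/px at %gx\n",
              object@detector_shape[1], object@detector_shape[2],
              object@pixel_size_um, object@magnification))
  cat(sprintf("  %d dark / %d flat frames\n", object@n_dark, object@n_flat))
})
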