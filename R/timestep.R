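#' WindowSpec: a contiguous projection subset of a continuous scan
#'
#' A window is the half-open index range `[start_index, start_index +
#' n_window)` of the scan file; `stride` is the index step between successive
#' windows in an enumeration. With the fence-post convention a 180 degree
#' window at a 0.072 degree step holds 2501 frames, consecutive disjoint
#' windows (stride 2500) share exactly one boundary frame's angle span, and
#' any stride down to one frame period gives overlapping windows - the
#' refinement of the nominal time step that motivates the time-stepping
#' interpretation.
#'
#' @slot start_index zero-based index of the first frame.
#' @slot n_window number of frames in the window (>= 2).
#' @slot stride index step to the next window (>= 1).
#' @export
setClass("WindowSpec",
  representation(start_index = "integer", n_window = "integer",
                 stride = "integer"))

setValidity("WindowSpec", function(object) {
  msgs <- character()
  if (object@start_index < 0L) msgs <- c(msgs, "start_index must be >= 0")
  if (object@n_window < 2L) msgs <- c(msgs, "n_window must be >= 2")
  if (object@stride < 1L) msgs <- c(msgs, "stride must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a WindowSpec
#' @param start_index zero-based first frame index.
#' @param n_window frame count (default 2501, a 180 degree window at the
#'   reference 0.072 degree step).
#' @param stride index step between successive windows (default 2500:
#'   disjoint 180 degree windows).
#' @return A [WindowSpec-class].
#' @export
windowSpec <- function(start_index = 0L, n_window = 2501L, stride = 2500L) {
  new("WindowSpec", start_index = as.integer(start_index),
      n_window = as.integer(n_window), stride = as.integer(stride))
}

.checkWindow <- function(spec, n_total) {
  if (spec@start_index + spec@n_window > n_total)
    stop(sprintf(
      "window [%d, %d) exceeds the scan's %d projections",
      spec@start_index, spec@start_index + spec@n_window, n_total),
      call. = FALSE)
  invisible(TRUE)
}

#' TomogramWindow: a window with its derived angle and time labels
#'
#' Carries the per-frame unwrapped angles and the start/mid/end exposure
#' times of the window. The headline time label of a reconstruction is
#' `t_mid_s` (the object evolves during the window); `t_start_s` is the
#' first-projection start time used when reporting hh:mm:ss differences
#' between tomograms.
#'
#' @slot spec the [WindowSpec-class].
#' @slot angles_deg per-frame unwrapped angles.
#' @slot t_start_s,t_mid_s,t_end_s exposure-start times of the first, middle
#'   and last frame, seconds.
#' @slot label ordinal of the window within its enumeration (1-based).
#' @export
setClass("TomogramWindow",
  representation(spec = "WindowSpec", angles_deg = "numeric",
                 t_start_s = "numeric", t_mid_s = "numeric",
                 t_end_s = "numeric", label = "integer"))

setMethod("show", "TomogramWindow", function(object) {
  s <- object@spec
  cat(sprintf(
    "TomogramWindow #%d  frames [%d, %d)  angles %.6g..%.6g deg  t_start %s (t_mid %.6g s)\n",
    object@label, s@start_index, s@start_index + s@n_window,
    object@angles_deg[1], object@angles_deg[length(object@angles_deg)],
    formatHMS(object@t_start_s), object@t_mid_s))
})

#' Build the TomogramWindow for a WindowSpec under a geometry
#' @param geom a [ScanGeometry-class].
#' @param spec a [WindowSpec-class].
#' @param label ordinal label (default 1).
#' @return A [TomogramWindow-class].
#' @export
tomogramWindow <- function(geom, spec, label = 1L) {
  stopifnot(is(geom, "ScanGeometry"), is(spec, "WindowSpec"))
  .checkWindow(spec, geom@n_projections)
  idx <- seq.int(spec@start_index, spec@start_index + spec@n_window - 1L)
  mid <- spec@start_index + (spec@n_window - 1) / 2
  new("TomogramWindow", spec = spec, angles_deg = angleOfIndex(geom, idx),
      t_start_s = timeOfIndex(geom, idx[1]),
      t_mid_s = mid * framePeriod(geom),
      t_end_s = timeOfIndex(geom, idx[length(idx)]),
      label = as.integer(label))
}

#' Enumerate the reconstruction windows of a scan
#'
#' Windows are `[s, s + n_window)` for `s = 0, stride, 2 stride, ...` while
#' they fit in the scan, ordered by start index; the count is
#' `floor((N - n_window)/stride) + 1`. The reference scan of 15 001 frames
#' yields six disjoint 2501-frame/180 degree windows at stride 2500; smaller
#' strides give overlapping windows whose start times are `stride` frame
#' periods apart, down to a single frame period.
#'
#' @param geom a [ScanGeometry-class].
#' @param n_window frames per window (default 2501).
#' @param stride index step between windows (default 2500).
#' @return List of [TomogramWindow-class], ordered by start; `t_mid` is
#'   strictly increasing along the list.
#' @export
enumerateWindows <- function(geom, n_window = 2501L, stride = 2500L) {
  stopifnot(is(geom, "ScanGeometry"), stride >= 1)
  n_window <- as.integer(n_window); stride <- as.integer(stride)
  N <- geom@n_projections
  if (n_window > N)
    stop(sprintf("n_window (%d) exceeds the scan's %d projections",
                 n_window, N), call. = FALSE)
  starts <- seq.int(0L, N - n_window, by = stride)
  lapply(seq_along(starts), function(k)
    tomogramWindow(geom, windowSpec(starts[k], n_window, stride), label = k))
}

#' Tabulate an enumeration of windows
#'
#' One row per window: ordinal, start index, start/mid angle, start/mid/end
#' time, and the hh:mm:ss difference between each window's first-projection
#' start time and the first window's.
#'
#' @param windows list of [TomogramWindow-class] from [enumerateWindows()].
#' @return A `data.frame`.
#' @export
windowTable <- function(windows) {
  stopifnot(length(windows) >= 1)
  df <- do.call(rbind, lapply(windows, function(w) {
    s <- w@spec
    data.frame(
      label = w@label, start_index = s@start_index, n_window = s@n_window,
      start_angle_deg = w@angles_deg[1],
      mid_angle_deg = (w@angles_deg[1] + w@angles_deg[length(w@angles_deg)]) / 2,
      t_start_s = w@t_start_s, t_mid_s = w@t_mid_s, t_end_s = w@t_end_s)
  }))
  df$dt_from_first <- formatHMS(df$t_start_s - df$t_start_s[1])
  df
}

#' Extract a window of projections as a sub-stack
#'
#' The sub-stack preserves each frame's original unwrapped angle and
#' timestamp (no re-zeroing) and inherits the parent's dark and flat frames;
#' its geometry records the window's frame count and start angle. Frames
#' shared by overlapping windows are value-identical.
#'
#' @param stack a [ProjectionStack-class].
#' @param spec a [WindowSpec-class] valid for the stack.
#' @return A [ProjectionStack-class] holding the window's frames.
#' @export
extractWindow <- function(stack, spec) {
  stopifnot(is(stack, "ProjectionStack"), is(spec, "WindowSpec"))
  n_total <- dim(stack@frames)[3]
  .checkWindow(spec, n_total)
  idx <- seq.int(spec@start_index + 1L, spec@start_index + spec@n_window)
  g <- stack@geom
  sub_geom <- scanGeometry(
    angular_step_deg = g@angular_step_deg, exposure_s = g@exposure_s,
    overhead_s = g@overhead_s, n_projections = spec@n_window,
    start_angle_deg = stack@angles_deg[idx[1]],
    detector_shape = g@detector_shape, pixel_size_um = g@pixel_size_um,
    magnification = g@magnification, n_dark = g@n_dark, n_flat = g@n_flat)
  new("ProjectionStack",
      frames = stack@frames[, , idx, drop = FALSE],
      angles_deg = stack@angles_deg[idx], times_s = stack@times_s[idx],
      darks = stack@darks, flats = stack@flats, geom = sub_geom,
      provenance = c(sprintf("extractWindow [%d, %d)", spec@start_index,
                             spec@start_index + spec@n_window),
                     stack@provenance))
}
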