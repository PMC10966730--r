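#' Sinogram: line integrals of one detector row across a projection window
#'
#' Rows are the dark/flat-corrected, log-transformed values of one detector
#' row for each projection in a window, ordered by time, each carrying its
#' projection's unwrapped angle and timestamp.
#'
#' @slot values numeric matrix `[n_proj, n_detector]` of line integrals.
#' @slot angles_deg per-row unwrapped angle, strictly increasing.
#' @slot times_s per-row exposure-start time.
#' @slot slice_index detector row of origin (1-based).
#' @slot center_offset_px rotation-axis offset from the detector mid-column.
#' @slot qc list of quality metrics (clamped-pixel count, dead-pixel count).
#' @export
setClass("Sinogram",
  representation(values = "matrix", angles_deg = "numeric", times_s = "numeric",
                 slice_index = "integer", center_offset_px = "numeric",
                 qc = "list"))

setValidity("Sinogram", function(object) {
  msgs <- character()
  n <- nrow(object@values)
  if (!all(is.finite(object@values))) msgs <- c(msgs, "values must be finite")
  if (length(object@angles_deg) != n || length(object@times_s) != n)
    msgs <- c(msgs, "angles_deg/times_s must have one entry per sinogram row")
  if (n > 1 && any(diff(object@angles_deg) <= 0))
    msgs <- c(msgs, "angles must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram  %d projections x %d detector px (slice %d)\n",
              nrow(object@values), ncol(object@values), object@slice_index))
  cat(sprintf("  angles %.6g .. %.6g deg | clamped %d, dead %d px\n",
              object@angles_deg[1], object@angles_deg[length(object@angles_deg)],
              object@qc$n_clamped %||% 0L, object@qc$n_dead %||% 0L))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combine dark- or flat-field frames into a reference image
#'
#' Pixelwise median by default (robust against zingers); mean optionally.
#' @param arr array `(rows, cols, n)` of frames.
#' @param stat `"median"` or `"mean"`.
#' @return Matrix `(rows, cols)`.
#' @export
combineFields <- function(arr, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(length(dim(arr)) == 3)
  f <- if (stat == "median") stats::median else mean
  apply(arr, c(1, 2), f)
}

# fill pixels flagged TRUE in `dead` with the nearest (Euclidean) valid pixel
.fillNearest <- function(img, dead) {
  if (!any(dead)) return(img)
  valid <- which(!dead, arr.ind = TRUE)
  bad <- which(dead, arr.ind = TRUE)
  for (k in seq_len(nrow(bad))) {
    d2 <- (valid[, 1] - bad[k, 1])^2 + (valid[, 2] - bad[k, 2])^2
    j <- which.min(d2)
    img[bad[k, 1], bad[k, 2]] <- img[valid[j, 1], valid[j, 2]]
  }
  img
}

#' Dark/flat-field correction to transmittance
#'
#' `T = (P - D) / (F - D)` pixelwise. Pixels where the flat does not exceed
#' the dark (`F <= D`) are dead: they are filled with the nearest valid
#' pixel's transmittance and flagged in the `"deadMask"` attribute of the
#' result. A frame with no valid pixel at all is an error.
#'
#' The correction is scale-invariant: multiplying `P`, `D` and `F` by a
#' common positive constant leaves `T` unchanged.
#'
#' @param frame raw detector frame (matrix).
#' @param dark_mean combined dark field (matrix, same shape).
#' @param flat_mean combined flat field (matrix, same shape).
#' @return Transmittance matrix with attribute `deadMask` (logical matrix).
#' @export
flatDarkCorrect <- function(frame, dark_mean, flat_mean) {
  stopifnot(is.matrix(frame),
            identical(dim(frame), dim(dark_mean)),
            identical(dim(frame), dim(flat_mean)))
  denom <- flat_mean - dark_mean
  dead <- !(denom > 0)
  if (all(dead))
    stop("flat field nowhere exceeds dark field: all detector pixels dead",
         call. = FALSE)
  tr <- (frame - dark_mean) / denom
  tr[dead] <- NA_real_
  tr <- .fillNearest(tr, dead)
  attr(tr, "deadMask") <- dead
  tr
}

#' Beer-Lambert negative log transform
#'
#' `p = -ln(max(T, eps))`; the clamp makes the transform total on noisy
#' transmittance (zero or negative values map to `-ln(eps)`). The number of
#' clamped pixels is recorded in the `"nClamped"` attribute as a QC metric.
#'
#' @param transmittance matrix (or vector) of transmittance values.
#' @param eps clamp floor, default `1e-6`.
#' @return Line-integral image `p >= 0` wherever `T <= 1`.
#' @export
negLog <- function(transmittance, eps = 1e-6) {
  stopifnot(eps > 0)
  n_clamped <- sum(transmittance < eps)
  p <- -log(pmax(transmittance, eps))
  attributes(p) <- attributes(transmittance)["dim"]
  attr(p, "nClamped") <- n_clamped
  p
}

#' Assemble the sinogram of one detector row over a projection window
#'
#' Applies dark/flat correction (reference fields combined per
#' [combineFields()]) and the negative log transform to the chosen detector
#' row of every projection in the window, carrying each projection's angle
#' and timestamp into the sinogram rows.
#'
#' @param stack a [ProjectionStack-class].
#' @param slice_index detector row (1-based), default 1.
#' @param window a [WindowSpec-class], or `NULL` for the full stack.
#' @param center_offset_px rotation-axis offset recorded on the sinogram.
#' @param stat dark/flat combination statistic, see [combineFields()].
#' @param eps clamp floor for [negLog()].
#' @return A [Sinogram-class].
#' @export
assembleSinogram <- function(stack, slice_index = 1L, window = NULL,
                             center_offset_px = 0, stat = "median",
                             eps = 1e-6) {
  stopifnot(is(stack, "ProjectionStack"))
  d <- dim(stack@frames)
  if (slice_index < 1L || slice_index > d[1])
    stop(sprintf("slice_index out of range: valid rows are 1 .. %d", d[1]),
         call. = FALSE)
  idx <- if (is.null(window)) seq_len(d[3]) else {
    stopifnot(is(window, "WindowSpec"))
    .checkWindow(window, d[3])
    seq.int(window@start_index + 1L, window@start_index + window@n_window)
  }
  dark <- combineFields(stack@darks, stat)
  flat <- combineFields(stack@flats, stat)
  dark_row <- dark[slice_index, ]
  flat_row <- flat[slice_index, ]
  denom <- flat_row - dark_row
  dead <- !(denom > 0)
  if (all(dead))
    stop("flat field nowhere exceeds dark field on this detector row",
         call. = FALSE)
  raw <- stack@frames[slice_index, , idx, drop = TRUE]   # [n_det, n_win]
  raw <- matrix(raw, nrow = d[2])
  tr <- (raw - dark_row) / denom
  if (any(dead)) {                     # 1-D nearest-valid fill along the row
    good <- which(!dead)
    for (j in which(dead)) tr[j, ] <- tr[good[which.min(abs(good - j))], ]
  }
  n_clamped <- sum(tr < eps)
  vals <- t(-log(pmax(tr, eps)))       # [n_win, n_det]
  new("Sinogram", values = vals,
      angles_deg = stack@angles_deg[idx], times_s = stack@times_s[idx],
      slice_index = as.integer(slice_index),
      center_offset_px = as.numeric(center_offset_px),
      qc = list(n_clamped = n_clamped, n_dead = sum(dead)))
}
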