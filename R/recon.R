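setClassUnion("TomogramWindowOrNULL", c("TomogramWindow", "NULL"))

#' Tomogram: one reconstructed attenuation slice with provenance
#'
#' @slot image numeric `(n, n)` matrix of reconstructed attenuation; values
#'   outside the inscribed reconstruction circle are zero.
#' @slot voxel_size_um reconstructed voxel size, micrometres.
#' @slot window the [TomogramWindow-class] the slice was reconstructed from
#'   (or `NULL` for a bare sinogram reconstruction).
#' @slot filter_name reconstruction filter used.
#' @slot center_offset_px rotation-axis offset applied, pixels.
#' @slot provenance free text sufficient to re-run the reconstruction.
#' @export
setClass("Tomogram",
  representation(image = "matrix", voxel_size_um = "numeric",
                 window = "TomogramWindowOrNULL", filter_name = "character",
                 center_offset_px = "numeric", provenance = "character"))

setValidity("Tomogram", function(object) {
  if (nrow(object@image) != ncol(object@image))
    return("image must be square (n_detector x n_detector)")
  TRUE
})

#' @describeIn Tomogram-class the reconstructed image matrix.
#' @param tomo a `Tomogram`.
#' @export
tomogramImage <- function(tomo) { stopifnot(is(tomo, "Tomogram")); tomo@image }

#' @describeIn Tomogram-class mid-window time label (seconds), `NA` for bare
#'   reconstructions.
#' @export
tomogramTime <- function(tomo) {
  stopifnot(is(tomo, "Tomogram"))
  if (is.null(tomo@window)) NA_real_ else tomo@window@t_mid_s
}

setMethod("show", "Tomogram", function(object) {
  cat(sprintf("Tomogram  %d x %d px @ %.4g um (filter %s, center offset %.3g px)\n",
              nrow(object@image), ncol(object@image), object@voxel_size_um,
              object@filter_name, object@center_offset_px))
  if (!is.null(object@window))
    cat(sprintf("  window #%d: t_start %s, t_mid %.6g s\n", object@window@label,
                formatHMS(object@window@t_start_s), object@window@t_mid_s))
})

# band-limited ramp convolution kernel (spatial domain, unit sample pitch):
# h[0] = 1/4, h[k] = -1/(pi^2 k^2) for odd k, 0 for even k != 0
.rampKernelSpatial <- function(L) {
  k <- c(0:(L %/% 2), -((L - L %/% 2 - 1):1))
  h <- numeric(L)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi^2 * k[odd]^2)
  h[k == 0] <- 0.25
  h
}

# frequency response of the (apodized) ramp filter for rows padded to length L
.filterResponse <- function(L, filter_name) {
  H <- Re(stats::fft(.rampKernelSpatial(L)))
  f <- c(0:(L %/% 2), -((L - L %/% 2 - 1):1)) / L   # cycles/sample
  fhat <- abs(f) / 0.5                              # 0..1 of Nyquist
  w <- switch(filter_name,
    "ramp" = , "ram-lak" = rep(1, L),
    "shepp-logan" = ifelse(fhat == 0, 1, sin(pi * fhat / 2) / (pi * fhat / 2)),
    "hann" = 0.5 * (1 + cos(pi * fhat)),
    stop("unknown filter: ", filter_name, call. = FALSE))
  H * w
}

#' Ramp-filter sinogram rows
#'
#' Linear convolution of each row with the band-limited ramp kernel,
#' implemented by FFT with zero padding to at least twice the row length;
#' optional Shepp-Logan or Hann apodization of the frequency response.
#'
#' @param values sinogram matrix `[n_proj, n_det]`.
#' @param pixel_size_um detector pitch (scales the filtered rows by `1/pitch`).
#' @param filter_name `"ramp"` (alias `"ram-lak"`), `"shepp-logan"` or `"hann"`.
#' @return Filtered matrix of the same shape.
#' @export
filterSinogramRows <- function(values, pixel_size_um = 1, filter_name = "ramp") {
  n <- ncol(values)
  L <- 2^ceiling(log2(2 * n))
  H <- .filterResponse(L, filter_name)
  pad <- matrix(0, nrow(values), L)
  pad[, seq_len(n)] <- values
  ft <- t(apply(pad, 1, function(row) Re(stats::fft(stats::fft(row) * H,
                                                    inverse = TRUE)) / L))
  ft[, seq_len(n), drop = FALSE] / pixel_size_um
}

#' Filtered back-projection of a sinogram
#'
#' Parallel-beam FBP supporting arbitrary (unwrapped) projection angles: each
#' filtered row is smeared across the image at its own acquisition angle, so
#' windows starting anywhere on the circle reconstruct identically for a
#' static object (the parallel-beam identity `p(theta + 180, r) = p(theta, -r)`
#' is honoured automatically by the backprojection geometry). Angles must be
#' uniformly spaced and span at least 180 degrees; spans covering the circle
#' multiple times (e.g. a full 1080 degree scan) are averaged over their
#' half-turn coverage.
#'
#' Conventions: linear interpolation into the filtered rows; pixel-centre
#' coordinates with the rotation axis projecting to detector column
#' `(n_det + 1)/2 + center_offset_px` (1-based); output grid `n_det x n_det`
#' at the detector pitch; pixels outside the inscribed circle set to zero.
#' The output grayscale is unnormalized attenuation per micrometre.
#'
#' Linear in the sinogram and deterministic; a zero sinogram reconstructs to
#' zero.
#'
#' @param sino a [Sinogram-class].
#' @param filter_name see [filterSinogramRows()].
#' @param center_offset_px rotation-axis offset (pixels); defaults to the
#'   sinogram's recorded offset.
#' @param pixel_size_um reconstructed voxel size; default 1.
#' @param window optional [TomogramWindow-class] provenance to attach.
#' @return A [Tomogram-class].
#' @export
fbpReconstruct <- function(sino, filter_name = "ramp",
                           center_offset_px = sino@center_offset_px,
                           pixel_size_um = 1, window = NULL) {
  stopifnot(is(sino, "Sinogram"))
  ang <- sino@angles_deg
  n_proj <- length(ang)
  span <- ang[n_proj] - ang[1]
  if (span < 180 - 1e-9)
    stop(sprintf("insufficient angular coverage: span %.6g deg < 180 deg", span),
         call. = FALSE)
  steps <- diff(ang)
  if (max(steps) - min(steps) > 1e-6 * mean(steps))
    stop("non-uniform angle spacing beyond tolerance", call. = FALSE)
  dtheta <- mean(steps) * pi / 180

  n_det <- ncol(sino@values)
  q <- filterSinogramRows(sino@values, pixel_size_um, filter_name)

  # pixel-centre grid, x along columns, y along rows, origin at image centre
  c0 <- (n_det + 1) / 2
  x <- (seq_len(n_det) - c0)
  X <- matrix(x, n_det, n_det, byrow = TRUE)
  Y <- matrix(x, n_det, n_det)
  acc <- matrix(0, n_det, n_det)
  det_center <- c0 + center_offset_px
  th <- (ang %% 360) * pi / 180   # wrapped: start angle costs nothing
  for (i in seq_len(n_proj)) {
    tpos <- X * cos(th[i]) + Y * sin(th[i]) + det_center   # detector column
    j0 <- floor(tpos)
    fr <- tpos - j0
    row <- q[i, ]
    v0 <- ifelse(j0 >= 1 & j0 <= n_det, row[pmin(pmax(j0, 1L), n_det)], 0)
    v1 <- ifelse(j0 + 1 >= 1 & j0 + 1 <= n_det, row[pmin(pmax(j0 + 1L, 1L), n_det)], 0)
    acc <- acc + (1 - fr) * v0 + fr * v1
  }
  coverage <- span / 180                       # number of half-turns covered
  img <- acc * dtheta / coverage
  R <- sqrt(X^2 + Y^2)
  img[R > n_det / 2] <- 0
  new("Tomogram", image = img, voxel_size_um = as.numeric(pixel_size_um),
      window = window, filter_name = filter_name,
      center_offset_px = as.numeric(center_offset_px),
      provenance = sprintf(
        "fbp filter=%s center=%.6g n_proj=%d angles=[%.6g,%.6g] slice=%d",
        filter_name, center_offset_px, n_proj, ang[1], ang[n_proj],
        sino@slice_index))
}

#' Reconstruct one window of a projection stack
#'
#' Composition of the preprocessing chain and [fbpReconstruct()]:
#' dark/flat-correct and log-transform the window's frames, assemble the
#' sinogram of the requested detector row, reconstruct, and attach the
#' window's time labels as provenance.
#'
#' @param stack a [ProjectionStack-class].
#' @param spec a [WindowSpec-class] or [TomogramWindow-class].
#' @param slice_index detector row to reconstruct (1-based).
#' @param filter_name reconstruction filter.
#' @param center_offset_px rotation-axis offset, pixels.
#' @return A [Tomogram-class] with `voxel_size_um` from the stack geometry.
#' @export
reconstructWindow <- function(stack, spec, slice_index = 1L,
                              filter_name = "ramp", center_offset_px = 0) {
  stopifnot(is(stack, "ProjectionStack"))
  if (is(spec, "TomogramWindow")) {
    win <- spec; spec <- spec@spec
  } else {
    stopifnot(is(spec, "WindowSpec"))
    win <- NULL
  }
  n_total <- dim(stack@frames)[3]
  .checkWindow(spec, n_total)
  if (is.null(win)) {
    # derive labels directly from the stack's own angle/time tables
    idx <- seq.int(spec@start_index + 1L, spec@start_index + spec@n_window)
    mid <- (spec@start_index + 1L + spec@start_index + spec@n_window) / 2
    win <- new("TomogramWindow", spec = spec,
               angles_deg = stack@angles_deg[idx],
               t_start_s = stack@times_s[idx[1]],
               t_mid_s = stats::approx(seq_along(stack@times_s), stack@times_s,
                                       xout = mid)$y,
               t_end_s = stack@times_s[idx[length(idx)]], label = 1L)
  }
  sino <- assembleSinogram(stack, slice_index, spec,
                           center_offset_px = center_offset_px)
  fbpReconstruct(sino, filter_name = filter_name,
                 center_offset_px = center_offset_px,
                 pixel_size_um = stack@geom@pixel_size_um, window = win)
}

#' Normalized root-mean-square difference between two images
#'
#' RMS of the voxelwise difference divided by the dynamic range of the
#' reference, evaluated inside the reconstruction circle. The window
#' invariance of static-object reconstructions is stated in this metric.
#'
#' @param img image to compare (matrix or [Tomogram-class]).
#' @param ref reference image (same shape).
#' @return Scalar normalized RMSE.
#' @export
nrmse <- function(img, ref) {
  if (is(img, "Tomogram")) img <- img@image
  if (is(ref, "Tomogram")) ref <- ref@image
  stopifnot(identical(dim(img), dim(ref)))
  n <- nrow(ref)
  x <- (seq_len(n) - (n + 1) / 2)
  R <- sqrt(outer(x^2, x^2, `+`))
  inside <- R <= n / 2
  rng <- diff(range(ref[inside]))
  if (rng == 0) rng <- 1
  sqrt(mean((img[inside] - ref[inside])^2)) / rng
}

#' Write a Tomogram as 32-bit TIFF with JSON provenance sidecar
#'
#' The image is normalized to `[0, 1]` for the TIFF container; the sidecar
#' (`<path>.json`) records the scale, voxel size, filter, centre offset,
#' window labels and provenance needed to interpret and re-run it.
#'
#' @param tomo a [Tomogram-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeTomogram <- function(tomo, path) {
  stopifnot(is(tomo, "Tomogram"))
  rng <- range(tomo@image)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((tomo@image - rng[1]) / scale, path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  side <- list(format = "flytomo-tomogram-1",
               min = rng[1], max = rng[2],
               voxel_size_um = tomo@voxel_size_um,
               filter_name = tomo@filter_name,
               center_offset_px = tomo@center_offset_px,
               provenance = tomo@provenance)
  if (!is.null(tomo@window)) {
    w <- tomo@window
    side$window <- list(start_index = w@spec@start_index,
                        n_window = w@spec@n_window, stride = w@spec@stride,
                        t_start_s = w@t_start_s, t_mid_s = w@t_mid_s,
                        t_end_s = w@t_end_s, label = w@label,
                        start_angle_deg = w@angles_deg[1],
                        angular_step_deg = if (length(w@angles_deg) > 1)
                          w@angles_deg[2] - w@angles_deg[1] else NA_real_)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a Tomogram written by [writeTomogram()]
#' @param path TIFF path (sidecar `<path>.json` must be present).
#' @return A [Tomogram-class].
#' @export
readTomogram <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "flytomo-tomogram-1"))
    stop("not a flytomo tomogram: ", path, call. = FALSE)
  img <- tiff::readTIFF(path) * (side$max - side$min) + side$min
  win <- NULL
  if (!is.null(side$window)) {
    w <- side$window
    spec <- windowSpec(w$start_index, w$n_window, w$stride)
    ang <- w$start_angle_deg +
      (seq_len(w$n_window) - 1L) * (w$angular_step_deg %||% 0)
    win <- new("TomogramWindow", spec = spec, angles_deg = ang,
               t_start_s = w$t_start_s, t_mid_s = w$t_mid_s,
               t_end_s = w$t_end_s, label = as.integer(w$label))
  }
  new("Tomogram", image = img, voxel_size_um = side$voxel_size_um,
      window = win, filter_name = side$filter_name,
      center_offset_px = side$center_offset_px,
      provenance = as.character(side$provenance))
}
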