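#' DetectorModel: pixel response and noise of the imaging detector
#'
#' The response is separable: an additive dark offset plus a multiplicative
#' flat-field sensitivity (a smooth deterministic vignette), with optional
#' Poisson noise on photon counts and Gaussian read noise on dark frames.
#' There is no nonlinearity.
#'
#' @slot flux incident photons per pixel per frame at unit sensitivity.
#' @slot dark_level mean dark offset, detector counts.
#' @slot read_noise_sd Gaussian read-noise standard deviation, counts.
#' @slot vignette relative amplitude (0-1) of the parabolic flat-field
#'   sensitivity fall-off towards the detector edges.
#' @slot noise logical: apply Poisson/read noise by default.
#' @export
setClass("DetectorModel",
  representation(flux = "numeric", dark_level = "numeric",
                 read_noise_sd = "numeric", vignette = "numeric",
                 noise = "logical"))

setValidity("DetectorModel", function(object) {
  msgs <- character()
  if (object@flux <= 0) msgs <- c(msgs, "flux must be positive")
  if (object@dark_level < 0) msgs <- c(msgs, "dark_level must be >= 0")
  if (object@read_noise_sd < 0) msgs <- c(msgs, "read_noise_sd must be >= 0")
  if (object@vignette < 0 || object@vignette >= 1)
    msgs <- c(msgs, "vignette must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DetectorModel
#'
#' The default flux (5000 photons/pixel/frame) gives a signal-to-noise ratio
#' at which the phantom's rod texture is visible in a single 180 degree
#' reconstruction but not noise-free.
#'
#' @param flux photons per pixel per frame at unit sensitivity.
#' @param dark_level mean dark offset, counts.
#' @param read_noise_sd read-noise SD on dark frames, counts.
#' @param vignette flat-field sensitivity fall-off amplitude (0-1).
#' @param noise apply noise by default in [simulateFlyscan()].
#' @return A [DetectorModel-class].
#' @export
detectorModel <- function(flux = 5000, dark_level = 100, read_noise_sd = 2,
                          vignette = 0.1, noise = TRUE) {
  new("DetectorModel", flux = as.numeric(flux),
      dark_level = as.numeric(dark_level),
      read_noise_sd = as.numeric(read_noise_sd),
      vignette = as.numeric(vignette), noise = isTRUE(noise))
}

# deterministic flat-field sensitivity map for a (rows, cols) detector
.sensitivityMap <- function(detector, shape) {
  nr <- shape[1]; nc <- shape[2]
  u <- if (nc > 1) 2 * (seq_len(nc) - 1) / (nc - 1) - 1 else 0
  v <- if (nr > 1) 2 * (seq_len(nr) - 1) / (nr - 1) - 1 else 0
  sens_c <- 1 - detector@vignette * u^2
  sens_r <- 1 - 0.5 * detector@vignette * v^2
  outer(sens_r, sens_c)
}

#' ProjectionStack: raw frames of one continuous-rotation scan
#'
#' Holds the detector frames exactly as a beamline scan file would: raw
#' intensities (dark offset and flat sensitivity included), the per-frame
#' unwrapped angle and exposure-start timestamp, and the dark-/flat-field
#' frames recorded at the start of the scan.
#'
#' @slot frames numeric array `(det_rows, det_cols, n_projections)`.
#' @slot angles_deg per-frame unwrapped angle, strictly increasing.
#' @slot times_s per-frame exposure-start time, strictly increasing.
#' @slot darks array `(det_rows, det_cols, n_dark)`.
#' @slot flats array `(det_rows, det_cols, n_flat)`.
#' @slot geom the [ScanGeometry-class] of this (sub-)stack.
#' @slot provenance free-text provenance, including the config hash when
#'   produced by the simulator.
#' @export
setClass("ProjectionStack",
  representation(frames = "array", angles_deg = "numeric", times_s = "numeric",
                 darks = "array", flats = "array", geom = "ScanGeometry",
                 provenance = "character"))

setValidity("ProjectionStack", function(object) {
  msgs <- character()
  dims <- dim(object@frames)
  n <- dims[3]
  if (length(dims) != 3) msgs <- c(msgs, "frames must be (rows, cols, n) array")
  if (n != object@geom@n_projections)
    msgs <- c(msgs, "number of frames must equal geom n_projections")
  if (length(object@angles_deg) != n || length(object@times_s) != n)
    msgs <- c(msgs, "angles_deg and times_s must have one entry per frame")
  if (n > 1 && (any(diff(object@angles_deg) <= 0) || any(diff(object@times_s) <= 0)))
    msgs <- c(msgs, "angles_deg and times_s must be strictly increasing")
  for (nm in c("darks", "flats")) {
    a <- slot(object, nm)
    if (length(dim(a)) != 3 || any(dim(a)[1:2] != dims[1:2]))
      msgs <- c(msgs, sprintf("%s must share the frames' detector shape", nm))
  }
  if (any(object@frames < 0) || any(object@darks < 0) || any(object@flats < 0))
    msgs <- c(msgs, "raw intensities must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ProjectionStack-class raw frame array `(rows, cols, n)`.
#' @param stack a `ProjectionStack`.
#' @export
frames <- function(stack) { stopifnot(is(stack, "ProjectionStack")); stack@frames }

#' @describeIn ProjectionStack-class per-frame unwrapped angles (degrees).
#' @export
angles <- function(stack) { stopifnot(is(stack, "ProjectionStack")); stack@angles_deg }

#' @describeIn ProjectionStack-class per-frame exposure-start times (seconds).
#' @export
frameTimes <- function(stack) { stopifnot(is(stack, "ProjectionStack")); stack@times_s }

#' @describeIn ProjectionStack-class dark-field frames.
#' @export
darks <- function(stack) { stopifnot(is(stack, "ProjectionStack")); stack@darks }

#' @describeIn ProjectionStack-class flat-field frames.
#' @export
flats <- function(stack) { stopifnot(is(stack, "ProjectionStack")); stack@flats }

#' @describeIn ProjectionStack-class the stack's [ScanGeometry-class].
#' @export
stackGeometry <- function(stack) { stopifnot(is(stack, "ProjectionStack")); stack@geom }

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ProjectionStack  %d frames of %d x %d px\n", d[3], d[1], d[2]))
  cat(sprintf("  angles %.6g .. %.6g deg, times %.6g .. %.6g s\n",
              object@angles_deg[1], object@angles_deg[d[3]],
              object@times_s[1], object@times_s[d[3]]))
  cat(sprintf("  %d darks, %d flats | %s\n",
              dim(object@darks)[3], dim(object@flats)[3],
              object@provenance[1]))
})

# bilinear sampling of matrix `field` at fractional (row, col) positions;
# points outside the grid contribute 0
.bilinear <- function(field, row, col) {
  nr <- nrow(field); nc <- ncol(field)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  val <- numeric(length(row))
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- field[cbind(r[ok], c[ok])]
    v
  }
  val <- at(r0, c0) * (1 - fr) * (1 - fc) +
         at(r0 + 1, c0) * fr * (1 - fc) +
         at(r0, c0 + 1) * (1 - fr) * fc +
         at(r0 + 1, c0 + 1) * fr * fc
  val
}

#' Parallel-beam forward projection (Radon transform) of one slice
#'
#' Integrates the attenuation field along parallel rays at the given angle.
#' The detector coordinate axis at angle theta is the unit vector
#' `(cos theta, sin theta)` in (x = column, y = row) sample coordinates, rays
#' run along the orthogonal direction, and the rotation axis projects onto
#' the detector centre `(n_detector + 1)/2` (1-based). Linear in the field;
#' rotating the field by delta equals shifting the angle by delta to within
#' interpolation tolerance, and the profile at `theta + 180` is the reversed
#' profile at `theta`.
#'
#' @param field numeric matrix `(ny, nx)` of attenuation per micrometre; all
#'   non-zero values must lie inside the inscribed reconstruction circle of
#'   the detector span (checked; aliasing under rotation otherwise).
#' @param angle_deg projection angle in degrees (any real; used modulo 360).
#' @param n_detector number of detector columns; defaults to `ncol(field)`.
#' @param pixel_size_um detector/field sampling pitch, micrometres.
#' @return Numeric vector of `n_detector` line integrals (attenuation units
#'   times micrometres).
#' @export
forwardProject <- function(field, angle_deg, n_detector = ncol(field),
                           pixel_size_um = 1) {
  stopifnot(is.matrix(field), length(angle_deg) == 1, is.finite(angle_deg),
            n_detector >= 2, pixel_size_um > 0)
  ny <- nrow(field); nx <- ncol(field)
  # containment check: non-zero attenuation outside the reconstruction circle
  # of the detector span would alias when rotated
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r_max_px <- n_detector / 2
  nz <- which(field != 0, arr.ind = TRUE)
  if (nrow(nz) > 0) {
    rr <- sqrt((nz[, 1] - cy)^2 + (nz[, 2] - cx)^2)
    if (max(rr) > r_max_px)
      stop("field extends beyond the reconstruction circle of the detector span",
           call. = FALSE)
  }
  th <- (angle_deg %% 360) * pi / 180   # wrap first: frames at angles equal
  ct <- cos(th); st <- sin(th)          # mod 360 must be bit-identical
  tdet <- (seq_len(n_detector) - (n_detector + 1) / 2)   # pixel units
  s <- (seq_len(n_detector) - (n_detector + 1) / 2)      # integration samples
  # sample points: p = t * (ct, st) + s * (-st, ct), in (x, y) pixel offsets
  X <- outer(tdet * ct, -s * st, `+`)   # [n_det, n_s]
  Y <- outer(tdet * st, s * ct, `+`)
  vals <- .bilinear(field, row = as.vector(Y) + cy, col = as.vector(X) + cx)
  rowSums(matrix(vals, n_detector, n_detector)) * pixel_size_um
}

# run code with a local, restored RNG state when seed is given
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  ge <- globalenv()
  if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
    old <- get(".Random.seed", envir = ge)
    on.exit(assign(".Random.seed", old, envir = ge), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = ge, inherits = FALSE))
      rm(".Random.seed", envir = ge), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a continuous-rotation (fly-scan) acquisition
#'
#' Renders every frame of the scan at the instantaneous angle and time of its
#' exposure start: frame `i` is the detector response to
#' `exp(-R[attenuationAt(state, timeOfIndex(i))](angleOfIndex(i)))`, with the
#' flat-field sensitivity applied multiplicatively and the dark offset added.
#' Dark and flat frames are simulated once, at the start of the scan, and
#' stored inline. With noise disabled and a static phantom, frames at angles
#' equal modulo 360 degrees are identical.
#'
#' At the reference geometry the stage moves only 0.072 degrees during one
#' 0.5 s exposure - well below a detector pixel at the sample edge - so the
#' default renders one instantaneous angle per frame; `blur_substeps > 1`
#' averages that many sub-angle renders across the exposure for stress tests.
#'
#' @param state a [PhantomState-class] (2D slice or extruded 3D).
#' @param geom a [ScanGeometry-class]; `detector_shape` must accommodate the
#'   phantom (columns >= phantom grid, rows >= number of phantom slices).
#' @param detector a [DetectorModel-class].
#' @param seed integer seed for the noise realization (`NULL` leaves the RNG
#'   state alone); equal seeds give bit-identical stacks.
#' @param noise override the detector's noise flag.
#' @param blur_substeps integer >= 1; number of intra-frame sub-angles averaged.
#' @return A [ProjectionStack-class].
#' @export
simulateFlyscan <- function(state, geom, detector = detectorModel(),
                            seed = NULL, noise = detector@noise,
                            blur_substeps = 1L) {
  stopifnot(is(state, "PhantomState"), is(geom, "ScanGeometry"),
            is(detector, "DetectorModel"), blur_substeps >= 1L)
  shp <- state@grid_shape
  is3d <- length(shp) == 3L
  ny <- shp[length(shp) - 1L]; nx <- shp[length(shp)]
  n_slices <- if (is3d) shp[1L] else 1L
  det_rows <- geom@detector_shape[1]; det_cols <- geom@detector_shape[2]
  if (det_cols < max(nx, ny) || det_rows < n_slices)
    stop(sprintf(
      "detector (%d x %d px) would truncate the phantom (%s voxels): widen the detector or shrink the sample",
      det_rows, det_cols, paste(shp, collapse = " x ")), call. = FALSE)

  n <- geom@n_projections
  idx <- seq_len(n) - 1L
  ang <- angleOfIndex(geom, idx)
  tim <- timeOfIndex(geom, idx)
  # render angles reduced in *index* space where the step divides a full
  # turn, so frames at angles equal mod 360 degrees are bit-identical
  turns <- 360 / geom@angular_step_deg
  ang_render <- if (abs(turns - round(turns)) < 1e-6)
    (idx %% as.integer(round(turns))) * geom@angular_step_deg +
      geom@start_angle_deg
  else ang
  sens <- .sensitivityMap(detector, c(det_rows, det_cols))
  I0 <- detector@flux * sens

  .withSeed(seed, {
    # darks and flats first: they are acquired before the rotation starts
    darks <- array(0, dim = c(det_rows, det_cols, geom@n_dark))
    for (k in seq_len(geom@n_dark)) {
      d <- detector@dark_level + (if (noise)
        stats::rnorm(det_rows * det_cols, 0, detector@read_noise_sd) else 0)
      darks[, , k] <- pmax(0, d)
    }
    flats <- array(0, dim = c(det_rows, det_cols, geom@n_flat))
    for (k in seq_len(geom@n_flat)) {
      photons <- if (noise) stats::rpois(det_rows * det_cols, as.vector(I0)) else as.vector(I0)
      flats[, , k] <- detector@dark_level + photons
    }

    frames <- array(0, dim = c(det_rows, det_cols, n))
    sub <- (seq_len(blur_substeps) - 0.5) / blur_substeps - 0.5  # fractions of a step
    for (i in seq_len(n)) {
      field <- attenuationAt(state, tim[i])
      slices <- if (is3d) lapply(seq_len(n_slices), function(z) field[z, , ])
                else list(field)
      p <- matrix(0, det_rows, det_cols)
      for (z in seq_len(n_slices)) {
        prof <- 0
        for (f in sub)
          prof <- prof + forwardProject(slices[[z]],
                                        ang_render[i] + f * geom@angular_step_deg,
                                        det_cols, state@voxel_size_um)
        p[z, ] <- prof / blur_substeps
      }
      expected <- I0 * exp(-p)
      counts <- if (noise) stats::rpois(det_rows * det_cols, as.vector(expected))
                else as.vector(expected)
      frames[, , i] <- detector@dark_level + counts
    }
    new("ProjectionStack", frames = frames, angles_deg = ang, times_s = tim,
        darks = darks, flats = flats, geom = geom,
        provenance = sprintf("simulateFlyscan seed=%s noise=%s",
                             ifelse(is.null(seed), "NA", seed), noise))
  })
}

#' Write a ProjectionStack to a directory (TIFF stack + JSON sidecar)
#'
#' Frames, darks and flats are written as multi-page 32-bit TIFF stacks with
#' intensities normalized to `[0, 1]`; the JSON sidecar `scan.json` records
#' the normalization ranges, per-frame angles and times, the serialized scan
#' geometry and the provenance string, so [readProjectionStack()] restores
#' the stack (to within the 32-bit quantization of the TIFF container).
#'
#' @param stack a [ProjectionStack-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeProjectionStack <- function(stack, dir) {
  stopifnot(is(stack, "ProjectionStack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(arr, path) {
    rng <- range(arr)
    scale <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(k) (arr[, , k, drop = TRUE] - rng[1]) / scale)
    pages <- lapply(pages, function(m) if (is.matrix(m)) m else matrix(m, dim(arr)[1]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                    reduce = FALSE)
    list(min = rng[1], max = rng[2])
  }
  meta <- list(
    format = "flytomo-scan-1",
    geometry = geometryToList(stack@geom),
    angles_deg = stack@angles_deg,
    times_s = stack@times_s,
    provenance = stack@provenance,
    scale = list(
      frames = wr(stack@frames, file.path(dir, "frames.tif")),
      darks  = wr(stack@darks,  file.path(dir, "darks.tif")),
      flats  = wr(stack@flats,  file.path(dir, "flats.tif"))))
  jsonlite::write_json(meta, file.path(dir, "scan.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a ProjectionStack written by [writeProjectionStack()]
#' @param dir directory containing `frames.tif`, `darks.tif`, `flats.tif`
#'   and `scan.json`.
#' @return A [ProjectionStack-class].
#' @export
readProjectionStack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scan.json"), simplifyVector = TRUE)
  if (!identical(meta$format, "flytomo-scan-1"))
    stop("not a flytomo scan directory: ", dir, call. = FALSE)
  rd <- function(path, sc) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    arr * (sc$max - sc$min) + sc$min
  }
  g <- meta$geometry
  g$detector_shape <- as.integer(g$detector_shape)
  new("ProjectionStack",
      frames = rd(file.path(dir, "frames.tif"), meta$scale$frames),
      darks = rd(file.path(dir, "darks.tif"), meta$scale$darks),
      flats = rd(file.path(dir, "flats.tif"), meta$scale$flats),
      angles_deg = as.numeric(meta$angles_deg),
      times_s = as.numeric(meta$times_s),
      geom = geometryFromList(g),
      provenance = as.character(meta$provenance))
}
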