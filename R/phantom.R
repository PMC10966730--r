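#' DissolutionModel: kinetics and geometry of the acid-dissolution cavity
#'
#' Describes the exposed (unvarnished) window on the sample boundary and the
#' advance of the demineralization front behind it. The front depth is 0 up to
#' `onset_s` and grows linearly afterwards at `front_speed_um_per_s`,
#' optionally faster along the enamel-rod direction (`anisotropy_gain`),
#' giving the cavity the anisotropic shape seen in demineralized enamel.
#' Dissolved material never re-mineralizes: the attenuation at a voxel is
#' non-increasing in time.
#'
#' @slot window_center_deg polar angle (degrees) of the centre of the exposed
#'   window on the sample boundary.
#' @slot window_width_um arc width of the exposed window, micrometres.
#' @slot front_speed_um_per_s radial advance rate of the dissolution front.
#' @slot mu_dissolved_frac residual attenuation fraction (0-1) inside the
#'   dissolved region: 0 removes the mineral entirely, 1 means no contrast.
#' @slot onset_s time at which acid exposure begins, seconds.
#' @slot anisotropy_gain multiplicative speed-up (>= 1) of the front along the
#'   rod direction.
#' @slot rod_angle_deg orientation of the rod axis in the slice plane.
#' @export
setClass("DissolutionModel",
  representation(
    window_center_deg   = "numeric",
    window_width_um     = "numeric",
    front_speed_um_per_s = "numeric",
    mu_dissolved_frac   = "numeric",
    onset_s             = "numeric",
    anisotropy_gain     = "numeric",
    rod_angle_deg       = "numeric"
  )
)

setValidity("DissolutionModel", function(object) {
  msgs <- character()
  if (object@window_width_um <= 0) msgs <- c(msgs, "window_width_um must be positive")
  if (object@front_speed_um_per_s < 0) msgs <- c(msgs, "front_speed_um_per_s must be >= 0")
  if (object@mu_dissolved_frac < 0 || object@mu_dissolved_frac > 1)
    msgs <- c(msgs, "mu_dissolved_frac must be in [0, 1]")
  if (object@onset_s < 0) msgs <- c(msgs, "onset_s must be >= 0")
  if (object@anisotropy_gain < 1) msgs <- c(msgs, "anisotropy_gain must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DissolutionModel
#'
#' Defaults give a front that starts at 300 s and advances at 0.01 um/s with a
#' 30 percent speed-up along the rods, leaving a quarter of the baseline
#' attenuation in the lesion. These are order-of-magnitude choices for a
#' bench-scale synthetic sample, not physiological rates.
#'
#' @param window_center_deg,window_width_um position/arc width of the exposed window.
#' @param front_speed_um_per_s radial front speed, um/s.
#' @param mu_dissolved_frac residual attenuation fraction in the lesion (0-1).
#' @param onset_s acid-exposure start time, s.
#' @param anisotropy_gain front speed-up along the rod axis (>= 1).
#' @param rod_angle_deg rod-axis orientation in the slice plane.
#' @return A [DissolutionModel-class].
#' @export
dissolutionModel <- function(window_center_deg = 0, window_width_um = 30,
                             front_speed_um_per_s = 0.01,
                             mu_dissolved_frac = 0.25, onset_s = 300,
                             anisotropy_gain = 1.3, rod_angle_deg = 0) {
  new("DissolutionModel",
      window_center_deg = as.numeric(window_center_deg),
      window_width_um = as.numeric(window_width_um),
      front_speed_um_per_s = as.numeric(front_speed_um_per_s),
      mu_dissolved_frac = as.numeric(mu_dissolved_frac),
      onset_s = as.numeric(onset_s),
      anisotropy_gain = as.numeric(anisotropy_gain),
      rod_angle_deg = as.numeric(rod_angle_deg))
}

#' PhantomState: time-parameterized attenuation phantom
#'
#' A deterministic 2D (or extruded 3D) attenuation field mimicking a block of
#' enamel in a liquid bath: a circular sample support holds an enamel disc
#' carrying a quasi-periodic rod/inter-rod texture; a [DissolutionModel-class]
#' opens a progressively growing cavity behind an exposed window on the enamel
#' boundary. The field is a pure function of `(state, t)` - there is no hidden
#' randomness, so repeated evaluations are bit-identical.
#'
#' @slot grid_shape integer `(ny, nx)` or `(nz, ny, nx)` voxels.
#' @slot voxel_size_um voxel edge length, micrometres.
#' @slot mu_enamel baseline linear attenuation of enamel (per micrometre,
#'   arbitrary units).
#' @slot mu_liquid attenuation of the surrounding bath (`0 <= mu_liquid < mu_enamel`).
#' @slot texture_amplitude relative modulation (0-1) of the rod texture.
#' @slot rod_period_um spatial period of the rod texture.
#' @slot dissolution a [DissolutionModel-class].
#' @slot support_radius_frac radius of the liquid-filled support as a fraction
#'   of the grid half-width (<= 1 keeps the sample inside the reconstruction circle).
#' @slot enamel_radius_frac radius of the enamel disc as a fraction of the
#'   support radius.
#' @export
setClass("PhantomState",
  representation(
    grid_shape         = "integer",
    voxel_size_um      = "numeric",
    mu_enamel          = "numeric",
    mu_liquid          = "numeric",
    texture_amplitude  = "numeric",
    rod_period_um      = "numeric",
    dissolution        = "DissolutionModel",
    support_radius_frac = "numeric",
    enamel_radius_frac = "numeric"
  )
)

setValidity("PhantomState", function(object) {
  msgs <- character()
  if (!length(object@grid_shape) %in% c(2L, 3L) || any(object@grid_shape < 4L))
    msgs <- c(msgs, "grid_shape must be (ny, nx) or (nz, ny, nx), each >= 4")
  if (object@voxel_size_um <= 0) msgs <- c(msgs, "voxel_size_um must be positive")
  if (object@mu_liquid < 0 || object@mu_liquid >= object@mu_enamel)
    msgs <- c(msgs, "need 0 <= mu_liquid < mu_enamel")
  if (object@texture_amplitude < 0 || object@texture_amplitude >= 1)
    msgs <- c(msgs, "texture_amplitude must be in [0, 1)")
  if (object@mu_enamel * (1 - object@texture_amplitude) < 0)
    msgs <- c(msgs, "attenuation must stay non-negative")
  if (object@rod_period_um <= 0) msgs <- c(msgs, "rod_period_um must be positive")
  if (object@support_radius_frac <= 0 || object@support_radius_frac > 1)
    msgs <- c(msgs, "support_radius_frac must be in (0, 1]")
  if (object@enamel_radius_frac <= 0 || object@enamel_radius_frac >= 1)
    msgs <- c(msgs, "enamel_radius_frac must be in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhantomState
#'
#' Defaults describe the bench-scale test sample used throughout the package:
#' a 96 x 96 grid of 1 um voxels, an enamel disc of ~34 um radius with a 6 um
#' rod texture at 15 percent modulation, in a dilute bath, with the default
#' [dissolutionModel()]. `mu_enamel = 0.02` per um gives an optical depth of
#' order one across the disc, i.e. realistic imaging contrast.
#'
#' @param grid_shape `(ny, nx)` or `(nz, ny, nx)`.
#' @param voxel_size_um voxel size, um.
#' @param mu_enamel,mu_liquid attenuation of enamel / bath (per um).
#' @param texture_amplitude relative rod-texture modulation in `[0, 1)`.
#' @param rod_period_um rod-texture period, um.
#' @param dissolution a [DissolutionModel-class].
#' @param support_radius_frac support radius / grid half-width.
#' @param enamel_radius_frac enamel radius / support radius.
#' @return A [PhantomState-class].
#' @examples
#' ph <- phantomState()
#' f0 <- attenuationAt(ph, 0)
#' demineralizedVolume(ph, 1000)  # um^2, grows after onset
#' @export
phantomState <- function(grid_shape = c(96L, 96L), voxel_size_um = 1,
                         mu_enamel = 0.02, mu_liquid = 0.004,
                         texture_amplitude = 0.15, rod_period_um = 6,
                         dissolution = dissolutionModel(),
                         support_radius_frac = 0.95,
                         enamel_radius_frac = 0.75) {
  new("PhantomState",
      grid_shape = as.integer(grid_shape),
      voxel_size_um = as.numeric(voxel_size_um),
      mu_enamel = as.numeric(mu_enamel), mu_liquid = as.numeric(mu_liquid),
      texture_amplitude = as.numeric(texture_amplitude),
      rod_period_um = as.numeric(rod_period_um),
      dissolution = dissolution,
      support_radius_frac = as.numeric(support_radius_frac),
      enamel_radius_frac = as.numeric(enamel_radius_frac))
}

# centred voxel coordinates (um) of a 2D slice; x along columns, y along rows
.sliceCoords <- function(state) {
  shp <- state@grid_shape
  d <- length(shp)
  ny <- shp[d - 1L]; nx <- shp[d]
  vx <- state@voxel_size_um
  x <- (seq_len(nx) - (nx + 1) / 2) * vx
  y <- (seq_len(ny) - (ny + 1) / 2) * vx
  list(X = matrix(x, ny, nx, byrow = TRUE), Y = matrix(y, ny, nx),
       ny = ny, nx = nx,
       half_width = min(nx, ny) / 2 * vx)
}

# deterministic rod/inter-rod texture in [-1, 1]: two oblique sinusoids,
# softly thresholded (clipped at 1.5x gain) into a near-binary pattern
.rodTexture <- function(state, phase = 0) {
  co <- .sliceCoords(state)
  rho <- state@dissolution@rod_angle_deg * pi / 180
  k <- 2 * pi / state@rod_period_um
  u <- k * (co$X * cos(rho) + co$Y * sin(rho)) + phase
  v <- k * (co$X * cos(rho + pi / 3) + co$Y * sin(rho + pi / 3)) + phase
  matrix(pmax(-1, pmin(1, 1.5 * (sin(u) + sin(v)))), nrow(u), ncol(u))
}

# baseline (t = 0) attenuation of one slice
.baseSlice <- function(state, phase = 0) {
  co <- .sliceCoords(state)
  r <- sqrt(co$X^2 + co$Y^2)
  r_support <- state@support_radius_frac * co$half_width
  r_enamel <- state@enamel_radius_frac * r_support
  mu <- matrix(0, co$ny, co$nx)
  mu[r <= r_support] <- state@mu_liquid
  en <- r <= r_enamel
  tex <- .rodTexture(state, phase)
  mu[en] <- state@mu_enamel * (1 + state@texture_amplitude * tex[en])
  mu
}

#' Enamel-disc radius of a phantom
#' @param state a [PhantomState-class].
#' @return Radius of the enamel disc, micrometres.
#' @export
enamelRadius <- function(state) {
  stopifnot(is(state, "PhantomState"))
  co <- .sliceCoords(state)
  state@enamel_radius_frac * state@support_radius_frac * co$half_width
}

#' Current depth of the dissolution front
#'
#' Zero up to the onset time, then `front_speed_um_per_s * (t - onset_s)`;
#' along the rod axis the depth is additionally multiplied by
#' `anisotropy_gain`. Monotone non-decreasing in `t`.
#' @param state a [PhantomState-class].
#' @param t time in seconds (vectorized).
#' @return Isotropic front depth(s), micrometres.
#' @export
frontDepth <- function(state, t) {
  stopifnot(is(state, "PhantomState"))
  dm <- state@dissolution
  pmax(0, t - dm@onset_s) * dm@front_speed_um_per_s
}

#' Logical mask of currently dissolved voxels (one slice)
#'
#' A voxel is dissolved when it lies inside the enamel disc, within the
#' angular sector of the exposed window, and within the (direction-dependent)
#' front depth of the enamel surface.
#' @param state a [PhantomState-class].
#' @param t time, seconds.
#' @return Logical `(ny, nx)` matrix.
#' @export
dissolvedMask <- function(state, t) {
  stopifnot(is(state, "PhantomState"), length(t) == 1, t >= 0)
  dm <- state@dissolution
  d <- frontDepth(state, t)
  co <- .sliceCoords(state)
  r_en <- enamelRadius(state)
  if (d <= 0) return(matrix(FALSE, co$ny, co$nx))
  r <- sqrt(co$X^2 + co$Y^2)
  phi <- atan2(co$Y, co$X)                      # radians
  dphi <- ((phi * 180 / pi - dm@window_center_deg + 180) %% 360) - 180
  half_arc_deg <- (dm@window_width_um / 2) / r_en * 180 / pi
  rho <- dm@rod_angle_deg * pi / 180
  d_eff <- d * (1 + (dm@anisotropy_gain - 1) * cos(phi - rho)^2)
  (r <= r_en) & (abs(dphi) <= half_arc_deg) & ((r_en - r) <= d_eff)
}

#' Attenuation field of the phantom at time t
#'
#' Deterministic in `(state, t)`. Outside the dissolution region the field
#' equals its `t = 0` value; inside the current front the attenuation is
#' `mu_liquid + mu_dissolved_frac * (mu0 - mu_liquid)`. For a 3D grid the 2D
#' slice is extruded with a slow axial phase drift of the rod texture (the
#' dissolution geometry is identical in every slice).
#'
#' @param state a [PhantomState-class].
#' @param t time in seconds (>= 0).
#' @return Numeric matrix `(ny, nx)`, or array `(nz, ny, nx)` for 3D grids,
#'   of linear attenuation values (per um, arbitrary units).
#' @export
attenuationAt <- function(state, t) {
  stopifnot(is(state, "PhantomState"), length(t) == 1, is.finite(t), t >= 0)
  dm <- state@dissolution
  one <- function(phase) {
    mu <- .baseSlice(state, phase)
    mask <- dissolvedMask(state, t)
    mu[mask] <- state@mu_liquid + dm@mu_dissolved_frac * (mu[mask] - state@mu_liquid)
    mu
  }
  shp <- state@grid_shape
  if (length(shp) == 2L) return(one(0))
  nz <- shp[1L]
  out <- array(0, dim = shp)
  for (iz in seq_len(nz))                      # slow axial variation
    out[iz, , ] <- one(2 * pi * 0.05 * (iz - 1) / nz)
  out
}

#' Demineralized volume (or area) at time t
#'
#' Volume of voxels whose attenuation at `t` lies strictly below their
#' `t = 0` value, times the voxel volume. Monotone non-decreasing in `t`;
#' identically zero when `mu_dissolved_frac = 1` (contrast-free dissolution).
#'
#' @param state a [PhantomState-class].
#' @param t time in seconds.
#' @return Area in um^2 for 2D grids, volume in um^3 for 3D grids.
#' @export
demineralizedVolume <- function(state, t) {
  stopifnot(is(state, "PhantomState"))
  f0 <- attenuationAt(state, 0)
  ft <- attenuationAt(state, t)
  d <- length(state@grid_shape)
  sum(ft < f0) * state@voxel_size_um^d
}

setMethod("show", "PhantomState", function(object) {
  shp <- object@grid_shape
  cat(sprintf("PhantomState  %s voxels @ %.3g um\n",
              paste(shp, collapse = " x "), object@voxel_size_um))
  cat(sprintf("  mu_enamel %.4g, mu_liquid %.4g, texture %.0f%% @ %.3g um period\n",
              object@mu_enamel, object@mu_liquid,
              100 * object@texture_amplitude, object@rod_period_um))
  dm <- object@dissolution
  cat(sprintf("  dissolution: onset %.4g s, front %.3g um/s (gain %.2g), residual %.0f%%\n",
              dm@onset_s, dm@front_speed_um_per_s, dm@anisotropy_gain,
              100 * dm@mu_dissolved_frac))
})
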