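# Shared fixtures, built in code and cached for the duration of the test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fx[[name]])) .fx[[name]] <- maker()
  .fx[[name]]
}

# soft-edged uniform disc (1-voxel linear edge ramp)
softDisc <- function(n, r, mu = 1) {
  x <- (seq_len(n) - (n + 1) / 2)
  R <- sqrt(outer(x^2, x^2, `+`))
  matrix(mu * pmin(1, pmax(0, r + 0.5 - R)), n, n)
}

# noiseless analytic sinogram of a static field over the given angles
mkSino <- function(field, angles_deg, n_det = ncol(field), center_offset = 0) {
  vals <- t(vapply(angles_deg, function(a) forwardProject(field, a, n_det, 1),
                   numeric(n_det)))
  new("Sinogram", values = vals, angles_deg = angles_deg,
      times_s = seq_along(angles_deg) * 0.5 - 0.5 + 1e-9 * seq_along(angles_deg),
      slice_index = 1L, center_offset_px = center_offset, qc = list())
}

testConfig <- function(seed = 101L) demoConfig(seed = seed)

fxStackEvolving <- function() fixture("stack_evolving", function() {
  cfg <- testConfig()
  simulateFlyscan(cfg@phantom, cfg@geometry, cfg@detector,
                  seed = 101L, noise = TRUE)
})

fxStackStaticClean <- function() fixture("stack_static_clean", function() {
  cfg <- testConfig()
  static <- cfg@phantom
  static@dissolution@front_speed_um_per_s <- 0
  simulateFlyscan(static, cfg@geometry, cfg@detector,
                  seed = 101L, noise = FALSE)
})

fxStackStaticNoisy <- function() fixture("stack_static_noisy", function() {
  cfg <- testConfig()
  static <- cfg@phantom
  static@dissolution@front_speed_um_per_s <- 0
  simulateFlyscan(static, cfg@geometry, cfg@detector,
                  seed = 202L, noise = TRUE)
})

fxWindows <- function() fixture("windows", function() {
  cfg <- testConfig()
  enumerateWindows(cfg@geometry, cfg@n_window, cfg@stride)
})

fxTomosEvolving <- function() fixture("tomos_evolving", function() {
  stack <- fxStackEvolving()
  lapply(fxWindows(), function(w) reconstructWindow(stack, w))
})

fxTomosStaticNoisy <- function() fixture("tomos_static_noisy", function() {
  stack <- fxStackStaticNoisy()
  lapply(fxWindows(), function(w) reconstructWindow(stack, w))
})

fxCurveEvolving <- function() fixture("curve_evolving", function()
  progressionCurve(fxTomosEvolving()))

# static-phantom null curve segmented at the evolving curve's threshold
fxCurveNull <- function() fixture("curve_null", function()
  progressionCurve(fxTomosStaticNoisy(),
                   threshold = fxCurveEvolving()@threshold_used))

fxNullBand <- function() {
  v <- fxCurveNull()@cavity_volume[-1]
  mean(v) + 3 * stats::sd(v)
}
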