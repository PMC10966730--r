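# Independent filtered back-projection oracle: direct (time-domain)
# convolution with the band-limited ramp kernel, followed by brute-force
# per-pixel back-projection with linear interpolation. Deliberately written
# as plain loops from the textbook formulas, sharing no code with the
# package's FFT/vectorized implementation.

fbpOracle <- function(values, angles_deg, center_offset_px = 0) {
  n_proj <- nrow(values)
  n_det <- ncol(values)
  # band-limited ramp kernel at unit pitch: h(0) = 1/4, h(k) = -1/(pi k)^2
  # for odd lags, 0 for even lags
  lags <- -(n_det - 1):(n_det - 1)
  h <- ifelse(lags == 0, 0.25,
              ifelse(lags %% 2 != 0, -1 / (pi^2 * lags^2), 0))
  q <- matrix(0, n_proj, n_det)
  for (i in seq_len(n_proj))
    for (j in seq_len(n_det))
      q[i, j] <- sum(values[i, ] * h[(j - seq_len(n_det)) + n_det])
  th <- angles_deg * pi / 180
  dth <- (angles_deg[2] - angles_deg[1]) * pi / 180
  coverage <- (angles_deg[n_proj] - angles_deg[1]) / 180
  c0 <- (n_det + 1) / 2
  det_center <- c0 + center_offset_px
  img <- matrix(0, n_det, n_det)
  for (r in seq_len(n_det)) {
    for (cc in seq_len(n_det)) {
      x <- cc - c0; y <- r - c0
      if (sqrt(x^2 + y^2) > n_det / 2) next
      acc <- 0
      for (i in seq_len(n_proj)) {
        tpos <- x * cos(th[i]) + y * sin(th[i]) + det_center
        j0 <- floor(tpos); fr <- tpos - j0
        v0 <- if (j0 >= 1 && j0 <= n_det) q[i, j0] else 0
        v1 <- if (j0 + 1 >= 1 && j0 + 1 <= n_det) q[i, j0 + 1] else 0
        acc <- acc + (1 - fr) * v0 + fr * v1
      }
      img[r, cc] <- acc * dth / coverage
    }
  }
  img
}
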