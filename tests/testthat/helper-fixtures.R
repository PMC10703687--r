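# Shared fixtures, built in code.

# largest gradient area achievable by a symmetric trapezoid/triangle of the
# given total duration under amplitude and slew limits (closed form): the
# independent oracle for minimum-duration claims
max_area_for_duration <- function(duration_ms, gmax, sr) {
  if (duration_ms >= 2 * gmax / sr) gmax * (duration_ms - gmax / sr)
  else sr * duration_ms^2 / 4
}

# numeric Stejskal-Tanner b-value: b = gamma^2 int q(t)^2 dt with
# q(t) = int g dt, both lobes sampled at dt_us microseconds
b_value_numeric <- function(g_mT_per_m, delta_ms, Delta_ms, ramp_ms,
                            dt_us = 1) {
  dt <- dt_us * 1e-6                      # s
  tmax <- (Delta_ms + delta_ms) * 1e-3
  t <- seq(0, tmax, by = dt)
  lobe <- function(t0) {
    # trapezoid starting at t0 (s): ramp up, flat, ramp down
    r <- ramp_ms * 1e-3; d <- delta_ms * 1e-3
    tt <- t - t0
    amp <- g_mT_per_m * 1e-3              # T/m
    ifelse(tt < 0, 0,
    ifelse(tt < r, amp * tt / r,
    ifelse(tt < d, amp,
    ifelse(tt < d + r, amp * (1 - (tt - d) / r), 0))))
  }
  g <- lobe(0) - lobe(Delta_ms * 1e-3)    # second lobe after the 180 flips sign
  q <- cumsum(g) * dt
  (2.6752e8)^2 * sum(q^2) * dt * 1e-6     # s/mm^2
}

# small smooth 2D test image (phase encode along rows)
blob_image <- function(n = 32) {
  y <- matrix(seq_len(n), n, n)
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  exp(-((y - 0.38 * n)^2 + (x - 0.5 * n)^2) / (0.02 * n^2)) +
    0.7 * exp(-((y - 0.68 * n)^2 + (x - 0.3 * n)^2) / (0.012 * n^2))
}

# full discrete EPI acquisition of one image under off-resonance: per read
# column, phase accrues as exp(-2i pi f t_k) on phase-encode line k acquired
# at t_k = (k - n/2) * es_eff; the independent distortion oracle
epi_kspace_oracle <- function(img, fmap_hz, es_eff_ms, pe_direction = 1) {
  n <- nrow(img)
  out <- img * 0
  kidx <- 0:(n - 1)
  t_k <- (kidx - n %/% 2) * es_eff_ms / 1000 * pe_direction
  for (j in seq_len(ncol(img))) {
    col <- img[, j]
    f <- fmap_hz[, j]
    s <- vapply(seq_len(n), function(ki) {
      sum(col * exp(-2i * pi * (kidx[ki] - n %/% 2) * (0:(n - 1)) / n) *
            exp(-2i * pi * f * t_k[ki]))
    }, complex(1))
    out[, j] <- Re(vapply(0:(n - 1), function(y) {
      sum(s * exp(2i * pi * (kidx - n %/% 2) * y / n)) / n
    }, complex(1)))
  }
  out
}

# hand-built sensitivity_set for algebraic checks
toy_sensitivity_set <- function(values, dims) {
  structure(list(values = values, dim = dims,
                 grid = list(x = seq_len(dims[1]), y = seq_len(dims[2]),
                             z = seq_len(dims[3]))),
            class = "sensitivity_set")
}

# smooth complex sensitivities for an nch-channel 2D toy grid
toy_grid_sensitivities <- function(nx, ny, nch, seed = 1) {
  set.seed(seed)
  vals <- matrix(0 + 0i, nch, nx * ny)
  xs <- seq(-1, 1, length.out = nx)
  ys <- seq(-1, 1, length.out = ny)
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  ang <- 2 * pi * (seq_len(nch) - 1) / nch
  for (ch in seq_len(nch)) {
    c0 <- 1.4 * c(cos(ang[ch]), sin(ang[ch]))
    d2 <- (pts[, 1] - c0[1])^2 + (pts[, 2] - c0[2])^2
    mag <- 1 / (0.3 + d2)
    ph <- 2 * pi * (0.13 * ch + 0.4 * pts[, 1] * sin(ang[ch]) -
                      0.3 * pts[, 2] * cos(ang[ch]))
    vals[ch, ] <- mag * exp(1i * ph)
  }
  toy_sensitivity_set(vals, c(nx, ny, 1L))
}
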