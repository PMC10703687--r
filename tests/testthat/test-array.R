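test_that("helmet layouts have the expected row structure and determinism", {
  g <- build_helmet_array(96, seed = 3)
  expect_equal(g$n_channels, 96L)
  expect_equal(nrow(g$centers), 96)
  # 12/18/24 in the top rows, 42 in the rim band (rows share one z height)
  row_counts <- as.integer(table(round(g$centers[, 3], 6)))
  z_order <- order(as.numeric(names(table(round(g$centers[, 3], 6)))),
                   decreasing = TRUE)
  expect_equal(row_counts[z_order], c(12L, 18L, 24L, 42L))
  g2 <- build_helmet_array(96, seed = 3)
  expect_identical(g$centers, g2$centers)
  expect_false(identical(g$centers, build_helmet_array(96, seed = 4)$centers))
  # centres on the helmet surface within 1 mm
  rho <- sqrt(rowSums(sweep(g$centers, 2, g$semi_axes_mm, `/`)^2))
  expect_lt(max(abs(rho - 1)) * mean(g$semi_axes_mm), 1)
  # ~4 cm loops at 96 channels
  expect_gt(mean(2 * g$radii), 30)
  expect_lt(mean(2 * g$radii), 50)
  expect_error(build_helmet_array(17), "unsupported")
})

test_that("loop sensitivities decay along the loop axis", {
  g <- build_helmet_array(8, seed = 1)
  ch <- 1
  n <- g$normals[ch, ]
  pts <- -outer(seq(15, 120, by = 15), n) + rep(g$centers[ch, ], each = 8)
  # evaluate along the axis via a degenerate grid per point
  mags <- vapply(seq_len(nrow(pts)), function(i) {
    ss <- sensitivities(g, list(x = pts[i, 1], y = pts[i, 2], z = pts[i, 3]))
    Mod(ss$values[ch, 1])
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("noise covariance is positive definite with identity limit", {
  g <- build_helmet_array(32, seed = 2)
  psi0 <- noise_cov(g, coupling_scale = 0)
  expect_equal(psi0, diag(32))
  for (seed in 1:5) {
    gg <- build_helmet_array(64, seed = seed)
    psi <- noise_cov(gg, coupling_scale = 0.4)
    ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(psi, t(psi))
  }
})

test_that("optimal combination reduces to known closed forms", {
  # one channel: SNR = |S| / sigma
  s1 <- toy_sensitivity_set(matrix(3 + 4i, 1, 4), c(2, 2, 1))
  expect_equal(as.vector(snr_map(s1, matrix(4))), rep(5 / 2, 4))
  # two identical uncorrelated channels: sqrt(2) gain
  s2 <- toy_sensitivity_set(matrix(3 + 4i, 2, 4), c(2, 2, 1))
  expect_equal(as.vector(snr_map(s2, diag(2))),
               sqrt(2) * as.vector(snr_map(s1, matrix(1))))
  # adding a channel never decreases the information at any voxel
  set.seed(11)
  for (i in 1:20) {
    nch <- sample(2:6, 1)
    vals <- matrix(complex(real = rnorm(nch * 5), imaginary = rnorm(nch * 5)),
                   nch, 5)
    sA <- toy_sensitivity_set(vals[-nch, , drop = FALSE], c(5, 1, 1))
    sB <- toy_sensitivity_set(vals, c(5, 1, 1))
    expect_true(all(snr_map(sB, diag(nch)) >=
                      snr_map(sA, diag(nch - 1)) - 1e-12))
  }
})

test_that("retained SNR is 1 without acceleration and <= 1 with it", {
  s <- toy_grid_sensitivities(16, 16, 8)
  psi <- diag(8) * 0.5
  r1 <- retained_snr_map(s, psi, sampling_pattern(1, 1, 0))
  expect_true(all(r1 == 1))
  r2 <- retained_snr_map(s, psi, sampling_pattern(2, 1, 0))
  expect_true(all(r2 <= 1 + 1e-12))
  expect_true(all(r2 > 0))
  expect_error(retained_snr_map(s, psi, sampling_pattern(3, 1, 0)),
               "divisible")
})

test_that("analytic g matches Monte-Carlo noise propagation within 2%", {
  nx <- 16; ny <- 16; nch <- 8
  s <- toy_grid_sensitivities(nx, ny, nch, seed = 5)
  # correlated noise
  set.seed(5)
  a <- matrix(rnorm(nch * nch, sd = 0.15), nch)
  psi <- diag(nch) + (a + t(a)) / 2
  psi <- psi + diag(nch) * max(0, 0.1 - min(eigen(psi)$values))
  r <- 2
  inv_g <- retained_snr_map(s, psi, sampling_pattern(r, 1, 0))
  ndraw <- 1e5
  u <- chol(psi)
  sv <- s$values
  set.seed(99)
  noise <- crossprod(u, matrix(complex(real = rnorm(nch * ndraw),
                                       imaginary = rnorm(nch * ndraw)) /
                                 sqrt(2), nch, ndraw))
  vox <- function(x, y) x + nx * (y - 1)
  for (y0 in c(1, 4, 7)) {
    for (x in c(3, 9)) {
      idx <- vox(x, c(y0, y0 + ny / r))
      sa <- sv[, idx]
      m <- crossprod(Conj(sa), solve(psi, sa))
      unfold <- solve(m, t(Conj(solve(psi, sa)))) # SENSE unfolding matrix
      rec <- unfold %*% noise
      var_mc <- apply(rec, 1, function(z) stats::var(Re(z)) + stats::var(Im(z)))
      g_mc <- sqrt(var_mc * Re(diag(m)))
      g_an <- 1 / inv_g[cbind(x, c(y0, y0 + ny / r), 1)]
      expect_equal(g_mc, g_an, tolerance = 0.02, ignore_attr = TRUE)
    }
  }
})

test_that("higher channel counts retain more SNR at matched acceleration", {
  ph <- make_phantom(n = c(24, 24, 18), spacing_mm = 6, seed = 2)
  roi <- roi_split(ph$mask, ph$grid)
  med_invg <- c(); periph <- c(); central <- c()
  for (nc in c(32, 64, 96)) {
    g <- build_helmet_array(nc)
    s <- sensitivities(g, ph)
    psi <- noise_cov(g)
    rn <- retained_snr_map(s, psi, sampling_pattern(4, 3, 1))
    sm <- snr_map(s, psi)
    med_invg <- c(med_invg, stats::median(rn[ph$mask]))
    periph <- c(periph, mean(sm[roi$peripheral & ph$mask]))
    central <- c(central, mean(sm[roi$central]))
  }
  expect_true(all(diff(med_invg) > 0))
  # the periphery gains more than the centre from added channels
  expect_true(all(diff(periph) > 0))
  expect_gt((periph[3] / periph[1]), (central[3] / central[1]))
})
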