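test_that("zero field map distorts nothing and shifts scale with dwell", {
  img <- blob_image(32)
  expect_equal(epi_distort(img, img * 0, 1.5, +1), img, tolerance = 1e-12)
  # halving the effective echo spacing halves every displacement
  fmap <- matrix(20, 32, 32)
  cen <- function(m) sum((1:32) * rowSums(m)) / sum(m)
  d_full <- cen(epi_distort(img, fmap, 2, +1)) - cen(img)
  d_half <- cen(epi_distort(img, fmap, 1, +1)) - cen(img)
  expect_equal(d_full, 2 * d_half, tolerance = 1e-3)
  # opposite phase-encode direction flips the shift
  d_neg <- cen(epi_distort(img, fmap, 2, -1)) - cen(img)
  expect_equal(d_neg, -d_full, tolerance = 1e-3)
  expect_error(epi_distort(img, fmap + 1e4, 2, +1), "exceeds")
})

test_that("forward model matches the discrete EPI phase-accrual oracle", {
  n <- 32
  img <- blob_image(n)
  fmap <- matrix(rep(30 * sin(seq(0, pi, length.out = n)), each = n), n, n) *
    matrix(rep(seq(0.5, 1, length.out = n), times = n), n, n, byrow = TRUE)
  fwd <- epi_distort(img, fmap, 2, +1)
  oracle <- epi_kspace_oracle(img, fmap, 2, +1)
  # per-column centroid displacement agrees within 0.1 pixel
  cen <- function(m, j) sum((1:n) * m[, j]) / sum(m[, j])
  d_f <- vapply(1:n, function(j) cen(fwd, j) - cen(img, j), numeric(1))
  d_o <- vapply(1:n, function(j) cen(oracle, j) - cen(img, j), numeric(1))
  expect_lt(max(abs(d_f - d_o)), 0.1)
  expect_lt(max(abs(fwd - oracle)) / max(img), 0.05)
})

test_that("opposite-polarity distortions invert each other", {
  img <- blob_image(48)
  set.seed(2)
  fmap <- matrix(rep(25 * sin(seq(0, 2, length.out = 48)), 48), 48, 48)
  rt <- epi_distort(epi_distort(img, fmap, 1.2, +1), fmap, 1.2, -1)
  expect_lt(sqrt(mean((rt - img)^2)) / sqrt(mean(img^2)), 0.01)
})

test_that("warp estimation recovers a known smooth field within 0.3 mm", {
  ph <- make_phantom(n = c(64, 64, 8), spacing_mm = 3, seed = 3)
  sl <- t(ph$pd[, , 4])           # phase encode along rows (y axis)
  fm <- t(ph$fieldmap_hz[, , 4])
  msk <- t(ph$mask[, , 4])
  es_eff <- 0.7
  ap <- epi_distort(sl, fm, es_eff, +1)
  pa <- epi_distort(sl, fm, es_eff, -1)
  u_true <- fm * 64 * es_eff / 1000 * ph$spacing_mm # mm
  w <- estimate_warp(ap, pa, spacing_mm = ph$spacing_mm)
  expect_s3_class(w, "warp_field")
  expect_lt(sqrt(mean((w$u_mm[msk] - u_true[msk])^2)), 0.3)
  # identical images give a (near) zero field
  w0 <- estimate_warp(sl, sl, spacing_mm = 3)
  expect_lt(max(abs(w0$u_mm)), 1e-6)
  # antisymmetry under swapping the pair
  w_sw <- estimate_warp(pa, ap, spacing_mm = ph$spacing_mm)
  expect_lt(sqrt(mean((w_sw$u_mm[msk] + w$u_mm[msk])^2)), 0.1)
})

test_that("estimated warp magnitude scales with echo spacing across coils", {
  imp <- load_coil_preset("impulse")
  xr <- load_coil_preset("xr_body")
  p <- epi_protocol(0.6, 192, 320, grappa_r = 3, partial_fourier = 6/8)
  es_i <- as.numeric(min_echo_spacing(p, imp)) / 3
  es_x <- as.numeric(min_echo_spacing(p, xr)) / 3
  ph <- make_phantom(n = c(64, 64, 8), spacing_mm = 3, seed = 5)
  sl <- t(ph$pd[, , 4]); fm <- t(ph$fieldmap_hz[, , 4]); msk <- t(ph$mask[, , 4])
  est_mag <- function(es) {
    ap <- epi_distort(sl, fm, es, +1)
    pa <- epi_distort(sl, fm, es, -1)
    w <- estimate_warp(ap, pa, spacing_mm = ph$spacing_mm)
    mean(abs(w$u_mm[msk & abs(fm) > 10]))
  }
  ratio <- est_mag(es_i) / est_mag(es_x)
  expect_equal(ratio, es_i / es_x, tolerance = 0.1)
})
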