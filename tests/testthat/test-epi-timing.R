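imp <- load_coil_preset("impulse")
ac <- load_coil_preset("ac84")
xr <- load_coil_preset("xr_body")

test_that("echo spacing reproduces the published operating points", {
  p06 <- epi_protocol(0.6, 192, 320, grappa_r = 3, partial_fourier = 6/8)
  p05 <- epi_protocol(0.5, 192, 384, grappa_r = 3, partial_fourier = 6/8)
  expect_equal(as.numeric(min_echo_spacing(p06, imp)), 0.58, tolerance = 0.02)
  expect_equal(as.numeric(min_echo_spacing(p06, xr)), 1.21, tolerance = 0.02)
  expect_equal(as.numeric(min_echo_spacing(p05, imp)), 0.68, tolerance = 0.02)
  expect_equal(as.numeric(min_echo_spacing(p05, xr)), 1.41, tolerance = 0.02)
})

test_that("minimum TE reproduces the published pairs", {
  p06 <- epi_protocol(0.6, 192, 320, grappa_r = 3, partial_fourier = 6/8)
  p05 <- epi_protocol(0.5, 192, 384, grappa_r = 3, partial_fourier = 6/8)
  t06i <- min_te(p06, imp)
  expect_equal(t06i$echoes_before_center, 27L) # ceil(320 * 0.25 / 3)
  expect_equal(t06i$n_echoes, 80L)             # ceil(320 * 0.75 / 3)
  expect_equal(t06i$te_min_ms, 17, tolerance = 0.02)
  expect_equal(min_te(p06, xr)$te_min_ms, 34, tolerance = 0.02)
  expect_equal(min_te(p05, imp)$te_min_ms, 23, tolerance = 0.02)
  # structural identities
  expect_equal(t06i$train_ms, t06i$n_echoes * t06i$es_ms)
  expect_equal(t06i$es_eff_ms, t06i$es_ms / 3)
  expect_gte(t06i$te_min_ms, t06i$echoes_before_center * t06i$es_ms)
})

test_that("echo spacings inside a forbidden band are bumped to its edge", {
  # matrix 504 at FOV 192 puts the raw impulse ES near 0.85 ms
  p <- epi_protocol(192 / 504, 192, 504)
  expect_warning(es <- min_echo_spacing(p, imp), "forbidden band")
  expect_equal(as.numeric(es), 0.92)
  expect_true(attr(es, "bumped"))
  # the same readout on a band-free coil is untouched
  es2 <- min_echo_spacing(p, gradient_coil("nobands", 200, 85, 900))
  expect_false(attr(es2, "bumped"))
  expect_lt(as.numeric(es2), 0.92)
})

test_that("limit and boundary cases behave", {
  # near-infinite limits: es collapses to the dead time
  fast <- gradient_coil("fast", 1e7, 1e7, 1e12)
  p <- epi_protocol(0.6, 192, 320)
  expect_equal(as.numeric(min_echo_spacing(p, fast)), 0.03, tolerance = 1e-3)
  # minimal partial-Fourier asymmetry: one echo before the centre
  pmin <- epi_protocol(0.6, 192, 320, partial_fourier = 0.5 + 1 / 320)
  tm <- min_te(pmin, imp)
  expect_equal(tm$echoes_before_center, 1L)
  expect_equal(tm$te_min_ms, 1.3 + tm$es_ms)
  expect_error(epi_protocol(0.6, 192, 320, partial_fourier = 0.5),
               "partial_fourier")
})

test_that("timing is monotone in coil limits and acceleration", {
  p <- epi_protocol(0.6, 192, 320, grappa_r = 2, partial_fourier = 0.75)
  set.seed(7)
  for (i in 1:20) {
    g <- runif(1, 30, 150); sr <- runif(1, 100, 800)
    c1 <- gradient_coil("a", g, g, sr)
    c2 <- gradient_coil("b", g * 1.3, g * 1.3, sr)
    c3 <- gradient_coil("c", g, g, sr * 1.3)
    es1 <- as.numeric(min_echo_spacing(p, c1))
    # a faster slew always shortens the lobe; a higher amplitude cap only
    # when the pulse was amplitude-limited (had a flat top)
    expect_lt(as.numeric(min_echo_spacing(p, c3)), es1)
    es2 <- as.numeric(min_echo_spacing(p, c2))
    amp_limited <- trapezoid_for_area(
      readout_area(p$matrix_n, p$fov_mm), c1)$flat_ms > 0
    if (amp_limited) expect_lt(es2, es1) else expect_equal(es2, es1)
  }
  te_r <- vapply(1:4, function(r) {
    pr <- epi_protocol(0.6, 192, 320, grappa_r = r, partial_fourier = 0.75)
    min_te(pr, xr)$te_min_ms
  }, numeric(1))
  expect_true(all(diff(te_r) <= 1e-9))
})

test_that("achievable resolution ranks the coils and is a fixed point", {
  ri <- achievable_resolution(imp, 26, 200, grappa_r = 4, partial_fourier = 0.75)
  ra <- achievable_resolution(ac, 26, 200, grappa_r = 4, partial_fourier = 0.75)
  rx <- achievable_resolution(xr, 26, 200, grappa_r = 4, partial_fourier = 0.75)
  expect_lt(ri, ra)
  expect_lt(ra, rx)
  # fixed point: the returned matrix is feasible, matrix + grappa_r is not
  m <- attr(rx, "matrix_n")
  te_at <- function(mm) {
    p <- epi_protocol(200 / mm, 200, mm, grappa_r = 4, partial_fourier = 0.75)
    suppressWarnings(min_te(p, xr)$te_min_ms)
  }
  expect_lte(te_at(m), 26)
  expect_gt(te_at(m + 4), 26)
  # a uniformly stronger coil never yields a coarser result
  expect_lte(ri, rx)
  expect_error(achievable_resolution(imp, 1.31, 200), "no feasible|exceed")
})
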