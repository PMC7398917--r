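test_that("compute_r2eff reproduces the intensity-ratio formula", {
  expect_equal(compute_r2eff(100, 100, 0.030, 2)$r2eff, 0)
  expect_equal(compute_r2eff(50, 100, 0.030, 1)$r2eff, -log(0.5) / 0.030,
               tolerance = 1e-12) # 23.105 1/s
  # sigma = 1/(T_relax * SNR): SNR = 50 -> 0.667 1/s
  expect_equal(compute_r2eff(50, 100, 0.030, 1)$sigma, 1 / (0.030 * 50),
               tolerance = 1e-12)
  expect_error(compute_r2eff(-1, 100, 0.030, 1), "domain")
  expect_error(compute_r2eff(50, 100, 0.030, 0), "noise")
})

test_that("compute_r2eff inverts the exponential decay model", {
  r2 <- c(0.5, 5, 14, 30, 60)
  I <- 100 * exp(-r2 * 0.030)
  expect_equal(compute_r2eff(I, 100, 0.030, 1)$r2eff, r2, tolerance = 1e-12)
  # strictly decreasing in I
  rr <- compute_r2eff(seq(10, 90, by = 10), 100, 0.030, 1)$r2eff
  expect_true(all(diff(rr) < 0))
})

test_that("build_series converts, sorts, averages duplicates and drops bad points", {
  nu <- default_nu_grid()
  g <- intensity_group(86, ctx800(), nu, 100 * exp(-14 * 0.030 * rep(1, 11)),
                       100, 2)
  s <- build_series(g)
  expect_s3_class(s, "dispersion_series")
  expect_equal(nrow(s$points), 11)
  expect_equal(s$points$r2eff, rep(14, 11), tolerance = 1e-10)

  g_bad <- intensity_group(86, ctx800(), nu[1:3], c(70, 75, 80), -5, 2)
  expect_error(build_series(g_bad), "reference")

  # duplicate frequencies: intensities averaged, noise combined in quadrature
  g_dup <- intensity_group(7, ctx800(), c(nu[1], nu[1]), c(60, 70), 100, 2)
  expect_warning(s_dup <- build_series(g_dup), "duplicate")
  expect_equal(nrow(s_dup$points), 1)
  expect_equal(s_dup$points$r2eff, -log(65 / 100) / 0.030, tolerance = 1e-12)
  expect_equal(s_dup$points$sigma, (sqrt(8) / 2 / 65) / 0.030,
               tolerance = 1e-12)
})

test_that("baseline estimation is robust to outliers and permutation", {
  flat <- lapply(1:10, function(r) flat_series(r, 14.0))
  bl <- estimate_baseline(flat)
  expect_equal(bl$r2inf, 14.0)
  expect_equal(bl$spread, 0)
  expect_equal(bl$n_supporting_residues, 10)

  with_out <- c(lapply(1:9, function(r) flat_series(r, 14.0)),
                list(flat_series(10, 20.0)))
  bl2 <- estimate_baseline(with_out)
  expect_equal(bl2$r2inf, 14.0)
  expect_equal(bl2$excluded_residues, 10)

  perm <- estimate_baseline(rev(with_out))
  expect_equal(perm$r2inf, bl2$r2inf)
  expect_error(estimate_baseline(flat[1:4]), "at least 5")
})

test_that("baseline recovers the centre of scattered flat profiles", {
  set.seed(42)
  scatter <- lapply(1:20, function(r) flat_series(r, 14.0 + rnorm(1, sd = 0.3)))
  bl <- estimate_baseline(scatter)
  expect_lt(abs(bl$r2inf - 14.0), 0.2)
})

test_that("regimes classify by amplitude then elevation", {
  flat <- lapply(1:10, function(r) flat_series(r, 14.0))
  bl <- estimate_baseline(flat)
  expect_equal(classify_regime(flat[[1]], bl)$label, "no_exchange")
  # flat profile sitting 5 1/s above the exchange-free line -> fast
  expect_equal(classify_regime(flat_series(99, 19.0), bl)$label, "fast")
  # forward-model dispersive profile
  p <- two_state_params(0.05, 500, 3, 14)
  disp <- simulate_series(p, default_nu_grid(), ctx800(), snr = 50, seed = 4)
  expect_equal(classify_regime(disp, bl)$label, "dispersive")
  # noise-free forward model with dw = 0 is indistinguishable from baseline
  p0 <- two_state_params(0.05, 500, 0, 14)
  s0 <- simulate_series(p0, default_nu_grid(), ctx800())
  s0$points$sigma <- rep(0.3, 11)
  expect_equal(classify_regime(s0, bl)$label, "no_exchange")
})
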