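test_that("pulse train planner enforces relaxation compensation", {
  tr <- pulse_train(0.030, 66.7) # printed value snaps to 200/3
  expect_equal(tr$n_pulses, 4)
  expect_equal(tr$delta_s, 0.0075)
  expect_equal(tr$nu_effective_s1, 200 / 3)
  expect_equal(sum(tr$events$duration_s), 0.030)

  tr2 <- pulse_train(0.030, 1000)
  expect_equal(tr2$n_pulses, 60)
  expect_equal(tr2$delta_s, 5e-4)

  # N = 3 is not divisible by 4: error lists nearest admissible frequencies
  expect_error(pulse_train(0.030, 50), "admissible")
  expect_equal(admissible_nu(0.030)[1], 200 / 3)
})

test_that("bm_r2eff reduces to r2inf without exchange", {
  ctx <- ctx800()
  nu <- default_nu_grid()
  p_small <- two_state_params(1e-12, 500, 3, 12)
  expect_equal(bm_r2eff(p_small, nu, ctx), rep(12, 11), tolerance = 1e-9)
  p_zero_dw <- two_state_params(0.05, 500, 0, 12)
  expect_equal(bm_r2eff(p_zero_dw, nu, ctx), rep(12, 11), tolerance = 1e-12)
})

test_that("bm_r2eff matches the fine-step brute-force propagator", {
  ctx <- ctx800()
  p <- two_state_params(0.05, 500, 3, 12)
  nu <- c(200 / 3, 1000)
  bm <- bm_r2eff(p, nu, ctx)
  expect_gt(bm[1], bm[2]) # dispersion decays with pulsing rate
  br <- brute_force_r2eff(c(0.95, 0.05), two_state_K(0.05, 500),
                          c(0, ppm_to_rad(3, 800.4)), nu, 0.030, r2 = 12)
  expect_lt(max(abs(bm - br)), 0.01)
})

test_that("exchange contribution respects model symmetries", {
  nu <- default_nu_grid()
  rex <- function(pB, kex, dwr)
    cpmgrd:::bm_rex_curve_cpp(pB, kex, dwr, nu, 0.030)
  dwr <- ppm_to_rad(3, 800.4)
  # sign of dw is unobservable
  expect_equal(rex(0.05, 500, dwr), rex(0.05, 500, -dwr), tolerance = 1e-12)
  # state relabelling (pB <-> pA, dw -> -dw) leaves R2eff unchanged:
  # the overall frame offset is refocused by the echo train
  expect_equal(rex(0.05, 500, dwr), rex(0.95, 500, -dwr), tolerance = 1e-8)
  # refocusing limit: monotone approach to r2inf at high nu_CPMG
  for (pB in c(0.02, 0.1)) for (kex in c(300, 2000)) for (dw in c(1, 4)) {
    r <- rex(pB, kex, ppm_to_rad(dw, 800.4))
    expect_lt(r[length(r)], 0.25 * r[1] + 1e-9)
    expect_lt(r[length(r)], min(r[1:6]) + 1e-9)
  }
})

test_that("Carver-Richards agrees with the propagator in its validity domain", {
  ctx <- ctx600()
  nu <- default_nu_grid()
  p <- two_state_params(0.03, 1000, 2, 12)
  expect_lt(max(abs(carver_richards_r2eff(p, nu, ctx) - bm_r2eff(p, nu, ctx)) /
                bm_r2eff(p, nu, ctx)), 0.02)
  p0 <- two_state_params(1e-12, 1000, 2, 12)
  expect_equal(carver_richards_r2eff(p0, nu, ctx), rep(12, 11),
               tolerance = 1e-9)
})

test_that("fast-exchange excess approaches pA pB dw^2 / kex at low nu", {
  # T_relax = 120 ms admits nu = 16.7 1/s where the Meiboom finite-pulsing
  # correction (1 - 4 nu / kex) is ~1.3%; at the 30 ms minimum of 66.7 1/s
  # that correction alone is 5.3%
  ctx <- spectrometer_context(800.4, 298, t_relax_s = 0.12)
  dw_ppm <- 500 / ppm_to_rad(1, 800.4)
  p <- two_state_params(0.05, 5000, dw_ppm, 12)
  excess <- bm_r2eff(p, 1 / (2 * 0.12) * 4, ctx) - 12
  expect_lt(abs(excess - 0.95 * 0.05 * 500^2 / 5000) / 2.375, 0.05)
})

test_that("simulate_series is exact when noise-free and seeded when not", {
  ctx <- ctx800()
  nu <- default_nu_grid()
  p <- two_state_params(0.05, 500, 3, 12)
  s <- simulate_series(p, nu, ctx)
  expect_equal(s$points$r2eff, bm_r2eff(p, nu, ctx))
  s1 <- simulate_series(p, nu, ctx, snr = 50, seed = 11)
  s2 <- simulate_series(p, nu, ctx, snr = 50, seed = 11)
  expect_identical(s1$points, s2$points)
  expect_equal(s1$points$sigma, rep(1 / (0.030 * 50), 11))
})

test_that("Monte-Carlo noise SD matches the sigma formula", {
  ctx <- ctx800()
  p <- two_state_params(0.05, 500, 3, 12)
  draws <- vapply(1:1000, function(sd)
    simulate_series(p, 200 / 3, ctx, snr = 50, seed = sd)$points$r2eff,
    numeric(1))
  expect_lt(abs(sd(draws) - 1 / (0.030 * 50)) / (1 / (0.030 * 50)), 0.05)
})
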