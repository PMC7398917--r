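sim_pair <- function(pB, kex, dw, T_K = 283, snr = NULL, seed = NULL,
                     residue_id = 1L) {
  list(simulate_series(two_state_params(pB, kex, dw, 11), default_nu_grid(),
                       ctx600(T_K), snr = snr, seed = seed,
                       residue_id = residue_id),
       simulate_series(two_state_params(pB, kex, dw, 14), default_nu_grid(),
                       ctx800(T_K), snr = snr,
                       seed = if (is.null(seed)) NULL else seed + 5000L,
                       residue_id = residue_id))
}

test_that("individual fits recover noise-free parameters to < 1%", {
  fit <- fit_individual(sim_pair(0.05, 500, 3))
  expect_true(fit$converged)
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$pars$value, c(0.05, 500, 3), tolerance = 0.01)
  expect_equal(fit$df, 22 - 5)
  expect_equal(fit$r2inf$value, c(11, 14), tolerance = 1e-3)
})

test_that("flat profiles are flagged non-identifiable, not silently fitted", {
  expect_warning(fit <- fit_individual(sim_pair(0.05, 500, 0)),
                 "non-identifiable")
  expect_true(fit$converged)
  expect_true(length(fit$warnings) > 0)
})

test_that("reported uncertainties calibrate and CIs cover the truth", {
  # 100 noisy replicates at snr = 50: per-parameter 95% CIs should cover the
  # truth in >= 90 seeds, and the reported sigma(p_B) should track the
  # empirical scatter within a factor 1.5
  true <- c(0.05, 500, 3)
  est <- sig <- matrix(NA_real_, 100, 3)
  for (sd_i in 1:100) {
    f <- fit_individual(sim_pair(0.05, 500, 3, snr = 50, seed = sd_i),
                        n_polish = 6)
    est[sd_i, ] <- f$pars$value
    sig[sd_i, ] <- f$pars$sigma
  }
  cover <- colMeans(abs(est - rep(true, each = 100)) <
                    qnorm(0.975) * sig) * 100
  expect_true(all(cover >= 90))
  ratio <- sd(est[, 1]) / mean(sig[, 1])
  expect_lt(ratio, 1.5)
  expect_gt(ratio, 1 / 1.5)
})

test_that("global per-temperature fits share p_B and k_ex", {
  sl <- unlist(lapply(1:5, function(i)
    sim_pair(0.08, 800, c(2, 2.5, 3, 3.5, 4)[i], residue_id = 100L + i)),
    recursive = FALSE)
  g <- fit_global_temperature(sl)
  expect_true(g$converged)
  expect_lt(g$chi2, 1e-6)
  expect_equal(g$pars$value[g$pars$name == "p_B"], 0.08, tolerance = 0.02)
  expect_equal(g$pars$value[g$pars$name == "k_ex"], 800, tolerance = 0.02)
  expect_equal(g$pars$value[3:7], c(2, 2.5, 3, 3.5, 4), tolerance = 0.02)

  # single residue: reduces to the individual fit
  one <- sim_pair(0.05, 500, 3, residue_id = 7L)
  g1 <- fit_global_temperature(one)
  f1 <- fit_individual(one)
  expect_equal(g1$pars$value, f1$pars$value, tolerance = 1e-3)
  expect_equal(g1$df, f1$df)
})

test_that("global fits expose shared-parameter misspecification", {
  a <- sim_pair(0.05, 500, 3, snr = 200, seed = 1, residue_id = 1L)
  b <- sim_pair(0.05, 2000, 3, snr = 200, seed = 2, residue_id = 2L)
  find <- list(fit_individual(a, n_polish = 6), fit_individual(b, n_polish = 6))
  g <- fit_global_temperature(c(a, b), n_polish = 6)
  sum_ind <- sum(vapply(find, `[[`, numeric(1), "chi2"))
  expect_gt(g$chi2, 10 * sum_ind)
  expect_gt(g$chi2, g$df) # and the global fit fails the chi2 < DF criterion
})

test_that("all-temperature fits recover the generating thermodynamics", {
  tr <- truth_paperlike(1)
  ds <- gen_dispersion_dataset(tr, snr = NULL, seed = 1)
  sl <- dataset_series(ds, residues = tr$dispersive$residue_id)
  fu <- fit_global_all(sl, constrained = FALSE)
  fc <- fit_global_all(sl, constrained = TRUE)
  expect_lt(fu$chi2, 1e-6)
  expect_lt(fc$chi2, 1e-6)
  # unconstrained per-temperature values follow the generating laws < 2%
  for (T_K in c(278, 283, 290, 298)) {
    pB_true <- predict_pB(tr$eq, T_K)
    kex_true <- predict_k(tr$ts, T_K) / pB_true
    expect_equal(fu$pars$value[fu$pars$name == sprintf("p_B_%gK", T_K)],
                 pB_true, tolerance = 0.02)
    expect_equal(fu$pars$value[fu$pars$name == sprintf("k_ex_%gK", T_K)],
                 kex_true, tolerance = 0.02)
  }
  # constrained fit recovers all four thermodynamic parameters < 2%
  expect_equal(fc$pars$value[1:4], c(-30, -120, 50, -40), tolerance = 0.02)
  # fewer free parameters -> more degrees of freedom
  expect_gt(fc$df, fu$df)
  # nesting: chi2(constrained) >= chi2(unconstrained) within optimizer noise
  expect_gt(fc$chi2, fu$chi2 - 1e-8)
})

test_that("fits are deterministic for identical data", {
  sl <- sim_pair(0.05, 500, 3, snr = 50, seed = 3)
  f1 <- fit_individual(sl)
  f2 <- fit_individual(sl)
  expect_identical(f1$pars, f2$pars)
  expect_identical(f1$chi2, f2$chi2)
})

test_that("model selection tabulates chi2 vs DF and demands matching data", {
  a <- sim_pair(0.05, 500, 3, residue_id = 1L)
  b <- sim_pair(0.05, 500, 4, residue_id = 2L)
  ind <- list(fit_individual(a), fit_individual(b))
  g <- fit_global_temperature(c(a, b))
  ms <- model_select(ind, g)
  expect_true(ms$consistent) # noise-free: chi2 ~ 0 at every level
  expect_equal(nrow(ms$table), 2)
  expect_error(model_select(ind[1], g), "mismatch")
})

test_that("compare_series detects quenching but not repeated noise", {
  s1 <- simulate_series(two_state_params(0.05, 500, 3, 14), default_nu_grid(),
                        ctx800(283))
  s1n <- simulate_series(two_state_params(0.05, 500, 3, 14), default_nu_grid(),
                         ctx800(283), snr = 50, seed = 1)
  expect_equal(compare_series(s1, s1)$chi2_per_point, 0)
  expect_false(compare_series(s1, s1)$changed)
  flat <- simulate_series(two_state_params(1e-12, 500, 3, 14),
                          default_nu_grid(), ctx800(283), snr = 50, seed = 2)
  expect_true(compare_series(s1n, flat)$changed)
  short <- simulate_series(two_state_params(0.05, 500, 3, 14),
                           default_nu_grid()[1:5], ctx800(283))
  expect_error(compare_series(s1, short), "grid")
})
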