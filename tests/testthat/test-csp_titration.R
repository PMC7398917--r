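shift_tab <- function(dH, dN, ids = seq_along(dH)) {
  data.frame(residue_id = ids, delta_H = dH, delta_N = dN)
}

test_that("CSP reproduces the weighted-shift formula", {
  free <- shift_tab(c(8.0, 8.0, 8.0), c(120, 120, 120))
  bound <- shift_tab(c(8.0, 8.1, 8.2), c(120, 121, 120))
  csp <- compute_csp(free, bound)
  expect_equal(csp$csp_ppm[1], 0, tolerance = 1e-12)
  expect_equal(csp$csp_ppm[2], 0.1, tolerance = 1e-12)        # sqrt(.5*.01+.5*.01)
  expect_equal(csp$csp_ppm[3], sqrt(0.5 * 0.04), tolerance = 1e-12) # 0.1414
  expect_error(compute_csp(free, bound[1:2, ]), "mismatch")
})

test_that("CSP is symmetric and referencing-invariant", {
  set.seed(2)
  free <- shift_tab(runif(10, 7.5, 9.5), runif(10, 105, 130))
  bound <- shift_tab(free$delta_H + rnorm(10, sd = 0.05),
                     free$delta_N + rnorm(10, sd = 0.5))
  expect_equal(compute_csp(free, bound)$csp_ppm,
               compute_csp(bound, free)$csp_ppm, tolerance = 1e-12)
  shifted <- bound; shifted$delta_H <- shifted$delta_H + 0.37
  shifted$delta_N <- shifted$delta_N + 1.9
  free2 <- free; free2$delta_H <- free2$delta_H + 0.37
  free2$delta_N <- free2$delta_N + 1.9
  expect_equal(compute_csp(free2, shifted)$csp_ppm,
               compute_csp(free, bound)$csp_ppm, tolerance = 1e-12)
})

test_that("significance labelling follows mean + 2 SD and scales", {
  equal <- data.frame(residue_id = 1:6, csp_ppm = rep(0.02, 6))
  expect_false(any(label_significant(equal)$significant))
  mix <- data.frame(residue_id = 1:20, csp_ppm = c(rep(0.01, 19), 0.2))
  lab <- label_significant(mix)
  expect_equal(which(lab$significant), 20L)
  scaled <- mix; scaled$csp_ppm <- scaled$csp_ppm * 7
  expect_equal(label_significant(scaled)$significant, lab$significant)
  expect_error(label_significant(mix[1:3, ]), "5")
})

test_that("hotspot flags recover the planted perturbations", {
  ds <- gen_csp_dataset(100, c(5, 25, 60, 86, 96), noise_ppm = 0, seed = 1)
  lab <- label_significant(compute_csp(ds$free, ds$bound))
  expect_setequal(lab$residue_id[lab$significant], ds$truth$hotspots)
  # seed reproducibility
  ds2 <- gen_csp_dataset(100, c(5, 25, 60, 86, 96), noise_ppm = 0, seed = 1)
  expect_identical(ds$bound, ds2$bound)
})

test_that("temperature coefficients fit delta_HN versus T", {
  tc <- temp_coefficient(c(278, 298), c(8.50, 8.40))
  expect_equal(tc$slope_ppb_per_K, -5, tolerance = 1e-10)
  flat <- temp_coefficient(c(278, 283, 290, 298), rep(8.1, 4))
  expect_equal(flat$slope_ppb_per_K, 0)
  expect_equal(flat$r_squared, 1) # zero-variance convention
  expect_error(temp_coefficient(c(278, 278), c(8.5, 8.4)), "duplicate")

  set.seed(3)
  T_K <- c(278, 283, 290, 298)
  delta <- 8.5 - 4.2e-3 * (T_K - 278) + rnorm(4, sd = 0.002)
  noisy <- temp_coefficient(T_K, delta)
  expect_lt(abs(noisy$slope_ppb_per_K - (-4.2)), 1)
})

test_that("temperature-coefficient tables iterate residues", {
  tabs <- lapply(c(278, 283, 290, 298), function(T_K) {
    out <- shift_tab(c(8.5, 8.0) - c(5e-3, 2e-3) * (T_K - 278), c(120, 118),
                     ids = c(10, 11))
    attr(out, "context") <- ctx800(T_K)
    out
  })
  res <- temp_coefficient_table(tabs)
  expect_equal(res$slope_ppb_per_K, c(-5, -2), tolerance = 1e-8)
})
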