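test_that("intensity tables parse, group and validate", {
  df <- data.frame(residue = rep(c(80, 86), each = 3),
                   nu_cpmg = rep(c(0, 200/3, 1000), 2),
                   intensity = c(100, 70, 80, 100, 60, 75),
                   noise = 2)
  groups <- read_intensity_table(write_tsv_fixture(df), ctx800())
  expect_length(groups, 2)
  expect_equal(vapply(groups, `[[`, integer(1), "residue_id"), c(80L, 86L))
  expect_equal(groups[[1]]$data$nu_cpmg[1], 0) # reference row identified first

  # missing noise column -> schema error naming the column
  expect_error(read_intensity_table(write_tsv_fixture(df[, -4]), ctx800()),
               "noise")
  # residue 86 without a reference record -> validation error naming it
  df2 <- df[!(df$residue == 86 & df$nu_cpmg == 0), ]
  expect_error(read_intensity_table(write_tsv_fixture(df2), ctx800()), "86")
  # non-numeric cell -> parse error with row number
  df3 <- df; df3$intensity <- as.character(df3$intensity)
  df3$intensity[4] <- "oops"
  expect_error(read_intensity_table(write_tsv_fixture(df3), ctx800()),
               "row 4")
})

test_that("context validation rejects unphysical metadata", {
  expect_error(spectrometer_context(800.4, 25), "250")
  expect_error(spectrometer_context(800.4, 298, t_relax_s = 0), "t_relax")
  expect_error(spectrometer_context(-1, 298), "proton_frequency")
})

test_that("relaxation tables validate rates and round-trip", {
  df <- data.frame(residue = 1:3, R1 = c(1.5, 1.6, 1.4), R1_err = 0.02,
                   R2 = c(12, 13, 12.5), R2_err = 0.2,
                   NOE = c(0.8, 0.78, 0.82), NOE_err = 0.02)
  rec <- read_relaxation_table(write_tsv_fixture(df), ctx800())
  expect_equal(nrow(rec), 3)
  df_bad <- df; df_bad$R2[2] <- -1
  expect_error(read_relaxation_table(write_tsv_fixture(df_bad), ctx800()),
               "positive")

  # write_report / read_report round trip preserves numerics to 1e-12 relative
  set.seed(1)
  res <- data.frame(pB = runif(4) / 10, kex = exp(runif(4, 4, 9)),
                    chi2 = rnorm(4)^2 * 1e-7)
  path <- tempfile(fileext = ".tsv")
  write_report(res, path, units = c("1", "1/s", "1"))
  back <- read_report(path)
  expect_equal(back, res, tolerance = 1e-12)
  first <- readLines(path, n = 1)
  expect_match(first, "^# cpmgrd")
})

test_that("empty result sets give header-only reports", {
  path <- tempfile(fileext = ".tsv")
  write_report(data.frame(pB = numeric(0), kex = numeric(0)), path)
  back <- read_report(path)
  expect_equal(nrow(back), 0)
  expect_named(back, c("pB", "kex"))
})

test_that("shift tables distinguish conditions and reject duplicates", {
  df_free <- data.frame(residue = c("86R", "111L"), delta_H = c(8.2, 7.9),
                        delta_N = c(118.3, 121.0))
  df_bound <- data.frame(residue = c(86, 111), delta_H = c(8.4, 8.3),
                         delta_N = c(119.0, 122.5))
  free <- read_shift_table(write_tsv_fixture(df_free), ctx800(cond = "free"))
  bound <- read_shift_table(write_tsv_fixture(df_bound), ctx800(cond = "bound"))
  expect_equal(free$residue_id, c(86L, 111L)) # letter suffixes stripped
  expect_equal(attr(free, "context")$condition, "free")
  expect_equal(attr(bound, "context")$condition, "bound")

  dup <- rbind(df_bound, df_bound[1, ])
  expect_error(read_shift_table(write_tsv_fixture(dup), ctx800()), "duplicat")

  empty <- df_bound[0, ]
  expect_warning(out <- read_shift_table(write_tsv_fixture(empty), ctx800()),
                 "empty")
  expect_equal(nrow(out), 0)
})

test_that("delimiter auto-detection and grouping order are deterministic", {
  df <- data.frame(residue = c(2, 1, 1, 2), nu_cpmg = c(0, 200/3, 0, 200/3),
                   intensity = c(90, 60, 100, 55), noise = 1.5)
  p_csv <- tempfile(fileext = ".csv")
  write.csv(df, p_csv, row.names = FALSE, quote = FALSE)
  g_csv <- read_intensity_table(p_csv, ctx800())
  g_tsv <- read_intensity_table(write_tsv_fixture(df), ctx800())
  expect_equal(vapply(g_csv, `[[`, integer(1), "residue_id"), c(1L, 2L))
  expect_equal(g_csv[[1]]$data, g_tsv[[1]]$data)
})
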