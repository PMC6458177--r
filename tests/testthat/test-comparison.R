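ratio_df <- function(thickness, ratio) {
  data.frame(thickness = thickness, ratio_dance_volpara = ratio)
}

test_that("ratio summaries stratify by the four thickness classes", {
  out <- summarize_ratios(ratio_df(50, 1.0), "ratio_dance_volpara")
  expect_equal(nrow(out), 4)
  row <- out[out$class == "41-60", ]
  expect_equal(row$n, 1)
  expect_equal(c(row$min, row$max, row$mean, row$sd), c(1, 1, 1, 0))
  expect_equal(sum(out$n), 1)

  # hand-computed sample SD with the n-1 denominator
  out2 <- summarize_ratios(ratio_df(c(50, 55), c(0.8, 1.2)),
                           "ratio_dance_volpara")
  row2 <- out2[out2$class == "41-60", ]
  expect_equal(row2$mean, 1.0)
  expect_equal(row2$sd, 0.2828427, tolerance = 1e-6)

  # fractional thicknesses are rounded before class assignment
  out3 <- summarize_ratios(ratio_df(c(40.4, 40.6), c(1, 1)),
                           "ratio_dance_volpara")
  expect_equal(out3$n[out3$class == "20-40"], 1)
  expect_equal(out3$n[out3$class == "41-60"], 1)

  # sub-20 mm thickness goes to the first class with a warning
  expect_warning(out4 <- summarize_ratios(ratio_df(15, 0.9),
                                          "ratio_dance_volpara"),
                 "20 mm")
  expect_equal(out4$n[out4$class == "20-40"], 1)
})

test_that("ratio summaries are invariant to record order and N sums to cohort size", {
  co <- small_cohort()
  agd <- compute_agd_table(co$records, default_tables())
  s1 <- summarize_ratios(agd)
  s2 <- summarize_ratios(agd[sample(nrow(agd)), ])
  expect_equal(s1, s2)
  expect_equal(sum(s1$n[s1$ratio == "ratio_dance_volpara"]), nrow(agd))
})

test_that("density categories use quartile bins with lower-bin boundary assignment", {
  out <- density_categories(c(10, 30, 60, 90))
  expect_equal(out$count, c(1, 1, 1, 1))
  expect_equal(density_categories(rep(12, 7))$count, c(7, 0, 0, 0))
  # boundary 25 belongs to category 1; 0 belongs to category 1
  expect_equal(density_categories(c(25, 0))$count, c(2, 0, 0, 0))
  expect_equal(sum(density_categories(runif(50, 0, 100))$count), 50)
  expect_error(density_categories(c(40, 104)), "\\[0, 100\\]")
})

test_that("glandularity regression recovers a noiseless plane exactly", {
  set.seed(2)
  df <- data.frame(age = runif(40, 20, 80), thickness = runif(40, 20, 100))
  df$volpara_gpw <- 60 - 0.3 * df$age - 0.4 * df$thickness
  # noiseless plane: summary.lm warns about the (intended) perfect fit
  fit <- suppressWarnings(fit_glandularity_regression(df))
  expect_equal(unname(fit$coefficients), c(60, -0.3, -0.4),
               tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-10)
  expect_true(all(fit$se >= 0))
})

test_that("constant glandularity yields zero slopes and zero R-squared", {
  df <- data.frame(age = c(30, 40, 50, 60), thickness = c(30, 70, 50, 90),
                   volpara_gpw = 25)
  fit <- suppressWarnings(fit_glandularity_regression(df))
  expect_equal(unname(fit$coefficients[2:3]), c(0, 0), tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)
  expect_error(fit_glandularity_regression(
    data.frame(age = c(30, 30, 30), thickness = c(50, 50, 50),
               volpara_gpw = c(10, 20, 30))), "singular")
  expect_error(fit_glandularity_regression(
    data.frame(age = 30, thickness = 50, volpara_gpw = 10)), "3")
})

test_that("Pearson ratio-covariate correlation matches the closed-form value", {
  df <- data.frame(thickness = c(1, 2, 3, 4),
                   ratio_dance_volpara = c(1, 3, 2, 4))
  ct <- ratio_covariate_correlation(df)
  expect_equal(ct$r, 0.8, tolerance = 1e-12)
  expect_equal(ct$n, 4)
  # perfectly linear pairs
  df2 <- data.frame(age = 1:10, ratio_dance_volpara = 2 + 3 * (1:10))
  expect_equal(ratio_covariate_correlation(df2, covariate = "age")$r, 1,
               tolerance = 1e-12)
  # degenerate inputs
  df3 <- data.frame(thickness = 1:5, ratio_dance_volpara = 1)
  expect_error(ratio_covariate_correlation(df3), "zero variance")
  expect_error(ratio_covariate_correlation(df[1:2, ]), "3")
})

test_that("synthetic cohorts reproduce the qualitative thin-to-thick ratio trend", {
  co <- small_cohort(n = 1000, seed = 13)
  agd <- compute_agd_table(co$records, default_tables())
  s <- summarize_ratios(agd, "ratio_dance_volpara")
  m_thin <- s$mean[s$class == "20-40"]
  m_thick <- s$mean[s$class == ">80"]
  expect_lt(m_thin, 1)                       # personalized AGD higher
  expect_lt(abs(m_thick - 1), abs(m_thin - 1))  # and converging with size
  # the thin-breast discrepancy comes with positive thickness correlation
  ct <- ratio_covariate_correlation(agd, "ratio_dance_volpara", "thickness")
  expect_gt(ct$r, 0)
  expect_lt(ct$p_value, 0.001)
})
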