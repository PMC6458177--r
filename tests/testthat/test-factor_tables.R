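test_that("published g, c and glandularity grids are reproduced exactly at nodes", {
  ft <- default_tables()
  for (j in seq_along(table1$thickness)) {
    for (h in c(0.3, 0.5, 0.8)) {
      hs <- as.character(h)
      expect_equal(g_factor(ft, table1$thickness[j], h),
                   unname(table1$g[j, hs]), tolerance = 1e-12)
      expect_equal(c_factor(ft, table1$gland[j], table1$thickness[j], h),
                   unname(table1$c[j, hs]), tolerance = 1e-12)
    }
    expect_equal(dance_glandularity(ft, age = 55, table1$thickness[j]),
                 table1$gland[j], tolerance = 1e-12)
  }
})

test_that("thickness-class reference c-values are reproduced exactly", {
  ft <- default_tables()
  ref <- dose_ratio_reference(ft)
  expect_equal(nrow(ref), 14)  # 7 classes x 2 age groups
  expect_equal(c_factor(ft, ref$gland_dance, ref$thickness_mm,
                        ref$hvl_mm_al),
               ref$c_dance, tolerance = 1e-12)
  expect_equal(c_factor(ft, ref$gland_volpara, ref$thickness_mm,
                        ref$hvl_mm_al),
               ref$c_volpara, tolerance = 1e-12)
  # spot values: thinnest class, HVL 0.380
  young <- ref[ref$age_group == "40-49", ]
  expect_equal(c_factor(ft, 46.2, young$thickness_mm[1], 0.380), 1.012)
  expect_equal(c_factor(ft, 94.4, young$thickness_mm[1], 0.380), 0.882)
  expect_lt(c_factor(ft, 94.4, young$thickness_mm[1], 0.380),
            c_factor(ft, 46.2, young$thickness_mm[1], 0.380))
})

test_that("g interpolates bilinearly between nodes and matches an independent oracle", {
  ft <- default_tables()
  v <- g_factor(ft, 45, 0.5)
  expect_gt(v, 0.259)
  expect_lt(v, 0.319)
  # independent bilinear oracle
  skip_if_not_installed("pracma")
  set.seed(11)
  tq <- runif(40, 20, 110)
  hq <- runif(40, 0.3, 0.8)
  oracle <- pracma::interp2(x = c(0.3, 0.5, 0.8), y = table1$thickness,
                            Z = table1$g, xp = hq, yp = tq,
                            method = "linear")
  expect_equal(g_factor(ft, tq, hq), oracle, tolerance = 1e-12)
})

test_that("g is monotone: decreasing in thickness, increasing in HVL", {
  ft <- default_tables()
  for (h in c(0.3, 0.42, 0.5, 0.65, 0.8)) {
    v <- g_factor(ft, seq(20, 110, 2.5), h)
    expect_true(all(diff(v) < 0))
  }
  for (t in c(20, 37, 55, 80.5, 110)) {
    v <- g_factor(ft, t, seq(0.3, 0.8, 0.02))
    expect_true(all(diff(v) > 0))
  }
})

test_that("out-of-range queries raise errors naming the offending axis", {
  ft <- default_tables()
  expect_error(g_factor(ft, 15, 0.5), "thickness")
  expect_error(g_factor(ft, 115, 0.5), "thickness")
  expect_error(g_factor(ft, 50, 0.25), "HVL")
  expect_error(g_factor(ft, 50, 0.9), "HVL")
  expect_error(c_factor(ft, 120, 50, 0.5), "glandularity")
  expect_error(c_factor(ft, 50, 15, 0.5), "thickness")
  expect_error(dance_glandularity(ft, 55, 150), "thickness")
})

test_that("c is 1 at 50% glandularity within tabulation precision and strictly decreasing", {
  ft <- default_tables()
  expect_equal(c_factor(ft, 50, 40, 0.3), 0.998)
  for (h in c(0.3, 0.5, 0.8)) {
    expect_lte(abs(c_factor(ft, 50, 40, h) - 1), 0.002 + 1e-12)
  }
  set.seed(7)
  for (k in 1:12) {
    t <- runif(1, 20, 110); h <- runif(1, 0.3, 0.8)
    v <- c_factor(ft, seq(0, 100, 4), t, h)
    expect_true(all(diff(v) < 0),
                info = sprintf("t=%.1f h=%.3f", t, h))
  }
})

test_that("interpolated c never overshoots its bracketing station curves", {
  ft <- default_tables()
  set.seed(21)
  for (k in 1:30) {
    g <- runif(1, 0, 100); t <- runif(1, 20, 110); h <- runif(1, 0.3, 0.8)
    it <- findInterval(t, table1$thickness)
    it <- min(max(it, 1), 9)
    hb <- c(0.3, 0.5, 0.8)
    ih <- min(max(findInterval(h, hb), 1), 2)
    corners <- c_factor(ft, g,
                        rep(table1$thickness[c(it, it + 1)], 2),
                        rep(hb[c(ih, ih + 1)], each = 2))
    v <- c_factor(ft, g, t, h)
    expect_gte(v, min(corners) - 1e-12)
    expect_lte(v, max(corners) + 1e-12)
  }
})

test_that("s-factor lookups work and unknown combinations fail informatively", {
  ft <- default_tables()
  expect_identical(s_factor(ft, "Mo", "Mo"), 1)
  expect_gt(s_factor(ft, "Rh", "Rh"), 1)
  expect_equal(s_factor(ft, c("Mo", "W"), c("Rh", "Rh")),
               c(1.017, 1.042))
  expect_error(s_factor(ft, "W", "unobtainium"), "supported")
})

test_that("population glandularity follows the age-group policy with neighbour substitution", {
  ft <- default_tables()
  expect_equal(dance_glandularity(ft, 55, 30), 72)
  expect_equal(dance_glandularity(ft, 70, 30), 72)  # >=65 uses 50-64 group
  expect_equal(dance_glandularity(ft, 30, 30),
               dance_glandularity(ft, 45, 30))      # <40 uses 40-49 group
  # hand oracle: midway between the 20 mm (100%) and 30 mm (72%) rows
  expect_equal(dance_glandularity(ft, 55, 25), 86)
  v <- dance_glandularity(ft, 55, 25)
  expect_gt(v, 72); expect_lt(v, 100)
  # younger group is denser than the older group at equal thickness
  expect_gt(dance_glandularity(ft, 45, 40), dance_glandularity(ft, 60, 40))
  expect_error(dance_glandularity(ft, -2, 40), "age")
  # custom policy partition validation
  expect_error(age_group_policy(data.frame(lower = 10, upper = 60,
                                           group = "40-49")),
               "partition")
})

test_that("loader validates table files and names missing pieces", {
  df <- utils::read.csv(system.file("extdata", "dance_default_factors.csv",
                                    package = "mammodose"))
  bad <- df
  bad$value[bad$table == "g"][1] <- -0.1
  f <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(load_factor_tables(f), "positive")

  noaxis <- df
  noaxis$hvl_mm_al[noaxis$table == "g"] <- NA
  utils::write.csv(noaxis, f, row.names = FALSE)
  expect_error(load_factor_tables(f), "hvl_mm_al")

  nog <- df[df$table != "g", ]
  utils::write.csv(nog, f, row.names = FALSE)
  expect_error(load_factor_tables(f), "'g'")

  expect_error(load_factor_tables(tempfile()), "not found")
  # a faithful copy loads identically
  utils::write.csv(df, f, row.names = FALSE)
  ft2 <- load_factor_tables(f)
  expect_equal(g_factor(ft2, 40, 0.5), 0.319)
})
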