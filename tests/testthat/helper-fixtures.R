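# shared fixtures: the default factor tables are loaded once per test run
.test_env <- new.env()

default_tables <- function() {
  if (is.null(.test_env$tables)) {
    .test_env$tables <- load_factor_tables("paper-default")
  }
  .test_env$tables
}

# the published grid (typed independently of the packaged CSV so a
# transcription error in either copy is caught)
table1 <- list(
  thickness = seq(20, 110, 10),
  gland = c(100, 72, 50, 33, 21, 12, 7, 4, 3, 3),
  c = cbind(`0.3` = c(0.863, 0.923, 0.998, 1.08, 1.15, 1.21, 1.26, 1.29,
                      1.31, 1.32),
            `0.5` = c(0.885, 0.935, 1.00, 1.07, 1.13, 1.19, 1.23, 1.26,
                      1.28, 1.29),
            `0.8` = c(0.917, 0.952, 1.00, 1.06, 1.11, 1.15, 1.18, 1.21,
                      1.22, 1.23)),
  g = cbind(`0.3` = c(0.390, 0.273, 0.207, 0.165, 0.136, 0.115, 0.099,
                      0.0868, 0.0774, 0.0699),
            `0.5` = c(0.541, 0.405, 0.319, 0.259, 0.215, 0.182, 0.157,
                      0.138, 0.123, 0.112),
            `0.8` = c(0.683, 0.555, 0.460, 0.388, 0.333, 0.289, 0.254,
                      0.226, 0.204, 0.186)))

# one valid exposure record at a grid node
node_record <- function(...) {
  defaults <- list(age = 55, thickness = 40, hvl = 0.5, anode = "Mo",
                   filter = "Mo", iak = 1, volpara_gpw = 50,
                   vendor_agd = 0.319)
  args <- utils::modifyList(defaults, list(...))
  as.data.frame(args, stringsAsFactors = FALSE)
}

small_cohort <- function(n = 200, seed = 42) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.test_env[[key]])) {
    .test_env[[key]] <- generate_cohort(cohort_params(n = n), seed = seed,
                                        tables = default_tables())
  }
  .test_env[[key]]
}
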