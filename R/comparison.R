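.thickness_classes <- data.frame(
  class = c("20-40", "41-60", "61-80", ">80"),
  lower = c(-Inf, 41, 61, 81),
  upper = c(40, 60, 80, Inf),
  stringsAsFactors = FALSE)

.assign_thickness_class <- function(thickness) {
  t_int <- round(thickness)
  if (any(t_int < 20)) {
    warning(sum(t_int < 20), " record(s) below 20 mm assigned to the ",
            "20-40 mm class", call. = FALSE)
  }
  cls <- .thickness_classes$class[findInterval(t_int,
                                               c(41, 61, 81)) + 1L]
  factor(cls, levels = .thickness_classes$class)
}

#' Stratified dose-ratio summary by thickness class
#'
#' Pools the pairwise AGD ratios into the four compressed-thickness classes
#' 20-40, 41-60, 61-80 and >80 mm (fractional thicknesses are rounded to
#' integer mm before assignment, matching the integer class labels; values
#' below 20 mm go to the first class with a warning) and reports N, min,
#' max, mean and sample (n-1) standard deviation per class and ratio kind.
#'
#' @param agd_table Output of [compute_agd_table()], or any data frame with
#'   a `thickness` column and one or more `ratio_*` columns.
#' @param ratios Character vector of ratio column names to summarize.
#' @return Data frame with columns `ratio`, `class`, `n`, `min`, `max`,
#'   `mean`, `sd`; all four classes are always present (empty ones with
#'   `n = 0` and `NA` statistics).
#' @export
summarize_ratios <- function(agd_table,
                             ratios = c("ratio_dance_volpara",
                                        "ratio_wu_volpara",
                                        "ratio_dance_wu")) {
  stopifnot(is.data.frame(agd_table), nrow(agd_table) > 0,
            "thickness" %in% names(agd_table))
  ratios <- intersect(ratios, names(agd_table))
  if (length(ratios) == 0) {
    stop("no ratio columns found in agd_table", call. = FALSE)
  }
  cls <- .assign_thickness_class(agd_table$thickness)
  out <- NULL
  for (rt in ratios) {
    for (cl in levels(cls)) {
      v <- agd_table[[rt]][cls == cl]
      out <- rbind(out, data.frame(
        ratio = rt, class = cl, n = length(v),
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else
          if (length(v) == 1) 0 else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Density-category distribution
#'
#' Counts glandularities into the four quartile bins used as a proxy for the
#' four-level radiologist density classification (category 1 = 0-25%
#' glandularity, and so on). Boundary values fall into the lower bin; 0
#' belongs to category 1.
#'
#' @param glandularity Numeric vector of glandularities in \[0, 100\].
#' @param breaks Bin boundaries partitioning \[0, 100\] (default quartiles).
#' @return Data frame with `category`, `lower`, `upper`, `count`.
#' @export
density_categories <- function(glandularity, breaks = c(0, 25, 50, 75, 100)) {
  if (any(!is.finite(glandularity) | glandularity < 0 |
          glandularity > 100)) {
    stop("glandularity values must lie in [0, 100]", call. = FALSE)
  }
  if (breaks[1] != 0 || breaks[length(breaks)] != 100 ||
      any(diff(breaks) <= 0)) {
    stop("breaks must partition [0, 100]", call. = FALSE)
  }
  b <- cut(glandularity, breaks = breaks, include.lowest = TRUE,
           right = TRUE, labels = FALSE)
  data.frame(category = seq_len(length(breaks) - 1),
             lower = breaks[-length(breaks)], upper = breaks[-1],
             count = tabulate(b, nbins = length(breaks) - 1))
}

#' Ordinary-least-squares glandularity regression on age and thickness
#'
#' Fits `glandularity = c + a * age + b * thickness` by OLS and reports the
#' coefficients with standard errors, the coefficient of determination and
#' the overall-F ANOVA p-value.
#'
#' @param records Data frame with columns `volpara_gpw` (or `glandularity`),
#'   `age` and `thickness`.
#' @return A `glandularity_fit` list: `coefficients` (named: intercept,
#'   age, thickness), `se`, `r_squared`, `p_value`, `n`, `residual_sd`.
#' @export
fit_glandularity_regression <- function(records) {
  df <- as.data.frame(records)
  y <- if (!is.null(df$volpara_gpw)) df$volpara_gpw else df$glandularity
  if (is.null(y)) {
    stop("records need a volpara_gpw (or glandularity) column", call. = FALSE)
  }
  keep <- stats::complete.cases(y, df$age, df$thickness)
  y <- y[keep]; age <- df$age[keep]; thickness <- df$thickness[keep]
  if (length(y) < 3) {
    stop("need at least 3 complete records", call. = FALSE)
  }
  X <- cbind(1, age, thickness)
  if (qr(X)$rank < 3) {
    stop("singular design: age and thickness are collinear or constant",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ age + thickness)
  sm <- summary(fit)
  co <- stats::coef(fit)
  names(co) <- c("intercept", "age", "thickness")
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- names(co)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r2 <- 0
    p <- 1
  } else {
    r2 <- sm$r.squared
    f <- sm$fstatistic
    p <- stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  }
  structure(list(coefficients = co, se = se, r_squared = unname(r2),
                 p_value = unname(p), n = length(y),
                 residual_sd = sm$sigma),
            class = "glandularity_fit")
}

#' @export
print.glandularity_fit <- function(x, ...) {
  cat(sprintf(
    "glandularity = %.3f %+.4f * age %+.4f * thickness   (n = %d)\n",
    x$coefficients[1], x$coefficients[2], x$coefficients[3], x$n))
  cat(sprintf("  SE: %.3f / %.4f / %.4f   R^2 = %.3f, ANOVA p = %.3g\n",
              x$se[1], x$se[2], x$se[3], x$r_squared, x$p_value))
  invisible(x)
}

#' Pearson correlation of an AGD ratio with a covariate
#'
#' @param agd_table Output of [compute_agd_table()].
#' @param ratio Ratio column name, e.g. `"ratio_dance_volpara"`.
#' @param covariate One of `"thickness"`, `"age"`, `"glandularity"`
#'   (personalized, `volpara_gpw`) or `"dance_gland"`.
#' @return List with `r` (Pearson coefficient), `p_value` (two-sided),
#'   `n`, `ratio`, `covariate`.
#' @export
ratio_covariate_correlation <- function(agd_table,
                                        ratio = "ratio_dance_volpara",
                                        covariate = c("thickness", "age",
                                                      "glandularity",
                                                      "dance_gland")) {
  covariate <- match.arg(covariate)
  col <- switch(covariate, glandularity = "volpara_gpw", covariate)
  x <- agd_table[[col]]
  y <- agd_table[[ratio]]
  if (is.null(x) || is.null(y)) {
    stop("agd_table lacks column '", if (is.null(x)) col else ratio, "'",
         call. = FALSE)
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in ",
         if (stats::sd(x) == 0) covariate else ratio, call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       ratio = ratio, covariate = covariate)
}

#' Scatter plot of an AGD ratio against a covariate
#'
#' @inheritParams ratio_covariate_correlation
#' @param file Optional PNG output path; when `NULL`, plots to the active
#'   device.
#' @return The correlation list from [ratio_covariate_correlation()],
#'   invisibly.
#' @export
plot_ratio_scatter <- function(agd_table, ratio = "ratio_dance_volpara",
                               covariate = "thickness", file = NULL) {
  ct <- ratio_covariate_correlation(agd_table, ratio, covariate)
  col <- switch(covariate, glandularity = "volpara_gpw", covariate)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 120)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(agd_table[[col]], agd_table[[ratio]], pch = 16,
                 cex = 0.4, col = "#00000055",
                 xlab = covariate, ylab = ratio,
                 main = sprintf("%s vs %s (Pearson r = %.3f)", ratio,
                                covariate, ct$r))
  graphics::abline(h = 1, lty = 2)
  invisible(ct)
}
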