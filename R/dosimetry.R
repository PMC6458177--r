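#' Exposure records
#'
#' Validates a data frame of per-exposure records and normalizes it to the
#' canonical column set. One row is one exposure. Required columns:
#' `age` (years), `thickness` (mm), `hvl` (mm Al), `anode`, `filter`,
#' `iak` (incident air kerma without backscatter, mGy). Optional columns
#' (filled with `NA` when absent): `exam_id`, `view`, `entrance_exposure`,
#' `vendor_agd` (mGy, the equipment-reported Wu-method AGD),
#' `volpara_gpw` (% by weight), `volpara_vbd` (% by volume).
#'
#' @param df A data frame of exposures.
#' @return The validated data frame with class `exam_records`.
#' @export
exam_records <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("age", "thickness", "hvl", "anode", "filter", "iak")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop("exam records are missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  optional <- c("exam_id", "view", "entrance_exposure", "vendor_agd",
                "volpara_gpw", "volpara_vbd")
  for (col in optional) if (is.null(df[[col]])) df[[col]] <- NA
  if (all(is.na(df$exam_id))) df$exam_id <- sprintf("EX%05d", seq_len(nrow(df)))
  with_val <- function(x) x[!is.na(x)]
  if (any(with_val(df$thickness) <= 0)) {
    stop("exam records: thickness must be > 0 mm", call. = FALSE)
  }
  if (any(with_val(df$hvl) <= 0)) {
    stop("exam records: hvl must be > 0 mm Al", call. = FALSE)
  }
  if (any(with_val(df$iak) < 0)) {
    stop("exam records: iak must be >= 0 mGy", call. = FALSE)
  }
  for (col in c("volpara_gpw", "volpara_vbd")) {
    v <- with_val(df[[col]])
    if (any(v < 0 | v > 100)) {
      stop("exam records: ", col, " must lie in [0, 100]", call. = FALSE)
    }
  }
  class(df) <- unique(c("exam_records", class(df)))
  df
}

#' Dosimetry pipeline configuration
#'
#' @param glandularity_source Glandularity feeding the Dance-formalism AGD:
#'   `"dance_model"` (population value from age and thickness) or
#'   `"volpara"` (the record's personalized `volpara_gpw`).
#' @param wu_mode `"passthrough"` returns the equipment-reported `vendor_agd`
#'   unchanged (what the study analysed); `"compute"` evaluates
#'   entrance exposure x DgN with the densest-region glandularity.
#' @param densest_region_mode,cap See [densest_region_glandularity()].
#' @param on_error `"fail"` aborts on the first record that cannot be
#'   computed; `"skip"` drops such records and reports them.
#' @return A list of class `agd_config`.
#' @export
agd_config <- function(glandularity_source = c("dance_model", "volpara"),
                       wu_mode = c("passthrough", "compute"),
                       densest_region_mode = c("double_capped", "identity"),
                       cap = 100,
                       on_error = c("fail", "skip")) {
  structure(list(glandularity_source = match.arg(glandularity_source),
                 wu_mode = match.arg(wu_mode),
                 densest_region_mode = match.arg(densest_region_mode),
                 cap = cap,
                 on_error = match.arg(on_error)),
            class = "agd_config")
}

#' Densest-region glandularity heuristic
#'
#' The automatic exposure control of the modelled equipment estimates breast
#' density in the densest part of the image rather than over the whole
#' breast. That peak value approaches the whole-breast glandularity for very
#' dense and very fatty breasts but is roughly twice the whole-breast value
#' otherwise; `"double_capped"` implements that approximation as
#' `min(2 * gpw, cap)`.
#'
#' @param whole_breast_gpw Whole-breast glandularity, % by weight, in
#'   \[0, 100\] (vectorized).
#' @param mode `"double_capped"` or `"identity"`.
#' @param cap Upper cap in percent, in (0, 100\].
#' @return Densest-region glandularity in percent by weight.
#' @export
densest_region_glandularity <- function(whole_breast_gpw,
                                        mode = c("double_capped", "identity"),
                                        cap = 100) {
  mode <- match.arg(mode)
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0 || cap > 100) {
    stop("cap must lie in (0, 100]", call. = FALSE)
  }
  .check_range(whole_breast_gpw, 0, 100, "glandularity", "% by weight")
  if (mode == "identity") return(whole_breast_gpw)
  pmin(2 * whole_breast_gpw, cap)
}

.record_glandularity <- function(records, tables, source, policy = NULL) {
  if (source == "volpara") {
    if (any(is.na(records$volpara_gpw))) {
      stop("missing volpara_gpw for record(s) ",
           paste(utils::head(records$exam_id[is.na(records$volpara_gpw)], 5),
                 collapse = ", "),
           ": required when glandularity_source = 'volpara'", call. = FALSE)
    }
    records$volpara_gpw
  } else {
    dance_glandularity(tables, records$age, records$thickness, policy)
  }
}

#' Dance-formalism average glandular dose
#'
#' `AGD = IAK * g(thickness, HVL) * c(glandularity, thickness, HVL) *
#' s(anode, filter)`, with the glandularity drawn either from the population
#' age/thickness model or from the record's personalized measurement. The two
#' choices are otherwise identical: the formalism differs only through the
#' glandularity estimate.
#'
#' @param records An [exam_records] data frame (or coercible).
#' @param tables A [factor_tables] object.
#' @param glandularity_source `"dance_model"` or `"volpara"`.
#' @param policy Optional [age_group_policy].
#' @return Numeric vector of AGD in mGy.
#' @export
dance_agd <- function(records, tables,
                      glandularity_source = c("dance_model", "volpara"),
                      policy = NULL) {
  glandularity_source <- match.arg(glandularity_source)
  records <- exam_records(as.data.frame(records))
  need <- c("iak", "thickness", "hvl")
  for (col in need) {
    if (any(is.na(records[[col]]))) {
      stop("missing ", col, " for record(s) ",
           paste(utils::head(records$exam_id[is.na(records[[col]])], 5),
                 collapse = ", "), call. = FALSE)
    }
  }
  gl <- .record_glandularity(records, tables, glandularity_source, policy)
  records$iak *
    g_factor(tables, records$thickness, records$hvl) *
    c_factor(tables, gl, records$thickness, records$hvl) *
    s_factor(tables, records$anode, records$filter)
}

#' Dance-formalism AGD with personalized glandularity
#'
#' Convenience wrapper for [dance_agd()] with
#' `glandularity_source = "volpara"`.
#'
#' @inheritParams dance_agd
#' @return Numeric vector of AGD in mGy.
#' @export
volpara_agd <- function(records, tables) {
  dance_agd(records, tables, glandularity_source = "volpara")
}

.dgn_lookup <- function(tables, glandularity, thickness, hvl, anode, filter) {
  dgn <- tables$dgn
  if (is.null(dgn)) {
    # Dance-equivalent fallback: DgN per unit incident air kerma.
    return(g_factor(tables, thickness, hvl) *
             c_factor(tables, glandularity, thickness, hvl) *
             s_factor(tables, anode, filter))
  }
  if (is.numeric(dgn) && length(dgn) == 1) {
    return(rep(dgn, length(glandularity)))
  }
  if (is.function(dgn)) {
    return(dgn(glandularity, thickness, hvl, anode, filter))
  }
  # data-frame grid: sequential linear interpolation per anode/filter subset
  out <- rep(NA_real_, length(glandularity))
  key <- paste(tolower(anode), tolower(filter))
  for (k in unique(key)) {
    sub <- dgn[paste(tolower(dgn$anode), tolower(dgn$filter)) == k, ,
               drop = FALSE]
    if (nrow(sub) == 0) {
      stop("DgN table has no rows for anode/filter ", k, call. = FALSE)
    }
    sel <- which(key == k)
    out[sel] <- vapply(sel, function(i) {
      .interp_grid3(sub, glandularity[i], thickness[i], hvl[i])
    }, numeric(1))
  }
  out
}

# trilinear-by-axis interpolation on a long-form (gland, thickness, hvl) grid
.interp_grid3 <- function(sub, g, t, h) {
  collapse <- function(df, col, x) {
    ax <- sort(unique(df[[col]]))
    if (length(ax) == 1) return(df)
    b <- .bilinear_weights(min(max(x, ax[1]), ax[length(ax)]), ax)
    lo <- df[df[[col]] == ax[b$i], , drop = FALSE]
    hi <- df[df[[col]] == ax[b$i + 1], , drop = FALSE]
    lo$value <- (1 - b$w) * lo$value +
      b$w * hi$value[match(do.call(paste, lo[setdiff(c("glandularity_pct",
                                                       "thickness_mm",
                                                       "hvl_mm_al"),
                                                     col)]),
                           do.call(paste, hi[setdiff(c("glandularity_pct",
                                                       "thickness_mm",
                                                       "hvl_mm_al"),
                                                    col)]))]
    lo
  }
  sub <- collapse(sub, "glandularity_pct", g)
  sub <- collapse(sub, "thickness_mm", t)
  sub <- collapse(sub, "hvl_mm_al", h)
  sub$value[1]
}

#' Wu-formalism (equipment-style) average glandular dose
#'
#' In `"passthrough"` mode (the default, matching how clinical analyses read
#' the value) the equipment-reported `vendor_agd` is returned unchanged. In
#' `"compute"` mode the dose is `entrance_exposure * DgN`, where DgN is read
#' from the pluggable table attached to `tables` (or, absent one, from the
#' approximate Dance-equivalent fallback) at the densest-region glandularity
#' derived from the record's whole-breast value.
#'
#' @inheritParams dance_agd
#' @param mode `"passthrough"` or `"compute"`.
#' @param densest_region_mode,cap Passed to [densest_region_glandularity()]
#'   in compute mode.
#' @return Numeric vector of AGD in mGy.
#' @export
wu_agd <- function(records, tables, mode = c("passthrough", "compute"),
                   densest_region_mode = c("double_capped", "identity"),
                   cap = 100) {
  mode <- match.arg(mode)
  records <- exam_records(as.data.frame(records))
  if (mode == "passthrough") {
    if (any(is.na(records$vendor_agd))) {
      stop("missing vendor_agd for record(s) ",
           paste(utils::head(records$exam_id[is.na(records$vendor_agd)], 5),
                 collapse = ", "),
           ": required in passthrough mode", call. = FALSE)
    }
    return(records$vendor_agd)
  }
  x <- records$entrance_exposure
  if (any(is.na(x))) {
    stop("missing entrance_exposure for record(s) ",
         paste(utils::head(records$exam_id[is.na(x)], 5), collapse = ", "),
         ": required in compute mode", call. = FALSE)
  }
  if (any(is.na(records$volpara_gpw))) {
    stop("missing volpara_gpw for record(s) ",
         paste(utils::head(records$exam_id[is.na(records$volpara_gpw)], 5),
               collapse = ", "),
         ": required to form the densest-region glandularity", call. = FALSE)
  }
  dens <- densest_region_glandularity(records$volpara_gpw,
                                      mode = densest_region_mode, cap = cap)
  x * .dgn_lookup(tables, dens, records$thickness, records$hvl,
                  records$anode, records$filter)
}

#' All three AGD estimates and their pairwise ratios, per record
#'
#' Computes the Dance (population glandularity), Wu (equipment) and
#' personalized (Dance formalism with measured glandularity) AGD for every
#' record, plus the three pairwise ratios. The ratio triple satisfies the
#' closure identity `(dance/wu) * (wu/volpara) = (dance/volpara)`.
#'
#' @inheritParams dance_agd
#' @param config An [agd_config].
#' @return A data frame with one row per computed record: `exam_id`, `age`,
#'   `thickness`, `hvl`, the glandularities used, `dance_agd`, `wu_agd`,
#'   `volpara_agd` (mGy) and `ratio_dance_volpara`, `ratio_wu_volpara`,
#'   `ratio_dance_wu`. Records skipped under `on_error = "skip"` are
#'   reported in the `"skipped"` attribute (exam id and reason).
#' @export
compute_agd_table <- function(records, tables, config = agd_config()) {
  stopifnot(inherits(config, "agd_config"))
  records <- exam_records(as.data.frame(records))
  run <- function(df) {
    data.frame(
      exam_id = df$exam_id,
      age = df$age,
      thickness = df$thickness,
      hvl = df$hvl,
      dance_gland = dance_glandularity(tables, df$age, df$thickness),
      volpara_gpw = df$volpara_gpw,
      dance_agd = dance_agd(df, tables, glandularity_source = "dance_model"),
      wu_agd = wu_agd(df, tables, mode = config$wu_mode,
                      densest_region_mode = config$densest_region_mode,
                      cap = config$cap),
      volpara_agd = volpara_agd(df, tables),
      stringsAsFactors = FALSE)
  }
  skipped <- data.frame(exam_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (config$on_error == "fail") {
    out <- run(records)
  } else {
    ok <- logical(nrow(records))
    reasons <- character(nrow(records))
    rows <- vector("list", nrow(records))
    for (i in seq_len(nrow(records))) {
      res <- tryCatch(run(records[i, , drop = FALSE]), error = identity)
      if (inherits(res, "error")) {
        reasons[i] <- conditionMessage(res)
      } else {
        ok[i] <- TRUE
        rows[[i]] <- res
      }
    }
    out <- do.call(rbind, rows[ok])
    if (any(!ok)) {
      skipped <- data.frame(exam_id = records$exam_id[!ok],
                            reason = reasons[!ok], stringsAsFactors = FALSE)
      message(sum(!ok), " record(s) skipped; see attr(, 'skipped')")
    }
    if (is.null(out)) {
      stop("no computable records", call. = FALSE)
    }
  }
  out$ratio_dance_volpara <- out$dance_agd / out$volpara_agd
  out$ratio_wu_volpara <- out$wu_agd / out$volpara_agd
  out$ratio_dance_wu <- out$dance_agd / out$wu_agd
  attr(out, "skipped") <- skipped
  out
}

#' Single-record AGD triple
#'
#' @inheritParams compute_agd_table
#' @param record A one-row data frame (or list coercible to one).
#' @return A list of class `agd_triple` with the three AGDs (mGy) and the
#'   three pairwise ratios.
#' @export
compute_agd_triple <- function(record, tables, config = agd_config()) {
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 1)
  tab <- compute_agd_table(df, tables, config)
  structure(list(dance_agd = tab$dance_agd, wu_agd = tab$wu_agd,
                 volpara_agd = tab$volpara_agd,
                 ratio_dance_volpara = tab$ratio_dance_volpara,
                 ratio_wu_volpara = tab$ratio_wu_volpara,
                 ratio_dance_wu = tab$ratio_dance_wu),
            class = "agd_triple")
}

#' @export
print.agd_triple <- function(x, ...) {
  cat(sprintf("AGD [mGy]  dance: %.4f  wu: %.4f  personalized: %.4f\n",
              x$dance_agd, x$wu_agd, x$volpara_agd))
  cat(sprintf("ratios  dance/volpara: %.3f  wu/volpara: %.3f  dance/wu: %.3f\n",
              x$ratio_dance_volpara, x$ratio_wu_volpara, x$ratio_dance_wu))
  invisible(x)
}
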