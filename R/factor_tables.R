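#' Conversion-factor tables for breast dosimetry
#'
#' A `factor_tables` object bundles everything the Dance formalism needs to
#' turn an incident air kerma into an average glandular dose (AGD):
#'
#' * `g`: the 50%-glandularity conversion factor, gridded over compressed
#'   breast thickness (mm) and half-value layer (mm Al);
#' * `c`: the glandularity correction, stored as piecewise-linear
#'   glandularity curves attached to (thickness, HVL) "stations";
#' * `s`: the spectral correction keyed by anode/filter combination
#'   (`s(Mo, Mo) = 1` by definition);
#' * `glandularity`: the population glandularity (% by weight) by age group
#'   and thickness;
#' * `reference`: the thickness-class reference points (class-representative
#'   thickness, HVL, Dance and personalized glandularities with their
#'   c-values) used for worked-example dose-ratio checks.
#'
#' The shipped default (`"paper-default"`) reproduces every published grid
#' value exactly at its node; see the package vignette for the provenance of
#' each block and for the interpolation scheme between nodes.
#'
#' @name factor_tables
NULL

.c_anchor_tol <- 1e-6
.station_match_tol <- 1e-6

#' Load conversion-factor tables
#'
#' Reads a long-form CSV of factor-table nodes and assembles a validated
#' [factor_tables] object. The CSV must carry the columns `table`
#' (`"g"`, `"c"`, `"s"`, `"glandularity"`, optionally `"dgn"` and
#' `"reference_sd"`), `age_group`, `anode`, `filter`, `glandularity_pct`,
#' `thickness_mm`, `hvl_mm_al`, `value` and `role` (`"grid"` for nodes of the
#' rectangular base grid, `"station"` for additional off-grid c-factor
#' stations).
#'
#' @param path Path to a factor CSV, or the built-in name `"paper-default"`
#'   (equivalently `"default"`) for the packaged table set.
#' @param dgn Optional normalized-glandular-dose table for the
#'   entrance-exposure (Wu) pathway: either a function
#'   `f(glandularity, thickness, hvl, anode, filter)` returning DgN per unit
#'   exposure, a single scalar, or a data frame with columns
#'   `glandularity_pct`, `thickness_mm`, `hvl_mm_al`, `anode`, `filter`,
#'   `value`. When `NULL` (default) the Wu compute pathway falls back to a
#'   Dance-equivalent DgN (`g * c * s` per unit incident air kerma), which is
#'   approximate and documented as such.
#' @return A `factor_tables` object.
#' @examples
#' ft <- load_factor_tables()
#' g_factor(ft, thickness = 40, hvl = 0.5)
#' @export
load_factor_tables <- function(path = "paper-default", dgn = NULL) {
  if (path %in% c("paper-default", "default")) {
    path <- system.file("extdata", "dance_default_factors.csv",
                        package = "mammodose", mustWork = TRUE)
    builtin <- TRUE
  } else {
    builtin <- FALSE
    if (!file.exists(path)) {
      stop("factor table file not found: ", path, call. = FALSE)
    }
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("table", "age_group", "anode", "filter", "glandularity_pct",
                "thickness_mm", "hvl_mm_al", "value", "role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("factor table load error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  build_factor_tables(df, source = if (builtin) "paper-default" else path,
                      dgn = dgn)
}

#' Assemble a factor_tables object from long-form node rows
#'
#' @param df Data frame with the columns documented in [load_factor_tables()].
#' @param source Character label recorded on the object.
#' @param dgn Optional DgN table, see [load_factor_tables()].
#' @return A `factor_tables` object.
#' @export
build_factor_tables <- function(df, source = "user", dgn = NULL) {
  num_tables <- c("g", "c", "s", "glandularity", "dgn")
  vals <- df$value[df$table %in% num_tables]
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("factor table validation error: all g, c, s, DgN and glandularity ",
         "values must be finite and strictly positive", call. = FALSE)
  }
  gpct <- df$glandularity_pct[df$table == "c"]
  if (any(gpct < 0 | gpct > 100, na.rm = TRUE)) {
    stop("factor table validation error: glandularity_pct must lie in [0, 100]",
         call. = FALSE)
  }

  g <- .build_g_grid(df[df$table == "g", , drop = FALSE])
  cc <- .build_c_model(df[df$table == "c", , drop = FALSE])
  s <- .build_s_table(df[df$table == "s", , drop = FALSE])
  gland <- .build_glandularity(df[df$table == "glandularity", , drop = FALSE])
  ref <- .build_reference(df)

  if (!is.null(dgn)) dgn <- .validate_dgn(dgn)
  structure(list(g = g, c = cc, s = s, glandularity = gland,
                 reference = ref, dgn = dgn, source = source),
            class = "factor_tables")
}

.build_g_grid <- function(gdf) {
  if (nrow(gdf) == 0) {
    stop("factor table load error: no rows for table 'g'", call. = FALSE)
  }
  for (ax in c("thickness_mm", "hvl_mm_al")) {
    if (any(is.na(gdf[[ax]]))) {
      stop("factor table load error: table 'g' is missing required axis '",
           ax, "'", call. = FALSE)
    }
  }
  tg <- sort(unique(gdf$thickness_mm))
  hg <- sort(unique(gdf$hvl_mm_al))
  m <- matrix(NA_real_, length(tg), length(hg))
  i <- match(gdf$thickness_mm, tg)
  j <- match(gdf$hvl_mm_al, hg)
  m[cbind(i, j)] <- gdf$value
  if (any(is.na(m))) {
    stop("factor table load error: g grid is not a complete ",
         "thickness x HVL rectangle", call. = FALSE)
  }
  if (min(tg) > 20 || max(tg) < 110 || min(hg) > 0.3 || max(hg) < 0.8) {
    stop("factor table validation error: g grid must cover at least ",
         "thickness 20-110 mm and HVL 0.3-0.8 mm Al", call. = FALSE)
  }
  list(thickness = tg, hvl = hg, values = m)
}

# One c "station" = a strictly decreasing piecewise-linear glandularity curve
# at a fixed (thickness, HVL). Printed nodes are kept exactly; the curve is
# anchored at the definitional c(50%) = 1 when no node sits at 50%, and
# extended to glandularity 0 and 100 with its end-segment slopes so queries
# never fall outside the node span.
.build_station_curve <- function(gland, value) {
  o <- order(gland)
  g <- gland[o]; v <- value[o]
  keep <- !duplicated(g)
  g <- g[keep]; v <- v[keep]
  if (!any(abs(g - 50) < .c_anchor_tol)) {
    g <- c(g, 50); v <- c(v, 1.0)
    o <- order(g); g <- g[o]; v <- v[o]
  }
  if (length(g) < 2) return(list(gland = g, value = v, partial = TRUE))
  if (min(g) > 0) {
    sl <- (v[2] - v[1]) / (g[2] - g[1])
    g <- c(0, g); v <- c(v[1] - sl * g[2], v)
  }
  n <- length(g)
  if (max(g) < 100) {
    sl <- (v[n] - v[n - 1]) / (g[n] - g[n - 1])
    g <- c(g, 100); v <- c(v, v[n] + sl * (100 - g[n]))
  }
  v <- pmax(v, 1e-6)
  if (any(diff(v) >= 0)) {
    stop("factor table validation error: c-factor station at the node set (",
         paste(signif(g, 4), collapse = ", "),
         ") is not strictly decreasing in glandularity", call. = FALSE)
  }
  list(gland = g, value = v, partial = FALSE)
}

.build_c_model <- function(cdf) {
  if (nrow(cdf) == 0) {
    stop("factor table load error: no rows for table 'c'", call. = FALSE)
  }
  for (ax in c("glandularity_pct", "thickness_mm", "hvl_mm_al")) {
    if (any(is.na(cdf[[ax]]))) {
      stop("factor table load error: table 'c' is missing required axis '",
           ax, "'", call. = FALSE)
    }
  }
  if (is.null(cdf$role)) cdf$role <- "grid"
  grid_df <- cdf[cdf$role != "station", , drop = FALSE]
  aux_df <- cdf[cdf$role == "station", , drop = FALSE]

  tg <- sort(unique(grid_df$thickness_mm))
  hg <- sort(unique(grid_df$hvl_mm_al))
  curves <- vector("list", length(tg) * length(hg))
  dim(curves) <- c(length(tg), length(hg))
  for (i in seq_along(tg)) {
    for (j in seq_along(hg)) {
      sel <- grid_df$thickness_mm == tg[i] & grid_df$hvl_mm_al == hg[j]
      if (!any(sel)) {
        stop("factor table load error: c grid has no node at thickness ",
             tg[i], " mm, HVL ", hg[j], " mm Al", call. = FALSE)
      }
      curves[[i, j]] <- .build_station_curve(grid_df$glandularity_pct[sel],
                                             grid_df$value[sel])
    }
  }
  # single-node stations (a printed node exactly at 50% glandularity) borrow
  # their glandularity slope from the neighbouring thickness stations
  for (j in seq_along(hg)) {
    for (i in seq_along(tg)) {
      cv <- curves[[i, j]]
      if (!isTRUE(cv$partial)) next
      nb <- c(if (i > 1) i - 1L, if (i < length(tg)) i + 1L)
      slopes <- vapply(nb, function(k) {
        ck <- curves[[k, j]]
        (ck$value[length(ck$value)] - ck$value[1]) /
          (ck$gland[length(ck$gland)] - ck$gland[1])
      }, numeric(1))
      sl <- mean(slopes)
      g0 <- cv$gland[1]; v0 <- cv$value[1]
      g <- c(0, g0, 100)
      v <- pmax(c(v0 - sl * g0, v0, v0 + sl * (100 - g0)), 1e-6)
      curves[[i, j]] <- list(gland = g, value = v, partial = FALSE)
    }
  }
  aux <- list()
  if (nrow(aux_df) > 0) {
    key <- paste(signif(aux_df$thickness_mm, 12), signif(aux_df$hvl_mm_al, 12))
    for (k in unique(key)) {
      sel <- key == k
      aux[[length(aux) + 1]] <- c(
        list(thickness = aux_df$thickness_mm[sel][1],
             hvl = aux_df$hvl_mm_al[sel][1]),
        .build_station_curve(aux_df$glandularity_pct[sel], aux_df$value[sel]))
    }
  }
  list(thickness = tg, hvl = hg, curves = curves, aux = aux)
}

.build_s_table <- function(sdf) {
  if (nrow(sdf) == 0) {
    stop("factor table load error: no rows for table 's'", call. = FALSE)
  }
  s <- data.frame(anode = trimws(sdf$anode), filter = trimws(sdf$filter),
                  value = sdf$value, stringsAsFactors = FALSE)
  momo <- tolower(s$anode) == "mo" & tolower(s$filter) == "mo"
  if (!any(momo) || any(s$value[momo] != 1)) {
    stop("factor table validation error: s(Mo, Mo) must be present and ",
         "exactly 1", call. = FALSE)
  }
  s
}

.build_glandularity <- function(gdf) {
  if (nrow(gdf) == 0) {
    stop("factor table load error: no rows for table 'glandularity'",
         call. = FALSE)
  }
  if (any(is.na(gdf$thickness_mm))) {
    stop("factor table load error: table 'glandularity' is missing required ",
         "axis 'thickness_mm'", call. = FALSE)
  }
  if (any(gdf$value < 0 | gdf$value > 100)) {
    stop("factor table validation error: glandularity values must lie in ",
         "[0, 100]", call. = FALSE)
  }
  out <- list()
  for (grp in unique(gdf$age_group)) {
    sel <- gdf$age_group == grp
    o <- order(gdf$thickness_mm[sel])
    out[[grp]] <- list(thickness = gdf$thickness_mm[sel][o],
                       value = gdf$value[sel][o])
  }
  out
}

.build_reference <- function(df) {
  cdf <- df[df$table == "c" & df$role == "station", , drop = FALSE]
  if (nrow(cdf) == 0) return(NULL)
  sddf <- df[df$table == "reference_sd", , drop = FALSE]
  lab <- sub("_(dance|volpara)$", "", cdf$source)
  kind <- sub("^.*_", "", cdf$source)
  out <- NULL
  for (grp in unique(cdf$age_group)) {
    for (cl in unique(lab[cdf$age_group == grp])) {
      sel_d <- cdf$age_group == grp & lab == cl & kind == "dance"
      sel_v <- cdf$age_group == grp & lab == cl & kind == "volpara"
      if (!any(sel_d) || !any(sel_v)) next
      sdv <- sddf$value[sddf$age_group == grp &
                          sub("^class_", "", cl) ==
                          sub("^class_", "", sddf$source)]
      out <- rbind(out, data.frame(
        age_group = grp,
        class = sub("^class_", "", cl),
        thickness_mm = cdf$thickness_mm[sel_d][1],
        hvl_mm_al = cdf$hvl_mm_al[sel_d][1],
        gland_dance = cdf$glandularity_pct[sel_d][1],
        gland_volpara = cdf$glandularity_pct[sel_v][1],
        sd_volpara = if (length(sdv) > 0) sdv[1] else NA_real_,
        c_dance = cdf$value[sel_d][1],
        c_volpara = cdf$value[sel_v][1],
        stringsAsFactors = FALSE))
    }
  }
  ord <- order(out$age_group, out$thickness_mm)
  out[ord, , drop = FALSE]
}

.validate_dgn <- function(dgn) {
  if (is.function(dgn) || (is.numeric(dgn) && length(dgn) == 1)) return(dgn)
  if (is.data.frame(dgn)) {
    need <- c("glandularity_pct", "thickness_mm", "hvl_mm_al", "anode",
              "filter", "value")
    miss <- setdiff(need, names(dgn))
    if (length(miss) > 0) {
      stop("DgN table is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (any(dgn$value <= 0)) {
      stop("factor table validation error: DgN values must be strictly ",
           "positive", call. = FALSE)
    }
    return(dgn)
  }
  stop("dgn must be a function, a scalar, or a data frame", call. = FALSE)
}

.check_range <- function(x, lo, hi, axis, unit) {
  bad <- !is.finite(x) | x < lo | x > hi
  if (any(bad)) {
    stop(sprintf("%s out of supported range: value(s) %s outside [%g, %g] %s",
                 axis, paste(signif(utils::head(x[bad], 3), 5), collapse = ", "),
                 lo, hi, unit), call. = FALSE)
  }
  invisible(TRUE)
}

# bilinear interpolation helper on a rectangular grid with exact node return
.bilinear_weights <- function(x, grid) {
  i <- findInterval(x, grid, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(grid) - 1L)
  w <- (x - grid[i]) / (grid[i + 1L] - grid[i])
  list(i = i, w = w)
}

#' g-factor: kerma-to-dose conversion for a 50% glandular breast
#'
#' Bilinear interpolation of the tabulated g grid in compressed breast
#' thickness and half-value layer. Exact at grid nodes; queries outside the
#' tabulated validity range (thickness 20-110 mm, HVL 0.3-0.8 mm Al for the
#' default tables) are an error, not an extrapolation.
#'
#' @param tables A [factor_tables] object.
#' @param thickness Compressed breast thickness in mm (vectorized).
#' @param hvl Half-value layer in mm Al (vectorized).
#' @return Numeric vector of dimensionless g values.
#' @export
g_factor <- function(tables, thickness, hvl) {
  stopifnot(inherits(tables, "factor_tables"))
  n <- max(length(thickness), length(hvl))
  thickness <- rep_len(thickness, n); hvl <- rep_len(hvl, n)
  g <- tables$g
  .check_range(thickness, min(g$thickness), max(g$thickness),
               "thickness", "mm")
  .check_range(hvl, min(g$hvl), max(g$hvl), "HVL", "mm Al")
  bt <- .bilinear_weights(thickness, g$thickness)
  bh <- .bilinear_weights(hvl, g$hvl)
  v00 <- g$values[cbind(bt$i, bh$i)]
  v10 <- g$values[cbind(bt$i + 1L, bh$i)]
  v01 <- g$values[cbind(bt$i, bh$i + 1L)]
  v11 <- g$values[cbind(bt$i + 1L, bh$i + 1L)]
  (1 - bt$w) * (1 - bh$w) * v00 + bt$w * (1 - bh$w) * v10 +
    (1 - bt$w) * bh$w * v01 + bt$w * bh$w * v11
}

.eval_curve <- function(curve, gland) {
  stats::approx(curve$gland, curve$value, xout = gland, rule = 2)$y
}

#' c-factor: glandularity correction
#'
#' Corrects the 50%-glandularity dose for the actual breast composition
#' (c > 1 for fattier, c < 1 for denser breasts; c(50%) = 1 by definition).
#' Evaluation is piecewise linear in glandularity along per-(thickness, HVL)
#' station curves and bilinear across the rectangular station grid. Stations
#' placed off the rectangular grid (the thickness-class reference points of
#' the default tables) take precedence when the query matches their
#' (thickness, HVL) exactly, so every tabulated value is reproduced exactly.
#'
#' @inheritParams g_factor
#' @param glandularity Glandularity in percent by weight, in \[0, 100\]
#'   (vectorized).
#' @return Numeric vector of dimensionless c values.
#' @export
c_factor <- function(tables, glandularity, thickness, hvl) {
  stopifnot(inherits(tables, "factor_tables"))
  n <- max(length(glandularity), length(thickness), length(hvl))
  glandularity <- rep_len(glandularity, n)
  thickness <- rep_len(thickness, n); hvl <- rep_len(hvl, n)
  cc <- tables$c
  .check_range(glandularity, 0, 100, "glandularity", "% by weight")
  .check_range(thickness, min(cc$thickness), max(cc$thickness),
               "thickness", "mm")
  .check_range(hvl, min(tables$g$hvl), max(tables$g$hvl), "HVL", "mm Al")

  out <- rep(NA_real_, n)
  done <- rep(FALSE, n)
  for (st in cc$aux) {
    hit <- !done & abs(thickness - st$thickness) < .station_match_tol &
      abs(hvl - st$hvl) < .station_match_tol
    if (any(hit)) {
      out[hit] <- .eval_curve(st, glandularity[hit])
      done[hit] <- TRUE
    }
  }
  if (any(!done)) {
    idx <- which(!done)
    bt <- .bilinear_weights(thickness[idx], cc$thickness)
    bh <- .bilinear_weights(hvl[idx], cc$hvl)
    corner <- function(di, dj) {
      v <- numeric(length(idx))
      key <- paste(bt$i + di, bh$i + dj)
      for (k in unique(key)) {
        sel <- key == k
        ij <- as.integer(strsplit(k, " ")[[1]])
        v[sel] <- .eval_curve(cc$curves[[ij[1], ij[2]]],
                              glandularity[idx][sel])
      }
      v
    }
    v00 <- corner(0L, 0L); v10 <- corner(1L, 0L)
    v01 <- corner(0L, 1L); v11 <- corner(1L, 1L)
    out[idx] <- (1 - bt$w) * (1 - bh$w) * v00 + bt$w * (1 - bh$w) * v10 +
      (1 - bt$w) * bh$w * v01 + bt$w * bh$w * v11
  }
  out
}

#' s-factor: spectral correction by anode/filter combination
#'
#' @inheritParams g_factor
#' @param anode Anode material, e.g. `"Mo"`, `"Rh"`, `"W"` (vectorized).
#' @param filter Filter material (vectorized).
#' @return Numeric vector of dimensionless s values; `s(Mo, Mo) = 1`.
#' @export
s_factor <- function(tables, anode, filter) {
  stopifnot(inherits(tables, "factor_tables"))
  n <- max(length(anode), length(filter))
  anode <- rep_len(as.character(anode), n)
  filter <- rep_len(as.character(filter), n)
  key <- paste(tolower(trimws(anode)), tolower(trimws(filter)))
  tab_key <- paste(tolower(tables$s$anode), tolower(tables$s$filter))
  m <- match(key, tab_key)
  if (anyNA(m)) {
    bad <- unique(paste0(anode[is.na(m)], "/", filter[is.na(m)]))
    stop("unknown anode/filter combination(s): ",
         paste(bad, collapse = ", "), "; supported: ",
         paste(paste0(tables$s$anode, "/", tables$s$filter), collapse = ", "),
         call. = FALSE)
  }
  tables$s$value[m]
}

#' Age-group policy for the population glandularity tables
#'
#' The population glandularity model is tabulated for the two age groups
#' 40-49 and 50-64 years. The default policy substitutes the neighbouring
#' tabulated group outside that range: ages below 40 use the 40-49 values
#' and ages 65 and above use the 50-64 values.
#'
#' @param breaks Data frame with columns `lower`, `upper` (age bounds,
#'   lower-inclusive) and `group` (tabulated group label). The default maps
#'   `[0, 50)` to `"40-49"` and `[50, 130)` to `"50-64"`.
#' @return An `age_group_policy` object.
#' @export
age_group_policy <- function(breaks = NULL) {
  if (is.null(breaks)) {
    breaks <- data.frame(lower = c(0, 50), upper = c(50, 130),
                         group = c("40-49", "50-64"),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("lower", "upper", "group") %in% names(breaks)))
  o <- order(breaks$lower)
  breaks <- breaks[o, , drop = FALSE]
  if (breaks$lower[1] > 0 || breaks$upper[nrow(breaks)] < 130 ||
      any(breaks$lower[-1] != breaks$upper[-nrow(breaks)])) {
    stop("age group policy must partition [0, 130) without gaps",
         call. = FALSE)
  }
  structure(breaks, class = c("age_group_policy", "data.frame"))
}

.assign_age_group <- function(age, policy) {
  if (any(!is.finite(age) | age < 0 | age >= 130)) {
    stop("age out of supported range [0, 130)", call. = FALSE)
  }
  i <- findInterval(age, c(policy$lower, policy$upper[nrow(policy)]),
                    rightmost.closed = FALSE)
  policy$group[pmin(i, nrow(policy))]
}

#' Population (Dance-model) glandularity from age and thickness
#'
#' Looks up the tabulated glandularity (% by weight) for the patient's age
#' group and interpolates linearly in compressed breast thickness. Thickness
#' between the table's outermost nodes and the supported 20-110 mm range is
#' extrapolated with the end-segment slope and clipped to \[0, 100\].
#'
#' @inheritParams g_factor
#' @param age Patient age in years (vectorized).
#' @param policy An [age_group_policy]; `NULL` for the default
#'   neighbour-substitution rule.
#' @return Numeric vector of glandularity in percent by weight.
#' @export
dance_glandularity <- function(tables, age, thickness, policy = NULL) {
  stopifnot(inherits(tables, "factor_tables"))
  if (is.null(policy)) policy <- age_group_policy()
  n <- max(length(age), length(thickness))
  age <- rep_len(age, n); thickness <- rep_len(thickness, n)
  .check_range(thickness, min(tables$g$thickness), max(tables$g$thickness),
               "thickness", "mm")
  grp <- .assign_age_group(age, policy)
  out <- rep(NA_real_, n)
  for (gname in unique(grp)) {
    tab <- tables$glandularity[[gname]]
    if (is.null(tab)) {
      stop("no glandularity table for age group '", gname, "'",
           call. = FALSE)
    }
    sel <- grp == gname
    out[sel] <- .interp_extrap(tab$thickness, tab$value, thickness[sel])
  }
  pmin(pmax(out, 0), 100)
}

.interp_extrap <- function(x, y, xout) {
  v <- stats::approx(x, y, xout = xout, rule = 2)$y
  n <- length(x)
  lo <- xout < x[1]
  if (any(lo) && n >= 2) {
    sl <- (y[2] - y[1]) / (x[2] - x[1])
    v[lo] <- y[1] + sl * (xout[lo] - x[1])
  }
  hi <- xout > x[n]
  if (any(hi) && n >= 2) {
    sl <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    v[hi] <- y[n] + sl * (xout[hi] - x[n])
  }
  v
}

#' Thickness-class reference points
#'
#' Returns the per-age-group, per-thickness-class reference rows shipped with
#' the default tables: class-representative thickness and HVL, the Dance and
#' personalized (image-measured) glandularities, the spread of the latter,
#' and the two tabulated c-values. The percentage dose ratio implied by a
#' pair is `100 * c_dance / c_volpara`.
#'
#' @inheritParams g_factor
#' @return A data frame, or `NULL` when the loaded tables carry no
#'   reference stations.
#' @export
dose_ratio_reference <- function(tables) {
  stopifnot(inherits(tables, "factor_tables"))
  tables$reference
}

#' @export
print.factor_tables <- function(x, ...) {
  cat("<factor_tables>  source:", x$source, "\n")
  cat(sprintf("  g grid: thickness %g-%g mm x HVL %g-%g mm Al (%d nodes)\n",
              min(x$g$thickness), max(x$g$thickness),
              min(x$g$hvl), max(x$g$hvl), length(x$g$values)))
  cat(sprintf("  c model: %d grid stations + %d reference stations\n",
              length(x$c$curves), length(x$c$aux)))
  cat(sprintf("  s table: %s\n",
              paste(paste0(x$s$anode, "/", x$s$filter), collapse = ", ")))
  cat(sprintf("  glandularity age groups: %s\n",
              paste(names(x$glandularity), collapse = ", ")))
  cat(sprintf("  DgN: %s\n",
              if (is.null(x$dgn)) "Dance-equivalent fallback (approximate)"
              else "user-supplied"))
  invisible(x)
}
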