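#' Attenuation model for the two-tissue breast
#'
#' Effective linear attenuation coefficients (per mm) of adipose and
#' glandular tissue at mammographic beam qualities, plus the reference pixel
#' value `p_fat` of a fully adipose tissue column. The defaults (0.057 and
#' 0.082 per mm) are representative effective values around 20 keV.
#'
#' @param mu_fat Effective linear attenuation of adipose tissue, per mm.
#' @param mu_dense Effective linear attenuation of glandular tissue, per mm.
#' @param p_fat Reference pixel value of a fully adipose column: a scalar or
#'   a per-pixel matrix. May be left `NULL` and estimated later with
#'   [estimate_p_fat()].
#' @return An `attenuation_model` object.
#' @export
attenuation_model <- function(mu_fat = 0.057, mu_dense = 0.082,
                              p_fat = NULL) {
  if (!(mu_dense > mu_fat && mu_fat > 0)) {
    stop("attenuation model requires mu_dense > mu_fat > 0", call. = FALSE)
  }
  if (!is.null(p_fat) && any(p_fat <= 0)) {
    stop("p_fat must be strictly positive", call. = FALSE)
  }
  structure(list(mu_fat = mu_fat, mu_dense = mu_dense, p_fat = p_fat),
            class = "attenuation_model")
}

#' Projection image container
#'
#' @param pixels Numeric matrix of pixel values, assumed linearly related to
#'   the energy imparted to the detector.
#' @param pixel_mm Pixel pitch in mm (> 0).
#' @param thickness_mm Recorded compressed breast thickness in mm.
#' @param mask Integer matrix of the same dimension: 0 = background,
#'   1 = breast interior, 2 = breast edge (excluded from density
#'   integration).
#' @return A `projection_image` object.
#' @export
projection_image <- function(pixels, pixel_mm, thickness_mm, mask) {
  stopifnot(is.matrix(pixels), is.matrix(mask),
            all(dim(pixels) == dim(mask)))
  if (pixel_mm <= 0) stop("pixel_mm must be > 0", call. = FALSE)
  if (thickness_mm <= 0) stop("thickness_mm must be > 0", call. = FALSE)
  if (!all(mask %in% c(0L, 1L, 2L))) {
    stop("mask labels must be 0 (background), 1 (interior) or 2 (edge)",
         call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_mm = pixel_mm,
                 thickness_mm = thickness_mm, mask = mask),
            class = "projection_image")
}

#' Per-pixel dense-tissue thickness map
#'
#' Inverts the two-tissue exponential transmission model: a pixel behind
#' `h_d` mm of glandular tissue in a breast of total thickness `t` reads
#' `P = P0 * exp(-mu_fat * (t - h_d) - mu_dense * h_d)`, so with the fully
#' adipose reference `P_fat = P0 * exp(-mu_fat * t)`,
#' `h_d = ln(P / P_fat) / (mu_fat - mu_dense)`. Both the logarithm (P below
#' P_fat) and the denominator (mu_fat - mu_dense) are negative for
#' attenuating dense tissue, so the quotient is the positive dense
#' thickness. Raw values below 0 (noise pushing P above P_fat) are clamped
#' to 0 and values above the recorded thickness are clamped down; clamp
#' counts are attached as attributes `n_clamped_low` / `n_clamped_high`.
#'
#' @param image A [projection_image].
#' @param atten An [attenuation_model] with a non-`NULL` `p_fat`.
#' @return Matrix of dense thickness in mm (0 outside the breast interior),
#'   with clamp-count attributes.
#' @export
dense_thickness_map <- function(image, atten) {
  stopifnot(inherits(image, "projection_image"),
            inherits(atten, "attenuation_model"))
  if (is.null(atten$p_fat)) {
    stop("attenuation model has no p_fat reference; estimate one with ",
         "estimate_p_fat()", call. = FALSE)
  }
  interior <- image$mask == 1L
  p <- image$pixels
  n_bad <- sum(p[interior] <= 0)
  if (n_bad > 0) {
    stop("projection image has ", n_bad,
         " non-positive pixel value(s) inside the breast mask",
         call. = FALSE)
  }
  pf <- if (is.matrix(atten$p_fat)) atten$p_fat[interior] else atten$p_fat
  hd_raw <- log(p[interior] / pf) / (atten$mu_fat - atten$mu_dense)
  n_lo <- sum(hd_raw < 0)
  n_hi <- sum(hd_raw > image$thickness_mm)
  hd <- pmin(pmax(hd_raw, 0), image$thickness_mm)
  out <- matrix(0, nrow(p), ncol(p))
  out[interior] <- hd
  attr(out, "n_clamped_low") <- n_lo
  attr(out, "n_clamped_high") <- n_hi
  out
}

#' Estimate the fully adipose reference pixel value
#'
#' @param image A [projection_image].
#' @param strategy `"known_reference"` returns the supplied ground-truth
#'   value (phantom work); `"percentile"` takes an upper percentile of the
#'   interior pixel values - under the transmission model the brightest
#'   interior pixels are the fattiest, so a high percentile approximates the
#'   fully adipose column. On breasts with no fully adipose region the
#'   percentile strategy underestimates `p_fat` and hence density.
#' @param reference Ground-truth value for `"known_reference"`.
#' @param prob Percentile (default 0.99) for `"percentile"`.
#' @return Scalar `p_fat` reference value.
#' @export
estimate_p_fat <- function(image,
                           strategy = c("known_reference", "percentile"),
                           reference = NULL, prob = 0.99) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(image, "projection_image"))
  interior <- image$mask == 1L
  if (!any(interior)) {
    stop("empty breast interior: cannot estimate p_fat", call. = FALSE)
  }
  if (strategy == "known_reference") {
    if (is.null(reference)) {
      stop("strategy 'known_reference' requires a reference value",
           call. = FALSE)
    }
    return(reference)
  }
  stats::quantile(image$pixels[interior], probs = prob, names = FALSE,
                  type = 7)
}

#' Volumetric breast density from a dense-thickness map
#'
#' Dense volume is the dense-thickness map integrated over the pixel area;
#' total volume is the interior breast area times the recorded thickness.
#'
#' @param map Dense thickness map (mm) from [dense_thickness_map()].
#' @param image The [projection_image] the map came from.
#' @return List with `vbd` (% by volume), `dense_volume_mm3` and
#'   `total_volume_mm3`.
#' @export
vbd_from_map <- function(map, image) {
  stopifnot(inherits(image, "projection_image"),
            all(dim(map) == dim(image$pixels)))
  interior <- image$mask == 1L
  n_int <- sum(interior)
  if (n_int == 0) stop("empty breast interior: zero area", call. = FALSE)
  px_area <- image$pixel_mm^2
  dense <- sum(map[interior]) * px_area
  total <- n_int * px_area * image$thickness_mm
  list(vbd = 100 * dense / total, dense_volume_mm3 = dense,
       total_volume_mm3 = total)
}

#' Parameters of the volume-to-weight density conversion
#'
#' @param rho_fat,rho_dense Tissue mass densities in g/cm^3 (standard
#'   literature values 0.93 and 1.04).
#' @param subcut_mm Subcutaneous adipose layer thickness removed from each
#'   side of the compressed breast before forming the core composition
#'   (default 5 mm per side, matching the 0.5 cm adipose surface layer of
#'   the population glandularity model).
#' @param edge_margin_px Mask erosion margin (pixels) approximating the
#'   exclusion of the uncompressed breast edge.
#' @return A `density_conversion_params` list.
#' @export
density_conversion_params <- function(rho_fat = 0.93, rho_dense = 1.04,
                                      subcut_mm = 5, edge_margin_px = 0) {
  stopifnot(rho_fat > 0, rho_dense > 0, subcut_mm >= 0, edge_margin_px >= 0)
  structure(list(rho_fat = rho_fat, rho_dense = rho_dense,
                 subcut_mm = subcut_mm, edge_margin_px = edge_margin_px),
            class = "density_conversion_params")
}

#' Convert volumetric breast density to glandularity by weight
#'
#' Removes a subcutaneous adipose layer from each side of the compressed
#' breast, attributes all dense tissue to the remaining core, and converts
#' the core volume fractions to mass fractions with the tissue densities.
#' Monotone increasing in `vbd`; reduces to the identity when the two tissue
#' densities are equal and the subcutaneous layer is zero.
#'
#' @param vbd Volumetric breast density, % by volume, in \[0, 100\]
#'   (vectorized).
#' @param thickness_mm Compressed breast thickness in mm; must exceed twice
#'   the subcutaneous layer.
#' @param params A [density_conversion_params] list.
#' @return Glandularity in percent by weight.
#' @export
vbd_to_gpw <- function(vbd, thickness_mm,
                       params = density_conversion_params()) {
  .check_range(vbd, 0, 100, "vbd", "% by volume")
  if (any(thickness_mm <= 2 * params$subcut_mm)) {
    stop("degenerate geometry: thickness must exceed twice the ",
         "subcutaneous layer (", 2 * params$subcut_mm, " mm)", call. = FALSE)
  }
  fc <- (thickness_mm - 2 * params$subcut_mm) / thickness_mm
  v <- pmin(vbd / 100, fc)
  dense_mass <- params$rho_dense * v
  fat_mass <- params$rho_fat * (fc - v)
  100 * dense_mass / (dense_mass + fat_mass)
}

#' Inverse of [vbd_to_gpw()]
#'
#' @param gpw Glandularity in percent by weight, in \[0, 100\] (vectorized).
#' @inheritParams vbd_to_gpw
#' @return Volumetric breast density in percent by volume.
#' @export
gpw_to_vbd <- function(gpw, thickness_mm,
                       params = density_conversion_params()) {
  .check_range(gpw, 0, 100, "gpw", "% by weight")
  if (any(thickness_mm <= 2 * params$subcut_mm)) {
    stop("degenerate geometry: thickness must exceed twice the ",
         "subcutaneous layer (", 2 * params$subcut_mm, " mm)", call. = FALSE)
  }
  fc <- (thickness_mm - 2 * params$subcut_mm) / thickness_mm
  q <- gpw / 100
  v <- q * params$rho_fat * fc /
    (params$rho_dense * (1 - q) + params$rho_fat * q)
  100 * v
}

#' Two-tissue phantom specification
#'
#' @param nx,ny Image size in pixels.
#' @param pixel_mm Pixel pitch in mm.
#' @param thickness_mm Compressed breast thickness in mm.
#' @param shape Breast footprint: `"rect"` (rectangle with a background
#'   border) or `"semicircle"` (half disc against the chest-wall edge).
#' @param margin_px Background border width in pixels for `"rect"`.
#' @param dense_regions List of rectangular dense inserts, each a list with
#'   `x0`, `x1`, `y0`, `y1` (mm, image coordinates) and `hd` (dense
#'   thickness in mm, must not exceed `thickness_mm`).
#' @param noise_sd Relative standard deviation of the multiplicative
#'   Gaussian pixel noise (0 = noiseless).
#' @param p0 Unattenuated pixel value.
#' @param mu_fat,mu_dense Linear attenuation coefficients per mm.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(nx = 300, ny = 300, pixel_mm = 0.2,
                         thickness_mm = 50, shape = c("rect", "semicircle"),
                         margin_px = 2, dense_regions = list(),
                         noise_sd = 0, p0 = 10000,
                         mu_fat = 0.057, mu_dense = 0.082) {
  shape <- match.arg(shape)
  for (r in dense_regions) {
    if (!all(c("x0", "x1", "y0", "y1", "hd") %in% names(r))) {
      stop("each dense region needs x0, x1, y0, y1 and hd", call. = FALSE)
    }
    if (r$hd > thickness_mm || r$hd < 0) {
      stop("phantom spec inconsistent: dense thickness ", r$hd,
           " mm outside [0, ", thickness_mm, "] mm", call. = FALSE)
    }
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(nx = nx, ny = ny, pixel_mm = pixel_mm,
                 thickness_mm = thickness_mm, shape = shape,
                 margin_px = margin_px, dense_regions = dense_regions,
                 noise_sd = noise_sd, p0 = p0, mu_fat = mu_fat,
                 mu_dense = mu_dense),
            class = "phantom_spec")
}

#' Forward-project a two-tissue phantom
#'
#' Builds the breast mask and ground-truth dense-thickness map from the
#' specification, forward-projects under the exponential two-tissue model
#' and applies multiplicative Gaussian noise. Deterministic under a fixed
#' seed.
#'
#' @param spec A [phantom_spec].
#' @param seed Integer seed for the noise stream.
#' @return List with `image` (a [projection_image]), `truth` (list with
#'   `hd` map, `vbd`, `p_fat`) and `atten` (the generating
#'   [attenuation_model] including the true `p_fat`).
#' @export
synth_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$nx; ny <- spec$ny
  xc <- (col(matrix(0, ny, nx)) - 0.5) * spec$pixel_mm
  yc <- (row(matrix(0, ny, nx)) - 0.5) * spec$pixel_mm
  mask <- matrix(0L, ny, nx)
  if (spec$shape == "rect") {
    m <- spec$margin_px
    mask[(m + 1):(ny - m), (m + 1):(nx - m)] <- 1L
  } else {
    r <- min(nx * spec$pixel_mm, ny * spec$pixel_mm / 2)
    cy <- ny * spec$pixel_mm / 2
    mask[sqrt(xc^2 + (yc - cy)^2) <= r] <- 1L
  }
  hd <- matrix(0, ny, nx)
  for (reg in spec$dense_regions) {
    inreg <- xc >= reg$x0 & xc <= reg$x1 & yc >= reg$y0 & yc <= reg$y1 &
      mask == 1L
    hd[inreg] <- reg$hd
  }
  p <- matrix(spec$p0, ny, nx)
  interior <- mask == 1L
  p[interior] <- spec$p0 *
    exp(-spec$mu_fat * (spec$thickness_mm - hd[interior]) -
          spec$mu_dense * hd[interior])
  if (spec$noise_sd > 0) {
    set.seed(as.integer(seed))
    p <- p * pmax(1 + stats::rnorm(length(p), 0, spec$noise_sd), 0.01)
  }
  p_fat_true <- spec$p0 * exp(-spec$mu_fat * spec$thickness_mm)
  img <- projection_image(p, spec$pixel_mm, spec$thickness_mm, mask)
  true_vbd <- 100 * sum(hd[interior]) / (sum(interior) * spec$thickness_mm)
  list(image = img,
       truth = list(hd = hd, vbd = true_vbd, p_fat = p_fat_true,
                    spec = spec, seed = as.integer(seed)),
       atten = attenuation_model(spec$mu_fat, spec$mu_dense, p_fat_true))
}

.erode_mask <- function(interior, margin_px) {
  if (margin_px <= 0) return(interior)
  m <- interior
  for (k in seq_len(margin_px)) {
    shifted <- m &
      rbind(FALSE, m[-nrow(m), , drop = FALSE]) &
      rbind(m[-1, , drop = FALSE], FALSE) &
      cbind(FALSE, m[, -ncol(m), drop = FALSE]) &
      cbind(m[, -1, drop = FALSE], FALSE)
    m <- shifted
  }
  m
}

#' Full image-based density estimate
#'
#' Runs the dense-thickness inversion, integrates it to a volumetric breast
#' density and converts to glandularity by weight.
#'
#' @param image A [projection_image].
#' @param atten An [attenuation_model]; when its `p_fat` is `NULL` it is
#'   estimated with [estimate_p_fat()] using `p_fat_strategy`.
#' @param p_fat_strategy,reference,prob Passed to [estimate_p_fat()].
#' @param conversion A [density_conversion_params] list.
#' @return A `density_result` list: `map`, `vbd`, `gpw`, `dense_volume_mm3`,
#'   `total_volume_mm3`, `p_fat`, clamp counts.
#' @export
estimate_density <- function(image, atten = attenuation_model(),
                             p_fat_strategy = c("known_reference",
                                                "percentile"),
                             reference = NULL, prob = 0.99,
                             conversion = density_conversion_params()) {
  if (is.null(atten$p_fat)) {
    p_fat_strategy <- match.arg(p_fat_strategy)
    atten$p_fat <- estimate_p_fat(image, p_fat_strategy,
                                  reference = reference, prob = prob)
  }
  if (conversion$edge_margin_px > 0) {
    interior <- .erode_mask(image$mask == 1L, conversion$edge_margin_px)
    image$mask[image$mask == 1L & !interior] <- 2L
  }
  map <- dense_thickness_map(image, atten)
  vol <- vbd_from_map(map, image)
  structure(list(map = map, vbd = vol$vbd,
                 gpw = vbd_to_gpw(vol$vbd, image$thickness_mm, conversion),
                 dense_volume_mm3 = vol$dense_volume_mm3,
                 total_volume_mm3 = vol$total_volume_mm3,
                 p_fat = atten$p_fat,
                 n_clamped_low = attr(map, "n_clamped_low"),
                 n_clamped_high = attr(map, "n_clamped_high")),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("<density_result> VBD %.2f %% by volume, GPW %.2f %% by weight\n",
              x$vbd, x$gpw))
  cat(sprintf("  dense %.0f mm^3 of %.0f mm^3; clamped %d low / %d high\n",
              x$dense_volume_mm3, x$total_volume_mm3,
              x$n_clamped_low, x$n_clamped_high))
  invisible(x)
}

#' Write / read a phantom image with its metadata sidecar
#'
#' The image is stored as a 16-bit TIFF (pixel values scaled by the recorded
#' `scale`), the mask as an 8-bit PNG label image, and pixel size, recorded
#' thickness and ground truth in a YAML sidecar.
#'
#' @param phantom A list as returned by [synth_phantom()].
#' @param stem Output path stem; writes `<stem>.tif`, `<stem>_mask.png` and
#'   `<stem>.yaml`.
#' @return `stem`, invisibly.
#' @export
write_phantom <- function(phantom, stem) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("png", quietly = TRUE)) {
    stop("writing phantoms requires the 'tiff' and 'png' packages",
         call. = FALSE)
  }
  img <- phantom$image
  scale <- max(img$pixels)
  tiff::writeTIFF(img$pixels / scale, paste0(stem, ".tif"),
                  bits.per.sample = 16)
  png::writePNG(img$mask / 255, paste0(stem, "_mask.png"))
  meta <- list(pixel_mm = img$pixel_mm, thickness_mm = img$thickness_mm,
               scale = scale,
               truth = list(vbd = phantom$truth$vbd,
                            p_fat = phantom$truth$p_fat,
                            seed = phantom$truth$seed),
               atten = list(mu_fat = phantom$atten$mu_fat,
                            mu_dense = phantom$atten$mu_dense))
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname write_phantom
#' @return For `read_phantom`: a list with `image` (a [projection_image]),
#'   `atten` and the sidecar `meta`.
#' @export
read_phantom <- function(stem) {
  if (!requireNamespace("tiff", quietly = TRUE) ||
      !requireNamespace("png", quietly = TRUE)) {
    stop("reading phantoms requires the 'tiff' and 'png' packages",
         call. = FALSE)
  }
  meta <- yaml::read_yaml(paste0(stem, ".yaml"))
  px <- tiff::readTIFF(paste0(stem, ".tif")) * meta$scale
  mask <- round(png::readPNG(paste0(stem, "_mask.png")) * 255)
  storage.mode(mask) <- "integer"
  img <- projection_image(px, meta$pixel_mm, meta$thickness_mm, mask)
  atten <- attenuation_model(meta$atten$mu_fat, meta$atten$mu_dense,
                             meta$truth$p_fat)
  list(image = img, atten = atten, meta = meta)
}
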