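#' Default DICOM tag map for exposure metadata
#'
#' Maps [exam_records] fields to DICOM attribute tags. Defaults follow the
#' standard exposure/dose attributes plus configurable slots for the private
#' density tags, whose addresses vary by equipment software version; adjust
#' the map rather than relying on hard-coded private addresses.
#'
#' @param ... Named overrides, e.g.
#'   `volpara_gpw = "(0011,1001)"`.
#' @return Named character vector of `"(gggg,eeee)"` tags.
#' @export
dicom_tag_map <- function(...) {
  map <- c(exam_id = "(0008,0018)",         # SOP Instance UID
           view = "(0018,5101)",            # View Position
           age = "(0010,1010)",             # Patient Age (AS)
           birth_date = "(0010,0030)",      # Patient Birth Date
           study_date = "(0008,0020)",      # Study Date
           thickness = "(0018,11a0)",       # Body Part Thickness (mm)
           hvl = "(0040,0314)",             # Half Value Layer (mm Al)
           anode = "(0018,1191)",           # Anode Target Material
           filter = "(0018,7050)",          # Filter Material
           iak = "(0040,8302)",             # Entrance Dose in mGy
           vendor_agd = "(0040,0316)",      # Organ Dose (dGy)
           volpara_gpw = "(0011,1001)",     # private: glandularity % weight
           volpara_vbd = "(0011,1002)")     # private: volumetric density %
  override <- c(...)
  map[names(override)] <- override
  map
}

# Minimal DICOM header parser: explicit VR, little endian, no pixel data.
.parse_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  offset <- 0L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    offset <- 132L
  } else if (length(raw) < 8) {
    return(NULL)
  } else {
    # no preamble: accept only if the stream starts with a plausible
    # explicit-VR element in group 0002 or 0008
    grp <- readBin(raw[1:2], "integer", size = 2, endian = "little",
                   signed = FALSE)
    vr <- rawToChar(raw[5:6])
    if (!(grp %in% c(2L, 8L)) || !grepl("^[A-Z]{2}$", vr)) return(NULL)
  }
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  string_vrs <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT",
                  "PN", "SH", "ST", "TM", "UI", "UT")
  elements <- list()
  i <- offset
  n <- length(raw)
  while (i + 8 <= n) {
    grp <- readBin(raw[(i + 1):(i + 2)], "integer", size = 2,
                   endian = "little", signed = FALSE)
    ele <- readBin(raw[(i + 3):(i + 4)], "integer", size = 2,
                   endian = "little", signed = FALSE)
    vr <- rawToChar(raw[(i + 5):(i + 6)])
    if (!grepl("^[A-Z]{2}$", vr)) break
    if (vr %in% long_vrs) {
      if (i + 12 > n) break
      len <- readBin(raw[(i + 9):(i + 12)], "integer", size = 4,
                     endian = "little")
      i <- i + 12L
    } else {
      len <- readBin(raw[(i + 7):(i + 8)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      i <- i + 8L
    }
    if (grp == 0x7fe0 && ele == 0x0010) break  # stop before pixel data
    if (len < 0 || i + len > n) break          # undefined/overrun length
    tag <- sprintf("(%04x,%04x)", grp, ele)
    if (len > 0) {
      bytes <- raw[(i + 1):(i + len)]
      elements[[tag]] <- if (vr %in% string_vrs) {
        trimws(rawToChar(bytes[bytes != as.raw(0)]))
      } else if (vr == "US") {
        readBin(bytes, "integer", size = 2, endian = "little",
                signed = FALSE)
      } else if (vr %in% c("UL", "SL")) {
        readBin(bytes, "integer", size = 4, endian = "little")
      } else if (vr == "FD") {
        readBin(bytes, "double", size = 8, endian = "little")
      } else if (vr == "FL") {
        readBin(bytes, "double", size = 4, endian = "little")
      } else {
        bytes
      }
    } else {
      elements[[tag]] <- ""
    }
    i <- i + len
  }
  if (length(elements) == 0) return(NULL)
  elements
}

.normalize_material <- function(x) {
  if (is.na(x)) return(x)
  key <- toupper(trimws(x))
  std <- c(MOLYBDENUM = "Mo", RHODIUM = "Rh", TUNGSTEN = "W",
           SILVER = "Ag", ALUMINUM = "Al", ALUMINIUM = "Al")
  if (key %in% names(std)) std[[key]] else x
}

.dicom_numeric <- function(x) {
  if (is.null(x)) return(NA_real_)
  if (is.numeric(x)) return(as.numeric(x[1]))
  suppressWarnings(as.numeric(strsplit(x, "\\\\")[[1]][1]))
}

.dicom_age_years <- function(elements, map) {
  age_str <- elements[[map[["age"]]]]
  if (!is.null(age_str) && nzchar(age_str)) {
    num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", age_str)))
    unit <- toupper(gsub("[^A-Za-z]", "", age_str))
    if (!is.na(num)) {
      return(switch(unit, M = num / 12, W = num / 52.18, D = num / 365.25,
                    num))
    }
  }
  bd <- elements[[map[["birth_date"]]]]
  sd <- elements[[map[["study_date"]]]]
  if (!is.null(bd) && !is.null(sd) && nzchar(bd) && nzchar(sd)) {
    b <- as.Date(bd, format = "%Y%m%d")
    s <- as.Date(sd, format = "%Y%m%d")
    if (!is.na(b) && !is.na(s)) {
      return(floor(as.numeric(s - b) / 365.25))
    }
  }
  NA_real_
}

#' Read exposure metadata from DICOM headers
#'
#' Parses the headers of explicit-VR little-endian DICOM files (pixel data
#' is never read) and populates one [exam_records] row per usable file.
#' Non-DICOM files are skipped with a logged reason; missing optional tags
#' leave the corresponding fields `NA` with a per-file log entry. The
#' equipment organ-dose attribute is stored in dGy and converted to mGy.
#'
#' @param paths Character vector of file paths (or a single directory, which
#'   is expanded to the files it contains).
#' @param tag_map A [dicom_tag_map()].
#' @param organ_dose_unit Unit of the organ-dose tag: `"dGy"` (DICOM
#'   standard, converted with a factor 100) or `"mGy"` (taken as is).
#' @return An [exam_records] data frame with attribute `"log"` (data frame
#'   of file, field, message entries).
#' @export
read_dicom_headers <- function(paths, tag_map = dicom_tag_map(),
                               organ_dose_unit = c("dGy", "mGy")) {
  organ_dose_unit <- match.arg(organ_dose_unit)
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, full.names = TRUE)
  }
  log <- data.frame(file = character(0), field = character(0),
                    message = character(0), stringsAsFactors = FALSE)
  note <- function(f, field, msg) {
    log <<- rbind(log, data.frame(file = f, field = field, message = msg,
                                  stringsAsFactors = FALSE))
  }
  rows <- list()
  for (p in paths) {
    el <- tryCatch(.parse_dicom(p), error = function(e) NULL)
    if (is.null(el)) {
      note(p, "*", "not a readable DICOM file; skipped")
      next
    }
    get_chr <- function(field) {
      v <- el[[tag_map[[field]]]]
      if (is.null(v) || !nzchar(v)) {
        note(p, field, "tag absent or empty")
        NA_character_
      } else v
    }
    get_num <- function(field) {
      v <- .dicom_numeric(el[[tag_map[[field]]]])
      if (is.na(v)) note(p, field, "tag absent or not numeric")
      v
    }
    vendor <- get_num("vendor_agd")
    if (!is.na(vendor) && organ_dose_unit == "dGy") vendor <- vendor * 100
    rows[[length(rows) + 1]] <- data.frame(
      exam_id = if (is.na(get_chr("exam_id"))) basename(p)
                else el[[tag_map[["exam_id"]]]],
      view = get_chr("view"),
      age = .dicom_age_years(el, tag_map),
      thickness = get_num("thickness"),
      hvl = get_num("hvl"),
      anode = .normalize_material(get_chr("anode")),
      filter = .normalize_material(get_chr("filter")),
      iak = get_num("iak"),
      entrance_exposure = NA_real_,
      vendor_agd = vendor,
      volpara_gpw = get_num("volpara_gpw"),
      volpara_vbd = get_num("volpara_vbd"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    stop("no usable DICOM files among ", length(paths), " path(s)",
         call. = FALSE)
  }
  out <- exam_records(do.call(rbind, rows))
  attr(out, "log") <- log
  out
}

#' Read exposure records from CSV
#'
#' @param path CSV file with the [exam_records] schema (column names as
#'   documented there).
#' @return An [exam_records] data frame.
#' @export
read_exam_csv <- function(path) {
  if (!file.exists(path)) {
    stop("exam CSV not found: ", path, call. = FALSE)
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop("exam CSV parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (nrow(df) == 0) stop("exam CSV is empty: ", path, call. = FALSE)
  exam_records(df)
}
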