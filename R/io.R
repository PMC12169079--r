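# Readers and writers for the pipeline's tabular and raster formats.
# CSV is the canonical tabular interchange; single-channel TIFF (0/255) the
# canonical raster format.

#' Read a clonotype table (AIRR-style CSV)
#'
#' Expects columns `sample_id`, `junction_aa`, `duplicate_count` and
#' optionally `v_call`, `j_call`, `junction`; non-AIRR exports can be
#' adapted with `column_map` (a named character vector mapping required
#' names to the file's column names). CDR3 sequences are upper-cased with a
#' warning when needed; malformed rows (empty/invalid CDR3 or non-positive
#' count) are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector, e.g.
#'   `c(duplicate_count = "clone_count")`.
#' @return Data frame of validated clonotype records.
#' @export
read_clonotype_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(tab)) stopf("mapped column '%s' not found in %s", src, path)
      tab[[std]] <- tab[[src]]
    }
  }
  req <- c("sample_id", "junction_aa", "duplicate_count")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    stopf("clonotype table %s lacks required column(s): %s",
          path, paste(miss, collapse = ", "))
  }
  upper <- toupper(tab$junction_aa)
  if (!identical(upper, tab$junction_aa)) {
    warnf("lower-case CDR3 sequences normalised to upper case in %s", path)
    tab$junction_aa <- upper
  }
  bad_aa <- !nzchar(tab$junction_aa) |
    grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), tab$junction_aa)
  cnt <- suppressWarnings(as.numeric(tab$duplicate_count))
  bad_cnt <- !is.finite(cnt) | cnt < 1 | cnt != round(cnt)
  bad <- bad_aa | bad_cnt
  if (any(bad)) {
    warnf("rejected %d malformed row(s) in %s (lines %s)",
          sum(bad), path,
          paste(utils::head(which(bad) + 1L, 10L), collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
  }
  if (!nrow(tab)) stopf("no valid clonotype records in %s", path)
  tab$duplicate_count <- as.integer(tab$duplicate_count)
  rownames(tab) <- NULL
  tab
}

#' Write a clonotype table
#' @param tab Clonotype data frame.
#' @param path Output CSV path.
#' @export
write_clonotype_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a CDR3 specificity reference table
#' @param path CSV with at least a `cdr3_aa` column (typically also
#'   `v_call`, `epitope`, `antigen`, `source_id`).
#' @return Data frame.
#' @export
read_cdr3_reference <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"cdr3_aa" %in% names(ref)) stopf("reference %s lacks a cdr3_aa column", path)
  ref
}

#' Read/write cell tables
#'
#' Cell CSVs carry `cell_id`, `x_um`, `y_um`, `cell_type`, optional
#' `marker_*` logical columns and optional `true_zone` / `true_clone`
#' ground-truth columns (empty strings are read as `NA`).
#'
#' @param path CSV path.
#' @return Data frame of cell records.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("cell_id", "x_um", "y_um", "cell_type")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stopf("cell table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  tab
}

#' @rdname read_cell_table
#' @param tab Cell data frame.
#' @export
write_cell_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read/write transcript tables
#'
#' Transcript CSVs carry `transcript_id`, `feature_name`, `x_um`, `y_um`,
#' `cell_id` (empty = unassigned) and `qv`.
#'
#' @param path CSV path.
#' @return Data frame of transcript records.
#' @export
read_transcript_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("transcript_id", "feature_name", "x_um", "y_um", "cell_id", "qv")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stopf("transcript table %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  tab
}

#' @rdname read_transcript_table
#' @param tab Transcript data frame.
#' @export
write_transcript_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read/write binary masks as single-channel TIFF
#'
#' Masks are stored as 8-bit single-channel TIFF with values 0/255.
#'
#' @param path TIFF path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

#' @rdname read_mask
#' @param mask Logical (or 0/1) matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask > 0), nrow(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Write/read a zone map (indexed TIFF + JSON legend)
#'
#' The label raster is stored as an 8-bit TIFF (codes 0-5) and the legend
#' (code-to-zone names, areas, pixel size, band width) as JSON. The duct
#' mask is not part of the raster; a reloaded zone map carries an empty
#' duct mask.
#'
#' @param zone_map A [build_zone_map()] result.
#' @param tif_path,json_path Output paths.
#' @export
write_zone_map <- function(zone_map, tif_path, json_path) {
  stopifnot(inherits(zone_map, "zone_map"))
  tiff::writeTIFF(zone_map$labels / 255, tif_path, bits.per.sample = 8L)
  legend <- list(
    zones = lapply(names(ZONE_LEVELS), function(z) {
      list(code = ZONE_LEVELS[[z]], zone = z, area_mm2 = zone_map$areas_mm2[[z]])
    }),
    pixel_size_um = zone_map$pixel_size_um,
    band_width_um = zone_map$band_width_um,
    total_tissue_mm2 = zone_map$total_tissue_mm2
  )
  jsonlite::write_json(legend, json_path, auto_unbox = TRUE, digits = NA)
  invisible(tif_path)
}

#' @rdname write_zone_map
#' @export
read_zone_map <- function(tif_path, json_path) {
  labels <- round(tiff::readTIFF(tif_path) * 255)
  storage.mode(labels) <- "integer"
  legend <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  areas <- stats::setNames(legend$zones$area_mm2, legend$zones$zone)[names(ZONE_LEVELS)]
  structure(
    list(labels = labels, pixel_size_um = legend$pixel_size_um,
         band_width_um = legend$band_width_um,
         areas_mm2 = areas, total_tissue_mm2 = legend$total_tissue_mm2,
         duct = matrix(FALSE, nrow(labels), ncol(labels))),
    class = "zone_map"
  )
}

#' Write a ground-truth manifest as JSON
#'
#' Matrix-valued entries (e.g. pre-bleed count matrices) are summarised by
#' their dimensions rather than serialised.
#'
#' @param manifest Manifest list (from the generators).
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  strip <- function(x) {
    if (inherits(x, "Matrix") || is.matrix(x)) {
      list(class = class(x)[1L], dim = dim(x))
    } else if (is.list(x)) {
      lapply(x, strip)
    } else x
  }
  jsonlite::write_json(strip(manifest), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
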