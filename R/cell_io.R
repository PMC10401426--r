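## Per-cell segmentation table I/O.
##
## The unit of spatial analysis is one TMA core: a `core_table` holds the
## cells of one core (one row per nucleated cell, centroid in micrometres)
## plus core geometry. Files are plain delimited text in the dialect of
## common digital-pathology exports; column names and units are supplied
## through a dialect config rather than hard-coded, because segmentation
## tools disagree ("Centroid X µm" vs "x").

#' Construct a core cell table
#'
#' @param cells data.frame with at least `cell_id`, `x`, `y` (micrometres);
#'   optional logical flag columns from [cell_panel()], a `phenotype`
#'   primary label, and `intensity_<marker>` columns.
#' @param core_id,patient_id identifiers.
#' @param area_um2 core area in square micrometres; if `NULL`, estimated
#'   from the convex hull of the cell centroids (fallback: a 500-micron
#'   radius disc when fewer than 3 cells are present).
#' @param geometry optional list `list(center = c(x, y), radius = r)`
#'   describing a circular core; used by edge-guard options.
#' @param provenance free-text origin (source file or "synthetic").
#' @return an object of class `core_table`.
#' @export
core_table <- function(cells, core_id, patient_id, area_um2 = NULL,
                       geometry = NULL, provenance = "constructed") {
  stopifnot(is.data.frame(cells))
  need <- c("cell_id", "x", "y")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stopf("cell table missing mandatory columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(cells)) {
    if (!all(is.finite(cells$x)) || !all(is.finite(cells$y)))
      stopf("core '%s': non-finite cell coordinates", core_id)
    if (anyDuplicated(cells$cell_id))
      stopf("core '%s': duplicate cell_id values", core_id)
  }
  cells$cell_id <- as.character(cells$cell_id)
  for (m in cell_panel())
    if (m %in% names(cells)) cells[[m]] <- as.logical(cells[[m]])
  if (is.null(area_um2)) area_um2 <- estimate_core_area(cells, geometry)
  if (!is_scalar_num(area_um2) || area_um2 <= 0)
    stopf("core '%s': area must be a positive number", core_id)
  structure(list(core_id = as.character(core_id),
                 patient_id = as.character(patient_id),
                 cells = cells, area_um2 = area_um2,
                 geometry = geometry, provenance = provenance),
            class = "core_table")
}

#' @export
print.core_table <- function(x, ...) {
  cat(sprintf("<core_table> core %s (patient %s): %d cells, %.3f mm^2\n",
              x$core_id, x$patient_id, nrow(x$cells), x$area_um2 / 1e6))
  flags <- intersect(cell_panel(), names(x$cells))
  if (length(flags) && nrow(x$cells)) {
    n <- vapply(flags, function(m) sum(x$cells[[m]], na.rm = TRUE), 0)
    cat("  positive cells:", paste(sprintf("%s=%d", flags, n), collapse = " "), "\n")
  }
  invisible(x)
}

estimate_core_area <- function(cells, geometry = NULL) {
  if (!is.null(geometry)) return(pi * geometry$radius^2)
  if (nrow(cells) < 3) return(pi * 500^2)
  h <- grDevices::chull(cells$x, cells$y)
  xs <- cells$x[h]; ys <- cells$y[h]
  a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  max(a, 1)
}

#' Dialect configuration for segmentation exports
#'
#' Maps file columns onto the canonical schema and declares coordinate
#' units. `label_cols` name pre-existing 0/1 phenotype columns to trust;
#' `intensity_cols` name per-marker mean-intensity columns used by
#' [classify_cells()].
#'
#' @param sep field separator; `NULL` auto-detects comma vs tab.
#' @param col_cell_id,col_core_id,col_patient_id,col_x,col_y column names.
#' @param units `"um"` or `"px"`; pixel inputs require `px_size_um`.
#' @param px_size_um physical pixel size, micrometres per pixel.
#' @param intensity_cols named character vector, marker -> column.
#' @param label_cols named character vector, marker -> 0/1 column.
#' @return a `cell_dialect` list.
#' @export
cell_dialect <- function(sep = NULL, col_cell_id = "cell_id",
                         col_core_id = "core_id", col_patient_id = "patient_id",
                         col_x = "x", col_y = "y",
                         units = c("um", "px"), px_size_um = NULL,
                         intensity_cols = NULL, label_cols = NULL) {
  units <- match.arg(units)
  if (units == "px" && !is_scalar_num(px_size_um %||% NA))
    stopf("pixel units require px_size_um")
  structure(list(sep = sep, col_cell_id = col_cell_id,
                 col_core_id = col_core_id, col_patient_id = col_patient_id,
                 col_x = col_x, col_y = col_y, units = units,
                 px_size_um = px_size_um, intensity_cols = intensity_cols,
                 label_cols = label_cols), class = "cell_dialect")
}

detect_sep <- function(path) {
  l1 <- readLines(path, n = 25L)
  l1 <- l1[!startsWith(l1, "#")][1]
  if (is.na(l1)) return(",")
  if (lengths(regmatches(l1, gregexpr("\t", l1))) > 0) "\t" else ","
}

#' Read per-cell segmentation tables
#'
#' Reads a delimited export (comment lines starting with `#` are skipped),
#' validates mandatory columns, converts pixel coordinates to micrometres,
#' and splits the rows into one [core_table] per core. Rows with missing
#' coordinates are dropped and counted, never silently discarded: the
#' returned list carries a `parse_report` attribute with
#' `n_rows_in`, `n_rows_kept`, `n_dropped_missing_coord`.
#'
#' @param path file path.
#' @param dialect a [cell_dialect()].
#' @return named list of `core_table` objects (by core id), with attribute
#'   `parse_report`.
#' @export
read_cell_table <- function(path, dialect = cell_dialect()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- dialect$sep %||% detect_sep(path)
  raw <- utils::read.csv(path, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  req <- c(dialect$col_cell_id, dialect$col_core_id, dialect$col_patient_id,
           dialect$col_x, dialect$col_y)
  miss <- setdiff(req, names(raw))
  if (length(miss)) stopf("missing mandatory columns: %s",
                          paste(miss, collapse = ", "))

  n_in <- nrow(raw)
  x <- suppressWarnings(as.numeric(raw[[dialect$col_x]]))
  y <- suppressWarnings(as.numeric(raw[[dialect$col_y]]))
  keep <- is.finite(x) & is.finite(y)
  raw <- raw[keep, , drop = FALSE]; x <- x[keep]; y <- y[keep]
  if (dialect$units == "px") {
    x <- x * dialect$px_size_um
    y <- y * dialect$px_size_um
  }

  cells <- data.frame(cell_id = as.character(raw[[dialect$col_cell_id]]),
                      x = x, y = y, stringsAsFactors = FALSE)
  for (m in names(dialect$intensity_cols %||% character())) {
    col <- dialect$intensity_cols[[m]]
    if (!col %in% names(raw)) stopf("intensity column '%s' absent", col)
    cells[[paste0("intensity_", m)]] <- as.numeric(raw[[col]])
  }
  for (m in names(dialect$label_cols %||% character())) {
    col <- dialect$label_cols[[m]]
    if (!col %in% names(raw)) stopf("label column '%s' absent", col)
    cells[[m]] <- as.logical(as.integer(raw[[col]]))
  }
  # canonical flag/phenotype columns written by write_cell_table round-trip
  for (m in intersect(c(cell_panel(), "phenotype"), names(raw)))
    if (!m %in% names(cells))
      cells[[m]] <- if (m == "phenotype") as.character(raw[[m]])
                    else as.logical(raw[[m]])

  core_ids <- as.character(raw[[dialect$col_core_id]])
  pat_ids <- as.character(raw[[dialect$col_patient_id]])
  area_col <- if ("core_area_um2" %in% names(raw))
    as.numeric(raw[["core_area_um2"]]) else NULL

  out <- list()
  for (cid in unique(core_ids)) {
    sel <- core_ids == cid
    area <- if (!is.null(area_col)) area_col[which(sel)[1]] else NULL
    out[[cid]] <- core_table(cells[sel, , drop = FALSE], core_id = cid,
                             patient_id = pat_ids[which(sel)[1]],
                             area_um2 = area, provenance = path)
  }
  attr(out, "parse_report") <- list(n_rows_in = n_in,
                                    n_rows_kept = sum(keep),
                                    n_dropped_missing_coord = n_in - sum(keep))
  out
}

#' Write core cell tables to delimited text
#'
#' One CSV with columns `cell_id, core_id, patient_id, x, y`, the flag /
#' phenotype / intensity columns present, and `core_area_um2`, preceded by
#' `#`-comment header lines (e.g. the simulation seed). The file reads
#' back with [read_cell_table()] under the default dialect (round trip).
#'
#' @param tables a `core_table` or list of them.
#' @param path output file path.
#' @param header named character vector written as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(tables, path, header = NULL) {
  if (inherits(tables, "core_table")) tables <- list(tables)
  rows <- lapply(tables, function(tb) {
    cc <- tb$cells
    if (!nrow(cc)) return(NULL)
    cbind(data.frame(cell_id = cc$cell_id, core_id = tb$core_id,
                     patient_id = tb$patient_id, x = cc$x, y = cc$y,
                     stringsAsFactors = FALSE),
          cc[, setdiff(names(cc), c("cell_id", "x", "y")), drop = FALSE],
          data.frame(core_area_um2 = tb$area_um2))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  con <- file(path, "w"); on.exit(close(con))
  for (h in names(header))
    writeLines(sprintf("# %s: %s", h, header[[h]]), con)
  if (length(rows)) {
    df <- do.call(rbind, rows)
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, quote = FALSE)
  } else {
    writeLines("cell_id,core_id,patient_id,x,y,core_area_um2", con)
  }
  invisible(path)
}

#' Gating configuration for phenotype classification
#'
#' @param thresholds named numeric vector, marker -> intensity threshold;
#'   a cell is positive iff intensity is strictly greater than the
#'   threshold (positivity cut-offs are not standardised across studies,
#'   so the strict-`>` convention is documented rather than assumed).
#' @param use_labels if `TRUE`, trust pre-existing flag columns and apply
#'   no thresholds.
#' @param cd8_implies_cd3 biological containment: force the CD3 flag on
#'   every CD8-positive cell. On by default.
#' @return a `gating_config` list.
#' @export
gating_config <- function(thresholds = NULL, use_labels = is.null(thresholds),
                          cd8_implies_cd3 = TRUE) {
  structure(list(thresholds = thresholds, use_labels = use_labels,
                 cd8_implies_cd3 = cd8_implies_cd3), class = "gating_config")
}

#' Convert marker intensities into phenotype flags
#'
#' @param tables a `core_table` or list of them.
#' @param gating a [gating_config()].
#' @return tables of the same shape with flag columns set.
#' @export
classify_cells <- function(tables, gating = gating_config()) {
  single <- inherits(tables, "core_table")
  if (single) tables <- list(tables)
  out <- lapply(tables, function(tb) {
    cc <- tb$cells
    if (!gating$use_labels) {
      for (m in names(gating$thresholds)) {
        col <- paste0("intensity_", m)
        if (!col %in% names(cc))
          stopf("marker '%s' has no intensity column in core '%s'",
                m, tb$core_id)
        cc[[m]] <- cc[[col]] > gating$thresholds[[m]]
      }
    }
    if (gating$cd8_implies_cd3 && all(c("CD3", "CD8") %in% names(cc)))
      cc$CD3 <- cc$CD3 | cc$CD8
    tb$cells <- cc
    tb
  })
  if (single) out[[1]] else out
}

#' Read / write per-patient clinical tables
#'
#' Delimited text, one row per patient. Recognised columns: `patient_id`,
#' `surgery_offset_months` (surgery time measured from diagnosis),
#' `followup_months` (last follow-up from diagnosis), `death_months` +
#' `death_event`, `metastasis_months` + `metastasis_event` (both from
#' diagnosis), `treatment_group`, `histology`.
#'
#' @param path file path.
#' @return data.frame of clinical records.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, sep = detect_sep(path), comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stopf("clinical table needs patient_id")
  validate_clinical(df)
  df
}

#' @rdname read_clinical_table
#' @param clinical data.frame as above.
#' @param header named character vector of `#` comment header lines.
#' @export
write_clinical_table <- function(clinical, path, header = NULL) {
  validate_clinical(clinical)
  con <- file(path, "w"); on.exit(close(con))
  for (h in names(header))
    writeLines(sprintf("# %s: %s", h, header[[h]]), con)
  utils::write.csv(clinical, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The closed set of treatment-group labels
#'
#' Initial-therapy categories recognised in clinical tables.
#'
#' @return character vector of valid `treatment_group` values.
#' @export
treatment_groups <- function()
  c("upfront_surgery", "neoadjuvant_rt", "neoadjuvant_chemo", "chemoradiation")

validate_clinical <- function(df) {
  tm <- intersect(c("surgery_offset_months", "followup_months",
                    "death_months", "metastasis_months"), names(df))
  for (col in tm)
    if (any(df[[col]] < 0, na.rm = TRUE)) stopf("negative %s", col)
  if ("treatment_group" %in% names(df)) {
    bad <- setdiff(unique(df$treatment_group), treatment_groups())
    if (length(bad)) stopf("unknown treatment group(s): %s",
                           paste(bad, collapse = ", "))
  }
  invisible(df)
}
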