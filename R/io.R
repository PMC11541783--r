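# Long-CSV interchange: one measurement per row, censoring explicit.

CSV_COLS <- c("species", "year", "composite_id", "replicate_id", "analyte_id",
              "chem_class", "value", "detection_limit", "censored",
              "n_fish", "pct_moisture", "pct_lipids")

#' Read measurements from a long CSV file
#'
#' Parses the canonical long interchange format (UTF-8, header required): one
#' analyte measurement per row with explicit censoring. Nondetects have an
#' empty `value` cell, `censored = TRUE` and a positive `detection_limit`;
#' a bare `"<DL"` string in the value column is rejected. An optional
#' `sample_type` column (`fillet`/`whole`/`roe`) defaults to `"fillet"`.
#'
#' @param path path to a CSV file with columns `species`, `year`,
#'   `composite_id`, `replicate_id`, `analyte_id`, `chem_class`, `value`,
#'   `detection_limit`, `censored`, `n_fish`, `pct_moisture`, `pct_lipids`.
#' @param catalog analyte catalog; defaults to [default_catalog()].
#' @return A validated [fishrisk_dataset()].
#' @export
read_measurements <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(value = "character"))
  missing_cols <- setdiff(CSV_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  vraw <- trimws(raw$value)
  bad <- which(!(vraw == "" | grepl("^[0-9eE+.\\-]+$", vraw)))
  if (length(bad) > 0) {
    stop("validation error: non-numeric value '", vraw[bad[1]], "' at row ",
         bad[1], " (nondetects must use an empty value with censored=TRUE)")
  }
  raw$value <- suppressWarnings(as.numeric(vraw))
  raw$censored <- as.logical(raw$censored)
  if (!"sample_type" %in% names(raw)) raw$sample_type <- "fillet"
  replicates <- unique(raw[REPLICATE_COLS])
  fishrisk_dataset(raw[MEASUREMENT_COLS], replicates = replicates,
                   catalog = catalog)
}

#' Write measurements to a long CSV file
#'
#' Inverse of [read_measurements()]: emits one row per measurement with the
#' replicate metadata repeated, so that reading the file back reproduces the
#' dataset losslessly (an empty dataset yields a header-only file).
#'
#' @param dataset a `fishrisk_dataset`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(dataset, path) {
  validate_dataset(dataset)
  out <- merge(dataset$measurements, dataset$replicates,
               by = c("species", "year", "composite_id", "replicate_id"),
               sort = FALSE)
  out <- out[c(CSV_COLS, "sample_type")]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the analyte catalog as a JSON sidecar
#'
#' @param catalog data.frame as from [default_catalog()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(catalog, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read an analyte catalog JSON sidecar
#'
#' @param path path to a JSON file written by [write_catalog()].
#' @return data.frame with columns `analyte_id`, `chem_class`,
#'   `is_dioxin_like`.
#' @export
read_catalog <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
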