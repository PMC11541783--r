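#' @keywords internal
"_PACKAGE"

CHEM_CLASSES <- c("PCB", "PBDE", "DIOXIN_FURAN", "PFAS")

SPECIES_LEVELS <- c(
  "Alewife", "American Shad Roe", "American Shad Fillet", "Blueback Herring",
  "Rainbow Smelt", "Rainbow Smelt large", "Rainbow Smelt small",
  "Striped Bass", "Sea Lamprey"
)

MEASUREMENT_COLS <- c(
  "species", "year", "composite_id", "replicate_id", "analyte_id",
  "chem_class", "value", "detection_limit", "censored"
)

REPLICATE_COLS <- c(
  "species", "year", "composite_id", "replicate_id",
  "n_fish", "pct_moisture", "pct_lipids", "sample_type"
)

#' Construct a residue dataset
#'
#' Bundles congener-level measurements, composite/replicate metadata and the
#' analyte catalog into a validated `fishrisk_dataset`. One measurement row is
#' one analyte observation in one technical replicate of one composite sample;
#' nondetects carry `censored = TRUE`, an empty `value` and a positive
#' detection limit (ng/g wet weight throughout).
#'
#' @param measurements data.frame with columns `species`, `year`,
#'   `composite_id`, `replicate_id`, `analyte_id`, `chem_class`, `value`
#'   (NA when censored), `detection_limit`, `censored`.
#' @param replicates data.frame of replicate metadata (`species`, `year`,
#'   `composite_id`, `replicate_id`, `n_fish`, `pct_moisture`, `pct_lipids`,
#'   `sample_type`). Derived from `measurements` when `NULL` (metadata filled
#'   with NA, `sample_type` "fillet").
#' @param catalog data.frame (`analyte_id`, `chem_class`, `is_dioxin_like`);
#'   defaults to the bundled catalog, extended with any unlisted analytes
#'   present in `measurements` (marked not dioxin-like).
#' @return An object of class `fishrisk_dataset`: a list with elements
#'   `measurements`, `replicates`, `catalog`.
#' @export
fishrisk_dataset <- function(measurements, replicates = NULL, catalog = NULL) {
  measurements <- as.data.frame(measurements)
  missing_cols <- setdiff(MEASUREMENT_COLS, names(measurements))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(replicates)) {
    meta_cols <- intersect(REPLICATE_COLS, names(measurements))
    replicates <- unique(measurements[meta_cols])
    for (col in setdiff(REPLICATE_COLS, names(replicates))) {
      replicates[[col]] <- if (col == "sample_type") "fillet" else NA_real_
    }
    replicates <- replicates[REPLICATE_COLS]
  } else {
    replicates <- as.data.frame(replicates)
    if (!"sample_type" %in% names(replicates)) replicates$sample_type <- "fillet"
    replicates <- replicates[REPLICATE_COLS]
  }
  rownames(replicates) <- NULL

  if (is.null(catalog)) catalog <- default_catalog()
  extra <- setdiff(measurements$analyte_id, catalog$analyte_id)
  if (length(extra) > 0) {
    cls <- measurements$chem_class[match(extra, measurements$analyte_id)]
    catalog <- rbind(catalog, data.frame(
      analyte_id = extra, chem_class = cls, is_dioxin_like = FALSE,
      stringsAsFactors = FALSE
    ))
  }

  ds <- structure(
    list(
      measurements = measurements[c(MEASUREMENT_COLS)],
      replicates = replicates,
      catalog = catalog
    ),
    class = "fishrisk_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate a residue dataset
#'
#' Checks the invariants of the measurement rows: positive detection limits,
#' no value on censored rows, nonnegative detected values, known chemical
#' classes, metadata percentages in `[0, 100]`, replicate ids unique within a
#' composite, and every analyte present in the catalog.
#'
#' @param dataset a `fishrisk_dataset`.
#' @return Invisibly `TRUE`; stops with a descriptive error (naming the first
#'   offending row) otherwise.
#' @export
validate_dataset <- function(dataset) {
  m <- dataset$measurements
  bad <- which(!m$chem_class %in% CHEM_CLASSES)
  if (length(bad) > 0) {
    stop("validation error: unknown chem_class '", m$chem_class[bad[1]],
         "' at row ", bad[1])
  }
  if (!is.logical(m$censored) || anyNA(m$censored)) {
    stop("validation error: 'censored' must be TRUE/FALSE with no missing values")
  }
  bad <- which(!(m$detection_limit > 0))
  if (length(bad) > 0) {
    stop("validation error: detection_limit must be > 0 at row ", bad[1])
  }
  bad <- which(m$censored & !is.na(m$value))
  if (length(bad) > 0) {
    stop("validation error: censored row carries a value at row ", bad[1])
  }
  bad <- which(!m$censored & (is.na(m$value) | m$value < 0))
  if (length(bad) > 0) {
    stop("validation error: detected row needs a nonnegative value at row ", bad[1])
  }
  r <- dataset$replicates
  for (col in c("pct_moisture", "pct_lipids")) {
    v <- r[[col]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop("validation error: ", col, " outside [0, 100]")
    }
  }
  if (anyDuplicated(r[c("composite_id", "replicate_id")]) > 0) {
    stop("validation error: replicate_id not unique within composite")
  }
  missing_analytes <- setdiff(m$analyte_id, dataset$catalog$analyte_id)
  if (length(missing_analytes) > 0) {
    stop("validation error: analyte(s) absent from catalog: ",
         paste(utils::head(missing_analytes, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.fishrisk_dataset <- function(x, ...) {
  m <- x$measurements
  cat("<fishrisk_dataset>\n")
  cat("  measurements:", nrow(m), "rows,",
      sum(m$censored), "censored (",
      if (nrow(m) > 0) sprintf("%.1f%%", 100 * mean(m$censored)) else "-", ")\n")
  cat("  replicates:  ", nrow(x$replicates), "in",
      length(unique(x$replicates$composite_id)), "composites,",
      length(unique(paste(x$replicates$species, x$replicates$year))),
      "species-year groups\n")
  cat("  classes:     ",
      paste(names(table(m$chem_class)), table(m$chem_class),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Keep measurements of one chemical class
#'
#' Subsets the measurement rows to a single chemical class while preserving
#' the replicate/composite structure: replicates left with zero measurements
#' remain present in the metadata so downstream grouping stays intact.
#'
#' @param dataset a `fishrisk_dataset`.
#' @param chem_class one of `"PCB"`, `"PBDE"`, `"DIOXIN_FURAN"`, `"PFAS"`.
#' @return A `fishrisk_dataset` with only the requested class.
#' @export
filter_class <- function(dataset, chem_class) {
  chem_class <- match.arg(chem_class, CHEM_CLASSES)
  out <- dataset
  out$measurements <- dataset$measurements[dataset$measurements$chem_class == chem_class, , drop = FALSE]
  rownames(out$measurements) <- NULL
  out
}

#' Merge residue datasets
#'
#' Row-binds the measurements of several datasets sharing a catalog, deduplicating
#' replicate metadata. Used to reassemble a dataset from per-class filters.
#'
#' @param ... `fishrisk_dataset` objects.
#' @return A combined `fishrisk_dataset`.
#' @export
merge_datasets <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  meas <- do.call(rbind, lapply(parts, `[[`, "measurements"))
  reps <- unique(do.call(rbind, lapply(parts, `[[`, "replicates")))
  rownames(meas) <- rownames(reps) <- NULL
  cats <- unique(do.call(rbind, lapply(parts, `[[`, "catalog")))
  fishrisk_dataset(meas, replicates = reps, catalog = cats)
}
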