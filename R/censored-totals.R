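# Chemical-class totals under left-censoring.
#
# A replicate's class total is n_analytes times the mean of the analyte
# concentrations, treating the panel as a left-censored sample: nondetects are
# known only to lie below their detection limits. The Kaplan-Meier route flips
# the data (x -> M - x), fits the right-censored product-limit estimator, takes
# the restricted mean and flips back; this avoids substituting any fraction of
# the detection limit. When censoring is too heavy for the product-limit
# estimator, the half-detection-limit substitution is used instead.

# Kaplan-Meier mean of a left-censored sample via the flipping construction.
# Restricted to the observed range (Efron convention: the survival curve is
# truncated at the largest flipped observation, which pins the smallest
# censored concentration at its detection limit).
km_mean_left <- function(value, detection_limit, censored) {
  x <- ifelse(censored, detection_limit, value)
  M <- max(x)
  y <- M - x
  event <- as.integer(!censored)
  fit <- survival::survfit(survival::Surv(y, event) ~ 1)
  times <- c(0, fit$time)
  surv <- c(1, fit$surv)
  e_y <- sum(diff(times) * surv[-length(surv)])
  M - e_y
}

class_total_row <- function(panel, total, method) {
  meta <- c("species", "year", "composite_id", "replicate_id")
  out <- data.frame(
    chem_class = panel$chem_class[1],
    total = total,
    method = method,
    n_analytes = nrow(panel),
    n_censored = sum(panel$censored),
    stringsAsFactors = FALSE
  )
  present <- intersect(meta, names(panel))
  if (length(present) > 0) out <- cbind(panel[1, present, drop = FALSE], out)
  rownames(out) <- NULL
  out
}

check_panel <- function(panel) {
  if (is.null(panel) || nrow(panel) == 0) stop("empty panel")
  if (length(unique(panel$chem_class)) != 1) {
    stop("panel must contain a single chem_class")
  }
  invisible(TRUE)
}

#' Kaplan-Meier class total for one replicate panel
#'
#' Estimates the class total for a single replicate's analyte panel as
#' `n_analytes` times the Kaplan-Meier mean of the left-censored
#' concentration sample (flipping construction; ties between a detected value
#' and an equal detection limit rank the detected value above the nondetect).
#' With no censoring this reduces exactly to the simple sum and is recorded
#' with method `"SIMPLE_SUM"`.
#'
#' @param panel data.frame of measurements of one chemical class (columns
#'   `value`, `detection_limit`, `censored`, `chem_class`; replicate metadata
#'   columns are carried through when present).
#' @param fallback_threshold censoring fraction above which the product-limit
#'   mean is considered unreliable (default 0.8); panels above it, or with
#'   fewer than two detected values, raise a condition of class
#'   `fishrisk_km_infeasible` so the caller can fall back to
#'   [half_dl_total()].
#' @return One-row data.frame (a `ClassTotal`): `total`, `method`,
#'   `n_analytes`, `n_censored` plus any metadata columns.
#' @export
km_total <- function(panel, fallback_threshold = 0.8) {
  check_panel(panel)
  n_det <- sum(!panel$censored)
  cen_frac <- mean(panel$censored)
  if (cen_frac == 0) {
    return(class_total_row(panel, sum(panel$value), "SIMPLE_SUM"))
  }
  if (n_det == 0 || cen_frac > fallback_threshold || n_det < 2) {
    cond <- structure(
      class = c("fishrisk_km_infeasible", "error", "condition"),
      list(message = sprintf(
        "KM infeasible: %d/%d analytes censored (threshold %.2f)",
        sum(panel$censored), nrow(panel), fallback_threshold
      ), call = sys.call(-1))
    )
    stop(cond)
  }
  km_mean <- km_mean_left(panel$value, panel$detection_limit, panel$censored)
  class_total_row(panel, nrow(panel) * km_mean, "KAPLAN_MEIER")
}

#' Half-detection-limit class total
#'
#' Substitution estimator: detected values enter at face value, nondetects at
#' half their detection limit. Used as the fallback when censoring is too
#' heavy for the Kaplan-Meier estimator.
#'
#' @inheritParams km_total
#' @return One-row data.frame with method `"HALF_DL"`.
#' @export
half_dl_total <- function(panel) {
  check_panel(panel)
  total <- sum(panel$value[!panel$censored]) +
    sum(panel$detection_limit[panel$censored] / 2)
  class_total_row(panel, total, "HALF_DL")
}

#' Per-replicate class totals for a dataset
#'
#' Computes one class total per replicate for the requested chemical class:
#' the Kaplan-Meier estimator is attempted first and the half-detection-limit
#' substitution is used for replicates whose censoring makes the
#' product-limit mean infeasible (including fully censored panels). The
#' method actually used is recorded per replicate.
#'
#' @param dataset a `fishrisk_dataset`.
#' @param chem_class chemical class to total.
#' @param fallback_threshold see [km_total()].
#' @return data.frame of `ClassTotal` rows, one per replicate that carries
#'   measurements of the class.
#' @export
class_totals <- function(dataset, chem_class, fallback_threshold = 0.8) {
  chem_class <- match.arg(chem_class, CHEM_CLASSES)
  m <- dataset$measurements[dataset$measurements$chem_class == chem_class, , drop = FALSE]
  if (nrow(m) == 0) {
    return(data.frame(
      species = character(), year = integer(), composite_id = character(),
      replicate_id = character(), chem_class = character(), total = numeric(),
      method = character(), n_analytes = integer(), n_censored = integer(),
      stringsAsFactors = FALSE
    ))
  }
  key <- interaction(m$composite_id, m$replicate_id, drop = TRUE)
  rows <- lapply(split(m, key), function(panel) {
    tryCatch(
      km_total(panel, fallback_threshold = fallback_threshold),
      fishrisk_km_infeasible = function(e) half_dl_total(panel)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$species, out$year, out$composite_id, out$replicate_id), ,
      drop = FALSE]
}
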