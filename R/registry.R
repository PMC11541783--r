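# Toxicity-reference registry: TEFs, reference doses, cancer slope factor,
# wildlife values, whole-fish conversion factors and exposure parameters,
# each held in a fixed canonical unit so mixed-unit arithmetic cannot occur:
#   concentrations       ng/g wet weight
#   noncancer doses/RfDs ng/kg body weight per day
#   cancer doses         mg/kg-day (conversion at the cancer-risk boundary)
#   wildlife values      ng/g whole-fish wet weight

# WHO 2005 mammalian toxic equivalency factors: 7 dioxins, 10 furans and the
# 12 dioxin-like (coplanar) PCBs, relative to 2,3,7,8-TCDD = 1.
who2005_tefs <- function() {
  c(
    "2,3,7,8-TCDD" = 1, "1,2,3,7,8-PeCDD" = 1,
    "1,2,3,4,7,8-HxCDD" = 0.1, "1,2,3,6,7,8-HxCDD" = 0.1,
    "1,2,3,7,8,9-HxCDD" = 0.1, "1,2,3,4,6,7,8-HpCDD" = 0.01,
    "OCDD" = 0.0003,
    "2,3,7,8-TCDF" = 0.1, "1,2,3,7,8-PeCDF" = 0.03, "2,3,4,7,8-PeCDF" = 0.3,
    "1,2,3,4,7,8-HxCDF" = 0.1, "1,2,3,6,7,8-HxCDF" = 0.1,
    "1,2,3,7,8,9-HxCDF" = 0.1, "2,3,4,6,7,8-HxCDF" = 0.1,
    "1,2,3,4,6,7,8-HpCDF" = 0.01, "1,2,3,4,7,8,9-HpCDF" = 0.01,
    "OCDF" = 0.0003,
    "PCB-77" = 0.0001, "PCB-81" = 0.0003, "PCB-126" = 0.1, "PCB-169" = 0.03,
    "PCB-105" = 0.00003, "PCB-114" = 0.00003, "PCB-118" = 0.00003,
    "PCB-123" = 0.00003, "PCB-156" = 0.00003, "PCB-157" = 0.00003,
    "PCB-167" = 0.00003, "PCB-189" = 0.00003
  )
}

#' Default exposure parameters
#'
#' Subsistence-consumption scenario: ingestion rate 40 g/day (the tribal
#' fish-advisory rate), adult body weight 80 kg, daily exposure
#' (exposure factor 1), 30-year exposure duration over a 78-year life
#' expectancy (used only by the cancer-risk calculation).
#'
#' @return list with `ingestion_rate_g_day`, `body_weight_kg`,
#'   `exposure_factor`, `exposure_duration_years`, `life_expectancy_years`.
#' @export
default_exposure <- function() {
  list(
    ingestion_rate_g_day = 40,
    body_weight_kg = 80,
    exposure_factor = 1,
    exposure_duration_years = 30,
    life_expectancy_years = 78
  )
}

#' Default toxicity-reference registry
#'
#' All reference constants used by the risk engine, in canonical units:
#' WHO 2005 mammalian TEFs; oral reference doses in ng/kg-BW/day
#' (Aroclor 1016 = 70, Aroclor 1254 = 20, BDE-99 = 100,
#' 2,3,7,8-TCDD TEQ = 0.0007, PFOS = 0.1 i.e. 1e-7 mg/kg-day,
#' PFHxA = 500, PFBA = 1000); the oral cancer slope factor 1.3e5
#' (mg/kg-day)^-1 for TCDD-like mixtures; wildlife values in ng/g whole-fish
#' wet weight (mink/total PCBs 72, American kestrel/total PBDEs 8.7, the
#' derived generic 2,3,7,8-TCDD value 6.2e-5, Canadian PFOS values 4.6 for
#' mammals and 8.2 for birds); and fillet-to-whole-fish conversion factors
#' (PCB and dioxin/furan 1.83, PBDE 1.5, PFOS 2.13 - the only PFAS with a
#' published factor).
#'
#' @return An object of class `toxicity_registry`.
#' @export
default_registry <- function() {
  structure(
    list(
      tefs = who2005_tefs(),
      rfds = c(
        aroclor_1016 = 70, aroclor_1254 = 20, bde_99 = 100,
        tcdd_teq = 0.0007, pfos = 0.1, pfhxa = 500, pfba = 1000
      ),
      slope_factor = 1.3e5,
      exposure = default_exposure(),
      wildlife_values = data.frame(
        receptor = c("MINK", "KESTREL", "TCDD_GENERIC", "MAMMAL_CA", "BIRD_CA"),
        chemical = c("PCB", "PBDE", "TCDD", "PFOS", "PFOS"),
        wv = c(72, 8.7, derive_dioxin_wv(), 4.6, 8.2),
        stringsAsFactors = FALSE
      ),
      conversion_factors = c(
        PCB = 1.83, DIOXIN_FURAN = 1.83, PBDE = 1.5, PFOS = 2.13
      )
    ),
    class = "toxicity_registry"
  )
}

#' @export
print.toxicity_registry <- function(x, ...) {
  cat("<toxicity_registry>\n")
  cat("  TEFs:", length(x$tefs), "dioxin-like congeners (WHO 2005 mammalian)\n")
  cat("  RfDs (ng/kg-BW/day):",
      paste(names(x$rfds), signif(x$rfds, 3), sep = "=", collapse = ", "), "\n")
  cat("  slope factor:", format(x$slope_factor), "(mg/kg-day)^-1\n")
  cat("  exposure: IR", x$exposure$ingestion_rate_g_day, "g/day, BW",
      x$exposure$body_weight_kg, "kg, EF", x$exposure$exposure_factor,
      ", ED/LE", x$exposure$exposure_duration_years, "/",
      x$exposure$life_expectancy_years, "years\n")
  cat("  wildlife values:", nrow(x$wildlife_values), "receptor-chemical pairs\n")
  invisible(x)
}

#' Derive the generic dioxin wildlife value
#'
#' Wildlife value for 2,3,7,8-TCDD in whole fish: the ambient water-quality
#' standard multiplied by the bioconcentration factor and by the
#' bioaccumulation factor, arithmetically averaged. With the default inputs
#' (3.1e-9 ug/L, BCF 15,000 L/kg, BAF 25,000 L/kg) this gives 6.2e-5 ng/g
#' (ug/kg and ng/g being the same scale).
#'
#' @param water_standard_ug_l water-quality standard, ug/L.
#' @param bcf bioconcentration factor, L/kg.
#' @param baf bioaccumulation factor, L/kg.
#' @return Wildlife value in ng/g wet weight.
#' @export
derive_dioxin_wv <- function(water_standard_ug_l = 3.1e-9, bcf = 15000,
                             baf = 25000) {
  if (any(c(water_standard_ug_l, bcf, baf) <= 0)) {
    stop("all inputs must be positive")
  }
  mean(c(water_standard_ug_l * bcf, water_standard_ug_l * baf))
}

# Override config: flat "key = value unit" lines; '#' starts a comment.
# Units are mandatory suffix tags checked per key family and converted to
# the canonical units above.
registry_key_units <- function() {
  list(
    rfd = c(ng_per_kg_day = 1, mg_per_kg_day = 1e6),
    tef = c(dimensionless = 1),
    slope_factor = c(per_mg_kg_day = 1),
    wv = c(ng_per_g = 1),
    cf = c(dimensionless = 1),
    exposure = NULL  # handled per sub-key below
  )
}

exposure_key_units <- function() {
  list(
    ingestion_rate = c(g_per_day = 1),
    body_weight = c(kg = 1),
    exposure_factor = c(dimensionless = 1),
    exposure_duration = c(years = 1),
    life_expectancy = c(years = 1)
  )
}

#' Load a toxicity registry with user overrides
#'
#' Reads a flat key/value override file and merges it over
#' [default_registry()]. Lines have the form `key = value unit`; units are
#' mandatory and checked against the key family, e.g.
#' `rfd.pfos = 1e-7 mg_per_kg_day` (converted to the canonical
#' ng/kg-BW/day), `exposure.ingestion_rate = 32 g_per_day`,
#' `cf.PFOS = 2.13 dimensionless`, `wv.MINK.PCB = 72 ng_per_g`,
#' `tef.PCB-126 = 0.1 dimensionless`. Unknown keys and unit mismatches are
#' errors; an empty file returns the defaults unchanged.
#'
#' @param path path to the override file (missing/empty yields defaults).
#' @return A `toxicity_registry`.
#' @export
load_registry <- function(path = NULL) {
  reg <- default_registry()
  if (is.null(path)) return(reg)
  if (!file.exists(path)) stop("registry override file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  fam_units <- registry_key_units()
  exp_units <- exposure_key_units()
  for (line in lines) {
    m <- regmatches(line, regexec("^([^=]+)=\\s*(\\S+)\\s+(\\S+)$", line))[[1]]
    if (length(m) != 4) {
      stop("cannot parse registry line (need 'key = value unit'): ", line)
    }
    key <- trimws(m[2]); val <- suppressWarnings(as.numeric(m[3])); unit <- m[4]
    if (is.na(val)) stop("non-numeric value in registry line: ", line)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    family <- parts[1]
    if (!family %in% names(fam_units)) {
      stop("unknown registry key '", key, "'; valid key families: ",
           paste(names(fam_units), collapse = ", "))
    }
    if (family == "exposure") {
      sub <- parts[2]
      if (length(parts) != 2 || !sub %in% names(exp_units)) {
        stop("unknown exposure key '", key, "'; valid: ",
             paste0("exposure.", names(exp_units), collapse = ", "))
      }
      units <- exp_units[[sub]]
      if (!unit %in% names(units)) {
        stop("unit mismatch for '", key, "': got '", unit, "', expected ",
             paste(names(units), collapse = " or "))
      }
      slot <- switch(sub,
        ingestion_rate = "ingestion_rate_g_day",
        body_weight = "body_weight_kg",
        exposure_factor = "exposure_factor",
        exposure_duration = "exposure_duration_years",
        life_expectancy = "life_expectancy_years"
      )
      reg$exposure[[slot]] <- val * units[[unit]]
      next
    }
    units <- fam_units[[family]]
    if (!unit %in% names(units)) {
      stop("unit mismatch for '", key, "': got '", unit, "', expected ",
           paste(names(units), collapse = " or "))
    }
    val <- val * units[[unit]]
    if (family == "rfd") {
      reg$rfds[parts[2]] <- val
    } else if (family == "tef") {
      reg$tefs[paste(parts[-1], collapse = ".")] <- val
    } else if (family == "slope_factor") {
      reg$slope_factor <- val
    } else if (family == "cf") {
      reg$conversion_factors[parts[2]] <- val
    } else if (family == "wv") {
      if (length(parts) != 3) stop("wv keys have the form wv.<RECEPTOR>.<CHEMICAL>", call. = FALSE)
      sel <- reg$wildlife_values$receptor == parts[2] &
        reg$wildlife_values$chemical == parts[3]
      if (any(sel)) {
        reg$wildlife_values$wv[sel] <- val
      } else {
        reg$wildlife_values <- rbind(
          reg$wildlife_values,
          data.frame(receptor = parts[2], chemical = parts[3], wv = val,
                     stringsAsFactors = FALSE)
        )
      }
    }
  }
  check_registry(reg)
  reg
}

# Invariants: positive RfDs, conversion factors >= 1, reference congener TEF 1.
check_registry <- function(reg) {
  if (any(reg$rfds <= 0)) stop("registry invariant violated: RfDs must be > 0")
  if (any(reg$conversion_factors < 1)) {
    stop("registry invariant violated: conversion factors must be >= 1")
  }
  if (!isTRUE(all.equal(unname(reg$tefs["2,3,7,8-TCDD"]), 1))) {
    stop("registry invariant violated: TEF(2,3,7,8-TCDD) must be 1")
  }
  invisible(TRUE)
}
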