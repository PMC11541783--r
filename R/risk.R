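# Human-health and wildlife risk arithmetic.
#
# Dose (ng/kg-BW/day) = concentration (ng/g ww) x ingestion rate (g/day)
#                       x exposure factor / body weight (kg)
# HQ = dose / RfD (same units); HQ < 1 indicates minimal noncancer risk.
# Cancer risk = lifetime-average daily dose (mg/kg-day) x oral slope factor
#               x (exposure duration / life expectancy).

#' Toxic equivalents (TEQ) of a dioxin-like congener panel
#'
#' TEF-weighted sum expressing a mixture of dioxins, furans and coplanar
#' PCBs as a single 2,3,7,8-TCDD-equivalent concentration. Nondetected
#' congeners contribute zero (`nd_policy = "ZERO"`, default) or half their
#' detection limit (`"HALF_DL"`).
#'
#' @param panel either a named numeric vector of detected concentrations
#'   (ng/g ww) or a data.frame with `analyte_id`, `value`, `detection_limit`,
#'   `censored`.
#' @param tefs named TEF vector (default WHO 2005 mammalian, from
#'   [default_registry()]).
#' @param nd_policy `"ZERO"` or `"HALF_DL"`.
#' @return list with `teq` (ng TEQ/g ww), `nd_policy`, `congeners_used`.
#' @export
teq <- function(panel, tefs = default_registry()$tefs,
                nd_policy = c("ZERO", "HALF_DL")) {
  nd_policy <- match.arg(nd_policy)
  if (is.numeric(panel)) {
    panel <- data.frame(analyte_id = names(panel), value = unname(panel),
                        detection_limit = NA_real_, censored = FALSE,
                        stringsAsFactors = FALSE)
  }
  missing_tef <- setdiff(panel$analyte_id, names(tefs))
  if (length(missing_tef) > 0) {
    stop("no TEF for dioxin-like analyte(s): ",
         paste(missing_tef, collapse = ", "))
  }
  tf <- tefs[panel$analyte_id]
  conc <- ifelse(panel$censored,
                 if (nd_policy == "ZERO") 0 else panel$detection_limit / 2,
                 panel$value)
  if (any(conc < 0)) stop("negative concentration in TEQ panel")
  list(teq = sum(tf * conc), nd_policy = nd_policy,
       congeners_used = nrow(panel))
}

#' Human exposure dose from a tissue concentration
#'
#' @param conc_ng_g concentration in fish tissue, ng/g wet weight.
#' @param exposure exposure parameters (see [default_exposure()]).
#' @return Dose in ng/kg-BW/day.
#' @export
exposure_dose <- function(conc_ng_g, exposure = default_exposure()) {
  if (any(conc_ng_g < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  conc_ng_g * exposure$ingestion_rate_g_day * exposure$exposure_factor /
    exposure$body_weight_kg
}

#' Noncancer hazard quotient
#'
#' @param dose exposure dose, ng/kg-BW/day.
#' @param rfd reference dose, ng/kg-BW/day (must be positive).
#' @return Dimensionless HQ = dose / RfD.
#' @export
hazard_quotient <- function(dose, rfd) {
  if (any(rfd <= 0)) stop("RfD must be > 0")
  dose / rfd
}

#' Lifetime cancer risk from a TEQ concentration
#'
#' Lifetime-average daily dose is the TEQ tissue concentration (mg/kg ww)
#' times the ingestion rate (converted to kg/day) over body weight, scaled
#' by the exposure duration over the life expectancy; risk is dose times the
#' oral cancer slope factor.
#'
#' @param teq_mg_kg TEQ concentration in tissue, mg/kg wet weight
#'   (1 ng/g = 1e-3 mg/kg).
#' @param slope_factor oral cancer slope factor, (mg/kg-day)^-1.
#' @param exposure exposure parameters (see [default_exposure()]).
#' @return list with `dose_mg_kg_day` and `risk` (dimensionless lifetime
#'   excess probability).
#' @export
cancer_risk <- function(teq_mg_kg, slope_factor = default_registry()$slope_factor,
                        exposure = default_exposure()) {
  if (any(teq_mg_kg < 0)) stop("TEQ concentration must be >= 0")
  ir_kg_day <- exposure$ingestion_rate_g_day / 1000
  dose <- teq_mg_kg * ir_kg_day * exposure$exposure_factor /
    exposure$body_weight_kg
  risk <- dose * slope_factor *
    exposure$exposure_duration_years / exposure$life_expectancy_years
  list(dose_mg_kg_day = dose, risk = risk)
}

#' Fillet-to-whole-fish concentration conversion
#'
#' Multiplies a fillet (or analyzed-portion) concentration by the chemical
#' group's whole-body conversion factor (PCB and dioxin/furan 1.83, PBDE
#' 1.5, PFOS 2.13). Chemicals without a published factor (all PFAS other
#' than PFOS) yield an explicit `NA` flagged with
#' `attr(, "reason") = "no conversion factor"` rather than a silent value.
#'
#' @param conc_ng_g portion concentration, ng/g wet weight.
#' @param chemical key into the conversion-factor table (`"PCB"`, `"PBDE"`,
#'   `"DIOXIN_FURAN"`, `"PFOS"`, ...).
#' @param conversion_factors named factor vector (from the registry).
#' @return Whole-fish concentration in ng/g ww, or flagged `NA`.
#' @export
whole_fish_convert <- function(conc_ng_g, chemical,
                               conversion_factors = default_registry()$conversion_factors) {
  if (any(conc_ng_g < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  if (!chemical %in% names(conversion_factors)) {
    return(structure(NA_real_, reason = "no conversion factor"))
  }
  conc_ng_g * conversion_factors[[chemical]]
}

#' Wildlife-value screening of a whole-fish concentration
#'
#' Compares a whole-fish concentration to every applicable wildlife value:
#' total PCBs against the mink value, total PBDEs against the American
#' kestrel value, 2,3,7,8-TCDD against the derived generic value, and PFOS
#' against the Canadian mammal and bird values. Exceedance is strict
#' (`conc > WV`); a chemical with no applicable receptor yields an empty
#' frame.
#'
#' @param whole_fish_conc whole-fish concentration, ng/g ww.
#' @param chemical `"PCB"`, `"PBDE"`, `"TCDD"` or `"PFOS"`.
#' @param registry a `toxicity_registry`.
#' @return data.frame (`WildlifeScreen` rows): `receptor`, `chemical`,
#'   `whole_fish_conc`, `wildlife_value`, `exceeds`.
#' @export
wv_screen <- function(whole_fish_conc, chemical,
                      registry = default_registry()) {
  wv <- registry$wildlife_values
  wv <- wv[wv$chemical == chemical, , drop = FALSE]
  if (nrow(wv) == 0 || is.na(whole_fish_conc)) {
    return(data.frame(receptor = character(), chemical = character(),
                      whole_fish_conc = numeric(), wildlife_value = numeric(),
                      exceeds = logical(), stringsAsFactors = FALSE))
  }
  data.frame(
    receptor = wv$receptor, chemical = wv$chemical,
    whole_fish_conc = whole_fish_conc, wildlife_value = wv$wv,
    exceeds = whole_fish_conc > wv$wv,
    stringsAsFactors = FALSE
  )
}
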