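# Assembly of the three risk reports:
#   hq_table       noncancer doses and hazard quotients per species x year
#   cancer_table   TEQ-based lifetime cancer risk per species (years pooled)
#   wildlife_table whole-fish conversions and wildlife-value screening

# Mean of one analyte across the replicates of a group, treating the
# replicate values as a left-censored sample. NA when nothing was detected
# (reported as a blank cell: no HQ is derived for a nondetected chemical).
analyte_mean <- function(value, detection_limit, censored) {
  det <- !censored
  if (!any(det)) return(NA_real_)
  if (all(det)) return(mean(value))
  if (sum(det) >= 2 && mean(censored) <= 0.8) {
    return(km_mean_left(value, detection_limit, censored))
  }
  mean(c(value[det], detection_limit[censored] / 2))
}

# Replicate-level TEQ over the dioxin-like analytes (17 dioxins/furans plus
# 12 coplanar PCBs per the catalog flag).
replicate_teqs <- function(dataset, registry = default_registry(),
                           nd_policy = "ZERO") {
  dl_analytes <- dataset$catalog$analyte_id[dataset$catalog$is_dioxin_like]
  m <- dataset$measurements
  m <- m[m$analyte_id %in% dl_analytes, , drop = FALSE]
  if (nrow(m) == 0) {
    return(data.frame(species = character(), year = integer(),
                      composite_id = character(), replicate_id = character(),
                      teq = numeric(), stringsAsFactors = FALSE))
  }
  key <- interaction(m$composite_id, m$replicate_id, drop = TRUE)
  rows <- lapply(split(m, key), function(panel) {
    data.frame(
      species = panel$species[1], year = panel$year[1],
      composite_id = panel$composite_id[1],
      replicate_id = panel$replicate_id[1],
      teq = teq(panel, tefs = registry$tefs, nd_policy = nd_policy)$teq,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Design-based group mean when >= 2 composites, plain mean otherwise.
group_mean <- function(total, composite_id) {
  if (length(unique(composite_id)) >= 2) {
    cluster_mean_var(total, composite_id)$mean
  } else {
    mean(total)
  }
}

group_analyte_mean <- function(m, analyte) {
  sub <- m[m$analyte_id == analyte, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  analyte_mean(sub$value, sub$detection_limit, sub$censored)
}

#' Build the three risk report tables
#'
#' Runs the whole assessment on a dataset: per-replicate class totals and
#' TEQs, species x year group means, human doses and hazard quotients, the
#' pooled-year cancer-risk table, and the whole-fish wildlife screen.
#'
#' The HQ table carries, per species x year: the total-PCB dose with HQs
#' against both the Aroclor 1016 and Aroclor 1254 RfDs; the BDE-99 congener
#' dose and HQ; the dioxin/furan/coplanar-PCB TEQ dose and HQ against the
#' 2,3,7,8-TCDD RfD; and the PFOS dose and HQ. Chemicals never detected in a
#' group are left as `NA` (blank cells). The cancer table pools both
#' collection years per species (size classes of one species are pooled
#' together). The wildlife table excludes roe samples (by sample-type
#' metadata) and screens converted whole-fish concentrations against the
#' applicable wildlife values with strict exceedance.
#'
#' @param dataset a `fishrisk_dataset`.
#' @param registry a `toxicity_registry`.
#' @param nd_policy TEQ nondetect policy, `"ZERO"` (default) or `"HALF_DL"`.
#' @param fallback_threshold see [km_total()].
#' @return list with data.frames `hq_table`, `cancer_table`,
#'   `wildlife_table`.
#' @export
build_reports <- function(dataset, registry = default_registry(),
                          nd_policy = "ZERO", fallback_threshold = 0.8) {
  validate_dataset(dataset)
  exposure <- registry$exposure
  m <- dataset$measurements

  tot_pcb <- class_totals(dataset, "PCB", fallback_threshold)
  tot_pbde <- class_totals(dataset, "PBDE", fallback_threshold)
  tot_df <- class_totals(dataset, "DIOXIN_FURAN", fallback_threshold)
  teqs <- replicate_teqs(dataset, registry, nd_policy)

  groups <- unique(dataset$replicates[c("species", "year")])
  groups <- groups[order(groups$species, groups$year), , drop = FALSE]

  hq_rows <- lapply(seq_len(nrow(groups)), function(i) {
    sp <- groups$species[i]; yr <- groups$year[i]
    gm <- m[m$species == sp & m$year == yr, , drop = FALSE]
    pick <- function(tt) tt[tt$species == sp & tt$year == yr, , drop = FALSE]

    pcb <- pick(tot_pcb)
    pcb_conc <- if (nrow(pcb) > 0) group_mean(pcb$total, pcb$composite_id) else NA
    bde99_conc <- group_analyte_mean(gm, "BDE-99")
    tq <- pick(teqs)
    teq_conc <- if (nrow(tq) > 0) group_mean(tq$teq, tq$composite_id) else NA
    pfos_conc <- group_analyte_mean(gm, "PFOS")

    dose <- function(conc) if (is.na(conc)) NA_real_ else exposure_dose(conc, exposure)
    hq <- function(d, rfd) if (is.na(d)) NA_real_ else hazard_quotient(d, rfd)

    pcb_dose <- dose(pcb_conc); bde99_dose <- dose(bde99_conc)
    teq_dose <- dose(teq_conc); pfos_dose <- dose(pfos_conc)
    data.frame(
      species = sp, year = yr,
      pcb_conc = pcb_conc, pcb_dose = pcb_dose,
      hq_aroclor_1016 = hq(pcb_dose, registry$rfds[["aroclor_1016"]]),
      hq_aroclor_1254 = hq(pcb_dose, registry$rfds[["aroclor_1254"]]),
      bde99_conc = bde99_conc, bde99_dose = bde99_dose,
      bde99_hq = hq(bde99_dose, registry$rfds[["bde_99"]]),
      teq_conc = teq_conc, teq_dose = teq_dose,
      teq_hq = hq(teq_dose, registry$rfds[["tcdd_teq"]]),
      pfos_conc = pfos_conc, pfos_dose = pfos_dose,
      pfos_hq = hq(pfos_dose, registry$rfds[["pfos"]]),
      stringsAsFactors = FALSE
    )
  })
  hq_table <- do.call(rbind, hq_rows)

  # Cancer risk: collection year not considered; size classes pooled.
  if (nrow(teqs) > 0) {
    pool <- sub(",? ?(large|small)$", "", teqs$species)
    cr_rows <- lapply(split(teqs, pool), function(g) {
      teq_ng_g <- mean(g$teq)
      cr <- cancer_risk(teq_ng_g * 1e-3, registry$slope_factor, exposure)
      data.frame(species = sub(",? ?(large|small)$", "", g$species[1]),
                 teq_mg_kg = teq_ng_g * 1e-3,
                 dose_mg_kg_day = cr$dose_mg_kg_day,
                 cancer_risk = cr$risk, stringsAsFactors = FALSE)
    })
    cancer_table <- do.call(rbind, cr_rows)
    rownames(cancer_table) <- NULL
  } else {
    cancer_table <- data.frame(species = character(), teq_mg_kg = numeric(),
                               dose_mg_kg_day = numeric(),
                               cancer_risk = numeric(), stringsAsFactors = FALSE)
  }

  # Wildlife screen: whole-fish conversion excludes roe samples.
  reps <- dataset$replicates
  roe_keys <- reps$composite_id[reps$sample_type == "roe"]
  wl_rows <- lapply(seq_len(nrow(groups)), function(i) {
    sp <- groups$species[i]; yr <- groups$year[i]
    sel_rep <- reps$species == sp & reps$year == yr & reps$sample_type != "roe"
    if (!any(sel_rep)) return(NULL)
    keep <- function(tt) {
      tt[tt$species == sp & tt$year == yr & !tt$composite_id %in% roe_keys, ,
         drop = FALSE]
    }
    pcb <- keep(tot_pcb); pbde <- keep(tot_pbde); df <- keep(tot_df)
    gm <- m[m$species == sp & m$year == yr &
              !m$composite_id %in% roe_keys, , drop = FALSE]
    cf <- registry$conversion_factors
    conv <- function(tt, chem) {
      if (nrow(tt) == 0) return(NA_real_)
      as.numeric(whole_fish_convert(group_mean(tt$total, tt$composite_id),
                                    chem, cf))
    }
    pcb_w <- conv(pcb, "PCB")
    pbde_w <- conv(pbde, "PBDE")
    tcdd_w <- conv(df, "DIOXIN_FURAN")
    pfos_conc <- group_analyte_mean(gm, "PFOS")
    pfos_w <- if (is.na(pfos_conc)) NA_real_
      else as.numeric(whole_fish_convert(pfos_conc, "PFOS", cf))
    exceeds <- function(conc, chem, receptor) {
      if (is.na(conc)) return(NA)
      s <- wv_screen(conc, chem, registry)
      s$exceeds[s$receptor == receptor]
    }
    data.frame(
      species = sp, year = yr,
      pcb_whole = pcb_w, pbde_whole = pbde_w, tcdd_whole = tcdd_w,
      pfos_whole = pfos_w,
      pcb_exceeds_mink = exceeds(pcb_w, "PCB", "MINK"),
      pbde_exceeds_kestrel = exceeds(pbde_w, "PBDE", "KESTREL"),
      tcdd_exceeds_wv = exceeds(tcdd_w, "TCDD", "TCDD_GENERIC"),
      pfos_exceeds_mammal = exceeds(pfos_w, "PFOS", "MAMMAL_CA"),
      pfos_exceeds_bird = exceeds(pfos_w, "PFOS", "BIRD_CA"),
      stringsAsFactors = FALSE
    )
  })
  wildlife_table <- do.call(rbind, wl_rows)
  rownames(hq_table) <- rownames(wildlife_table) <- NULL

  list(hq_table = hq_table, cancer_table = cancer_table,
       wildlife_table = wildlife_table)
}

#' Run the full assessment and optionally write report files
#'
#' Thin wrapper over [build_reports()] that writes the three report CSVs and
#' a JSON run manifest (input path, constants used, options) when `out_dir`
#' is given.
#'
#' @param dataset a `fishrisk_dataset` or path to a long CSV.
#' @param registry a `toxicity_registry`.
#' @param nd_policy TEQ nondetect policy.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param fallback_threshold see [km_total()].
#' @return The [build_reports()] list, invisibly when writing.
#' @export
assess <- function(dataset, registry = default_registry(),
                   nd_policy = "ZERO", out_dir = NULL,
                   fallback_threshold = 0.8) {
  input <- NA_character_
  if (is.character(dataset)) {
    input <- dataset
    dataset <- read_measurements(dataset)
  }
  reports <- build_reports(dataset, registry, nd_policy, fallback_threshold)
  if (is.null(out_dir)) return(reports)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(reports$hq_table, file.path(out_dir, "table_hq.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(reports$cancer_table, file.path(out_dir, "table_cancer.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(reports$wildlife_table,
                   file.path(out_dir, "table_wildlife.csv"),
                   row.names = FALSE, na = "")
  manifest <- list(
    input = input,
    n_measurements = nrow(dataset$measurements),
    nd_policy = nd_policy,
    fallback_threshold = fallback_threshold,
    exposure = registry$exposure,
    rfds = as.list(registry$rfds),
    slope_factor = registry$slope_factor,
    conversion_factors = as.list(registry$conversion_factors)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(reports)
}
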