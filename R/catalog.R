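# Analyte panel: 32 PCB congeners (incl. the 12 WHO dioxin-like/coplanar
# congeners), 27 PBDEs, 17 2,3,7,8-substituted dioxins/furans, 13 PFAS.

PCB_COPLANAR <- paste0("PCB-", c(77, 81, 105, 114, 118, 123, 126,
                                 156, 157, 167, 169, 189))

PCB_OTHER <- paste0("PCB-", c(8, 18, 28, 44, 52, 66, 87, 101, 110, 128,
                              138, 153, 170, 180, 183, 187, 194, 199, 206, 209))

PBDE_CONGENERS <- paste0("BDE-", c(17, 28, 47, 49, 66, 71, 85, 99, 100, 119,
                                   126, 138, 153, 154, 156, 183, 184, 191,
                                   196, 197, 201, 202, 203, 206, 207, 208, 209))

DIOXIN_FURAN_CONGENERS <- c(
  "2,3,7,8-TCDD", "1,2,3,7,8-PeCDD", "1,2,3,4,7,8-HxCDD", "1,2,3,6,7,8-HxCDD",
  "1,2,3,7,8,9-HxCDD", "1,2,3,4,6,7,8-HpCDD", "OCDD",
  "2,3,7,8-TCDF", "1,2,3,7,8-PeCDF", "2,3,4,7,8-PeCDF", "1,2,3,4,7,8-HxCDF",
  "1,2,3,6,7,8-HxCDF", "1,2,3,7,8,9-HxCDF", "2,3,4,6,7,8-HxCDF",
  "1,2,3,4,6,7,8-HpCDF", "1,2,3,4,7,8,9-HpCDF", "OCDF"
)

PFAS_ANALYTES <- c("PFBA", "PFBS", "PFHxA", "PFHpA", "PFHxS", "PFOA", "PFNA",
                   "PFDA", "PFUnA", "PFDoA", "PFTrDA", "PFOSA", "PFOS")

#' Bundled analyte catalog
#'
#' The full measured panel: 32 PCB congeners, 27 PBDEs, 17 dioxins/furans and
#' 13 PFAS. `is_dioxin_like` is `TRUE` exactly for the 17 dioxin/furan
#' congeners and the 12 coplanar (WHO dioxin-like) PCBs; these are the
#' analytes that enter TEQ computation.
#'
#' @return data.frame with columns `analyte_id`, `chem_class`,
#'   `is_dioxin_like`.
#' @export
default_catalog <- function() {
  pcb <- c(PCB_OTHER, PCB_COPLANAR)
  data.frame(
    analyte_id = c(pcb, PBDE_CONGENERS, DIOXIN_FURAN_CONGENERS, PFAS_ANALYTES),
    chem_class = c(rep("PCB", length(pcb)),
                   rep("PBDE", length(PBDE_CONGENERS)),
                   rep("DIOXIN_FURAN", length(DIOXIN_FURAN_CONGENERS)),
                   rep("PFAS", length(PFAS_ANALYTES))),
    is_dioxin_like = c(pcb %in% PCB_COPLANAR,
                       rep(FALSE, length(PBDE_CONGENERS)),
                       rep(TRUE, length(DIOXIN_FURAN_CONGENERS)),
                       rep(FALSE, length(PFAS_ANALYTES))),
    stringsAsFactors = FALSE
  )
}
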