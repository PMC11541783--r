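# Fixtures built in code: small panels and datasets for unit tests.

make_panel <- function(values, dls, censored, chem_class = "PCB",
                       species = "Alewife", year = 2017,
                       composite_id = "C1", replicate_id = "R1") {
  data.frame(
    species = species, year = year, composite_id = composite_id,
    replicate_id = replicate_id,
    analyte_id = paste0("A", seq_along(values)),
    chem_class = chem_class,
    value = ifelse(censored, NA_real_, values),
    detection_limit = dls, censored = censored,
    stringsAsFactors = FALSE
  )
}

# n_composites composites x n_replicates replicates of a single-class panel
# with given per-analyte replicate values (list of numeric vectors keyed by
# replicate index) - used where exact totals must be controlled.
make_dataset <- function(measurements) {
  fishrisk_dataset(measurements)
}

# Small two-species dataset with controlled values and some censoring.
tiny_dataset <- function() {
  rows <- list()
  specs <- list(Alewife = 10, `Striped Bass` = 50)
  for (sp in names(specs)) {
    base <- specs[[sp]]
    for (comp in 1:2) {
      for (rep in 1:2) {
        vals <- base * c(1, 0.5, 0.25) * (1 + 0.05 * rep) * (1 + 0.1 * comp)
        cen <- c(FALSE, FALSE, vals[3] < 5)
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, year = 2017,
          composite_id = paste0(gsub(" ", "", sp), "_C", comp),
          replicate_id = paste0("R", rep),
          analyte_id = c("PCB-153", "PCB-138", "PCB-126"),
          chem_class = "PCB",
          value = ifelse(cen, NA_real_, vals),
          detection_limit = 5, censored = cen,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  fishrisk_dataset(do.call(rbind, rows))
}

# uscore_matrix built from raw columns (single replicate per composite).
um_from_matrix <- function(v, cen, dl, species, year = 2017) {
  n <- nrow(v); p <- ncol(v)
  if (!is.matrix(dl)) {
    dl <- if (length(dl) == p) matrix(rep(dl, each = n), n, p)
          else matrix(dl, n, p)
  }
  m <- data.frame(
    species = rep(species, p), year = year,
    composite_id = rep(paste0("C", seq_len(n)), p),
    replicate_id = "R1",
    analyte_id = rep(paste0("X", seq_len(p)), each = n),
    chem_class = "PFAS",
    value = ifelse(c(cen), NA_real_, c(v)),
    detection_limit = c(dl), censored = c(cen),
    stringsAsFactors = FALSE
  )
  uscores(fishrisk_dataset(m), "PFAS")
}
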