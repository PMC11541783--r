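test_that("TEQ is the TEF-weighted sum with the chosen nondetect policy", {
  tefs <- default_registry()$tefs
  expect_equal(teq(c("2,3,7,8-TCDD" = 0.05), tefs)$teq, 0.05)
  expect_equal(teq(c("2,3,7,8-TCDD" = 0.01, "2,3,7,8-TCDF" = 0.2), tefs)$teq,
               0.01 + 0.1 * 0.2)
  panel <- data.frame(
    analyte_id = c("2,3,7,8-TCDD", "PCB-126"),
    value = NA_real_, detection_limit = c(0.004, 0.02), censored = TRUE
  )
  expect_equal(teq(panel, tefs, nd_policy = "ZERO")$teq, 0)
  expect_equal(teq(panel, tefs, nd_policy = "HALF_DL")$teq,
               0.002 * 1 + 0.01 * 0.1)
  expect_error(teq(c("not-a-congener" = 1), tefs), "not-a-congener")
  # ZERO never exceeds HALF_DL on the same panel
  set.seed(8)
  ids <- sample(names(tefs), 10)
  mixed <- data.frame(analyte_id = ids,
                      value = ifelse(runif(10) < 0.5, NA, rlnorm(10)),
                      detection_limit = runif(10, 0.001, 0.1))
  mixed$censored <- is.na(mixed$value)
  expect_lte(teq(mixed, tefs, "ZERO")$teq, teq(mixed, tefs, "HALF_DL")$teq)
})

test_that("exposure dose follows concentration x IR x EF / BW", {
  expect_equal(exposure_dose(0), 0)
  expect_equal(exposure_dose(6.37), 6.37 * 40 / 80)   # 3.185 ng/kg-BW/day
  expect_equal(exposure_dose(10.3), 5.15)
  # linear in concentration, inverse in body weight
  expect_equal(exposure_dose(20), 2 * exposure_dose(10))
  ex <- default_exposure(); ex$body_weight_kg <- 40
  expect_equal(exposure_dose(10, ex), 2 * exposure_dose(10))
  expect_error(exposure_dose(-1), ">= 0")
})

test_that("hazard quotients reproduce the published screening values", {
  expect_equal(hazard_quotient(5, 5), 1)
  # PFOS in Sea Lamprey 2017: 6.59 ng/g -> dose 3.295 -> HQ 33 (2 s.f.)
  expect_equal(signif(hazard_quotient(exposure_dose(6.59), 0.1), 2), 33)
  # TCDD TEQ in Striped Bass 2017: dose 0.0389 -> HQ 56 (2 s.f.)
  expect_equal(signif(hazard_quotient(0.0389, 0.0007), 2), 56)
  expect_error(hazard_quotient(1, 0), "> 0")
})

test_that("cancer risk applies the slope factor and duration scaling", {
  r <- cancer_risk(2.92e-5)
  expect_equal(r$dose_mg_kg_day, 1.46e-8)
  expect_equal(signif(r$risk, 2), 7.3e-4)
  expect_equal(signif(cancer_risk(2.20e-5)$risk, 2), 5.5e-4)
  expect_equal(cancer_risk(0)$risk, 0)
  # monotone in concentration
  expect_gt(cancer_risk(2e-5)$risk, cancer_risk(1e-5)$risk)
})

test_that("whole-fish conversion uses class factors and flags gaps", {
  expect_equal(as.numeric(whole_fish_convert(100, "PCB")), 183)
  expect_equal(as.numeric(whole_fish_convert(1.74, "PBDE")), 2.61)
  expect_equal(as.numeric(whole_fish_convert(6.59, "PFOS")), 6.59 * 2.13)
  nc <- whole_fish_convert(7.86, "PFUnA")
  expect_true(is.na(nc))
  expect_equal(attr(nc, "reason"), "no conversion factor")
  # round trip to machine precision
  cf <- default_registry()$conversion_factors
  expect_equal(as.numeric(whole_fish_convert(14.3, "PCB")) / cf[["PCB"]], 14.3)
})

test_that("wildlife screening is strict and receptor-complete", {
  reg <- default_registry()
  s <- wv_screen(183, "PCB", reg)
  expect_equal(s$receptor, "MINK")
  expect_true(s$exceeds)
  expect_false(wv_screen(26.1, "PCB", reg)$exceeds)
  expect_false(wv_screen(72, "PCB", reg)$exceeds)  # equality does not exceed
  pf <- wv_screen(8.91, "PFOS", reg)
  expect_setequal(pf$receptor, c("MAMMAL_CA", "BIRD_CA"))
  expect_true(all(pf$exceeds))                     # 8.91 > 4.6 and > 8.2
  pf2 <- wv_screen(7.50, "PFOS", reg)
  expect_equal(pf2$exceeds[pf2$receptor == "MAMMAL_CA"], TRUE)
  expect_equal(pf2$exceeds[pf2$receptor == "BIRD_CA"], FALSE)
  expect_equal(nrow(wv_screen(5, "PFUnA", reg)), 0)
})

test_that("report tables blank nondetected chemicals and pool cancer years", {
  gen <- reference_dataset(seed = 21,
                           species = c("Alewife", "Sea Lamprey"))
  rep_ <- build_reports(gen$dataset)
  hq <- rep_$hq_table
  # PFOS is never detected in Alewife -> blank dose and HQ cells
  expect_true(all(is.na(hq$pfos_hq[hq$species == "Alewife"])))
  expect_true(all(!is.na(hq$pfos_hq[hq$species == "Sea Lamprey"])))
  expect_true(all(!is.na(hq$pcb_dose)))
  # HQ = dose / RfD wherever both are present
  expect_equal(hq$pfos_hq[!is.na(hq$pfos_hq)],
               hq$pfos_dose[!is.na(hq$pfos_hq)] / 0.1)
  # cancer table pools both years into one row per species
  expect_equal(sort(rep_$cancer_table$species), c("Alewife", "Sea Lamprey"))

  # a single-year dataset gives the per-year TEQ risk directly
  one <- reference_dataset(seed = 21, species = "Sea Lamprey", years = 2017)
  r1 <- build_reports(one$dataset)
  teqs <- fishrisk:::replicate_teqs(one$dataset)
  expect_equal(r1$cancer_table$teq_mg_kg, mean(teqs$teq) * 1e-3)
  expect_equal(r1$cancer_table$cancer_risk,
               cancer_risk(mean(teqs$teq) * 1e-3)$risk)
})

test_that("roe samples are excluded from the wildlife screen by metadata", {
  gen <- reference_dataset(seed = 33,
                           species = c("American Shad Roe", "Striped Bass"))
  rep_ <- build_reports(gen$dataset)
  expect_false("American Shad Roe" %in% rep_$wildlife_table$species)
  expect_true("American Shad Roe" %in% rep_$hq_table$species)
  expect_true("Striped Bass" %in% rep_$wildlife_table$species)
  # the TCDD screening column always exceeds the 6.2e-5 ng/g generic value
  expect_true(all(rep_$wildlife_table$tcdd_exceeds_wv))
})
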