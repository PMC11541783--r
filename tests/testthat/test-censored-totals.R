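test_that("KM total reduces to the simple sum with no censoring", {
  panel <- make_panel(c(2, 3, 5), rep(0.01, 3), rep(FALSE, 3))
  res <- km_total(panel)
  expect_equal(res$total, 10)
  expect_equal(res$method, "SIMPLE_SUM")
  expect_equal(res$n_censored, 0L)
})

test_that("KM total matches the hand-computed product-limit table", {
  # Panel {4, 2, <1}: flipped about M = 4 the sample is {0, 2, 3+};
  # S(0) = 2/3, S(2) = 1/3, curve truncated at the censoring time 3, so
  # E[flipped] = 2/3 * 2 + 1/3 * 1 = 5/3, KM mean = 4 - 5/3 = 7/3,
  # total = 3 * 7/3 = 7.
  panel <- make_panel(c(4, 2, NA), c(0.01, 0.01, 1), c(FALSE, FALSE, TRUE))
  res <- km_total(panel)
  expect_equal(res$total, 7, tolerance = 1e-12)
  expect_equal(res$method, "KAPLAN_MEIER")
  expect_equal(res$n_censored, 1L)
})

test_that("heavy censoring raises the KM-infeasible condition", {
  panel <- make_panel(c(5, rep(NA, 9)), rep(1, 10),
                      c(FALSE, rep(TRUE, 9)))
  expect_error(km_total(panel), class = "fishrisk_km_infeasible")
  # exactly at the threshold the estimator still runs (> is strict) but a
  # single detected value is also infeasible; with two detects at 0.8 it runs
  panel2 <- make_panel(c(5, 4, rep(NA, 8)), rep(1, 10),
                       c(FALSE, FALSE, rep(TRUE, 8)))
  expect_silent(km_total(panel2, fallback_threshold = 0.8))
  expect_error(km_total(panel2, fallback_threshold = 0.79),
               class = "fishrisk_km_infeasible")
  expect_error(km_total(panel[0, ]), "empty panel")
})

test_that("half-DL totals follow the substitution arithmetic", {
  expect_equal(half_dl_total(make_panel(c(2.0, NA), c(0.01, 0.2),
                                        c(FALSE, TRUE)))$total, 2.1)
  res <- half_dl_total(make_panel(1:3, rep(0.01, 3), rep(FALSE, 3)))
  expect_equal(res$total, 6)  # equals the simple sum when nothing is censored
  # 17-analyte panel: 7 detected summing 0.10, 10 censored at DL 0.01
  vals <- c(rep(0.10 / 7, 7), rep(NA, 10))
  cen <- c(rep(FALSE, 7), rep(TRUE, 10))
  res <- half_dl_total(make_panel(vals, rep(0.01, 17), cen))
  expect_equal(res$total, 0.15)
  expect_error(half_dl_total(make_panel(1, 1, FALSE)[0, ]), "empty panel")
})

test_that("class_totals applies KM first and falls back per replicate", {
  ds <- tiny_dataset()  # no replicate exceeds the censoring threshold
  tot <- class_totals(ds, "PCB")
  expect_equal(nrow(tot), nrow(ds$replicates))
  expect_true(all(tot$method %in% c("SIMPLE_SUM", "KAPLAN_MEIER")))
  # replicates without censoring are recorded as plain sums
  uncensored <- tot$n_censored == 0
  expect_true(all(tot$method[uncensored] == "SIMPLE_SUM"))

  # engineer one replicate with 90% censoring -> that replicate HALF_DL
  m <- ds$measurements
  extra <- do.call(rbind, replicate(9, m[m$replicate_id == "R1" &
    m$composite_id == "Alewife_C1" & m$analyte_id == "PCB-126", ],
    simplify = FALSE))
  extra$analyte_id <- paste0("PCB-X", 1:9)
  extra$value <- NA_real_; extra$censored <- TRUE
  m2 <- rbind(m[!(m$composite_id == "Alewife_C1" & m$replicate_id == "R1" &
                    m$analyte_id %in% c("PCB-153", "PCB-138")), ], extra)
  ds2 <- fishrisk_dataset(m2, replicates = ds$replicates)
  tot2 <- class_totals(ds2, "PCB")
  bad <- tot2$composite_id == "Alewife_C1" & tot2$replicate_id == "R1"
  expect_equal(tot2$method[bad], "HALF_DL")
  expect_true(all(tot2$method[!bad] %in% c("SIMPLE_SUM", "KAPLAN_MEIER")))
})

test_that("KM total is bounded by the substitution estimators", {
  # On random censored panels: detected-only sum <= KM total <= full-DL
  # substitution total, and half-DL is between its own bounds.
  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(5:20, 1)
    x <- rlnorm(n, 0, 1)
    dl <- quantile(x, runif(1, 0.1, 0.6))
    cen <- x < dl
    if (!any(cen) || sum(!cen) < 2) next
    panel <- make_panel(ifelse(cen, NA, x), rep(dl, n), cen)
    km <- km_total(panel)$total
    full_sub <- sum(x[!cen]) + sum(dl * cen)
    half <- half_dl_total(panel)$total
    expect_lte(km, full_sub + 1e-9)
    expect_gte(km, sum(x[!cen]) - 1e-9)
    expect_lte(half, full_sub + 1e-9)
    expect_gte(half, sum(x[!cen]) - 1e-9)
  }
})

test_that("half-DL total is monotone in each detection limit", {
  panel <- make_panel(c(2, NA, NA), c(0.1, 0.4, 0.6),
                      c(FALSE, TRUE, TRUE))
  t1 <- half_dl_total(panel)$total
  panel$detection_limit[2] <- 0.8
  expect_gt(half_dl_total(panel)$total, t1)
})

test_that("KM class totals recover known means under moderate censoring", {
  # 10 analytes with known means, ~30% of draws censored, 30 replicates:
  # the mean KM total should sit within 10% of the true total.
  set.seed(404)
  mu <- exp(seq(log(2), log(0.05), length.out = 10))
  dl <- quantile(mu, 0.35)
  totals <- replicate(30, {
    x <- rlnorm(10, log(mu) - 0.18, 0.6)
    cen <- x < dl
    if (sum(!cen) < 2) return(NA_real_)
    km_total(make_panel(ifelse(cen, NA, x), rep(dl, 10), cen))$total
  })
  true_total <- sum(mu)  # meanlog = log(mu) - sd^2/2 with sd 0.6 gives E = mu
  expect_lt(abs(mean(totals, na.rm = TRUE) - true_total) / true_total, 0.10)
})
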