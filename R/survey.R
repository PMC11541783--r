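# Design-based inference over replicate class totals with the composite
# sample as the clustering unit. Technical replicates of one composite are
# not independent; the variance of the design-based mean is estimated by
# Taylor linearization over cluster (composite) score totals, the
# with-replacement first-stage approximation used for one-stage cluster
# samples. Equal weights are used throughout (balanced replicate design).

cluster_mean_var <- function(total, composite_id) {
  m <- length(total)
  ybar <- mean(total)
  z <- (total - ybar) / m
  zi <- tapply(z, composite_id, sum)
  n <- length(zi)
  list(mean = ybar, var = n / (n - 1) * sum(zi^2), n_clusters = n,
       n_replicates = m)
}

#' Design-based mean and confidence interval for one group
#'
#' Mean of replicate class totals for one species x year x class group, with
#' a cluster-robust standard error (composite = cluster, Taylor
#' linearization) and a t confidence interval on `n_composites - 1` degrees
#' of freedom.
#'
#' @param totals data.frame of `ClassTotal` rows for a single group (must
#'   contain `total` and `composite_id`; `species`, `year`, `chem_class`
#'   are carried through when constant).
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @return One-row data.frame (`SummaryRow`): `mean`, `ci_low`, `ci_high`,
#'   `n_composites`, `n_replicates`.
#' @export
survey_mean_ci <- function(totals, alpha = 0.05) {
  totals <- as.data.frame(totals)
  n_comp <- length(unique(totals$composite_id))
  if (n_comp < 2) stop("insufficient clusters: need >= 2 composites")
  est <- cluster_mean_var(totals$total, totals$composite_id)
  se <- sqrt(est$var)
  tq <- stats::qt(1 - alpha / 2, df = est$n_clusters - 1)
  out <- data.frame(
    mean = est$mean,
    ci_low = est$mean - tq * se,
    ci_high = est$mean + tq * se,
    se = se,
    n_composites = est$n_clusters,
    n_replicates = est$n_replicates,
    stringsAsFactors = FALSE
  )
  for (col in c("species", "year", "chem_class")) {
    if (col %in% names(totals) && length(unique(totals[[col]])) == 1) {
      out[[col]] <- totals[[col]][1]
    }
  }
  out
}

#' Survey-design two-group t-test
#'
#' Two-sided test of equal design-based means between two groups of replicate
#' class totals, using cluster-robust standard errors (composite clusters)
#' and `n_composites_A + n_composites_B - 2` degrees of freedom.
#'
#' @param group_a,group_b data.frames of `ClassTotal` rows (columns `total`,
#'   `composite_id`), each with at least two composites.
#' @return list with elements `t`, `p`, `df`, `diff` (mean A minus mean B).
#' @export
survey_t_test <- function(group_a, group_b) {
  na <- length(unique(group_a$composite_id))
  nb <- length(unique(group_b$composite_id))
  if (na < 2 || nb < 2) stop("insufficient clusters: need >= 2 composites per group")
  ea <- cluster_mean_var(group_a$total, group_a$composite_id)
  eb <- cluster_mean_var(group_b$total, group_b$composite_id)
  diff <- ea$mean - eb$mean
  se <- sqrt(ea$var + eb$var)
  df <- na + nb - 2
  if (diff == 0) {
    t <- 0
  } else if (se == 0) {
    t <- sign(diff) * Inf
  } else {
    t <- diff / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = df)
  list(t = t, p = min(1, p), df = df, diff = diff)
}

#' Summary table of class totals by species and year
#'
#' Applies [class_totals()] and [survey_mean_ci()] over every species x year
#' group, yielding a summary table in the shape of a monitoring report: one
#' row per group with the design-based mean, 95% CI, composite counts and
#' mean moisture/lipid content.
#'
#' @param dataset a `fishrisk_dataset`.
#' @param chem_class chemical class to summarize.
#' @param alpha two-sided error rate for the CIs.
#' @param fallback_threshold see [km_total()].
#' @return data.frame with one row per species x year group.
#' @export
summarize_dataset <- function(dataset, chem_class, alpha = 0.05,
                              fallback_threshold = 0.8) {
  tot <- class_totals(dataset, chem_class, fallback_threshold)
  if (nrow(tot) == 0) return(tot)
  groups <- split(tot, interaction(tot$species, tot$year, drop = TRUE))
  rows <- lapply(groups, function(g) {
    s <- survey_mean_ci(g, alpha = alpha)
    meta <- dataset$replicates
    sel <- meta$species == g$species[1] & meta$year == g$year[1]
    s$pct_moisture <- mean(meta$pct_moisture[sel])
    s$pct_lipids <- mean(meta$pct_lipids[sel])
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  cols <- c("species", "year", "chem_class", "n_composites", "n_replicates",
            "mean", "ci_low", "ci_high", "se", "pct_moisture", "pct_lipids")
  out[order(out$species, out$year), intersect(cols, names(out)), drop = FALSE]
}
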