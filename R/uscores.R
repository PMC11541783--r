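# U-score ranking for censored multivariate panels.
#
# A u-score replaces each observation by the sum of its determinate pairwise
# comparisons within an analyte column: detected-vs-detected pairs compare
# numerically; a detected value beats a nondetect only when it is at or above
# that nondetect's detection limit; two nondetects (intervals [0, DL) that
# always overlap) are indeterminate and score 0. Columns therefore sum to
# zero by antisymmetry, and any downstream rank-based statistic depends on
# the data only through determinate orderings.

uscore_pair <- function(vi, di, ci, vj, dj, cj) {
  if (!ci && !cj) return(sign(vi - vj))
  if (!ci && cj) return(as.numeric(vi >= dj))
  if (ci && !cj) return(-as.numeric(vj >= di))
  0
}

uscore_column <- function(value, detection_limit, censored) {
  n <- length(value)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s[i] <- s[i] + uscore_pair(value[i], detection_limit[i], censored[i],
                                 value[j], detection_limit[j], censored[j])
    }
  }
  s
}

#' U-score matrix for one chemical class
#'
#' Builds the replicates x analytes matrix of u-scores for a chemical class.
#' An analyte absent from a replicate's panel is treated as censored at a
#' default detection limit (`default_dls`, named by analyte, or a single
#' class-wide value); if no default is available the function errors.
#'
#' @param dataset a `fishrisk_dataset`.
#' @param chem_class chemical class to score.
#' @param default_dls named numeric vector of fallback detection limits per
#'   analyte, or a single value used for every absent analyte.
#' @param unit `"replicate"` (rows are technical replicates, default) or
#'   `"composite"` (replicate values are averaged within composite before
#'   scoring; a composite is censored only when all its replicates are, at
#'   the largest replicate detection limit).
#' @return An object of class `uscore_matrix`: list with `scores` (integer
#'   matrix, rows summing to zero column-wise), `species`, `year`, `rows`
#'   (row keys) and `analytes`.
#' @export
uscores <- function(dataset, chem_class, default_dls = NULL,
                    unit = c("replicate", "composite")) {
  chem_class <- match.arg(chem_class, CHEM_CLASSES)
  unit <- match.arg(unit)
  m <- dataset$measurements[dataset$measurements$chem_class == chem_class, , drop = FALSE]
  if (nrow(m) == 0) stop("no measurements of class ", chem_class)

  if (unit == "composite") {
    key <- paste(m$species, m$year, m$composite_id, m$analyte_id, sep = "\r")
    agg <- lapply(split(m, key), function(g) {
      det <- !g$censored
      data.frame(
        species = g$species[1], year = g$year[1],
        composite_id = g$composite_id[1], replicate_id = "pooled",
        analyte_id = g$analyte_id[1], chem_class = g$chem_class[1],
        value = if (any(det)) mean(g$value[det]) else NA_real_,
        detection_limit = max(g$detection_limit),
        censored = !any(det), stringsAsFactors = FALSE
      )
    })
    m <- do.call(rbind, agg)
  }

  m$row_key <- paste(m$species, m$year, m$composite_id, m$replicate_id, sep = "|")
  rows <- unique(m[c("row_key", "species", "year")])
  analytes <- unique(m$analyte_id)
  n <- nrow(rows)
  if (n < 2) stop("need >= 2 rows to compute u-scores")

  scores <- matrix(0, nrow = n, ncol = length(analytes),
                   dimnames = list(rows$row_key, analytes))
  for (a in analytes) {
    sub <- m[m$analyte_id == a, , drop = FALSE]
    idx <- match(rows$row_key, sub$row_key)
    value <- sub$value[idx]
    dl <- sub$detection_limit[idx]
    cen <- sub$censored[idx]
    absent <- is.na(idx)
    if (any(absent)) {
      fill_dl <- if (is.null(default_dls)) NA_real_
        else if (length(default_dls) == 1 && is.null(names(default_dls))) default_dls
        else unname(default_dls[a])
      if (is.na(fill_dl)) {
        stop("analyte ", a, " absent from some replicates and no default ",
             "detection limit available")
      }
      dl[absent] <- fill_dl
      cen[absent] <- TRUE
      value[absent] <- NA_real_
    }
    scores[, a] <- uscore_column(value, dl, cen)
  }
  structure(
    list(scores = scores, species = rows$species, year = rows$year,
         rows = rows$row_key, analytes = analytes),
    class = "uscore_matrix"
  )
}

#' @export
print.uscore_matrix <- function(x, ...) {
  cat("<uscore_matrix> ", nrow(x$scores), " rows x ", ncol(x$scores),
      " analytes (", length(unique(x$species)), " species, ",
      length(unique(x$year)), " years)\n", sep = "")
  invisible(x)
}

#' Kruskal-Wallis test on u-score ranks
#'
#' One-way comparison of a single (possibly censored) analyte across several
#' groups: observations are first reduced to u-scores over the pooled sample,
#' then the standard tie-corrected Kruskal-Wallis H is computed on the
#' scores. With uncensored data the u-scores are a monotone relabeling of the
#' values, so this reduces to the usual Kruskal-Wallis test.
#'
#' @param value numeric values (NA where censored).
#' @param detection_limit detection limits.
#' @param censored logical nondetect flags.
#' @param group group labels (>= 2 groups, total n >= 3).
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis_u <- function(value, detection_limit, censored, group) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (length(value) < 3) stop("need total n >= 3")
  u <- uscore_column(value, detection_limit, censored)
  if (length(unique(u)) == 1) {
    return(list(H = 0, p = 1, df = nlevels(group) - 1))
  }
  kt <- stats::kruskal.test(u, group)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-group comparison: exact when both groups have at most 10
#' observations and no ties, otherwise the normal approximation with tie
#' correction.
#'
#' @param group_a,group_b numeric vectors.
#' @return list with `W`, `p`, `exact`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= 10 && length(group_b) <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact)
  )
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # zero rank variance (all observations tied)
  list(W = unname(wt$statistic), p = p, exact = exact)
}

#' Principal-component biplot coordinates of a u-score matrix
#'
#' Singular-value decomposition of the column-centered u-score matrix; the
#' first two components are returned as row scores and column loadings for
#' biplot rendering, together with the fraction of variance each explains.
#'
#' @param um an `uscore_matrix`.
#' @return list with `row_scores` (n x 2), `col_loadings` (p x 2) and
#'   `variance_explained` (length 2, sums to <= 1).
#' @export
biplot_coordinates <- function(um) {
  scores <- um$scores
  if (nrow(scores) < 3) stop("need >= 3 rows")
  if (ncol(scores) < 2) stop("need >= 2 columns")
  centered <- scale(scores, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) stop("no variance in u-score matrix")
  pc <- stats::prcomp(centered, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2, ncol(pc$x))
  list(
    row_scores = pc$x[, seq_len(k), drop = FALSE],
    col_loadings = pc$rotation[, seq_len(k), drop = FALSE],
    variance_explained = ve[seq_len(k)]
  )
}
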