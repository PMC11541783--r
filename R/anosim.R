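# Analysis of similarity on u-score rows.

#' ANOSIM permutation test on a u-score matrix
#'
#' Tests multivariate separation of species or year groups: Euclidean
#' distances between u-score rows are rank-transformed and the ANOSIM
#' statistic R (mean between-group minus mean within-group rank distance,
#' scaled to `[-1, 1]`) is compared to its permutation distribution obtained
#' by shuffling row group labels. The permutation p-value is
#' `(1 + #{permuted R >= observed R}) / (n_permutations + 1)` and the seed
#' fully determines the permutation stream. Setting `on_ranks = TRUE` scores
#' the column-wise ranks of the u-scores instead of the u-scores themselves;
#' because ANOSIM only uses rank distances the two options give very similar
#' (typically identical) results.
#'
#' @param um an `uscore_matrix` from [uscores()].
#' @param grouping `"species"` or `"year"`.
#' @param n_permutations number of label permutations (default 999).
#' @param seed integer seed recorded in the result.
#' @param on_ranks score column-wise ranks of u-scores instead of raw
#'   u-scores.
#' @return An `anosim_result`: list with `R`, `p`, `n_permutations`, `seed`,
#'   `grouping`.
#' @export
uscore_anosim <- function(um, grouping = c("species", "year"),
                          n_permutations = 999, seed = 1, on_ranks = FALSE) {
  grouping <- match.arg(grouping)
  labels <- factor(um[[grouping]])
  if (nlevels(labels) < 2) stop("degenerate grouping: need >= 2 groups")
  if (any(table(labels) < 2)) stop("degenerate grouping: every group needs >= 2 rows")
  scores <- um$scores
  if (on_ranks) scores <- apply(scores, 2, rank)
  d <- stats::dist(scores)
  set.seed(seed)
  fit <- vegan::anosim(d, labels, permutations = n_permutations)
  structure(
    list(R = unname(fit$statistic), p = fit$signif,
         n_permutations = n_permutations, seed = seed, grouping = grouping),
    class = "anosim_result"
  )
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM by %s: R = %.3f, p = %.4g (%d permutations, seed %d)\n",
              x$grouping, x$R, x$p, x$n_permutations, x$seed))
  invisible(x)
}
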