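test_that("u-scores follow the pairwise comparison rules", {
  # all detected, strict ordering
  um <- um_from_matrix(matrix(c(1, 2, 3)), matrix(FALSE, 3, 1),
                       0.01, rep("A", 3))
  expect_equal(unname(um$scores[, 1]), c(-2, 0, 2))
  # detected at/above the nondetect's DL dominates it
  um <- um_from_matrix(matrix(c(5, NA)), matrix(c(FALSE, TRUE), 2, 1),
                       c(0.5, 1), rep("A", 2))
  expect_equal(unname(um$scores[, 1]), c(1, -1))
  # detected below the other's DL is indeterminate
  um <- um_from_matrix(matrix(c(0.5, NA)), matrix(c(FALSE, TRUE), 2, 1),
                       matrix(c(0.1, 1), 2, 1), rep("A", 2))
  expect_equal(unname(um$scores[, 1]), c(0, 0))
  # two nondetects always overlap
  um <- um_from_matrix(matrix(c(NA, NA)), matrix(TRUE, 2, 1),
                       matrix(c(1, 2), 2, 1), rep("A", 2))
  expect_equal(unname(um$scores[, 1]), c(0, 0))
})

test_that("u-score columns sum to zero and are bounded", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:12, 1); p <- sample(2:5, 1)
    v <- matrix(rlnorm(n * p), n, p)
    dl <- matrix(rep(apply(v, 2, quantile, runif(1, 0, 0.7)), each = n), n, p)
    cen <- v < dl
    um <- um_from_matrix(ifelse(cen, NA, v), cen, dl,
                         rep(c("A", "B"), length.out = n))
    expect_equal(unname(colSums(um$scores)), rep(0, p))
    expect_true(all(abs(um$scores) <= n - 1))
  }
})

test_that("absent analytes are treated as censored at the default DL", {
  m <- data.frame(
    species = c("A", "A", "B"), year = 2017,
    composite_id = c("C1", "C2", "C3"), replicate_id = "R1",
    analyte_id = c("X1", "X1", "X2"), chem_class = "PFAS",
    value = c(5, 3, 1), detection_limit = 0.1, censored = FALSE,
    stringsAsFactors = FALSE
  )
  ds <- fishrisk_dataset(m)
  expect_error(uscores(ds, "PFAS"), "no default")
  um <- uscores(ds, "PFAS", default_dls = c(X1 = 0.1, X2 = 0.1))
  # X1 column: detected 5 and 3 beat the filled-in nondetect of row 3
  expect_equal(sum(um$scores[, "X1"]), 0)
  expect_equal(min(um$scores[, "X1"]), -2)
})

test_that("Kruskal-Wallis on u-score ranks matches the hand rank formula", {
  # groups {1,2}, {3,4}, {5,6}: rank sums 3, 7, 11 ->
  # H = 12/(6*7) * (3^2/2 + 7^2/2 + 11^2/2) - 3*7 = 32/7
  r <- kruskal_wallis_u(1:6, rep(0.01, 6), rep(FALSE, 6),
                        rep(c("a", "b", "c"), each = 2))
  expect_equal(r$H, 32 / 7, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, pchisq(32 / 7, 2, lower.tail = FALSE))

  same <- kruskal_wallis_u(rep(2, 4), rep(0.01, 4), rep(FALSE, 4),
                           c("a", "a", "b", "b"))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  # fully censored columns are all indeterminate -> no evidence
  nd <- kruskal_wallis_u(rep(NA_real_, 4), rep(0.1, 4), rep(TRUE, 4),
                         c("a", "a", "b", "b"))
  expect_equal(nd$p, 1)
})

test_that("Wilcoxon exact p equals brute-force enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_true(r$exact)

  # enumeration oracle: two-sided p of the rank-sum statistic
  set.seed(77)
  for (i in 1:5) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    x <- sample(seq_len(50), na + nb)  # distinct -> no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    robs <- wilcoxon_rank_sum(a, b)
    pooled <- c(a, b)
    rk <- rank(pooled)
    wobs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
    combos <- combn(na + nb, na)
    wall <- apply(combos, 2, function(idx) sum(rk[idx]) - na * (na + 1) / 2)
    mu <- na * nb / 2
    p_enum <- mean(abs(wall - mu) >= abs(wobs - mu) - 1e-9)
    expect_equal(robs$p, p_enum, tolerance = 1e-12)
  }

  expect_equal(wilcoxon_rank_sum(1, 1)$p, 1)
  sym <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sym$p, 0.1)
})

test_that("biplot coordinates expose the constructed spectrum", {
  # rank-1 matrix: first component carries ~all the variance
  set.seed(5)
  u <- outer(rnorm(6), c(1, 2, -1))
  um <- list(scores = u, species = rep(c("A", "B"), 3), year = 2017)
  class(um) <- "uscore_matrix"
  bc <- biplot_coordinates(um)
  expect_gt(bc$variance_explained[1], 0.999)
  expect_lte(sum(bc$variance_explained), 1 + 1e-9)

  # orthogonal two-block design: two equal components
  block <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  um2 <- list(scores = block, species = rep("A", 4), year = 2017)
  class(um2) <- "uscore_matrix"
  bc2 <- biplot_coordinates(um2)
  expect_equal(bc2$variance_explained, c(0.5, 0.5), tolerance = 1e-12)

  # column reordering leaves row scores unchanged up to sign
  perm <- um$scores[, c(3, 1, 2)]
  um3 <- um; um3$scores <- perm
  bc3 <- biplot_coordinates(um3)
  expect_equal(abs(bc3$row_scores[, 1]), abs(bc$row_scores[, 1]),
               tolerance = 1e-9)

  um0 <- um; um0$scores <- matrix(3, 4, 3)
  expect_error(biplot_coordinates(um0), "no variance")
  expect_error(biplot_coordinates(list(scores = matrix(1:4, 2, 2))),
               "need >= 3 rows")
})

test_that("ANOSIM separates structured groups and is seed-reproducible", {
  set.seed(19)
  v <- rbind(matrix(rlnorm(24, 0, 0.2), 6, 4),
             matrix(rlnorm(24, 5, 0.2), 6, 4))
  um <- um_from_matrix(v, matrix(FALSE, 12, 4), 1e-4,
                       rep(c("A", "B"), each = 6))
  r <- uscore_anosim(um, "species", n_permutations = 999, seed = 23)
  expect_equal(r$R, 1)
  # only label permutations reproducing the two-group split can tie R = 1
  expect_lte(r$p, 5 / 1000)
  r2 <- uscore_anosim(um, "species", n_permutations = 999, seed = 23)
  expect_identical(r$p, r2$p)
  expect_identical(r$R, r2$R)

  # R depends on the data only through ranks: a monotone transform of the
  # concentrations yields identical u-scores and identical R
  um_t <- um_from_matrix(exp(v / 3), matrix(FALSE, 12, 4), 1e-300,
                         rep(c("A", "B"), each = 6))
  expect_equal(um_t$scores, um$scores, ignore_attr = TRUE)
  r_t <- uscore_anosim(um_t, "species", n_permutations = 99, seed = 23)
  expect_equal(r_t$R, r$R)

  # degenerate groupings are refused
  um1 <- um; um1$species <- rep("A", 12)
  expect_error(uscore_anosim(um1, "species"), "degenerate")
  um2 <- um; um2$species <- c(rep("A", 11), "B")
  expect_error(uscore_anosim(um2, "species"), "degenerate")
})

test_that("composite-unit u-scores pool replicates before ranking", {
  gen <- reference_dataset(seed = 13, species = "Sea Lamprey")
  um_rep <- uscores(gen$dataset, "PFAS")
  um_comp <- uscores(gen$dataset, "PFAS", unit = "composite")
  expect_equal(nrow(um_comp$scores),
               length(unique(gen$dataset$replicates$composite_id)))
  expect_equal(nrow(um_rep$scores), nrow(gen$dataset$replicates))
  expect_equal(unname(colSums(um_comp$scores)),
               rep(0, ncol(um_comp$scores)))
})
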