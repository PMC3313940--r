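# Cohort integration: Spearman policy, one-tailed rank-sum, prediction
# intersection, combined target ranking.

test_that("spearman_correlation handles monotone and tied inputs", {
  expect_equal(spearman_correlation(1:4 * 1.0, c(4, 3, 2, 1) * 1.0)$rho, -1)
  r <- spearman_correlation(c(1, 5, 9, 12), c(1, 25, 81, 144))
  expect_equal(r$rho, 1)
  # tied input agrees with independent average-rank-then-Pearson
  x <- c(1, 2, 2, 4)
  y <- c(4, 3, 3, 1)
  rx <- brute_avg_ranks(x)
  ry <- brute_avg_ranks(y)
  ref <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_correlation(x, y)$rho, ref, tolerance = 1e-12)
  expect_warning(out <- spearman_correlation(rep(1, 5), 1:5 * 1.0),
                 "constant")
  expect_true(is.na(out$rho))
  expect_error(spearman_correlation(1:3, 1:3), "at least 4")
})

test_that("spearman p-values follow the stated size policy", {
  # large n: t approximation
  set.seed(71)
  x <- rnorm(50)
  y <- -x + rnorm(50, 0, 0.3)
  r <- spearman_correlation(x, y)
  expect_equal(r$method, "t-approximation")
  tt <- r$rho * sqrt(48 / (1 - r$rho^2))
  expect_equal(r$p, 2 * pt(-abs(tt), 48), tolerance = 1e-12)
  # small n: exact permutation enumeration
  r <- spearman_correlation(c(1, 2, 3, 4, 5) * 1.0, c(5, 4, 3, 2, 1) * 1.0)
  expect_equal(r$method, "exact permutation")
  expect_equal(r$p, 2 / factorial(5))  # |rho| = 1 twice among 120 perms
  # invariance under strictly monotone transforms
  set.seed(72)
  a <- rnorm(20)
  b <- rnorm(20)
  r1 <- spearman_correlation(a, b)
  r2 <- spearman_correlation(exp(a), b^3 + 5 * b)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})

test_that("one-tailed rank-sum matches exact enumeration", {
  res <- subclass_test(c(1, 2, 3, 4, 5, 6),
                       rep(c("proneural", "other"), each = 3), "proneural")
  expect_equal(res$p, 1 / 20)
  expect_equal(res$method, "exact")
  # identical group multisets give no one-sided evidence
  res <- subclass_test(c(1, 2, 3, 1, 2, 3),
                       rep(c("proneural", "other"), each = 3), "proneural")
  expect_gte(res$p, 0.5)
  # exact path equals the independent enumeration oracle, all tie-free
  # inputs n1 + n2 <= 10
  set.seed(73)
  for (n1 in 2:5) {
    for (n2 in 2:(10 - n1)) {
      v <- sample(seq_len(40), n1 + n2)  # distinct -> tie-free
      labs <- rep(c("proneural", "other"), c(n1, n2))
      got <- subclass_test(v, labs, "proneural")
      expect_equal(got$method, "exact")
      expect_equal(got$p, brute_wilcoxon_less(v[1:n1], v[-(1:n1)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("exact and normal-approximation paths agree for n = 8 vs 8", {
  set.seed(74)
  for (k in 1:10) {
    v <- sample(seq_len(100), 16)
    labs <- rep(c("proneural", "other"), each = 8)
    p_exact <- subclass_test(v, labs, "proneural")$p
    p_norm <- suppressWarnings(
      wilcox.test(v[1:8], v[9:16], alternative = "less",
                  exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_norm), 0.01)
  }
})

test_that("p53 stratification filters samples and validates groups", {
  vals <- c(1, 2, 3, 4, 10, 11, 12, 13)
  labs <- rep(c("proneural", "other"), each = 4)
  p53 <- c("mutant", "mutant", "wild-type", "unknown",
           "mutant", "wild-type", "wild-type", "unknown")
  res <- subclass_test(vals, labs, "proneural", p53_status = p53,
                       p53_stratum = "mutant")
  expect_equal(res$n1 + res$n2, 3L)  # unknowns and wild-type excluded
  expect_error(
    subclass_test(vals, labs, "neural", p53_status = p53,
                  p53_stratum = "mutant"),
    "neural")
})

test_that("prediction intersection applies strict thresholds", {
  a <- c(g1 = -0.5, g2 = -0.05, g3 = -0.2)
  b <- c(g1 = -0.2, g2 = -0.2, g4 = -1)
  expect_equal(intersect_predictions(a, -0.1, b, 0), "g1")
  # boundary: score exactly at the threshold is excluded
  expect_equal(intersect_predictions(c(g1 = -0.1), -0.1, b, 0), character(0))
  # commutative with matched thresholds
  expect_equal(intersect_predictions(a, -0.1, b, 0),
               intersect_predictions(b, 0, a, -0.1))
  expect_equal(intersect_predictions(c(x = -1), -0.1, c(y = -1), 0),
               character(0))
  expect_error(intersect_predictions(a, Inf, b, 0), "finite")
})

test_that("integration ranks the doubly-lowest candidate first", {
  set.seed(75)
  co <- generate_cohort(seed = 76)
  fit <- structure(list(table = data.frame(
    gene_id = rownames(co$cohort$mrna_expr),
    t_tilde = c(-8, rnorm(99)),  # TARGET most down-regulated
    stringsAsFactors = FALSE)), class = "moderated_t")
  res <- integrate_candidates(rownames(co$cohort$mrna_expr), fit,
                              co$cohort, "miR-34a")
  # most negative on both axes: combined rank 2, overall position 1
  expect_equal(res$gene_id[1], "TARGET")
  expect_equal(res$combined_rank[1], 2L)
  expect_equal(res$position, seq_len(nrow(res)))
  # output invariant to candidate input order
  res2 <- integrate_candidates(rev(rownames(co$cohort$mrna_expr)), fit,
                               co$cohort, "miR-34a")
  expect_equal(res, res2, ignore_attr = TRUE)
  # unknown candidates are reported and excluded
  expect_warning(
    res3 <- integrate_candidates(c("TARGET", "NOPE"), fit, co$cohort,
                                 "miR-34a"),
    "missing")
  expect_equal(attr(res3, "missing"), "NOPE")
  expect_error(integrate_candidates(character(), fit, co$cohort, "miR-34a"),
               "no candidate")
  expect_error(integrate_candidates("TARGET", fit, co$cohort, "miR-999"),
               "not in cohort")
})
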