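# Tumor-cohort integration: miRNA/mRNA anticorrelation, subclass contrasts,
# target-prediction intersection, and the combined target nomination rank.

#' Construct a paired miRNA/mRNA cohort dataset
#'
#' Holds a miRNA expression matrix and an mRNA expression matrix over a
#' shared sample set, plus per-sample subclass and p53-status labels.  All
#' analyses are restricted to the sample intersection of the two matrices;
#' the realized n is recorded in the object.
#'
#' @param mirna_expr miRNAs x samples numeric matrix.
#' @param mrna_expr genes x samples numeric matrix.
#' @param samples data frame with columns `sample_id`, `subclass`
#'   (`proneural` / `neural` / `classical` / `mesenchymal`), `p53_status`
#'   (`wild-type` / `mutant` / `unknown`).
#' @return Object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(mirna_expr, mrna_expr, samples) {
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) < 4L)
    stop("miRNA and mRNA matrices share fewer than 4 samples")
  if (!all(c("sample_id", "subclass", "p53_status") %in% names(samples)))
    stop("samples needs columns sample_id, subclass, p53_status")
  if (!all(shared %in% samples$sample_id))
    stop("sample annotation does not cover all shared samples")
  samples <- samples[match(shared, samples$sample_id), , drop = FALSE]
  structure(list(
    mirna_expr = mirna_expr[, shared, drop = FALSE],
    mrna_expr = mrna_expr[, shared, drop = FALSE],
    samples = samples,
    n = length(shared)
  ), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Cohort:", x$n, "samples,", nrow(x$mirna_expr), "miRNAs,",
      nrow(x$mrna_expr), "mRNAs\n")
  print(table(x$samples$subclass))
  invisible(x)
}

#' Spearman correlation with the study's p-value policy
#'
#' Rho is the Pearson correlation of average-ranked values (ties get average
#' ranks).  Two-sided p-value: the large-sample t approximation
#' t = rho * sqrt((n-2)/(1-rho^2)) for n >= 10; below that, exact
#' permutation (all n! arrangements for n <= 7, otherwise 10,000 seeded
#' Monte-Carlo permutations).
#'
#' @param x,y paired numeric vectors, >= 4 complete pairs.
#' @param seed seed for the Monte-Carlo permutation branch.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_correlation <- function(x, y, seed = 1L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired samples")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n >= 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  } else {
    rho_perm <- if (n <= 7L) {
      perms <- all_permutations(n)
      apply(perms, 1L, function(ix) cor(rx, ry[ix]))
    } else {
      set.seed(seed)
      vapply(seq_len(10000L), function(i) cor(rx, sample(ry)), numeric(1L))
    }
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- if (n <= 7L) "exact permutation" else "monte-carlo permutation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

# all n! permutations of 1..n as rows (n <= 7 keeps this small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' One-tailed rank-sum test for subclass-specific down-regulation
#'
#' Wilcoxon rank-sum test of the target subclass against all other samples,
#' one-tailed for lower expression in the target subclass.  The exact
#' distribution is used when the smaller group has <= 8 samples and there
#' are no ties; otherwise the normal approximation with tie correction.
#' Optionally restricted to one p53 stratum (samples with unknown status are
#' excluded when stratifying, included otherwise).
#'
#' @param values per-sample expression (named by sample or aligned with
#'   `labels`).
#' @param labels per-sample subclass labels.
#' @param target_class the subclass tested for down-regulation.
#' @param p53_status optional per-sample p53 labels.
#' @param p53_stratum optional stratum (`"wild-type"` or `"mutant"`) to
#'   restrict to.
#' @param alternative direction of the test (default `"less"`: target class
#'   lower).
#' @return List with `p`, `statistic`, `n1`, `n2`, `method`.
#' @export
subclass_test <- function(values, labels, target_class, p53_status = NULL,
                          p53_stratum = NULL, alternative = "less") {
  if (!is.null(p53_stratum)) {
    if (is.null(p53_status)) stop("p53_stratum given without p53_status")
    keep <- p53_status == p53_stratum
    values <- values[keep]
    labels <- labels[keep]
  }
  x <- values[labels == target_class]
  y <- values[labels != target_class]
  if (length(x) == 0L || length(y) == 0L)
    stop("empty group for '", target_class, "'",
         if (!is.null(p53_stratum)) paste0(" in p53 ", p53_stratum, " stratum"))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(length(x), length(y)) <= 8L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n1 = length(x), n2 = length(y),
       method = if (exact) "exact" else "normal approximation")
}

#' Intersect two target-prediction lists at score thresholds
#'
#' Keeps genes scored by both predictors with score strictly below each
#' predictor's threshold (both predictors score lower = stronger).  The
#' canonical thresholds are miRanda miRSVR < -0.1 and TargetScan context
#' score < 0.
#'
#' @param list_a,list_b named numeric score vectors, or data frames with
#'   columns `gene_id` and `score`.
#' @param threshold_a,threshold_b strict upper bounds on the scores.
#' @return Sorted character vector of candidate gene ids.
#' @export
intersect_predictions <- function(list_a, threshold_a = -0.1,
                                  list_b, threshold_b = 0) {
  as_scores <- function(l) {
    if (is.data.frame(l)) setNames(l$score, l$gene_id) else l
  }
  a <- as_scores(list_a)
  b <- as_scores(list_b)
  if (!is.finite(threshold_a) || !is.finite(threshold_b))
    stop("thresholds must be finite")
  sort(intersect(names(a)[a < threshold_a], names(b)[b < threshold_b]))
}

#' Integrate overexpression response with cohort anticorrelation
#'
#' For every candidate gene, computes the Spearman correlation with the
#' miRNA across cohort samples and pairs it with the gene's moderated t from
#' the overexpression experiment.  Candidates are ordered by the combined
#' rank: rank(t ascending) + rank(rho ascending), ties broken by gene id, so
#' position 1 is the gene most down-regulated on both axes (the lower-left
#' corner of the response-vs-correlation scatter).
#'
#' @param candidates character vector of candidate gene ids (typically from
#'   [intersect_predictions()]).
#' @param fit `moderated_t` object from the overexpression experiment.
#' @param cohort a `cohort_dataset`.
#' @param mirna_id row of the cohort miRNA matrix to correlate against.
#' @return Data frame sorted by `position`: `gene_id`, `rho`, `p_rho`,
#'   `t_tilde`, `rank_t`, `rank_rho`, `combined_rank`, `position`.
#'   Candidates missing from the cohort or the fit are recorded in
#'   `attr(, "missing")` and excluded.
#' @export
integrate_candidates <- function(candidates, fit, cohort, mirna_id) {
  if (length(candidates) == 0L) stop("no candidate genes")
  if (!mirna_id %in% rownames(cohort$mirna_expr))
    stop("miRNA not in cohort: ", mirna_id)
  present <- candidates %in% rownames(cohort$mrna_expr) &
    candidates %in% fit$table$gene_id
  miss <- candidates[!present]
  if (length(miss) > 0L)
    warning(length(miss), " candidate(s) missing from cohort or fit: ",
            paste(head(miss, 5L), collapse = ", "))
  genes <- sort(candidates[present])
  if (length(genes) == 0L) stop("no candidates left after matching")

  mir <- cohort$mirna_expr[mirna_id, ]
  cors <- lapply(genes, function(gn)
    spearman_correlation(mir, cohort$mrna_expr[gn, ]))
  rho <- vapply(cors, `[[`, numeric(1L), "rho")
  p_rho <- vapply(cors, `[[`, numeric(1L), "p")
  tt <- fit$table$t_tilde[match(genes, fit$table$gene_id)]

  rank_of <- function(v) {
    r <- integer(length(v))
    r[order(v, genes)] <- seq_along(v)
    r
  }
  rank_t <- rank_of(tt)
  rank_rho <- rank_of(rho)
  combined <- rank_t + rank_rho
  ord <- order(combined, genes)
  out <- data.frame(
    gene_id = genes, rho = rho, p_rho = p_rho, t_tilde = tt,
    rank_t = rank_t, rank_rho = rank_rho, combined_rank = combined,
    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  out$position <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "missing") <- miss
  out
}
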