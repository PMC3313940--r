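# Word-enrichment engine: the running-sum statistic, its nulls, Z/FDR.

small_fixture <- function(G = 10, len = 30, seed = 51) {
  set.seed(seed)
  seqs <- setNames(replicate(G, random_dna(len)), sprintf("g%02d", 1:G))
  seqs
}

test_that("word_score matches its closed-form single-hit example", {
  counts <- matrix(c(1, 0, 0, 0, 0), 5, 1,
                   dimnames = list(paste0("g", 1:5), "AA"))
  ids <- paste0("g", 1:5)
  expect_equal(word_score(ids, counts, "AA"), 2 / sqrt(5),
               tolerance = 1e-12)
  # reversing the list sends the concentration to the bottom
  rev_score <- word_score(rev(ids), counts, "AA")
  expect_lt(rev_score, 0.1 * word_score(ids, counts, "AA"))
  # constant vector is unscorable
  counts1 <- matrix(1, 5, 1, dimnames = list(ids, "AA"))
  expect_error(word_score(ids, counts1, "AA"), "unscorable")
})

test_that("observed scores equal the independent brute-force oracle", {
  # G <= 12 genes, length-2 words, loops-only oracle
  for (seed in c(52, 53)) {
    seqs <- small_fixture(G = 12, len = 25, seed = seed)
    ids <- sample(names(seqs))
    scores <- score_all_words(ids, seqs, lengths = 2, B = 100, S = 1,
                              seed = seed)
    for (w in scores$word) {
      expect_equal(scores$score[scores$word == w],
                   brute_word_score(ids, seqs, w),
                   tolerance = 1e-12)
    }
    # unscorable words are exactly those the oracle cannot standardize
    for (w in attr(scores, "unscorable")) {
      expect_true(is.na(brute_word_score(ids, seqs, w)))
    }
  }
})

test_that("word_score and the batched scorer agree", {
  seqs <- small_fixture(G = 30, len = 60, seed = 54)
  ids <- names(seqs)
  counts <- count_words(seqs, 3)
  scores <- score_all_words(ids, seqs, lengths = 3, B = 100, S = 1, seed = 55)
  pick <- sample(scores$word, 20)
  for (w in pick) {
    expect_equal(scores$score[scores$word == w], word_score(ids, counts, w),
                 tolerance = 1e-12)
  }
})

test_that("permutation null is reproducible and centered", {
  seqs <- small_fixture(G = 40, len = 50, seed = 56)
  counts <- count_words(seqs, 2)
  a <- permutation_null(names(seqs), counts, "AC", B = 50, seed = 57)
  b <- permutation_null(names(seqs), counts, "AC", B = 50, seed = 57)
  expect_identical(a, b)
  expect_error(permutation_null(names(seqs), counts, "AC", B = 0), ">= 1")
  # central-limit check at B = 1000: null mean near 0 on the score scale
  # central-limit check at B = 1000: the prefix-sum maximum of a
  # standardized walk has a positive, O(1) mean, and the sample mean is
  # stable at the CLT rate between independent halves
  nn <- permutation_null(names(seqs), counts, "AC", B = 1000, seed = 58)
  expect_gt(mean(nn), 0)
  expect_lt(mean(nn), 2)
  expect_lt(abs(mean(nn[1:500]) - mean(nn[501:1000])),
            3 * sd(nn) / sqrt(250))
  # a word scored on randomly permuted counts is indistinguishable from its
  # own permutation null in most seeds
  hits <- 0
  for (k in 1:10) {
    set.seed(k)
    obs <- word_score(sample(names(seqs)), counts, "AC")
    p <- (1 + sum(nn >= obs)) / (1 + length(nn))
    if (p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("shuffle null respects fixed points and composition classes", {
  # all-A UTRs are invariant under dinucleotide shuffling
  allA <- setNames(rep(paste(rep("A", 20), collapse = ""), 5),
                   paste0("g", 1:5))
  reps <- shuffle_null(allA, 2, S = 2, seed = 59)
  base <- count_words(allA, 2)
  expect_identical(reps[[1]], base)
  expect_identical(reps[[2]], base)
  # fixed seed reproducibility
  seqs <- small_fixture(G = 20, len = 100, seed = 60)
  r1 <- shuffle_null(seqs, 2, S = 3, seed = 61)
  r2 <- shuffle_null(seqs, 2, S = 3, seed = 61)
  expect_identical(r1, r2)
  # dinucleotide counts are preserved exactly per gene and replicate
  expect_equal(r1[[1]][, ], count_words(seqs, 2)[, ])
  # for longer words the total window count is conserved exactly (same
  # sequence lengths) even though individual word counts randomize
  reps3 <- shuffle_null(seqs, 3, S = 5, seed = 62)
  total3 <- sum(count_words(seqs, 3))
  for (m in reps3) expect_equal(sum(m), total3)
  expect_false(identical(reps3[[1]], count_words(seqs, 3)))
})

test_that("score_all_words covers the full universe and annotates", {
  seqs <- small_fixture(G = 25, len = 120, seed = 63)
  scores <- score_all_words(names(seqs), seqs, lengths = c(2, 3), B = 100,
                            S = 2, seed = 64)
  expect_s3_class(scores, "word_scores")
  expect_equal(nrow(scores) + length(attr(scores, "unscorable")), 16L + 64L)
  expect_equal(sort(scores$rank), seq_len(nrow(scores)))
  # FDR monotone non-decreasing as Z decreases, within [0, 1]
  expect_true(all(diff(scores$FDR[order(-scores$Z)]) >= 0))
  expect_true(all(scores$FDR >= 0 & scores$FDR <= 1))
  # determinism under the master seed
  again <- score_all_words(names(seqs), seqs, lengths = c(2, 3), B = 100,
                           S = 2, seed = 64)
  expect_equal(as.data.frame(scores), as.data.frame(again))
  # genes without UTR are dropped with a warning
  expect_warning(
    score_all_words(c(names(seqs), "ghost"), seqs, lengths = 2, B = 100,
                    S = 1, seed = 65), "without a UTR")
  expect_error(
    score_all_words(names(seqs), seqs, lengths = 2, B = 50, S = 1, seed = 1),
    "B >= 100")
})

test_that("null Z values match the observed Z distribution under the null", {
  # a ranking that is itself random: observed scores are exchangeable with
  # the permutation null, so their Z distributions agree (KS)
  set.seed(66)
  seqs <- setNames(replicate(200, random_dna(150)), sprintf("g%03d", 1:200))
  ids <- sample(names(seqs))
  scores <- score_all_words(ids, seqs, lengths = 5, B = 500, S = 1,
                            seed = 67)
  # rebuild the pooled-null Z sample for the stratum
  nm <- scores$null_mean[1]
  ns <- scores$null_sd[1]
  counts <- count_words(seqs, 5)
  set.seed(child_seed(67, "perm", 5))
  orders <- vapply(seq_len(500), function(b) sample.int(200), integer(200))
  nulls <- mirword:::sparse_run_max_scores(counts[ids, ] * 1.0, orders)
  z_null <- (nulls[!is.na(nulls[, 1]), ] - nm) / ns
  ks <- suppressWarnings(stats::ks.test(scores$Z, as.vector(z_null)))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted-word recovery strengthens with effect size", {
  recover_rank1 <- function(delta, seed) {
    sim <- generate_utrs(G = 600, length_range = c(150, 600), f = 0.2,
                         seed = child_seed(seed, "u"))
    oe <- generate_overexpression(names(sim$utrs), sim$carriers,
                                  delta = delta, sigma = 1,
                                  seed = child_seed(seed, "e"))
    fit <- suppressWarnings(
      fit_moderated_t(normalize_median(oe$expr), oe$design))
    sc <- score_all_words(rank_genes(fit), sim$utrs, lengths = 7, B = 150,
                          S = 2, seed = child_seed(seed, "w"))
    sc$word[sc$rank == 1] == "CACTGCC"
  }
  hi <- sum(vapply(1:10, function(s) recover_rank1(1.0, s), logical(1)))
  lo <- sum(vapply(1:10, function(s) recover_rank1(0.25, s), logical(1)))
  expect_gte(hi, lo)
  expect_gte(hi, 9)
})

test_that("report_top_words renders ranked rows with seed capitalization", {
  seqs <- small_fixture(G = 25, len = 120, seed = 68)
  scores <- score_all_words(names(seqs), seqs, lengths = 3, B = 100, S = 1,
                            seed = 69)
  top <- report_top_words(scores, 10)
  expect_equal(nrow(top), 10L)
  expect_equal(top$rank, 1:10)
  expect_true(all(diff(top$Z) <= 0))
  expect_warning(all_rows <- report_top_words(scores, 10000), "exceeds")
  expect_equal(nrow(all_rows), nrow(scores))
  # aligned words capitalize their seed letters, unaligned stay lower-case
  aligned <- !is.na(scores$mir_start)
  expect_true(all(scores$word_display[!aligned] ==
                    tolower(scores$word[!aligned])))
})
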