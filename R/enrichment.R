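# Ranked-list word enrichment: a running-sum statistic over standardized
# 3'UTR word counts, calibrated against rank permutations and
# dinucleotide-shuffled sequences, summarized per word as Z, rank and
# empirical FDR.
#
# For a word with (optionally transformed) count x_i in the UTR at rank i
# (rank 1 = most down-regulated), standardize with the population sd over
# all G genes, z_i = (x_i - mean(x)) / sd(x), and take
#   score = max_k (sum_{i<=k} z_i) / sqrt(G).
# Large scores mean the word's occurrences concentrate among the most
# down-regulated genes.

.word_transform <- function(counts, use_presence, per_kb, utr_lengths) {
  x <- counts * 1.0
  if (use_presence) x <- (x > 0) * 1.0
  if (per_kb) {
    if (is.null(utr_lengths)) stop("per_kb = TRUE needs utr_lengths")
    x <- x / (utr_lengths / 1000)
  }
  x
}

#' Running-sum enrichment score for one word
#'
#' @param ranked character vector of gene ids in rank order (rank 1 = most
#'   down-regulated), or a data frame with a `gene_id` column as returned by
#'   [rank_genes()].
#' @param counts gene x word count matrix ([count_words()]); rows are looked
#'   up by gene id.
#' @param word the word to score (a column of `counts`).
#' @param use_presence score binary presence instead of occurrence counts.
#' @param per_kb normalize counts per kilobase of UTR.
#' @param utr_lengths named UTR lengths (needed for `per_kb`).
#' @return The observed score (numeric scalar).  A count vector that is
#'   constant across genes has no defined score: error.
#' @export
word_score <- function(ranked, counts, word, use_presence = FALSE,
                       per_kb = FALSE, utr_lengths = NULL) {
  ids <- if (is.data.frame(ranked)) ranked$gene_id else ranked
  if (!word %in% colnames(counts)) stop("word not in count matrix: ", word)
  x <- .word_transform(counts[ids, word], use_presence, per_kb,
                       utr_lengths[ids])
  g <- length(x)
  mu <- mean(x)
  sd_pop <- sqrt(max(mean(x * x) - mu * mu, 0))
  if (sd_pop <= 1e-12)
    stop("word '", word, "' has a constant count vector: unscorable")
  max(cumsum((x - mu) / sd_pop)) / sqrt(g)
}

#' Rank-permutation null scores for one word
#'
#' Scores `B` independent uniform permutations of the gene order with the
#' count vector held fixed.
#'
#' @inheritParams word_score
#' @param B number of permutations (>= 1).
#' @param seed RNG seed; the same seed reproduces the same samples.
#' @return Numeric vector of `B` null scores.
#' @export
permutation_null <- function(ranked, counts, word, B, seed = 1,
                             use_presence = FALSE, per_kb = FALSE,
                             utr_lengths = NULL) {
  if (B < 1L) stop("B must be >= 1")
  ids <- if (is.data.frame(ranked)) ranked$gene_id else ranked
  set.seed(seed)
  vapply(seq_len(B), function(b) {
    word_score(sample(ids), counts, word, use_presence, per_kb, utr_lengths)
  }, numeric(1L))
}

#' Dinucleotide-shuffle null count matrices
#'
#' Re-counts every word on `S` independently dinucleotide-shuffled copies of
#' every UTR.  Scoring these matrices in the original gene order contributes
#' sequence-composition-controlled null samples.
#'
#' @param utrs named character vector or [Biostrings::DNAStringSet].
#' @param lengths word lengths to count.
#' @param S number of shuffle replicates (>= 1).
#' @param seed RNG seed.
#' @return List of `S` count matrices (genes x words).
#' @export
shuffle_null <- function(utrs, lengths, S, seed = 1) {
  if (S < 1L) stop("S must be >= 1")
  lapply(seq_len(S), function(s) {
    set.seed(child_seed(seed, "shuffle", s))
    count_words(shuffle_utrs(utrs), lengths)
  })
}

#' Score every word of the given lengths against a ranked gene list
#'
#' The full enrichment engine: every word from [enumerate_words()] is scored
#' with the running-sum statistic; per word-length stratum a null ensemble
#' is assembled from `B` rank permutations plus `S` dinucleotide-shuffle
#' replicates, the observed score is standardized against it (Z), words are
#' ranked by Z descending, and an empirical FDR is attached:
#'   FDR(z) = (#\{Z_null >= z\} / (B + S)) / max(1, #\{Z_obs >= z\}),
#' capped at 1 and monotonized (non-decreasing down the ranking).  Null
#' calibration is stratified by word length because score variance tracks
#' word frequency, which scales with length.  Each word is annotated by
#' [align_word_to_mirna()].
#'
#' @param ranked ranked gene ids ([rank_genes()] output or character
#'   vector), rank 1 = most down-regulated.  Genes without a UTR are dropped
#'   with a warning.
#' @param utrs named character vector or [Biostrings::DNAStringSet] of UTRs.
#' @param lengths word lengths (default 5-7: the 21,504-word universe).
#' @param B rank permutations per stratum (default 500).
#' @param S shuffle replicates per stratum (default 5).
#' @param seed master seed; child seeds per (stratum, replicate) are derived
#'   with [child_seed()] so results are independent of evaluation order.
#' @param mirna miRNA used for the seed-alignment annotation.
#' @param use_presence score binary presence instead of counts.
#' @param per_kb normalize counts per kilobase of UTR.
#' @return Data frame of class `word_scores`, sorted by rank: `word`,
#'   `length`, `score`, `null_mean`, `null_sd`, `Z`, `rank`, `FDR`,
#'   `mir_start`, `mir_end`, `word_display`.  Unscorable words (constant
#'   count vector) are recorded in `attr(, "unscorable")`; `attr(, "null")`
#'   stores B, S and the seed.
#' @export
score_all_words <- function(ranked, utrs, lengths = c(5L, 6L, 7L), B = 500L,
                            S = 5L, seed = 1L, mirna = mir34a_5p,
                            use_presence = FALSE, per_kb = FALSE) {
  if (B < 100L || S < 1L)
    stop("null ensemble too small for a reported FDR: need B >= 100, S >= 1")
  ids <- if (is.data.frame(ranked)) ranked$gene_id else ranked
  if (!methods::is(utrs, "DNAStringSet"))
    utrs <- Biostrings::DNAStringSet(utrs)
  missing <- setdiff(ids, names(utrs))
  if (length(missing) > 0L) {
    warning(length(missing), " ranked gene(s) without a UTR dropped")
    ids <- setdiff(ids, missing)
  }
  utrs <- utrs[ids]  # rows in ranked order from here on
  g <- length(ids)
  utr_lengths <- setNames(Biostrings::width(utrs), ids)
  n_rep <- B + S

  strata <- lapply(sort(unique(as.integer(lengths))), function(L) {
    counts <- count_words(utrs, L)
    x <- .word_transform(counts, use_presence, per_kb, utr_lengths)

    set.seed(child_seed(seed, "perm", L))
    orders <- vapply(seq_len(B), function(b) sample.int(g),
                     integer(g))
    scores <- sparse_run_max_scores(x, cbind(seq_len(g), orders))
    scorable <- !is.na(scores[, 1L])
    words <- colnames(counts)[scorable]
    unscorable <- colnames(counts)[!scorable]
    if (length(words) == 0L)
      return(list(table = NULL, unscorable = unscorable))
    obs <- scores[scorable, 1L]
    null_perm <- scores[scorable, -1L, drop = FALSE]

    null_shuf <- vapply(seq_len(S), function(s) {
      set.seed(child_seed(seed, "shuffle", L, s))
      cs <- count_words(shuffle_utrs(utrs), L)
      xs <- .word_transform(cs, use_presence, per_kb, utr_lengths)
      sparse_run_max_scores(xs, matrix(seq_len(g), ncol = 1L))[scorable, 1L]
    }, numeric(length(words)))

    nulls <- c(null_perm, null_shuf)
    nulls <- nulls[is.finite(nulls)]
    null_mean <- mean(nulls)
    null_sd <- sd(nulls)
    z_obs <- (obs - null_mean) / null_sd
    z_null_sorted <- sort((nulls - null_mean) / null_sd)

    # per-stratum empirical FDR: expected null exceedances per replicate set
    # over observed exceedances
    n_null <- length(z_null_sorted)
    null_ge <- n_null - findInterval(z_obs - 1e-12, z_null_sorted)
    obs_sorted <- sort(z_obs)
    obs_ge <- length(z_obs) - findInterval(z_obs - 1e-12, obs_sorted)
    fdr <- pmin((null_ge / n_rep) / pmax(1, obs_ge), 1)

    list(table = data.frame(
      word = words, length = nchar(words[1L]), score = obs,
      null_mean = null_mean, null_sd = null_sd, Z = z_obs, FDR = fdr,
      row.names = NULL, stringsAsFactors = FALSE),
      unscorable = unscorable)
  })

  tab <- do.call(rbind, lapply(strata, `[[`, "table"))
  if (is.null(tab) || nrow(tab) == 0L) stop("no scorable words")
  ord <- order(-tab$Z, tab$word)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$FDR <- cummax(tab$FDR)  # monotone: non-decreasing as Z decreases

  aln <- lapply(tab$word, function(w) {
    if (nchar(w) >= 5L && nchar(w) <= 8L) align_word_to_mirna(w, mirna)
  })
  tab$mir_start <- vapply(aln, function(a)
    if (is.null(a)) NA_integer_ else a$mir_start, integer(1L))
  tab$mir_end <- vapply(aln, function(a)
    if (is.null(a)) NA_integer_ else a$mir_end, integer(1L))
  tab$word_display <- mapply(format_seed_word, tab$word, aln,
                             USE.NAMES = FALSE)
  rownames(tab) <- NULL
  tab <- tab[, c("word", "length", "score", "null_mean", "null_sd", "Z",
                 "rank", "FDR", "mir_start", "mir_end", "word_display")]
  attr(tab, "unscorable") <-
    unlist(lapply(strata, `[[`, "unscorable"), use.names = FALSE)
  attr(tab, "null") <- list(B = B, S = S, seed = seed)
  class(tab) <- c("word_scores", "data.frame")
  tab
}

#' Top-k report of the most down-regulation-associated words
#'
#' The report mirrors the usual presentation of such scans: one row per
#' word, seed-matching letters capitalized, with Z, rank and FDR.
#'
#' @param scores a `word_scores` table from [score_all_words()].
#' @param k rows to report (default 10).
#' @return Data frame with columns `word`, `Z`, `rank`, `FDR`.
#' @export
report_top_words <- function(scores, k = 10L) {
  if (nrow(scores) == 0L) stop("empty score table")
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(scores)) {
    warning("k exceeds the number of scored words; returning all rows")
    k <- nrow(scores)
  }
  out <- head(scores[order(scores$rank), ], k)
  data.frame(word = out$word_display, Z = out$Z, rank = out$rank,
             FDR = out$FDR, row.names = NULL, stringsAsFactors = FALSE)
}
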