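# Independent brute-force oracles: straight loops, no shared code with the
# package implementations they check.

# sliding-window occurrence count
brute_count <- function(sequence, word) {
  n <- nchar(sequence)
  w <- nchar(word)
  if (w > n) return(0L)
  hits <- 0L
  for (i in seq_len(n - w + 1L)) {
    if (substr(sequence, i, i + w - 1L) == word) hits <- hits + 1L
  }
  hits
}

# overlapping dinucleotide count vector (16 entries, fixed order)
brute_dinuc_vector <- function(sequence) {
  pairs <- substring(sequence, seq_len(nchar(sequence) - 1L),
                     2L:nchar(sequence))
  lv <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        paste0))
  table(factor(pairs, levels = sort(lv)))
}

# running-sum word score: count by loops, standardize with population sd,
# track the prefix-sum maximum directly
brute_word_score <- function(ranked_ids, seqs, word) {
  x <- numeric(length(ranked_ids))
  for (i in seq_along(ranked_ids)) {
    x[i] <- brute_count(seqs[[ranked_ids[i]]], word)
  }
  g <- length(x)
  mu <- sum(x) / g
  sd_pop <- sqrt(sum((x - mu)^2) / g)
  if (sd_pop == 0) return(NA_real_)
  run <- 0
  best <- -Inf
  for (i in seq_len(g)) {
    run <- run + (x[i] - mu) / sd_pop
    if (run > best) best <- run
  }
  best / sqrt(g)
}

# exact one-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (tie-free inputs)
brute_wilcoxon_less <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)])
  sets <- combn(length(v), n1)
  sums <- apply(sets, 2L, function(ix) sum(r[ix]))
  mean(sums <= obs)
}

# average ranks without rank(): used for the Spearman cross-check
brute_avg_ranks <- function(v) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }
  out
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
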