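# Canonical miRNA seed-site scanning and word-to-miRNA alignment.
#
# Site nomenclature follows the canonical-target-site convention: the seed is
# miRNA bases 2-8; a 6mer site is the (DNA) reverse complement of bases 2-7,
# a 7mer-m8 adds complementarity to base 8 on the 5' side, a 7mer-A1 adds an
# adenosine opposite base 1 on the 3' side, and an 8mer has both.

#' Seed-match words for a mature miRNA
#'
#' @param mirna mature miRNA sequence, 5'->3', RNA or DNA alphabet,
#'   length >= 8.
#' @return Named list with the DNA match words `six` (6mer), `m8` (7mer-m8),
#'   `a1` (7mer-A1) and `eight` (8mer).
#' @export
seed_words <- function(mirna = mir34a_5p) {
  m <- gsub("U", "T", toupper(mirna), fixed = TRUE)
  if (nchar(m) < 8L) stop("miRNA must be at least 8 nt (seed bases 1-8)")
  six <- reverse_complement(substr(m, 2L, 7L))
  m8 <- reverse_complement(substr(m, 2L, 8L))
  list(six = six, m8 = m8, a1 = paste0(six, "A"), eight = paste0(m8, "A"))
}

#' Scan a 3'UTR for canonical seed sites
#'
#' Scans the UTR 5'->3' for the four canonical site types and reports each
#' match once at its maximal type: a locus that qualifies as an 8mer is not
#' additionally reported as the contained 7mers or 6mer, and when two
#' candidate sites overlap the longer type wins (the earlier site at equal
#' length).  Coordinates are 0-based, half-open, on the given (mRNA-sense)
#' strand.
#'
#' @param utr UTR sequence (character) over \{A,C,G,T\}.
#' @param mirna mature miRNA sequence, length >= 8.
#' @return Data frame with columns `site_type` (factor-free character:
#'   "6mer", "7mer-A1", "7mer-m8", "8mer"), `start`, `end`.
#' @export
find_seed_sites <- function(utr, mirna = mir34a_5p) {
  utr <- toupper(as.character(utr))
  sw <- seed_words(mirna)
  n <- nchar(utr)
  empty <- data.frame(site_type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (n < 6L) return(empty)

  hits <- gregexpr(paste0("(?=", sw$six, ")"), utr, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(empty)

  cand <- lapply(as.integer(hits), function(p1) {
    p0 <- p1 - 1L                       # 0-based start of the 6mer core
    has_m8 <- p0 >= 1L && substr(utr, p0, p0) == substr(sw$m8, 1L, 1L)
    has_a1 <- p0 + 6L < n && substr(utr, p1 + 6L, p1 + 6L) == "A"
    if (has_m8 && has_a1) {
      list(type = "8mer", start = p0 - 1L, end = p0 + 7L)
    } else if (has_m8) {
      list(type = "7mer-m8", start = p0 - 1L, end = p0 + 6L)
    } else if (has_a1) {
      list(type = "7mer-A1", start = p0, end = p0 + 7L)
    } else {
      list(type = "6mer", start = p0, end = p0 + 6L)
    }
  })

  # subsume overlaps: sweep left to right, keep the longer site on conflict
  kept <- list()
  for (s in cand) {
    if (length(kept) > 0L) {
      prev <- kept[[length(kept)]]
      if (s$start < prev$end) {
        if ((s$end - s$start) > (prev$end - prev$start))
          kept[[length(kept)]] <- s
        next
      }
    }
    kept[[length(kept) + 1L]] <- s
  }
  data.frame(
    site_type = vapply(kept, `[[`, character(1L), "type"),
    start = vapply(kept, `[[`, integer(1L), "start"),
    end = vapply(kept, `[[`, integer(1L), "end"),
    stringsAsFactors = FALSE
  )
}

#' Scan a UTR collection for seed sites
#'
#' @param utrs named character vector or [Biostrings::DNAStringSet].
#' @param mirna mature miRNA sequence.
#' @return Data frame with columns `gene_id`, `site_type`, `start`, `end`.
#' @export
seed_scan <- function(utrs, mirna = mir34a_5p) {
  x <- if (methods::is(utrs, "DNAStringSet")) as.character(utrs) else utrs
  out <- lapply(names(x), function(id) {
    df <- find_seed_sites(x[[id]], mirna)
    if (nrow(df) > 0L) cbind(gene_id = id, df, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), site_type = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  out
}

#' Align a word to a miRNA sequence
#'
#' Reports which miRNA positions the word is reverse-complementary to: the
#' word, or a contiguous sub-word of length >= 5, is matched against every
#' window of the miRNA, preferring alignments that overlap seed positions
#' 2-8, then longer matches, then the 5'-most miRNA position.
#'
#' @param word DNA word of length 5-8.
#' @param mirna mature miRNA sequence.
#' @return A list with `mir_start`, `mir_end` (1-based miRNA positions,
#'   inclusive), `word_start`, `word_end` (matched stretch of the word), or
#'   `NULL` when nothing of length >= 5 aligns.
#' @export
align_word_to_mirna <- function(word, mirna = mir34a_5p) {
  word <- toupper(word)
  nw <- nchar(word)
  if (nw < 5L || nw > 8L) stop("word length must be 5-8")
  m <- gsub("U", "T", toupper(mirna), fixed = TRUE)
  nm <- nchar(m)
  rcw <- reverse_complement(word)

  best <- NULL
  best_key <- c(-1L, -1L, -1L)  # (seed overlap, length, -mir_start)
  for (len in seq(nw, 5L)) {
    for (a in seq_len(nw - len + 1L)) {
      sub <- substr(rcw, a, a + len - 1L)
      for (i in seq_len(nm - len + 1L)) {
        if (substr(m, i, i + len - 1L) != sub) next
        mir_start <- i
        mir_end <- i + len - 1L
        overlap <- max(0L, min(mir_end, 8L) - max(mir_start, 2L) + 1L)
        key <- c(overlap, len, -mir_start)
        if (key[1L] > best_key[1L] ||
            (key[1L] == best_key[1L] && key[2L] > best_key[2L]) ||
            (key[1L] == best_key[1L] && key[2L] == best_key[2L] &&
             key[3L] > best_key[3L])) {
          best_key <- key
          # rcw[a + t] pairs mirna[i + t]; word position j = nw + 1 - (a + t)
          best <- list(mir_start = mir_start, mir_end = mir_end,
                       word_start = nw + 1L - (a + len - 1L),
                       word_end = nw + 1L - a)
        }
      }
    }
  }
  best
}

#' Render a word with its seed-matching letters capitalized
#'
#' Letters whose aligned miRNA partner lies in the seed region (bases 2-8)
#' are upper-cased, all other letters lower-cased; a word with no alignment
#' renders fully lower-case.
#'
#' @param word DNA word.
#' @param alignment result of [align_word_to_mirna()] (or `NULL`).
#' @return Display string.
#' @export
format_seed_word <- function(word, alignment) {
  out <- tolower(word)
  if (is.null(alignment)) return(out)
  chars <- strsplit(out, "")[[1L]]
  for (j in seq(alignment$word_start, alignment$word_end)) {
    # word position j pairs miRNA position mir_end - (j - word_start)
    mir_pos <- alignment$mir_end - (j - alignment$word_start)
    if (mir_pos >= 2L && mir_pos <= 8L) chars[j] <- toupper(chars[j])
  }
  paste(chars, collapse = "")
}
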