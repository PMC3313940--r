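# Sequence handling: FASTA input, sanitization, k-mer enumeration/counting,
# dinucleotide-preserving shuffling.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Sanitize UTR sequences
#'
#' Upper-cases, maps U to T, and drops IUPAC ambiguity characters (N, R, Y,
#' ...) with a warning.  Characters outside the IUPAC nucleotide alphabet are
#' an error.  All counting and shuffling downstream assumes the strict
#' \{A,C,G,T\} alphabet this function guarantees.
#'
#' @param x character vector of sequences.
#' @return Character vector over \{A,C,G,T\}.
#' @export
sanitize_utr <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  residue <- gsub("[ACGT]", "", x)
  if (any(nzchar(residue))) {
    bad <- unique(strsplit(paste(residue, collapse = ""), "")[[1L]])
    if (!all(bad %in% IUPAC_CHARS))
      stop("non-IUPAC characters in sequence: ",
           paste(setdiff(bad, IUPAC_CHARS), collapse = ", "))
    n_dropped <- sum(nchar(residue))
    warning("dropped ", n_dropped, " ambiguous IUPAC base(s) (",
            paste(bad, collapse = ","), ") during sanitization")
    x <- gsub("[^ACGT]", "", x)
  }
  x
}

#' Read 3'UTR sequences from a FASTA file
#'
#' One record per gene; the header token up to the first whitespace is the
#' gene id.  Sequences are sanitized to the \{A,C,G,T\} alphabet (see
#' [sanitize_utr()]).  Duplicate ids, an empty file, and records left empty
#' after sanitization are errors.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @return A named [Biostrings::DNAStringSet], one entry per gene.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- sanitize_utr(as.character(set))
  if (any(!nzchar(seqs)))
    stop("record(s) empty after sanitization: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Enumerate all DNA words of the given lengths
#'
#' All distinct words over \{A,C,G,T\}, lexicographic within each length,
#' lengths in ascending order.  Lengths 5-7 give the 21,504-word universe
#' the enrichment analysis scans.
#'
#' @param lengths integer vector of word lengths (each >= 1).
#' @return Character vector of `sum(4^lengths)` words.
#' @export
enumerate_words <- function(lengths) {
  lengths <- sort(unique(as.integer(lengths)))
  if (length(lengths) == 0L || any(lengths <= 0L))
    stop("word lengths must be positive integers")
  unlist(lapply(lengths, function(L) {
    g <- expand.grid(rep(list(c("A", "C", "G", "T")), L),
                     stringsAsFactors = FALSE)
    # expand.grid varies the first column fastest; lexicographic order needs
    # the last character fastest, so paste the columns in reverse
    do.call(paste0, rev(g))
  }), use.names = FALSE)
}

#' Count occurrences of one word in one sequence
#'
#' Overlapping occurrences are counted: every start position where the word
#' matches exactly contributes one.  A word longer than the sequence gives 0.
#'
#' @param sequence DNA string.
#' @param word DNA word.
#' @return Integer count.
#' @export
count_word <- function(sequence, word) {
  n <- nchar(sequence)
  w <- nchar(word)
  if (w > n || w == 0L) return(0L)
  hits <- gregexpr(paste0("(?=", word, ")"), sequence, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) 0L else length(hits)
}

#' Count all words of the given lengths in a set of UTRs
#'
#' Builds the gene x word occurrence-count matrix (overlapping occurrences
#' included) for every word of each requested length, in the column order of
#' [enumerate_words()].
#'
#' @param utrs named character vector or [Biostrings::DNAStringSet] of
#'   sanitized UTR sequences.
#' @param lengths integer vector of word lengths.
#' @return Integer matrix, genes x words, with dimnames.
#' @export
count_words <- function(utrs, lengths = c(5L, 6L, 7L)) {
  if (!methods::is(utrs, "DNAStringSet"))
    utrs <- Biostrings::DNAStringSet(utrs)
  lengths <- sort(unique(as.integer(lengths)))
  mats <- lapply(lengths, function(L)
    Biostrings::oligonucleotideFrequency(utrs, width = L))
  out <- do.call(cbind, mats)
  rownames(out) <- names(utrs)
  out
}

#' Dinucleotide-preserving shuffle
#'
#' Randomizes a sequence while preserving the exact multiset of overlapping
#' dinucleotides (hence the length, the mononucleotide counts, and the first
#' and last base), sampling uniformly over the Eulerian rearrangements via
#' the Altschul-Erikson construction.  Used as the composition-controlled
#' null for the word-enrichment statistic.  Draws from R's RNG: call
#' `set.seed()` first for reproducibility.
#'
#' @param sequence DNA string (length < 2 is returned unchanged).
#' @return Shuffled DNA string.
#' @export
dinucleotide_shuffle <- function(sequence) {
  if (nchar(sequence) < 2L) return(sequence)
  dinuc_shuffle_cpp(sequence)
}

#' Shuffle every sequence in a UTR collection
#'
#' @param utrs named character vector or [Biostrings::DNAStringSet].
#' @return Named character vector of shuffled sequences.
#' @export
shuffle_utrs <- function(utrs) {
  x <- if (methods::is(utrs, "DNAStringSet")) as.character(utrs) else utrs
  out <- dinuc_shuffle_set_cpp(unname(x))
  names(out) <- names(x)
  out
}

#' Reverse complement of a DNA word
#'
#' @param x DNA string(s) over \{A,C,G,T\}.
#' @return Reverse-complemented string(s).
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}
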