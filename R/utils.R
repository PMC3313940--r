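#' Derive a child seed from a master seed and a tag
#'
#' All stochastic stages of the pipeline draw their own seed from the single
#' master seed and a stage-specific tag (e.g. `"perm/7"` for the length-7
#' rank-permutation null), so results do not depend on the order in which
#' stages run.  The derivation is a 31-ary string hash of the tag folded into
#' the master seed, reduced modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param ... tag components, pasted with "/".
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(master, ...) {
  tag <- paste(..., collapse = "/")
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483647
  as.integer(max(h, 1))
}

#' Write a data frame as a TSV file
#'
#' Tab-separated, header row, no quoting, no row names; the text formats the
#' pipeline exchanges are all of this shape.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated expression matrix
#'
#' First column is the gene identifier, remaining columns one sample each;
#' a header row is required.  Rows containing missing values are dropped
#' with a warning.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus samples")
  genes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in ", path)
  rownames(mat) <- genes
  bad <- rowSums(is.na(mat)) > 0L
  if (any(bad)) {
    warning(sum(bad), " gene(s) with missing values dropped")
    mat <- mat[!bad, , drop = FALSE]
  }
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene ids in ", path)
  mat
}

#' Read a two-arm design file
#'
#' TSV with columns `sample_id` and `arm` (values `treated` / `control`).
#'
#' @param path TSV file path.
#' @return Data frame with columns `sample_id`, `arm`.
#' @export
read_design_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "arm") %in% names(df)))
    stop("design file needs columns 'sample_id' and 'arm'")
  df
}

#' Write a run manifest
#'
#' Every pipeline entry point records its full parameter set (including the
#' seed) as YAML so that any output can be regenerated byte-identically.
#'
#' @param params named list of parameters.
#' @param path output path for the YAML manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}
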