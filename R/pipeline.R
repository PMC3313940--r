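# End-to-end orchestration: each run_* function wraps one analysis stage,
# reads/writes the TSV/FASTA formats, and records a YAML manifest so any
# output can be regenerated from its parameters and seed.  The exec/mirword
# script exposes these as shell subcommands.

.write_fasta <- function(utrs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  x <- if (methods::is(utrs, "DNAStringSet")) as.character(utrs) else utrs
  for (id in names(x)) {
    writeLines(paste0(">", id), con)
    writeLines(x[[id]], con)
  }
  invisible(path)
}

#' Simulate study fixtures
#'
#' Writes the synthetic UTR FASTA, the two-arm expression matrix and design,
#' the ground-truth carrier table, optionally the synthetic cohort, and a
#' manifest that reproduces everything byte-identically.
#'
#' @param outdir output directory (created if absent).
#' @param seed master seed; the UTR, expression and cohort generators get
#'   deterministic child seeds.
#' @param G,f,delta,sigma,n_reps,length_range,base_composition,planted_word
#'   passed to [generate_utrs()] / [generate_overexpression()].
#' @param cohort also write a synthetic cohort (default FALSE).
#' @param ... further arguments for [generate_cohort()].
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(outdir, seed = 1L, G = 2000L, f = 0.2, delta = 1,
                         sigma = 0.2, n_reps = 3L,
                         length_range = c(200L, 2000L),
                         base_composition = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25),
                         planted_word = "CACTGCC", cohort = FALSE, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_utrs(G = G, length_range = length_range,
                       base_composition = base_composition, f = f,
                       planted_word = planted_word,
                       seed = child_seed(seed, "utrs"))
  oe <- generate_overexpression(names(sim$utrs), sim$carriers,
                                n_reps = n_reps, delta = delta,
                                sigma = sigma,
                                seed = child_seed(seed, "overexpression"))
  paths <- list(
    fasta = file.path(outdir, "utrs.fasta"),
    expr = file.path(outdir, "expression.tsv"),
    design = file.path(outdir, "design.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    manifest = file.path(outdir, "manifest.yaml"))
  .write_fasta(sim$utrs, paths$fasta)
  write_tsv(data.frame(gene_id = rownames(oe$expr), oe$expr,
                       check.names = FALSE), paths$expr)
  write_tsv(oe$design, paths$design)
  write_tsv(data.frame(gene_id = names(sim$utrs),
                       carrier = names(sim$utrs) %in% sim$carriers),
            paths$truth)
  manifest <- list(stage = "simulate", seed = seed, utrs = sim$manifest,
                   overexpression = oe$manifest)
  if (cohort) {
    co <- generate_cohort(seed = child_seed(seed, "cohort"), ...)
    paths$mirna <- file.path(outdir, "cohort_mirna.tsv")
    paths$mrna <- file.path(outdir, "cohort_mrna.tsv")
    paths$annot <- file.path(outdir, "cohort_samples.tsv")
    write_tsv(data.frame(mirna_id = rownames(co$cohort$mirna_expr),
                         co$cohort$mirna_expr, check.names = FALSE),
              paths$mirna)
    write_tsv(data.frame(gene_id = rownames(co$cohort$mrna_expr),
                         co$cohort$mrna_expr, check.names = FALSE),
              paths$mrna)
    write_tsv(co$cohort$samples, paths$annot)
    manifest$cohort <- co$manifest
  }
  write_manifest(manifest, paths$manifest)
  invisible(paths)
}

#' Rank genes by moderated t from TSV inputs
#'
#' @param expr_tsv expression matrix TSV (gene_id + one column per sample).
#' @param design_tsv design TSV (`sample_id`, `arm`).
#' @param outdir output directory.
#' @param rank_by ranking metric, `"t"` (default) or `"lfc"`.
#' @param normalize median-center the matrix first (default TRUE; pass
#'   FALSE for pre-normalized input).
#' @return Invisibly, list of written paths.
#' @export
run_diffexpr <- function(expr_tsv, design_tsv, outdir, rank_by = "t",
                         normalize = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mat <- read_expression_tsv(expr_tsv)
  design <- read_design_tsv(design_tsv)
  if (normalize) mat <- normalize_median(mat)
  fit <- fit_moderated_t(mat, design)
  ranked <- rank_genes(fit, by = rank_by)
  paths <- list(fit = file.path(outdir, "moderated_t.tsv"),
                ranked = file.path(outdir, "ranked_genes.tsv"),
                manifest = file.path(outdir, "manifest.yaml"))
  write_tsv(fit$table, paths$fit)
  write_tsv(ranked, paths$ranked)
  write_manifest(list(stage = "diffexpr", expr = expr_tsv,
                      design = design_tsv, rank_by = rank_by,
                      normalize = normalize, d0 = fit$d0, s02 = fit$s02),
                 paths$manifest)
  invisible(paths)
}

#' Score all words against a ranked list from files
#'
#' @param ranked_tsv ranked gene list TSV (from [run_diffexpr()]).
#' @param fasta UTR FASTA.
#' @param outdir output directory.
#' @param lengths,B,S,seed,mirna,use_presence,per_kb see
#'   [score_all_words()].
#' @param top rows in the top-word report.
#' @param up reverse the list to test association with up-regulation.
#' @return Invisibly, list of written paths.
#' @export
run_words <- function(ranked_tsv, fasta, outdir, lengths = c(5L, 6L, 7L),
                      B = 500L, S = 5L, seed = 1L, top = 10L,
                      mirna = mir34a_5p, use_presence = FALSE,
                      per_kb = FALSE, up = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ranked <- read.delim(ranked_tsv, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(ranked))
    stop("ranked list needs a gene_id column")
  ids <- as.character(ranked$gene_id)
  if (up) ids <- rev(ids)
  utrs <- read_utr_fasta(fasta)
  scores <- score_all_words(ids, utrs, lengths = lengths, B = B, S = S,
                            seed = seed, mirna = mirna,
                            use_presence = use_presence, per_kb = per_kb)
  paths <- list(words = file.path(outdir, "word_scores.tsv"),
                top = file.path(outdir, "top_words.tsv"),
                manifest = file.path(outdir, "manifest.yaml"))
  write_tsv(as.data.frame(scores), paths$words)
  write_tsv(report_top_words(scores, top), paths$top)
  write_manifest(list(stage = "words", ranked = ranked_tsv, fasta = fasta,
                      lengths = as.integer(lengths), B = B, S = S,
                      seed = seed, top = top, up = up,
                      use_presence = use_presence, per_kb = per_kb,
                      n_scored = nrow(scores),
                      n_unscorable = length(attr(scores, "unscorable"))),
                 paths$manifest)
  invisible(paths)
}

#' Cohort integration from files
#'
#' @param mirna_tsv,mrna_tsv cohort expression TSVs.
#' @param annot_tsv sample annotation TSV (`sample_id`, `subclass`,
#'   `p53_status`).
#' @param fit_tsv moderated-t table TSV (from [run_diffexpr()]).
#' @param predictions_a,predictions_b prediction TSVs (`gene_id`, `score`).
#' @param threshold_a,threshold_b strict score thresholds (defaults -0.1
#'   and 0).
#' @param mirna_id cohort miRNA to correlate against.
#' @param target_class subclass tested for miRNA down-regulation.
#' @param outdir output directory.
#' @param stratify_p53 also run the subclass test within each p53 stratum.
#' @return Invisibly, list of written paths.
#' @export
run_cohort <- function(mirna_tsv, mrna_tsv, annot_tsv, fit_tsv,
                       predictions_a, predictions_b, threshold_a = -0.1,
                       threshold_b = 0, mirna_id = "miR-34a",
                       target_class = "proneural", outdir,
                       stratify_p53 = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mirna_expr <- read_expression_tsv(mirna_tsv)
  mrna_expr <- read_expression_tsv(mrna_tsv)
  annot <- read.delim(annot_tsv, stringsAsFactors = FALSE)
  cohort <- cohort_dataset(mirna_expr, mrna_expr, annot)
  fit_tab <- read.delim(fit_tsv, stringsAsFactors = FALSE)
  fit <- structure(list(table = fit_tab), class = "moderated_t")
  pa <- read.delim(predictions_a, stringsAsFactors = FALSE)
  pb <- read.delim(predictions_b, stringsAsFactors = FALSE)
  candidates <- intersect_predictions(pa, threshold_a, pb, threshold_b)

  res <- integrate_candidates(candidates, fit, cohort, mirna_id)

  mir <- cohort$mirna_expr[mirna_id, ]
  tests <- list(c(stratum = "all"))
  if (stratify_p53) tests <- c(tests, list(c(stratum = "wild-type")),
                               list(c(stratum = "mutant")))
  test_tab <- do.call(rbind, lapply(tests, function(tc) {
    stratum <- tc[["stratum"]]
    st <- subclass_test(mir, cohort$samples$subclass, target_class,
                        p53_status = cohort$samples$p53_status,
                        p53_stratum = if (stratum == "all") NULL else stratum)
    data.frame(target_class = target_class, p53_stratum = stratum,
               n1 = st$n1, n2 = st$n2, p = st$p, method = st$method,
               stringsAsFactors = FALSE)
  }))

  paths <- list(integration = file.path(outdir, "integration.tsv"),
                tests = file.path(outdir, "subclass_tests.tsv"),
                manifest = file.path(outdir, "manifest.yaml"))
  write_tsv(res, paths$integration)
  write_tsv(test_tab, paths$tests)
  write_manifest(list(stage = "cohort", mirna = mirna_tsv, mrna = mrna_tsv,
                      annot = annot_tsv, fit = fit_tsv,
                      predictions = c(predictions_a, predictions_b),
                      thresholds = c(threshold_a, threshold_b),
                      mirna_id = mirna_id, target_class = target_class,
                      n_samples = cohort$n,
                      n_candidates = nrow(res)),
                 paths$manifest)
  invisible(paths)
}

#' Seed-site scan from a FASTA file
#'
#' @param fasta UTR FASTA.
#' @param out output TSV path.
#' @param mirna mature miRNA sequence (>= 8 nt).
#' @return Invisibly, the output path.
#' @export
run_seedscan <- function(fasta, out, mirna = mir34a_5p) {
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt")
  utrs <- tryCatch(read_utr_fasta(fasta), error = function(e) {
    if (grepl("empty FASTA", conditionMessage(e))) {
      warning("empty FASTA: writing empty site table")
      NULL
    } else {
      stop(e)
    }
  })
  sites <- if (is.null(utrs)) {
    data.frame(gene_id = character(), site_type = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  } else {
    seed_scan(utrs, mirna)
  }
  write_tsv(sites, out)
  invisible(out)
}
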