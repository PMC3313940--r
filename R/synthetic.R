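# Synthetic fixtures with the statistical structure the analysis assumes:
# (a) random UTRs with a planted seed word in a carrier subset, (b) a
# triplicate-vs-triplicate overexpression experiment with carriers shifted
# down, and (c) a tumor cohort with four subclasses, the miRNA shifted down
# in one of them, and one target mRNA anticorrelated with the miRNA through
# a shared latent factor.  Every generator is a pure function of its
# parameters plus the seed, all of which are returned in the manifest.

#' Generate random UTRs with a planted seed word
#'
#' Draws `G` i.i.d.-base UTRs with lengths uniform over `length_range`, then
#' inserts `copies` occurrences of `planted_word` into a carrier fraction
#' `f` of genes at random positions (insertion points are chosen in the
#' original sequence so multiple copies cannot disrupt each other).
#'
#' @param G number of genes (>= 10).
#' @param length_range integer range of UTR lengths (uniform).
#' @param base_composition named probabilities for A, C, G, T (default
#'   uniform; e.g. `c(A = .2, C = .3, G = .3, T = .2)` for 60% GC).
#' @param f carrier fraction in (0, 1); `f = 0` gives the pure-null fixture
#'   (with a warning when `f > 0` rounds to zero carriers).
#' @param planted_word the inserted word (default the miR-34a 7mer-m8 match
#'   "CACTGCC").
#' @param copies possible per-carrier copy numbers (default 1-2, drawn
#'   uniformly).
#' @param seed RNG seed.
#' @return List with `utrs` (named [Biostrings::DNAStringSet]), `carriers`
#'   (character vector of carrier gene ids), and `manifest` (all
#'   parameters).
#' @export
generate_utrs <- function(G = 2000L, length_range = c(200L, 2000L),
                          base_composition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                          f = 0.2, planted_word = "CACTGCC",
                          copies = c(1L, 2L), seed = 1L) {
  if (G < 10L) stop("G must be >= 10")
  if (nchar(planted_word) > length_range[1L])
    stop("planted word does not fit in the minimum UTR length")
  set.seed(seed)
  ids <- sprintf("g%05d", seq_len(G))
  lens <- sample(seq(length_range[1L], length_range[2L]), G, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  prob <- base_composition[bases]
  seqs <- vapply(lens, function(L)
    paste(sample(bases, L, replace = TRUE, prob = prob), collapse = ""),
    character(1L))

  n_carriers <- round(f * G)
  if (f > 0 && n_carriers < 1L) {
    warning("f * G < 1: zero carriers (pure-null fixture)")
    n_carriers <- 0L
  }
  carriers <- sort(sample(G, n_carriers))
  for (i in carriers) {
    k <- sample(copies, 1L)
    cuts <- sort(sample(0L:nchar(seqs[i]), k))
    parts <- substring(seqs[i], c(1L, cuts + 1L), c(cuts, nchar(seqs[i])))
    seqs[i] <- paste(parts, collapse = planted_word)
  }

  utrs <- Biostrings::DNAStringSet(seqs)
  names(utrs) <- ids
  list(
    utrs = utrs,
    carriers = ids[carriers],
    manifest = list(G = G, length_range = length_range,
                    base_composition = as.list(base_composition), f = f,
                    planted_word = planted_word, copies = copies,
                    seed = seed)
  )
}

#' Generate a two-arm overexpression expression matrix
#'
#' Per gene, a baseline log2 level is drawn once; treated-arm replicates are
#' baseline minus `delta` for carriers plus Gaussian noise, control-arm
#' replicates baseline plus noise.  The default replicate noise
#' `sigma = 0.2` log2 units reflects triplicate cell-line array
#' measurements; the planted repression `delta = 1` is a clear direct-target
#' response.
#'
#' @param gene_ids character vector of gene ids.
#' @param carriers gene ids whose UTRs carry the planted word (down-shifted
#'   in the treated arm).
#' @param n_reps replicates per arm (default 3; >= 2).
#' @param delta planted down-shift in log2 units.
#' @param sigma replicate noise sd in log2 units.
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @param seed RNG seed.
#' @return List with `expr` (genes x 2*n_reps matrix), `design` (data frame
#'   `sample_id`, `arm`), and `manifest`.
#' @export
generate_overexpression <- function(gene_ids, carriers, n_reps = 3L,
                                    delta = 1, sigma = 0.2,
                                    baseline_mean = 8, baseline_sd = 1.5,
                                    seed = 1L) {
  if (n_reps < 2L) stop("need at least 2 replicates per arm")
  set.seed(seed)
  G <- length(gene_ids)
  is_carrier <- gene_ids %in% carriers
  baseline <- rnorm(G, baseline_mean, baseline_sd)
  treated <- matrix(baseline - delta * is_carrier, G, n_reps) +
    matrix(rnorm(G * n_reps, 0, sigma), G, n_reps)
  control <- matrix(baseline, G, n_reps) +
    matrix(rnorm(G * n_reps, 0, sigma), G, n_reps)
  expr <- cbind(treated, control)
  colnames(expr) <- c(paste0("mir34a_", seq_len(n_reps)),
                      paste0("ctrl_", seq_len(n_reps)))
  rownames(expr) <- gene_ids
  design <- data.frame(
    sample_id = colnames(expr),
    arm = rep(c("treated", "control"), each = n_reps),
    stringsAsFactors = FALSE)
  list(expr = expr, design = design,
       manifest = list(n_reps = n_reps, delta = delta, sigma = sigma,
                       baseline_mean = baseline_mean,
                       baseline_sd = baseline_sd, seed = seed))
}

#' Generate a synthetic miRNA/mRNA tumor cohort
#'
#' Emulates a subtype-labeled cohort: the miRNA is shifted down by `Delta`
#' log2 units in the proneural subclass; one designated target mRNA is
#' anticorrelated with the miRNA through a shared standard-normal latent
#' factor whose loading is tuned so the Spearman correlation is
#' approximately `-rho_target` (via the bivariate-normal relation
#' r_Pearson = 2 sin(pi * rho_s / 6)); decoy mRNAs and decoy miRNAs are
#' independent noise; p53 status is i.i.d. mutant with probability
#' `p53_mut_fraction`, independent of subclass.
#'
#' @param n_by_subclass named sample counts (defaults 55 proneural, 28
#'   neural, 52 classical, 56 mesenchymal: 191 samples).
#' @param Delta miRNA down-shift in the proneural subclass (log2 units).
#' @param rho_target targeted magnitude of the Spearman anticorrelation.
#' @param p53_mut_fraction probability a sample is p53 mutant.
#' @param n_decoys number of decoy mRNAs.
#' @param n_decoy_mirnas number of decoy miRNAs.
#' @param seed RNG seed.
#' @return List with `cohort` (a [cohort_dataset()]), `truth` (target gene,
#'   miRNA id, implied Pearson loading), and `manifest`.
#' @export
generate_cohort <- function(n_by_subclass = c(proneural = 55L, neural = 28L,
                                              classical = 52L,
                                              mesenchymal = 56L),
                            Delta = 1, rho_target = 0.6,
                            p53_mut_fraction = 0.35, n_decoys = 99L,
                            n_decoy_mirnas = 4L, seed = 1L) {
  if (any(n_by_subclass < 2L)) stop("every subclass needs >= 2 samples")
  set.seed(seed)
  n <- sum(n_by_subclass)
  sample_ids <- sprintf("s%04d", seq_len(n))
  subclass <- rep(names(n_by_subclass), times = n_by_subclass)
  p53 <- sample(c("mutant", "wild-type"), n, replace = TRUE,
                prob = c(p53_mut_fraction, 1 - p53_mut_fraction))

  r_pearson <- 2 * sin(pi * rho_target / 6)
  a <- sqrt(r_pearson)
  u <- rnorm(n)
  mir <- 6 - Delta * (subclass == "proneural") +
    a * u + sqrt(1 - r_pearson) * rnorm(n)
  target <- 9 - a * u + sqrt(1 - r_pearson) * rnorm(n)

  mirna_expr <- rbind(
    mir,
    matrix(rnorm(n_decoy_mirnas * n, 6, 1), n_decoy_mirnas, n))
  rownames(mirna_expr) <- c("miR-34a",
                            paste0("decoy-miR-", seq_len(n_decoy_mirnas)))
  colnames(mirna_expr) <- sample_ids

  mrna_expr <- rbind(
    target,
    matrix(rnorm(n_decoys * n, 9, 1), n_decoys, n))
  rownames(mrna_expr) <- c("TARGET", sprintf("DECOY%03d", seq_len(n_decoys)))
  colnames(mrna_expr) <- sample_ids

  samples <- data.frame(sample_id = sample_ids, subclass = subclass,
                        p53_status = p53, stringsAsFactors = FALSE)
  list(
    cohort = cohort_dataset(mirna_expr, mrna_expr, samples),
    truth = list(target_gene = "TARGET", mirna_id = "miR-34a",
                 r_pearson = r_pearson),
    manifest = list(n_by_subclass = as.list(n_by_subclass), Delta = Delta,
                    rho_target = rho_target,
                    p53_mut_fraction = p53_mut_fraction,
                    n_decoys = n_decoys, n_decoy_mirnas = n_decoy_mirnas,
                    seed = seed)
  )
}
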