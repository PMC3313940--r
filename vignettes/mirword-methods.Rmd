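---
title: "Ranked 3'UTR word enrichment for miRNA target discovery: methods"
author: "mirword"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked 3'UTR word enrichment for miRNA target discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When a single microRNA is over-expressed in a cell line, its direct targets
shift down in the mRNA expression profile, and the shared signature of that
shift is the miRNA's seed-match word in the targets' 3'UTRs.  `mirword`
implements the computational side of that experiment end to end:

1. rank genes by an empirical-Bayes **moderated t-statistic** comparing the
   miRNA-transfected arm with the control arm;
2. score **every DNA word of length 5-7** (4^5 + 4^6 + 4^7 = 21,504 words)
   for association with down-regulation along the ranked list, calibrated
   against two nulls — **dinucleotide-preserving shuffles** of the UTRs and
   **random permutations** of the ranked list — and summarized per word as
   a Z-score, a rank and an empirical FDR;
3. scan UTRs for **canonical seed sites** (6mer, 7mer-A1, 7mer-m8, 8mer);
4. **integrate a tumor cohort**: Spearman anticorrelation between the miRNA
   and each candidate mRNA, one-tailed rank-sum contrasts of miRNA
   expression between expression subclasses (optionally within p53 strata),
   intersection of two external target-prediction lists, and a combined
   rank that nominates genes down-regulated on both axes.

A synthetic-data module generates fixtures with exactly the statistical
structure these analyses assume, so the whole pipeline is testable without
any external download.

# The moderated t-statistic

For gene $g$ with $n_1$ treated and $n_2$ control replicates, let
$s^2_g$ be the pooled sample variance on $d_g = n_1 + n_2 - 2$ degrees of
freedom and $\mathrm{lfc}_g$ the mean log2 difference (treated − control).
The ensemble of $\log s^2_g$ is moment-matched to a scaled log-F prior with
parameters $(d_0, s_0^2)$ — the standard trigamma-inversion estimator — and
each variance is shrunk to

$$\tilde s^2_g = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g}, \qquad
\tilde t_g = \frac{\mathrm{lfc}_g}{\sqrt{\tilde s^2_g (1/n_1 + 1/n_2)}},$$

with $d_0 + d_g$ degrees of freedom.  Limits behave as expected: $d_0 = 0$
reproduces the classical pooled t exactly (tested to 1e-10), and
$d_0 \to \infty$ pools every gene to $s_0^2$.  The trigamma inversion uses
`uniroot` to a tolerance of 1e-10; when the moment equation has no positive
solution (sample variances less dispersed than pure chi-square noise, the
typical outcome for equal-variance simulations), the prior is degenerate
and $d_0 = \infty$ is used with a warning.  Genes with zero variance in
both arms are only a problem when $d_0 = 0$; they are then reported as `NA`
with a warning.  The package cross-checks this estimator against
`limma::fitFDist` in its test suite but does not use limma in the
implementation.

Normalization is deliberately plain **per-sample median centering** (and a
flag to accept pre-normalized matrices unchanged).  The heavier
variance-stabilizing normalizations used on raw array data operate below
the level this pipeline models; every downstream quantity depends only on
the gene *ranking*, which is robust to the choice at synthetic-data scale.

Gene ranking defaults to the moderated t, most down-regulated first; the
log-fold-change is available as an alternative metric (`rank_by = "lfc"`)
because "expression change" can reasonably mean either.  All sorts break
ties by gene id so results are deterministic.

# The word statistic

For a word $w$, let $x_i$ be its occurrence count (overlapping occurrences
included) in the UTR of the gene at rank $i$, $i = 1,\dots,G$.  With the
population standardization $z_i = (x_i - \bar x)/\mathrm{sd}(x)$, the score
is the running-sum maximum

$$S(w) = \max_k \frac{1}{\sqrt G}\sum_{i \le k} z_i ,$$

large when occurrences concentrate among the most down-regulated genes.
This statistic was chosen because it is exhaustively testable against a
brute-force implementation (the suite checks equality to 1e-12 on small
universes) and is sensitive to concentration at the top of the list.  Two
switches cover the natural variants: binary presence instead of counts
(`use_presence`), and counts per kilobase of UTR (`per_kb`); the defaults
are raw counts without length normalization.  Words whose count vector is
constant across genes (in practice: words absent from every UTR) have no
defined score and are reported separately as unscorable.

## Null model and calibration

Two complementary nulls are pooled:

* **Rank permutations** (`B`, default 500): the count vector is fixed and
  the gene order is permuted uniformly — destroys any association with the
  ranking while keeping the word's count distribution.
* **Dinucleotide shuffles** (`S`, default 5): every UTR is rearranged
  uniformly over the sequences with exactly the same multiset of
  overlapping dinucleotides (Altschul-Erikson sampling: a random last-exit
  edge per vertex, accepted when those edges form an arborescence into the
  terminal letter, then a uniform permutation of the remaining edges).
  This controls for local sequence composition, which pure rank
  permutations cannot.

Null samples are pooled **per word-length stratum** (5-, 6- and 7-mers
calibrated separately) because score variance tracks word frequency, which
scales with length.  Per stratum the pooled null mean and sd standardize
the observed scores to Z, and the empirical FDR at threshold $z$ is

$$\widehat{\mathrm{FDR}}(z) = \frac{\#\{Z_{\mathrm{null}} \ge z\}/(B+S)}
{\max(1, \#\{Z_{\mathrm{obs}} \ge z\})},$$

capped at 1 and monotonized by a running maximum down the Z-ranking.  This
exceedance-ratio estimate was preferred over Benjamini-Hochberg on
per-word p-values because overlapping words are strongly dependent and the
pooled null makes no independence assumption.  `B` and `S` are declared
defaults, not inferred values; the `NullEnsemble` contract refuses to
report an FDR from fewer than `B = 100` permutations.

The analysis is one-sided toward down-regulation; an `up` flag reverses
the ranked list for the opposite tail.

## Determinism and speed

One master seed drives everything; child seeds are derived per
(stage, word-length, replicate) with a documented string-hash
(`child_seed`), so results do not depend on evaluation order.  The scorer
exploits sparsity: a zero count contributes a constant negative step to the
running sum, so the prefix maximum can only occur at an occurrence (or at
position 1), and the permutation ensemble is computed gene-major over
non-zero entries in compiled code.  A full 7-mer scan of 2,000 UTRs with
`B = 500`, `S = 5` takes well under a minute on one CPU; the test suite
cross-checks the sparse scorer against a dense reference implementation.

# Seed-site scanning

Sites are named by the seed positions they complement: with the mature
miRNA 5'→3' and its seed at bases 2-8, the 6mer site is the DNA reverse
complement of bases 2-7, the 7mer-m8 extends complementarity to base 8,
the 7mer-A1 adds an adenosine opposite base 1, and the 8mer has both.
Each locus is reported once at its **maximal** type — an 8mer is not also
reported as its contained 7mers — and overlapping candidates resolve to
the longer type (the earlier site at equal length).  Coordinates are
0-based, half-open, on the sense strand only: 3'UTRs are supplied in mRNA
orientation, so reverse-strand scanning is deliberately out of scope.  The
bundled 22-nt mature hsa-miR-34a-5p sequence (`mir34a_5p`) drives the
defaults, and the packaged PDGFRA 3'UTR reporter segment provides the
canonical two-site example (one 7mer-A1, one 7mer-m8).

Word-to-miRNA alignment (the report's capitalization convention) matches
the word, or a contiguous sub-word of length ≥ 5, against every
reverse-complement window of the miRNA, preferring alignments overlapping
seed bases 2-8, then longer matches, then the 5'-most position; letters
aligned within the seed render upper-case, everything else lower-case.

# Cohort integration

* **Spearman correlation**: Pearson on average ranks; two-sided p from the
  large-sample t approximation for $n \ge 10$, exact permutation
  enumeration for $n \le 7$, and 10,000 seeded Monte-Carlo permutations
  for $n$ of 8-9.  Cohort-scale n makes the approximation standard; the
  tiny-n branches exist so unit tests can be exact.
* **Subclass contrast**: one-tailed Wilcoxon rank-sum (target subclass
  lower), exact when the smaller group has ≤ 8 samples and the data are
  tie-free, normal approximation with tie correction otherwise.  p53
  stratification excludes samples with unknown status; unstratified tests
  include them.
* **Prediction intersection**: strict inequalities at the published
  thresholds (miRSVR < −0.1, context score < 0); genes missing from either
  list are excluded.
* **Combined rank**: rank(t ascending) + rank(rho ascending), ties by gene
  id.  The rule is this package's own declared choice — the original
  analysis only displays the two axes as a scatter — and it is isolated in
  `integrate_candidates` so alternatives (e.g. rank products) can be
  swapped in one place.

# What the generators emulate — and what they do not

`generate_utrs` draws i.i.d.-base UTRs (uniform composition by default;
a GC-skew option exists because shuffle calibration is only informative
off-uniform) with lengths uniform on 200-2,000 nt, the human 3'UTR scale,
and plants 1-2 copies of the seed word in a carrier fraction `f` (default
0.2).  Insertion points are chosen in the original sequence so copies
cannot destroy each other; carrier identity is returned as ground truth.

`generate_overexpression` adds a per-gene baseline (N(8, 1.5²) log2 units)
and Gaussian replicate noise.  The default noise `sigma = 0.2` log2 units
reflects triplicate cell-line array replicates; the planted repression
`delta = 1` log2 unit is a clear direct-target response.  The word-recovery
experiments in the tests deliberately run at the harsher `sigma = 1` to
show recovery survives replicate noise of the same order as the effect.

`generate_cohort` uses the four subclass sizes 55/28/52/56 (191 samples),
shifts the miRNA down by `Delta = 1` log2 unit in the proneural subclass,
and couples one target mRNA to the miRNA through a shared standard-normal
latent factor.  The loading is set from the bivariate-normal relation
$r_{\mathrm{Pearson}} = 2\sin(\pi\rho_s/6)$ so the realized Spearman
correlation lands near $-\rho_{\mathrm{target}}$ (default 0.6); the
subclass shift slightly attenuates the marginal correlation, which the
tests' acceptance band absorbs.  p53 status is i.i.d. mutant with
probability 0.35, independent of subclass — adequate for testing the
stratified machinery, not a claim about real p53/subtype dependence.

None of the generators emulate probe-level array artifacts, batch effects,
UTR isoform heterogeneity, miRNA competition, or copy-number structure.
Passing the recovery tests therefore demonstrates that the *machinery* is
correct and calibrated on data satisfying its assumptions; it does not
certify performance on real microarray or tumor-cohort data, where those
un-modeled features dominate the error budget.

# Problem sizes used by the tests

The planted-word recovery experiment runs at its full stated design
(G = 2,000, f = 0.2, δ = 1, σ = 1, 3 vs 3, 7-mers, B = 500, S = 5, ten
master seeds).  The FDR-calibration experiment, whose design is otherwise
open, runs at G = 1,000, B = 200, S = 2 with 60% GC — null calibration is
insensitive to G, and B = 200 already gives the FDR numerator a resolution
of 0.5%.  Property tests that only need a direction (power monotone in
effect size) run at G = 500-600 with B = 150.  These are the package's
declared desk-scale designs; all of them are recomputed from scratch on
every test run.

# Known limitations

* The enrichment statistic tests one miRNA at a time; joint deconvolution
  of several active miRNAs, gapped or degenerate motifs, and motif logos
  are out of scope.
* Site scanning is pattern-matching only: no pairing thermodynamics, no
  conservation scoring (conservation enters only through the external
  prediction lists, which are consumed as given).
* Exactly two arms in the differential-expression model; no probe-level
  processing or multi-factor designs.
* The empirical FDR inherits the granularity of `B + S`; FDRs below
  `1/((B+S) · #words)` are reported as 0.
* p53 "unknown" handling (excluded when stratifying, included otherwise)
  is a declared convention; cohort bookkeeping always operates on explicit
  sample intersections and logs the realized n.
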