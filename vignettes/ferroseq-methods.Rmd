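---
title: "ferroseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ferroseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroseq)
```

## What the package models

`ferroseq` re-implements, as a tested and reusable pipeline, an analysis
design for acute-exposure endothelial transcriptomics: two conditions
(fresh media vs low-dose iron(II) citrate), **one strand-specific RNA-seq
library per condition** per timepoint, reads counted against the exons
and exon–exon junctions of each gene's coding strand, and differential
expression assessed per gene by treating that gene's features as the
replicates of a two-sample test. Around the sequencing arm sit the
validation statistics such a study needs: qPCR relative quantification
against two reference genes, sequencing/qPCR concordance regression, and
proportion / rank / fold-change comparisons for cellular damage assays
(comet tails, pan-nuclear γH2AX, DNA-damage-response foci, p53/GAPDH
ratios).

Because no raw data accompany the design, the package ships a
first-class synthetic-data generator with known ground truth. Every
stage therefore has a parameter-recovery test: the generator writes the
truth, the pipeline estimates it, the tests compare.

## Counting and normalization

Reads are quality-masked (bases with Phred < 20 become `N`), dropped
when shorter than 25 nt, and matched against gene-strand feature
sequences allowing at most 2 mismatches; an `N` always counts as a
mismatch, because a masked base carries no evidence either way. Reads
hitting more than 10 features are discarded. The shipped counter
(`qcAndCountReads`) is deliberately naive — it scans every feature per
read — because the pipeline targets desk-scale synthetic data; it
replaces, rather than wraps, a genome-scale aligner while preserving the
counting semantics the statistics consume.

Two conventions the counting contract leaves open were fixed as
follows, and are configurable:

* **Multi-hit reads** (2–10 hits) count once toward *each* hit feature
  (`multihit = "all"`); only the >10-hit discard rule is part of the
  contract. `multihit = "unique"` restricts counting to single-hit
  reads. Because once-per-hit counting can, under a pathologically
  repetitive annotation, push a library's summed counts above its
  valid-read count, the recorded library depth is floored at the column
  sum so FPKM stays well defined; the QC report always carries the true
  valid-read count.
* **Junction effective length.** A junction's mappable span is bounded
  by the read length, so junctions (and miRNA stem-loops) default to an
  effective length of 40 bp — the read length of the assay this models —
  unless the gene-model file supplies one explicitly.

Normalization is FPKM at feature level:

$$\mathrm{FPKM}_{ij} = \frac{c_{ij} \times 10^9}{L_i \, T_j}$$

with \(c_{ij}\) the count of feature \(i\) in library \(j\), \(L_i\) the
effective length in bp and \(T_j\) the library's total valid reads. The
zero pattern of FPKM always equals that of the counts, and the class
validity enforces it.

## The per-gene test

For gene \(g\) with features \(1..m\), the media and iron libraries give
paired vectors \(x, y \in \mathbb{R}^m\) of per-feature FPKM. The test
is Welch's unequal-variance two-sample \(t\):

$$t = \frac{\bar x - \bar y}{\sqrt{s_x^2/m + s_y^2/m}}, \qquad
\nu = \frac{(s_x^2/m + s_y^2/m)^2}
           {\frac{(s_x^2/m)^2}{m-1} + \frac{(s_y^2/m)^2}{m-1}}$$

with a two-sided p from \(t_\nu\). A variance-ratio F test
(larger/smaller variance, dfs ordered to match, two-sided
\(p = \min(1, 2P(F \ge f))\)) acts as a filter: genes whose feature
variances are demonstrably unequal (\(p_F \le 0.05\)) are excluded from
the ranked list but still reported. Genes are tested when detected
(≥ 1 read in either library) and carrying ≥ 2 features; single-feature
genes are reported untested. Results are ranked by ascending \(p_t\)
with gene-id tie-breaks, and counted at the 0.05 and 0.15 thresholds —
both over filter-passing genes and over all tested genes, since the
design leaves open whether filtered genes belong in the headline totals.

**Caveat stated plainly:** features within a gene are not independent
replicates — they share biology, library effects and length structure.
With one library per condition this test is a *descriptive ranking
device*, not a calibrated inference on biological replication. The
type-I property the test suite checks (nominal level under an
independent Gaussian feature null) verifies the arithmetic, not the
design. Two-sided tests are used throughout; both directions of
regulation are of interest.

Degenerate inputs are resolved explicitly: both variances zero with
equal means gives \(t = 0, p = 1\); zero variances with unequal means is
flagged and reported as \(p = 0\) (infinite evidence under the model).
The value scale is a switch (`fpkm` default, `raw` available): within a
gene, FPKM is a per-feature length rescale of the counts, which changes
the statistic, so the choice is surfaced rather than buried.

## Enrichment and the random-set null

Term enrichment uses the EASE score: the one-tailed hypergeometric
upper-tail probability evaluated after removing one gene from the
overlap, \(p = P(X \ge k-1)\) — conservative for small overlaps, with
\(k \le 1\) giving \(p = 1\). Both Benjamini–Hochberg and Bonferroni
adjustments are computed over the tested terms, since reporting
conventions differ on which to headline. Fold enrichment is
\((k/n)/(K/N)\).

Enriched terms are clustered by Cohen's kappa agreement of their
gene-membership vectors restricted to the query list, with greedy
single-linkage agglomeration at kappa ≥ 0.5 (a configurable knob; the
reference implementation of this style of clustering uses a multi-linkage
heuristic, which we do not reproduce). A cluster's enrichment score is
the mean \(-\log_{10} p\) of its members; the cluster-level fold
enrichment interval is a t-based interval across member-term fold
enrichments, documented as approximate because nothing in the design
defines it.

The negative control re-runs the *entire* enrichment on gene sets of
the query's size sampled without replacement — by default 10 sets, from
either the experiment's detected genes or a RefSeq-scale background of
19,107 protein-coding gene ids — summarizing each replicate by its
smallest adjusted p. The test suite scales this to 200 replicates on an
unplanted ontology and checks the significant fraction against exact
binomial bounds at 0.05.

Published term-level p-values from annotation-era databases are not
reproducible from synthetic annotations; the package reproduces the
*scoring structure*, and its tests check calibration and recovery of
planted signal, not specific terms.

## qPCR and assay statistics

Relative quantification assumes amplification efficiency 2.0 by
default: a pooled Ct becomes a quantity \(E^{-Ct}\), the per-sample
normalizer is the geometric mean of the two reference-gene quantities,
and everything is rescaled so the calibrator sample (the media-treated
sample, the natural control) sits at exactly 1. Replicates pool only
when their Ct standard deviation is ≤ 0.5 cycles (configurable);
scattered wells are flagged and excluded rather than averaged. Relative
quantities are invariant to adding a constant to every Ct of a sample —
the shift cancels through the normalizer — and the suite asserts this on
random plates.

Concordance between sequencing and qPCR is an ordinary least-squares
regression of Ct on log-transformed alignment values with a 0.5
pseudocount; \(r^2\) is provably invariant to the log base, so the base
is cosmetic (default 10). Replicate-matched designs should show
markedly higher \(r^2\) than cross-donor comparisons; with no raw Ct
pairs available this is exercised only as an ordering on synthetic data.

Proportions carry Wilson 95% intervals (good small-sample coverage;
the design itself reports only SEM bars). Reported percentages round
*upward* at the last displayed digit — the conservative convention for
adverse-event rates, which never understates a risk — and the unrounded
proportion is always returned alongside. Two-group comparisons are
Mann–Whitney, exact when both groups have ≤ 20 tie-free values and a
tie-corrected normal approximation otherwise; multi-group designs get
Kruskal–Wallis with Dunn's pairwise z tests, Bonferroni-adjusted across
pairs (raw pairwise p also emitted). Fold-change panels are summarized
by mean, t-based 95% interval, and minimum.

## The synthetic generator: what it does and does not emulate

`simulateUniverse` draws a biotype mix (default 55% mRNA, 15% miRNA,
15% lincRNA, 5% rRNA, 10% other — an rRNA-depleted total-RNA profile),
gives each mRNA gene \(n\) exons plus \(n-1\) junctions, each miRNA a
single stem-loop, and tags equal numbers of endothelial and
non-endothelial marker genes at fixed true abundances 200 and 2 FPKM
(ratio 100, so the marker-specificity check has a by-construction
answer). True abundances are log-normal (median 10 FPKM); fold changes
spike a chosen fraction of genes.

`simulateCounts` inverts the FPKM definition for the expected count,
\(\mu = \mathrm{fpkm} \cdot L/10^3 \cdot T/10^6\), and draws
negative-binomial counts with per-gene dispersion (Poisson at
dispersion 0). NB is the standard overdispersed count model; nothing in
the design specifies a noise model, and NB deliberately exposes how the
feature-level t-test behaves under realistic overdispersion. The
default library depth is \(10^5\)–\(10^6\) reads so a full pipeline run
takes seconds; the full-scale depth of the assay this models
(26 million valid reads per library) is retained only as a documented
parameter. `simulateReads` emits strand-consistent FASTQ with a
two-state (high/low) Phred profile so the masking path is genuinely
exercised.

Not emulated, by design: adapter contamination, realistic error
profiles, rRNA depletion artefacts, correlated feature counts within a
gene, positional coverage bias, and real annotation structure.
Passing tests therefore demonstrate that the *pipeline arithmetic* is
correct and calibrated under its stated model — not that the biological
conclusions of any particular dataset would replicate.

## Problem sizes and numerical tolerances used by the test suite

Chosen so the full suite runs in well under a minute while keeping
binomial/standard-error bounds tight:

* type-I control: 2,000 null genes × 8 features, exact binomial 99%
  bounds around 0.05;
* power: 150 spiked genes per fold-change arm (1, 2, 4, 8) at
  dispersion 0.05 and depth 5×10⁵; a pilot run of the generator at
  these conditions fixed the sensitivity floor at fold 4 (0.5) before
  the floor was frozen into the suite;
* random-set null: 200 replicates over a 40-term unplanted ontology on
  a 2,000-gene universe;
* read-path determinism: a 10-gene universe at depth 3×10⁶ (≈ 5,000
  reads), recounted exactly;
* oracle agreement: 100 random instances per statistic at 10⁻⁶
  (observed agreement is at machine precision; the oracles are
  enumeration, direct PMF summation, and density integration).

## Known limitations

* The feature-as-replicate t-test inherits the single-library design's
  caveats; the package states them rather than repairs them.
* Kappa clustering is greedy single-linkage and will chain loosely
  related terms at permissive thresholds.
* The naive counter is O(reads × features) and is not intended beyond
  desk scale (~10⁶ reads).
* Fold-enrichment cluster intervals are approximate summaries across
  member terms, not confidence intervals for a defined estimand.
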