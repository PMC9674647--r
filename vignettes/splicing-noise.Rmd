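---
title: "Quantifying splicing noise from RNA-seq splice junctions"
author: "spliceNoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying splicing noise from RNA-seq splice junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceNoise)
```

## The problem

Splicing is not perfectly precise. Beyond annotated introns, RNA-seq
reads support a long tail of low-frequency junctions at cryptic splice
sites — "splicing noise". When a splicing safeguard (a chromatin reader,
an RNA-binding protein, a spliceosome component) is lost, this noise
rises: unannotated junctions appear that are specific to the perturbed
condition, their splice sites score poorly against consensus models, and
occasionally a noisy event produces a consequential variant (progerin,
the toxic lamin A variant arising from a weak internal 5' splice site,
is the sentinel example). spliceNoise packages the full quantification
chain for this phenomenon:

1. **De novo junction detection** — junctions absent from the reference
   annotation, exclusive to one condition, after an artifact filter;
2. **Splice-site strength** — maximum-entropy sequence models over
   donor and acceptor windows, scored as log-odds against a background;
3. **Per-gene gain statistics** — gated on transcriptionally stable
   genes so that expression changes do not masquerade as noise changes;
4. **Cohort stratification** — ranking samples by normalized noise
   burden and contrasting the extreme quartiles;
5. **PSI / delta-psi** — isoform-level indices for validation assays.

A seeded synthetic-cohort generator produces complete fixtures (genome,
annotation, per-sample junction files, counts) with planted cryptic
junctions, so every stage can be exercised and checked end to end
without external data.

## De novo junction definition

A junction is an intron call `(contig, start, end, strand)` with a read
count; strand may be unknown (`*`), which matches either strand in all
set logic. The detection chain, per two-condition comparison:

* **classify** — a junction is *annotated* only if its identity exactly
  matches an annotated intron derived from the GTF (gaps between
  consecutive exons of a transcript, deduplicated). Sharing a single
  boundary does not count.
* **pool** — within each condition, all replicates' unannotated
  junctions are pooled (identities merged, counts summed). In `mouse`
  mode pooling and everything downstream happen within each tissue; in
  `cohort` mode all samples of a group form one pool.
* **span filter** — junctions spanning more than 20 kb are removed as
  likely alignment artifacts. The bound is inclusive: a 20,000 bp span
  survives, 20,001 does not. It is configurable (`maxSpan`).
* **exclusivity** — junction identities present in both conditions'
  pools are eliminated; what remains is *de novo* for its condition, so
  the two de novo sets are disjoint by construction.
* **per-sample counts** — the number of *distinct* de novo junctions of
  the sample's own condition observed in that sample (read count >= 1),
  both raw and per million mapped reads (`raw / total_reads * 1e6`).
  Counting distinct junctions rather than junction reads makes the
  quantity a breadth measure of noise, insensitive to a single highly
  covered event.

Condition comparison uses a paired two-sided t test across tissue means
(`mouse` mode, pairing the two genotypes within each tissue) or an
unpaired two-sided t test across samples (`cohort` mode), on the
normalized counts.

In `mouse` mode the per-condition union across tissues could, in
principle, contain an identity that is de novo for opposite conditions
in different tissues; such identities are dropped from both sets (and
tallied in the filter log) to keep the report's disjointness guarantee.

## Maximum-entropy splice-site models

Windows follow the junction geometry exactly: the donor window is the
last 3 exonic plus the first 6 intronic nucleotides (9 nt); the acceptor
window the last 20 intronic plus the first 3 exonic nucleotides (23 nt),
both read 5'->3' on the transcribed strand (minus-strand windows are
reverse-complemented). Junctions of unknown strand are extracted in both
orientations and the higher-scoring orientation is retained and flagged.

`fitMaxEnt()` fits a maximum-entropy distribution over the window's
sequence space under one of three constraint sets:

* `order1` — position marginals only; the model factorizes over
  positions (a position weight matrix).
* `adjacent2` — position and adjacent-pair marginals. The
  maximum-entropy solution for this decomposable constraint set is the
  first-order Markov chain consistent with the pair tables, so it is
  computed in closed form; no enumeration is needed, which is what makes
  the 23-nt acceptor tractable (4^23 is not enumerable).
* `pairwise2` — all pairwise marginals, fitted by iterative
  proportional fitting (IPF) over the fully enumerated space. This is
  restricted to enumerable widths (the 9-nt donor; 4^9 = 262,144
  sequences) and converges when every constrained marginal matches its
  target within `tol` (default 1e-6, at most 500 sweeps; non-convergence
  is an error carrying the residual).

Marginals are smoothed with a pseudocount of 0.5 per cell, which keeps
all probabilities positive. On toy spaces the adjacent-constraint closed
form and IPF run with the same constraints agree to below 1e-8 total
variation — the two implementations serve as mutual oracles in the test
suite.

A window's score is `log2(P_signal / P_background)` in bits; the
*consolidated* score of a junction is the arithmetic mean of its donor
and acceptor scores (the symmetric choice; donor-only and acceptor-only
scores are also reported). Signal models are fitted on the annotation's
own splice sites rather than shipping published parameter tables — this
keeps the package self-contained and valid on any genome, including
synthetic ones. The background is an order-1 model fitted on windows of
*shuffled* junctions: each junction relocated uniformly at random on its
own contig, preserving span and strand (seed-controlled). The
three-class comparison (annotated vs de novo vs shuffled) uses an
ordinary one-way ANOVA on consolidated scores and reports whether the
expected ordering annotated > de novo > shuffled holds.

The default model order for the pipeline is `adjacent2` for both sites:
it captures dinucleotide structure, needs no enumeration, and behaves
identically for the 9-nt and 23-nt windows; `pairwise2` is available for
donors when the full pairwise structure is wanted.

## Per-gene statistics and stratification

Per-gene analysis is gated on *expression-stable* genes: at least
`minTotalReads` (10) reads in total, and a between-condition fold change
of pseudocounted CPM means strictly below the gate (2.0 in the mouse
preset, 1.5 in the cohort preset — "affected less than N-fold" is read
literally, so the boundary itself is excluded). The gate uses CPM by
column sums; a model-based shrunken fold change would require a full
differential-expression fit, which is outside this package's scope.

De novo junctions are assigned to every gene whose span fully contains
the intron interval on a compatible strand — containment is the
strictest defensible rule and avoids crediting a gene with junctions
that merely poke into it. Per gene, the distinct-junction count per
sample is compared between conditions: fold change
`(mean_alt + 1) / (mean_ref + 1)` (pseudocount 1, since zero baselines
are the norm for noise counts) and a two-sided Welch t test. A *gain* is
`fold >= gainFold` (2.0 mouse, 1.5 cohort, inclusive per "N-fold or
more") with `p < alpha` (0.05 / 0.01); a *loss* is symmetric with the
reciprocal fold. When both groups are constant the t statistic is
undefined: identical groups are reported as p = 1, perfectly separated
constant groups (e.g. 0,0,0 vs 2,2,2) as p = 0. No multiple-testing
correction is applied by default because the procedure operates on raw
p-value thresholds; `p.adjust` can always be applied to the returned
table.

Cohort stratification ranks samples by normalized de novo count and cuts
the ranking into four groups whose sizes differ by at most one, with the
remainder given to the outer quartiles (206 samples give 52/51/51/52);
ties break stably by sample id. The upper-vs-lower-quartile contrast
runs a per-gene Welch t test on `log2(CPM + 1)` with a strict fold-change
threshold (default 1.5) and alpha 0.01.

## PSI and delta-psi

`deltaPsi(v1, v2) = v1 / (v1 + v2)` and the variant PSI is
`variant / (canonical + variant)`; both are undefined (NA, flagged) when
the denominator is zero, complementary (`deltaPsi(a,b) + deltaPsi(b,a) =
1`) and scale-invariant. Group summaries report the **mean of
per-sample PSIs**, not the PSI of summed copies — the two differ
whenever expression varies across samples, so the pooled value is
exposed under a separate name (`pooled_psi`) and never silently
substituted. PSI magnitudes around 0.05–0.2 in this context are
per-sample percentages; tables carry both `psi_fraction` and
`psi_percent`. Groups are compared with a two-sided Mann-Whitney U test.
`psiPowerSim()` checks detectability of a given PSI shift: per-sample
PSIs are Beta-distributed (concentration 50) around each group mean,
converted to binomial copy splits of a Poisson total (mean 500), and the
fraction of significant replicates is reported.

## The synthetic cohort

The generator's defaults encode the study conditions the analysis
assumes, and are fixed rather than tuned:

* **Design** — 2 genotypes (`WT`, `KO`) x 3 tissues x 3 replicates = 18
  samples (mouse preset); the cohort preset is 2 groups of 20 + 206
  samples in one tissue.
* **Genome** — 80 genes of 4 exons (exons 100–200 bp, introns
  150–600 bp) tiled with >= 1 kb spacing on one contig. Every annotated
  intron begins GT and ends AG on its coding strand; donor and acceptor
  windows are sampled from strong consensus profiles (fixed GT/AG,
  consensus-biased flanks, pyrimidine-rich acceptor tract).
* **Cryptic sites** — 3 per gene, placed inside gene bodies away from
  annotated splice windows, never coinciding with an annotated intron.
  Weakness is encoded by *degrading* the consensus: each non-fixed
  profile position is replaced by a uniform base with probability 0.5;
  the GT/AG dinucleotides are always retained, so the sites stay
  plausible but score between annotated and random windows. At
  degradation 0 the windows are profile-identical to annotated sites; at
  1 they score like random sequence; the mean score decreases
  monotonically in between.
* **Counts** — annotated junctions draw negative-binomial counts (mean
  = 50 x a lognormal gene factor x a mild tissue factor, dispersion
  0.1); an expressed cryptic junction draws a zero-truncated Poisson
  count (mean 2). A cryptic junction is expressed in a sample with
  probability rho: 0.03 in the reference and 0.3 in the perturbed
  condition — a 10x usage contrast, a tunable default rather than a
  biological claim. 10% of genes change expression 3-fold so the
  stability gate has something to reject.
* **Realism helpers** — 20 unannotated junctions shared by both
  conditions (eliminated by the exclusivity step) and 3 per-sample
  junctions spanning > 20 kb (eliminated by the span filter), so both
  filters operate on every fixture. NB/Poisson count shapes are the
  standard RNA-seq choices; the generator does not model read-level
  errors, sequencing biases, intron retention, or isoform-level
  expression, so passing tests demonstrate the statistical machinery,
  not robustness to alignment artifacts beyond the span class it plants.
* **Determinism** — one master seed expands into per-purpose and
  per-sample sub-seeds by a fixed counter scheme
  (`(seed mod 1e6) * 1013 + k * 7919 + 17`), so the whole fixture is a
  pure function of the design and samples stay independent.

Internally, coordinates live on 1-based closed GRanges (the Bioconductor
convention); the junction-BED dialect (0-based, anchor-block encoded) is
converted at the I/O boundary, where `[chromStart + blockSize1,
chromEnd - blockSize2)` recovers the intron and writing emits symmetric
1-bp anchors so a read/write round trip is lossless.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on the
default 80-gene, 18-sample fixture (240 annotated introns, ~240 planted
cryptic junctions), which completes in well under a minute; the
enumerable-space cross-checks of the maximum-entropy engine use widths
4–5, and the donor-width IPF (4^9) converges in ~10 sweeps. Windows
containing N or falling outside contig bounds are dropped and tallied,
never imputed. Parsers reject structurally invalid input (wrong block
counts, negative counts, duplicate labels, overlapping exons) rather
than repairing it.

## Worked example

```{r example, eval = FALSE}
library(spliceNoise)

fx <- file.path(tempdir(), "fixture")
emitFixture(simulationDesign(seed = 1), fx)

cfg <- pipelineConfig(fx, mode = "mouse", seed = 1)
run <- runNoisePipeline(cfg, file.path(tempdir(), "reports"))

run$comparison$means      # normalized de novo junctions per condition
run$comparison$p          # paired t test across tissues
run$classScores$classMeans  # annotated > de novo > shuffled (bits)
sum(run$geneGain$gain); sum(run$geneGain$loss)
```

## Known limitations

* "Annotated" is defined purely by the supplied GTF; incomplete
  annotations inflate de novo counts for both conditions symmetrically.
* Exclusivity is a set operation: one stray read in the other condition
  vetoes a junction. The `minReads` threshold (default 1) is the only
  guard; raising it trades sensitivity for robustness.
* Splice-site scores are annotation-relative, not comparable across
  genomes or to published scan tables.
* The per-gene test is a plain t test on small counts; with three
  replicates per group its power is limited and the perfect-separation
  convention (p = 0) is deliberately liberal. Treat mouse-mode per-gene
  p-values as screening statistics.
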