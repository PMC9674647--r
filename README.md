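# spliceNoise

Detection and quantification of **splicing noise** — the pervasive
low-level use of cryptic splice sites — from RNA-seq splice-junction
calls. The package is aimed at transcriptomics analysts studying
splicing fidelity: comparing a perturbed condition (a knockout, a
disease group) against a reference, it answers *how many unannotated,
condition-exclusive junctions appear, how weak their splice sites are,
which genes gain them, and which samples carry the heaviest burden*.

## What it computes

**De novo junctions.** For a two-condition design, per-sample junction
calls (BED12 junction dialect, as produced by junction extractors) are
classified against the annotation's introns; unannotated junctions are
pooled per condition, junctions spanning more than 20 kb are removed as
alignment artifacts, and identities present in both conditions are
eliminated. The remainder — unannotated, condition-exclusive — is *de
novo*. Per sample, the distinct de novo junction count is reported raw
and per million mapped reads, and conditions are compared with a paired
(tissue-matched) or unpaired two-sided t test.

**Splice-site strength.** Donor windows take the last 3 exonic + first
6 intronic nucleotides; acceptor windows the last 20 intronic + first 3
exonic, on the transcribed strand. A maximum-entropy sequence model is
fitted to the annotation's own sites — independent positions, an
adjacent-pair model solved in closed form as the consistent Markov
chain, or a full pairwise model via iterative proportional fitting on
the enumerated donor space — and each window is scored as

```
score = log2( P_signal(w) / P_background(w) )   [bits]
```

with the background fitted on shuffled (randomly relocated) junctions.
A junction's consolidated score is the mean of its donor and acceptor
bits; the annotated / de novo / shuffled classes are compared by
one-way ANOVA.

**Per-gene gains, stratification, PSI.** Genes passing an expression
stability gate (>= 10 reads, fold change strictly below 2.0 or 1.5
depending on the study preset) are tested for de novo junction gains
(fold `(m_alt+1)/(m_ref+1)` >= 2.0 / 1.5, p < 0.05 / 0.01). Cohorts are
ranked by normalized noise burden and the extreme quartiles contrasted
by per-gene Welch tests on log2 CPM. Isoform validation uses
`deltaPsi(v1, v2) = v1/(v1+v2)` and variant PSI = variant/(canonical +
variant), summarized as means of per-sample PSIs with Mann-Whitney
comparisons.

A seeded synthetic-cohort generator (`simulationDesign()`,
`cohortDesign()`, `emitFixture()`) builds complete fixtures — genome,
GTF, per-sample junction BEDs, counts table, planted-truth JSON — with
cryptic splice sites whose usage rate differs between conditions, so
the whole chain is testable without external data.

## Worked example

```r
library(spliceNoise)

fx <- file.path(tempdir(), "fixture")
emitFixture(simulationDesign(seed = 1), fx)   # 18-sample mouse-style cohort

cfg <- pipelineConfig(fx, mode = "mouse", seed = 1)
run <- runNoisePipeline(cfg, file.path(tempdir(), "reports"))

round(run$comparison$means, 2)
#>    WT    KO
#>  0.89 63.72
signif(run$comparison$p, 3)
#> [1] 0.000299
round(run$classScores$classMeans, 2)
#> annotated    denovo    random
#>      9.81      3.51    -10.16
run$report
#> NoiseReport (mouse mode): de novo junctions: WT=7, KO=203; 18 samples
```

Read: the perturbed condition carries ~64 de novo junctions per million
mapped reads per sample against ~0.9 in the reference (paired t test
across the three tissues, p = 3.0e-4); the planted cryptic sites score
between annotated splice sites (9.8 bits) and shuffled controls (-10.2
bits), as expected for weak but genuine sites. The per-gene table
(`run$geneGain`) flags 26 genes gaining de novo junctions and none
losing them. `runNoisePipeline()` also writes `noise_report.tsv`,
`scores.tsv`, `gene_noise.tsv` and `summary.json` to the output
directory. A thin command-line wrapper over the same functions lives at
`inst/scripts/splice-noise.R` (subcommands `simulate` and `run`).

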