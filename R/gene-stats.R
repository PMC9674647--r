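#' Gene gating and gain-test configuration
#'
#' Mode presets follow the two study designs: mouse (expression gate and
#' gain threshold twofold, alpha 0.05) and cohort (1.5-fold, alpha 0.01);
#' both require at least 10 reads per gene in total.
#'
#' @param mode `"mouse"` or `"cohort"`, loading the preset; individual
#'   arguments override it.
#' @param minTotalReads minimum total reads per gene across all samples.
#' @param maxExpressionFC expression gate: genes whose between-condition
#'   fold change is `>=` this value (either direction) are excluded
#'   (strictly-less-than gate).
#' @param gainFold per-gene de novo gain threshold (inclusive).
#' @param alpha significance level for the per-gene test.
#' @param pseudocount additive constant in fold computations.
#' @return a list of class `GeneGateConfig`.
#' @export
geneGateConfig <- function(mode = c("mouse", "cohort"),
                           minTotalReads = 10L,
                           maxExpressionFC = NULL, gainFold = NULL,
                           alpha = NULL, pseudocount = 1) {
    mode <- match.arg(mode)
    preset <- if (mode == "mouse")
        list(maxExpressionFC = 2.0, gainFold = 2.0, alpha = 0.05)
    else list(maxExpressionFC = 1.5, gainFold = 1.5, alpha = 0.01)
    cfg <- list(mode = mode, minTotalReads = minTotalReads,
                maxExpressionFC = maxExpressionFC %||% preset$maxExpressionFC,
                gainFold = gainFold %||% preset$gainFold,
                alpha = alpha %||% preset$alpha,
                pseudocount = pseudocount)
    stopifnot(cfg$minTotalReads > 0, cfg$maxExpressionFC > 1,
              cfg$gainFold > 1, cfg$alpha > 0, cfg$alpha < 1,
              cfg$pseudocount >= 0)
    class(cfg) <- "GeneGateConfig"
    cfg
}

#' Gate genes on expression stability
#'
#' A gene is eligible iff its total read count reaches `minTotalReads` and
#' its between-condition fold change of depth-normalized (counts per
#' million by column sums, pseudocounted) means is strictly below
#' `maxExpressionFC` in both directions.
#'
#' @param counts gene x sample integer matrix.
#' @param design data.frame with `sample_id` and `condition`.
#' @param config a [geneGateConfig()].
#' @return data.frame: `gene_id`, `total`, `fold` (non-reference over
#'   reference), `eligible`.
#' @export
gateGenes <- function(counts, design, config) {
    conds <- unique(design$condition)
    if (length(conds) != 2L) stop("design must have exactly two conditions")
    if (!all(colnames(counts) %in% design$sample_id))
        stop("counts table contains samples missing from the design")
    cpm <- t(t(counts) / pmax(colSums(counts), 1L)) * 1e6
    cond <- design$condition[match(colnames(counts), design$sample_id)]
    mRef <- rowMeans(cpm[, cond == conds[1L], drop = FALSE])
    mAlt <- rowMeans(cpm[, cond == conds[2L], drop = FALSE])
    pc <- config$pseudocount
    fold <- (mAlt + pc) / (mRef + pc)
    total <- rowSums(counts)
    eligible <- total >= config$minTotalReads &
        fold < config$maxExpressionFC & fold > 1 / config$maxExpressionFC
    data.frame(gene_id = rownames(counts), total = total, fold = fold,
               eligible = eligible, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Assign junctions to genes by containment
#'
#' A junction is assigned to every gene whose span fully contains its
#' intron interval on a compatible strand (unknown strand matches both).
#'
#' @param gr junction `GRanges`.
#' @param catalog an [AnnotationCatalog-class].
#' @return data.frame: `gene_id`, `junction` (index into `gr`), `key`.
#' @export
assignJunctionsToGenes <- function(gr, catalog) {
    hits <- findOverlaps(gr, catalog@genes, type = "within",
                         ignore.strand = FALSE)
    data.frame(
        gene_id = mcols(catalog@genes)$gene_id[subjectHits(hits)],
        junction = queryHits(hits),
        key = junctionKey(gr)[queryHits(hits)],
        stringsAsFactors = FALSE)
}

## t test robust to constant data: identical everywhere -> 1;
## zero variance in both groups but different means -> 0 (perfect
## separation); otherwise Welch
robustT <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (stats::sd(c(x, y)) == 0) return(1)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(0)
    stats::t.test(x, y)$p.value
}

#' Per-gene de novo junction gain analysis
#'
#' For each gated gene, counts the distinct de novo junctions (of the
#' sample's own condition) present per sample, computes the pseudocounted
#' fold change of the non-reference over the reference condition mean and
#' a two-sided t test across samples, and flags gains (fold `>=`
#' `gainFold` and p < alpha) and losses (fold `<=` 1/`gainFold` and
#' p < alpha).
#'
#' @param report a [NoiseReport-class].
#' @param gr the full junction `GRanges` the report was computed from.
#' @param catalog an [AnnotationCatalog-class].
#' @param counts gene x sample counts table (for the expression gate).
#' @param design data.frame with `sample_id`, `condition`.
#' @param config a [geneGateConfig()].
#' @return data.frame: `gene_id`, per-condition means, `fold`, `p`,
#'   `gain`, `loss`.
#' @export
perGeneGain <- function(report, gr, catalog, counts, design, config) {
    conds <- unique(design$condition)
    if (length(conds) != 2L) stop("need exactly two conditions")
    if (min(table(design$condition)) < 2L)
        stop("need at least two samples per condition")
    gate <- gateGenes(counts, design, config)
    genes <- gate$gene_id[gate$eligible]
    ## per-sample, per-gene distinct de novo junction counts
    dnAll <- unlist(report@denovo, use.names = FALSE)
    dnCond <- rep(names(report@denovo), lengths(report@denovo))
    assign <- assignJunctionsToGenes(dnAll, catalog)
    m <- matrix(0L, nrow = length(genes), ncol = nrow(design),
                dimnames = list(genes, design$sample_id))
    for (i in seq_len(nrow(design))) {
        sid <- design$sample_id[i]
        cc <- design$condition[i]
        sub <- gr[mcols(gr)$sample == sid & mcols(gr)$count >= 1L]
        own <- which(dnCond == cc)
        present <- own[matchesJunctionSet(dnAll[own], sub)]
        if (!length(present)) next
        tab <- table(assign$gene_id[assign$junction %in% present])
        hit <- intersect(names(tab), genes)
        m[hit, sid] <- as.integer(tab[hit])
    }
    refIds <- design$sample_id[design$condition == conds[1L]]
    altIds <- design$sample_id[design$condition == conds[2L]]
    pc <- config$pseudocount
    res <- lapply(genes, function(g) {
        x <- m[g, refIds]; y <- m[g, altIds]
        fold <- (mean(y) + pc) / (mean(x) + pc)
        p <- robustT(x, y)
        data.frame(gene_id = g, mean_ref = mean(x), mean_alt = mean(y),
                   fold = fold, p = p,
                   gain = isTRUE(fold >= config$gainFold & p < config$alpha),
                   loss = isTRUE(fold <= 1 / config$gainFold &
                                 p < config$alpha),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Stratify cohort samples by splicing-noise burden
#'
#' Ranks samples by normalized de novo count and splits them into four
#' quartile groups whose sizes differ by at most one (the remainder goes
#' to the outer quartiles, so 206 samples give 52/51/51/52). Ties are
#' broken stably by sample id. Q4 holds the highest burden.
#'
#' @param report a [NoiseReport-class].
#' @return list: `strata` (data.frame `sample_id`, `normalized`,
#'   `quartile`), `upper`, `lower` (sample id vectors).
#' @export
stratifyByNoise <- function(report) {
    smp <- report@samples
    n <- nrow(smp)
    if (n < 8L) stop("stratification needs at least 8 samples")
    ord <- order(smp$normalized, smp$sample_id)
    base <- n %/% 4L; rem <- n %% 4L
    sizes <- rep(base, 4L)
    ## distribute the remainder outer-first: Q1, Q4, then Q2, Q3
    extra <- c(1L, 4L, 2L, 3L)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
    quart <- rep(paste0("Q", 1:4), times = sizes)
    strata <- data.frame(sample_id = smp$sample_id[ord],
                         normalized = smp$normalized[ord],
                         quartile = quart, stringsAsFactors = FALSE)
    list(strata = strata,
         upper = strata$sample_id[strata$quartile == "Q4"],
         lower = strata$sample_id[strata$quartile == "Q1"])
}

#' Differential expression between noise quartiles
#'
#' Welch two-sided t test per gene on log2(counts-per-million + 1) between
#' the upper and lower noise quartiles; genes with fold change strictly
#' above `fcThreshold` (either direction, pseudocounted CPM means) and
#' p < alpha are reported, split by direction.
#'
#' @param counts gene x sample counts table.
#' @param upper,lower sample id vectors from [stratifyByNoise()].
#' @param fcThreshold fold-change threshold (strict).
#' @param alpha significance level.
#' @return list: `table` (per-gene fold and p), `up`, `down` (gene ids,
#'   up = higher in the upper quartile).
#' @export
deBetweenQuartiles <- function(counts, upper, lower, fcThreshold = 1.5,
                               alpha = 0.01) {
    if (length(upper) < 3L || length(lower) < 3L)
        stop("both quartile groups need at least 3 samples")
    if (!all(c(upper, lower) %in% colnames(counts)))
        stop("quartile samples missing from the counts table")
    cpm <- t(t(counts) / pmax(colSums(counts), 1L)) * 1e6
    lg <- log2(cpm + 1)
    up <- lg[, upper, drop = FALSE]; lo <- lg[, lower, drop = FALSE]
    p <- vapply(seq_len(nrow(lg)), function(i)
        robustT(lo[i, ], up[i, ]), numeric(1))
    mUp <- rowMeans(cpm[, upper, drop = FALSE])
    mLo <- rowMeans(cpm[, lower, drop = FALSE])
    fold <- (mUp + 1) / (mLo + 1)
    tab <- data.frame(gene_id = rownames(counts), fold = fold, p = p,
                      row.names = NULL, stringsAsFactors = FALSE)
    sig <- !is.na(p) & p < alpha
    list(table = tab,
         up = tab$gene_id[sig & fold > fcThreshold],
         down = tab$gene_id[sig & fold < 1 / fcThreshold])
}
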