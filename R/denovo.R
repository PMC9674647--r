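#' Partition junctions into annotated and unannotated
#'
#' A junction is annotated iff its identity (contig, start, end, strand
#' with `*` acting as a wildcard) exactly matches an annotated intron of
#' the catalog; junctions sharing only one boundary are unannotated, as
#' are junctions on contigs absent from the catalog.
#'
#' @param gr junction `GRanges`.
#' @param catalog an [AnnotationCatalog-class].
#' @return list with `annotated` and `unannotated` junction `GRanges`.
#' @export
classifyJunctions <- function(gr, catalog) {
    hit <- matchesJunctionSet(gr, catalog@introns)
    list(annotated = gr[hit], unannotated = gr[!hit])
}

#' Pool junctions across the samples of a condition
#'
#' Junctions with identical identity (contig, start, end, strand) are
#' merged, their read counts summed and their sample provenance collapsed
#' into a comma-separated `samples` column. Pooling is idempotent.
#'
#' @param gr junction `GRanges` (typically several samples concatenated).
#' @return pooled junction `GRanges`.
#' @export
poolJunctions <- function(gr) {
    if (!length(gr)) {
        mcols(gr)$samples <- character(0)
        return(gr)
    }
    key <- junctionKey(gr)
    idx <- split(seq_along(gr), key)
    first <- vapply(idx, `[`, integer(1), 1L)
    out <- gr[first]
    mcols(out)$count <- as.integer(unname(vapply(idx, function(i)
        sum(mcols(gr)$count[i]), numeric(1))))
    prev <- mcols(gr)$samples
    samp <- if (is.null(prev)) mcols(gr)$sample else prev
    mcols(out)$samples <- unname(vapply(idx, function(i)
        paste(sort(unique(unlist(strsplit(samp[i], ",", fixed = TRUE)))),
              collapse = ","), character(1)))
    mcols(out)$sample <- NULL
    names(out) <- NULL
    GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Filter junctions by maximum span
#'
#' Junctions spanning more than `maxSpan` bp are removed as likely
#' alignment artifacts; a junction spanning exactly `maxSpan` is retained.
#'
#' @param gr junction `GRanges`.
#' @param maxSpan maximum retained span in bp (default 20000).
#' @return list with `kept` (GRanges) and `removed` (count).
#' @export
filterSpan <- function(gr, maxSpan = 20000L) {
    keep <- junctionSpan(gr) <= maxSpan
    list(kept = gr[keep], removed = sum(!keep))
}

#' Condition-exclusive (de novo) junction calls
#'
#' Given the span-filtered unannotated pools of two conditions, a junction
#' is de novo for condition A iff its identity is absent from condition
#' B's pool (and vice versa); junctions present in both pools are
#' eliminated. Unknown strand matches either strand.
#'
#' @param poolA,poolB pooled unannotated junction `GRanges`.
#' @return list: `A`, `B` (exclusive GRanges), `sharedRemoved` (count of
#'   identities eliminated from either side).
#' @export
callDeNovo <- function(poolA, poolB) {
    inB <- matchesJunctionSet(poolA, poolB)
    inA <- matchesJunctionSet(poolB, poolA)
    list(A = poolA[!inB], B = poolB[!inA],
         sharedRemoved = sum(inB) + sum(inA))
}

#' Detect de novo junctions across a two-condition design
#'
#' Runs the full detection chain: per-sample classification against the
#' annotation, pooling of all samples of a condition (within each tissue
#' in `"mouse"` mode, globally in `"cohort"` mode), the span-artifact
#' filter, and condition-exclusivity. Produces per-sample raw and
#' depth-normalized (per million mapped reads) distinct de novo junction
#' counts.
#'
#' @param gr junction `GRanges` for all samples (with `sample` and `count`
#'   columns), e.g. several [readJunctionBed()] results concatenated.
#' @param catalog an [AnnotationCatalog-class].
#' @param design data.frame with columns `sample_id`, `condition`,
#'   `tissue`, `total_reads` covering every sample in `gr`.
#' @param mode `"mouse"` (exclusivity within each tissue) or `"cohort"`
#'   (single global comparison).
#' @param maxSpan span filter threshold in bp.
#' @param minReads minimum pooled read support for a junction to count as
#'   present in a condition pool.
#' @return a [NoiseReport-class].
#' @export
detectNoise <- function(gr, catalog, design, mode = c("mouse", "cohort"),
                        maxSpan = 20000L, minReads = 1L) {
    mode <- match.arg(mode)
    conds <- unique(design$condition)
    if (length(conds) != 2L)
        stop("design must contain exactly two conditions")
    smpls <- unique(mcols(gr)$sample)
    if (!all(smpls %in% design$sample_id))
        stop("sample(s) missing from design: ",
             paste(setdiff(smpls, design$sample_id), collapse = ", "))
    tissues <- if (mode == "mouse") unique(design$tissue) else "all"
    log <- list(input = length(gr), annotated = 0L, span_removed = 0L,
                shared_removed = 0L, low_support = 0L,
                cross_tissue_conflict = 0L)
    perCond <- list()
    perCondTissue <- list()
    for (ts in tissues) {
        inTissue <- if (mode == "mouse")
            design$sample_id[design$tissue == ts] else design$sample_id
        pools <- lapply(conds, function(cc) {
            ids <- intersect(inTissue,
                             design$sample_id[design$condition == cc])
            sub <- gr[mcols(gr)$sample %in% ids]
            cls <- classifyJunctions(sub, catalog)
            log$annotated <<- log$annotated + length(cls$annotated)
            pooled <- poolJunctions(cls$unannotated)
            low <- mcols(pooled)$count < minReads
            log$low_support <<- log$low_support + sum(low)
            pooled <- pooled[!low]
            sp <- filterSpan(pooled, maxSpan)
            log$span_removed <<- log$span_removed + sp$removed
            sp$kept
        })
        dn <- callDeNovo(pools[[1L]], pools[[2L]])
        log$shared_removed <- log$shared_removed + dn$sharedRemoved
        perCondTissue[[ts]] <- stats::setNames(list(dn$A, dn$B), conds)
    }
    ## union across tissues per condition; enforce global disjointness
    for (cc in conds) {
        u <- unlist(GRangesList(lapply(perCondTissue, `[[`, cc)),
                    use.names = FALSE)
        perCond[[cc]] <- u[!duplicated(junctionKey(u))]
    }
    clash <- intersect(coordKey(perCond[[1L]]), coordKey(perCond[[2L]]))
    if (length(clash)) {
        log$cross_tissue_conflict <- length(clash)
        for (cc in conds) {
            perCond[[cc]] <- perCond[[cc]][!coordKey(perCond[[cc]]) %in% clash]
            for (ts in tissues)
                perCondTissue[[ts]][[cc]] <-
                    perCondTissue[[ts]][[cc]][
                        !coordKey(perCondTissue[[ts]][[cc]]) %in% clash]
        }
    }
    ## per-sample counts, restricted to the sample's own condition's
    ## (and, in mouse mode, tissue's) de novo set
    smp <- design
    raw <- integer(nrow(smp))
    for (i in seq_len(nrow(smp))) {
        dnSet <- if (mode == "mouse")
            perCondTissue[[smp$tissue[i]]][[smp$condition[i]]]
        else perCond[[smp$condition[i]]]
        sub <- gr[mcols(gr)$sample == smp$sample_id[i] & mcols(gr)$count >= 1L]
        raw[i] <- sum(matchesJunctionSet(dnSet, sub))
    }
    smp$raw <- raw
    smp$normalized <- raw / smp$total_reads * 1e6
    dnList <- GRangesList(perCond)
    new("NoiseReport", denovo = dnList, samples = smp,
        filterLog = log,
        params = list(mode = mode, maxSpan = maxSpan, minReads = minReads))
}

#' Compare per-sample de novo counts between conditions
#'
#' Two-sided Student's t test on the normalized per-sample counts: paired
#' across tissue-matched condition means (mouse mode) or unpaired across
#' samples (cohort mode).
#'
#' @param report a [NoiseReport-class].
#' @param paired logical; pair by tissue (requires each tissue present in
#'   both conditions).
#' @return list: `means` (per condition), `difference`, `p`, `method`.
#' @export
compareConditions <- function(report, paired = report@params$mode == "mouse") {
    smp <- report@samples
    conds <- unique(smp$condition)
    if (length(conds) != 2L) stop("need exactly two conditions")
    means <- tapply(smp$normalized, smp$condition, mean)[conds]
    if (paired) {
        byTissue <- tapply(smp$normalized,
                           list(smp$tissue, smp$condition), mean)
        if (anyNA(byTissue))
            stop("paired mode requires every tissue in both conditions")
        if (nrow(byTissue) < 2L)
            stop("paired mode needs at least two tissue pairs")
        x <- byTissue[, conds[1L]]; y <- byTissue[, conds[2L]]
        d <- y - x
        p <- if (all(d == d[1L]) && d[1L] == 0) 1 else
            stats::t.test(y, x, paired = TRUE)$p.value
        method <- "paired two-sided t test on tissue means"
    } else {
        if (min(table(smp$condition)) < 2L)
            stop("need at least two samples per condition")
        x <- smp$normalized[smp$condition == conds[1L]]
        y <- smp$normalized[smp$condition == conds[2L]]
        p <- if (stats::sd(c(x, y)) == 0) 1 else
            stats::t.test(y, x)$p.value
        method <- "unpaired two-sided Welch t test on samples"
    }
    list(means = means, difference = unname(means[2L] - means[1L]),
         p = p, method = method)
}
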