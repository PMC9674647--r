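#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#'   mcols mcols<- findOverlaps reduce strand<- ranges ranges<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame queryHits subjectHits
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   reverseComplement subseq
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

#' Gene annotation catalog
#'
#' Holds gene spans, per-transcript exon structures and the derived,
#' deduplicated set of annotated introns against which "unannotated" is
#' defined. Coordinates are 1-based closed (GRanges convention); an intron
#' runs from the first to the last intronic base.
#'
#' @slot genes `GRanges` of gene spans with a `gene_id` metadata column.
#' @slot exons `GRangesList`, one element per transcript (names are
#'   transcript ids), exons sorted in genomic order, non-overlapping within
#'   a transcript.
#' @slot introns `GRanges` of deduplicated annotated introns with a
#'   `gene_id` metadata column (the gene of the first transcript deriving
#'   the intron).
#' @slot txGene named `character`, transcript id -> gene id.
#'
#' @exportClass AnnotationCatalog
setClass("AnnotationCatalog", slots = c(
    genes   = "GRanges",
    exons   = "GRangesList",
    introns = "GRanges",
    txGene  = "character"
))

setValidity("AnnotationCatalog", function(object) {
    msg <- character()
    if (!"gene_id" %in% names(mcols(object@genes)))
        msg <- c(msg, "genes must carry a gene_id column")
    if (length(object@exons) && is.null(names(object@exons)))
        msg <- c(msg, "exons must be named by transcript id")
    for (i in seq_along(object@exons)) {
        ex <- object@exons[[i]]
        if (length(ex) > 1L) {
            if (is.unsorted(start(ex)))
                msg <- c(msg, sprintf("exons of transcript '%s' are not ordered",
                                      names(object@exons)[i]))
            if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
                msg <- c(msg, sprintf("exons of transcript '%s' overlap",
                                      names(object@exons)[i]))
        }
    }
    if (anyDuplicated(junctionKey(object@introns)))
        msg <- c(msg, "annotated introns are not deduplicated")
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort simulation design
#'
#' Encodes the study conditions the synthetic-cohort generator emulates:
#' either a mouse-style design (two genotypes x several tissues x
#' replicates) or a cohort-style design (two groups of many samples). Every
#' random draw in the generator flows from `seed` through a documented
#' per-sample sub-seed scheme.
#'
#' @slot seed integer master seed.
#' @slot nGenes number of genes tiled on the synthetic contig.
#' @slot exonsPerGene exons per gene (introns per gene = exonsPerGene - 1).
#' @slot conditions `data.frame` with columns `label`, `rho` (probability a
#'   planted cryptic junction is expressed in a sample of that condition)
#'   and `replicates` (samples per condition per tissue). The first row is
#'   the reference condition.
#' @slot tissues tissue labels; each condition has `replicates` samples per
#'   tissue.
#' @slot depth mean read count of an annotated junction.
#' @slot dispersion negative-binomial dispersion of annotated-junction
#'   counts.
#' @slot deFraction,deFold fraction of genes with a true expression change
#'   in the non-reference condition, and their fold change.
#' @slot crypticPerGene planted cryptic junctions per gene.
#' @slot crypticMean mean of the zero-truncated Poisson read support of an
#'   expressed cryptic junction.
#' @slot degradation probability that a non-fixed consensus position of a
#'   cryptic splice-site window is drawn uniformly instead of from the
#'   strong consensus profile (0 = annotated-like, 1 = random-like).
#' @slot nSharedNoise unannotated junctions present in both conditions
#'   (removed by the exclusivity step downstream).
#' @slot nArtifacts per-sample random junctions spanning > 20 kb (removed
#'   by the span filter downstream).
#'
#' @exportClass SimulationDesign
setClass("SimulationDesign", slots = c(
    seed          = "integer",
    nGenes        = "integer",
    exonsPerGene  = "integer",
    conditions    = "data.frame",
    tissues       = "character",
    depth         = "numeric",
    dispersion    = "numeric",
    deFraction    = "numeric",
    deFold        = "numeric",
    crypticPerGene = "integer",
    crypticMean   = "numeric",
    degradation   = "numeric",
    nSharedNoise  = "integer",
    nArtifacts    = "integer"
))

setValidity("SimulationDesign", function(object) {
    msg <- character()
    cond <- object@conditions
    if (nrow(cond) < 2L)
        msg <- c(msg, "need two or more conditions")
    if (!all(c("label", "rho", "replicates") %in% names(cond)))
        msg <- c(msg, "conditions needs columns label, rho, replicates")
    else {
        if (any(cond$rho < 0 | cond$rho > 1))
            msg <- c(msg, "rho must lie in [0, 1]")
        if (any(cond$replicates < 1L))
            msg <- c(msg, "replicate counts must be positive")
        if (anyDuplicated(cond$label))
            msg <- c(msg, "condition labels must be unique")
    }
    if (object@nGenes < 1L || object@exonsPerGene < 2L)
        msg <- c(msg, "need nGenes >= 1 and exonsPerGene >= 2")
    if (object@depth <= 0 || object@dispersion <= 0)
        msg <- c(msg, "depth and dispersion must be positive")
    if (object@degradation < 0 || object@degradation > 1)
        msg <- c(msg, "degradation must lie in [0, 1]")
    if (object@deFraction < 0 || object@deFraction > 1)
        msg <- c(msg, "deFraction must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Maximum-entropy splice-site sequence model
#'
#' A maximum-entropy distribution over fixed-length nucleotide windows
#' defined by marginal constraints: independent positions (`order1`),
#' singleton plus adjacent-pair marginals realized in closed form as the
#' consistent first-order Markov chain (`adjacent2`), or singleton plus all
#' pairwise marginals fitted by iterative proportional fitting over the
#' fully enumerated sequence space (`pairwise2`, enumerable widths only).
#'
#' @slot kind free-text label ("donor", "acceptor", "background", ...).
#' @slot width window width in nucleotides.
#' @slot order one of "order1", "adjacent2", "pairwise2".
#' @slot pseudocount smoothing pseudocount per marginal cell.
#' @slot positionProbs 4 x width matrix of position marginals (rows
#'   A, C, G, T).
#' @slot pairProbs list of 4 x 4 joint tables for adjacent position pairs
#'   (adjacent2 only).
#' @slot jointProb numeric vector of length 4^width with the full fitted
#'   distribution (pairwise2 only), indexed by the enumeration order of
#'   the sequence space (first position most significant).
#' @slot fitMeta list: tolerance, iterations, training size, residual.
#'
#' @exportClass MaxEntModel
setClass("MaxEntModel", slots = c(
    kind          = "character",
    width         = "integer",
    order         = "character",
    pseudocount   = "numeric",
    positionProbs = "matrix",
    pairProbs     = "list",
    jointProb     = "numeric",
    fitMeta       = "list"
))

setValidity("MaxEntModel", function(object) {
    msg <- character()
    if (!object@order %in% c("order1", "adjacent2", "pairwise2"))
        msg <- c(msg, "order must be order1, adjacent2 or pairwise2")
    if (ncol(object@positionProbs) != object@width)
        msg <- c(msg, "positionProbs must have one column per position")
    if (object@pseudocount > 0 && any(object@positionProbs <= 0))
        msg <- c(msg, "all position probabilities must be positive")
    if (any(object@positionProbs < 0))
        msg <- c(msg, "position probabilities must be non-negative")
    if (any(abs(colSums(object@positionProbs) - 1) > 1e-9))
        msg <- c(msg, "position marginals must each sum to 1")
    if (object@order == "pairwise2") {
        if (length(object@jointProb) != 4^object@width)
            msg <- c(msg, "jointProb must enumerate the full sequence space")
        else if (abs(sum(object@jointProb) - 1) > 1e-9)
            msg <- c(msg, "jointProb must sum to 1")
        else if (object@pseudocount > 0 && any(object@jointProb <= 0))
            msg <- c(msg, "jointProb must be strictly positive")
    }
    if (length(msg)) msg else TRUE
})

#' Splicing-noise report
#'
#' Per-condition de novo junction sets and per-sample raw and
#' depth-normalized de novo junction counts, together with a log of how
#' many junctions each filtering stage removed.
#'
#' @slot denovo `GRangesList`, one element per condition label, holding the
#'   de novo (unannotated, condition-exclusive, span-filtered) junction
#'   identities of that condition.
#' @slot samples `data.frame` with columns `sample_id`, `condition`,
#'   `tissue`, `total_reads`, `raw` (distinct de novo junctions observed in
#'   the sample) and `normalized` (raw / total_reads * 1e6).
#' @slot filterLog list of per-stage removal tallies.
#' @slot params list of the parameters used (mode, max span, min reads).
#'
#' @exportClass NoiseReport
setClass("NoiseReport", slots = c(
    denovo    = "GRangesList",
    samples   = "data.frame",
    filterLog = "list",
    params    = "list"
))

setValidity("NoiseReport", function(object) {
    msg <- character()
    smp <- object@samples
    need <- c("sample_id", "condition", "tissue", "total_reads", "raw",
              "normalized")
    if (!all(need %in% names(smp)))
        msg <- c(msg, paste("samples needs columns",
                            paste(need, collapse = ", ")))
    else {
        if (any(smp$raw < 0) || any(smp$raw != round(smp$raw)))
            msg <- c(msg, "raw counts must be non-negative integers")
        if (any(smp$total_reads <= 0))
            msg <- c(msg, "total_reads must be positive")
        if (any(abs(smp$normalized - smp$raw / smp$total_reads * 1e6) > 1e-6))
            msg <- c(msg, "normalized must equal raw / total_reads * 1e6")
    }
    if (length(object@denovo) == 2L) {
        a <- coordKey(object@denovo[[1L]])
        b <- coordKey(object@denovo[[2L]])
        if (length(intersect(a, b)))
            msg <- c(msg, "the two conditions' de novo sets must be disjoint")
    }
    if (length(msg)) msg else TRUE
})
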