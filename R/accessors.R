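#' @name accessors
#' @title Accessors for spliceNoise S4 objects
#' @param x an object.
#' @param condition optional condition label to select one de novo set.
NULL

#' @describeIn accessors annotated introns of a catalog.
#' @export
annotatedIntrons <- function(x) {
    stopifnot(is(x, "AnnotationCatalog"))
    x@introns
}

#' @describeIn accessors gene spans of a catalog.
#' @export
geneRanges <- function(x) {
    stopifnot(is(x, "AnnotationCatalog"))
    x@genes
}

#' @describeIn accessors per-transcript exon structures of a catalog.
#' @export
transcriptExons <- function(x) {
    stopifnot(is(x, "AnnotationCatalog"))
    x@exons
}

#' @describeIn accessors per-condition de novo junction sets of a report.
#' @export
denovoJunctions <- function(x, condition = NULL) {
    stopifnot(is(x, "NoiseReport"))
    if (is.null(condition)) x@denovo else x@denovo[[condition]]
}

#' @describeIn accessors per-sample count table of a report.
#' @export
sampleCounts <- function(x) {
    stopifnot(is(x, "NoiseReport"))
    x@samples
}

#' @describeIn accessors filtering tallies of a report.
#' @export
filterLog <- function(x) {
    stopifnot(is(x, "NoiseReport"))
    x@filterLog
}

setMethod("show", "AnnotationCatalog", function(object) {
    cat("AnnotationCatalog:", length(object@genes), "genes,",
        length(object@exons), "transcripts,",
        length(object@introns), "annotated introns\n")
})

setMethod("show", "SimulationDesign", function(object) {
    cond <- object@conditions
    cat("SimulationDesign: seed", object@seed, "|", object@nGenes,
        "genes x", object@exonsPerGene, "exons |",
        nrow(cond), "conditions (",
        paste(sprintf("%s: rho=%.2g x%d", cond$label, cond$rho,
                      cond$replicates), collapse = ", "),
        ") x", length(object@tissues), "tissue(s)\n")
})

setMethod("show", "MaxEntModel", function(object) {
    cat(sprintf("MaxEntModel '%s': width %d, order %s, trained on %d windows\n",
                object@kind, object@width, object@order,
                object@fitMeta$training))
})

setMethod("show", "NoiseReport", function(object) {
    ns <- vapply(object@denovo, length, integer(1))
    cat("NoiseReport (", object@params$mode, " mode): de novo junctions: ",
        paste(sprintf("%s=%d", names(ns), ns), collapse = ", "),
        "; ", nrow(object@samples), " samples\n", sep = "")
})
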