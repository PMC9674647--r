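#' Construct a junction GRanges
#'
#' Junctions are represented as `GRanges` over the intron interval (first
#' to last intronic base, 1-based closed), with strand `+`, `-` or `*`
#' (unknown) and metadata columns `count` (read support) and `sample`.
#'
#' @param contig,start,end vectors of contig names and 1-based closed
#'   intron coordinates.
#' @param strand strand, `"*"` for unknown.
#' @param count non-negative integer read counts.
#' @param sample sample identifier(s).
#' @return a `GRanges` with `count` and `sample` metadata columns.
#' @examples
#' junctions("chr1", 101, 200, "+", count = 7, sample = "s1")
#' @export
junctions <- function(contig, start, end, strand = "*", count = 0L,
                      sample = NA_character_) {
    if (!length(contig)) {
        gr <- GRanges()
        mcols(gr)$count <- integer(0)
        mcols(gr)$sample <- character(0)
        return(gr)
    }
    if (any(end < start))
        stop("junction end must be >= start")
    if (any(end - start + 1L < 4L))
        stop("junction span must be >= 4 bp (room for GT..AG)")
    if (any(count < 0))
        stop("read counts must be non-negative")
    gr <- GRanges(contig, IRanges(start, end), strand = strand)
    mcols(gr)$count <- as.integer(count)
    mcols(gr)$sample <- as.character(sample)
    gr
}

## identity key including strand
junctionKey <- function(gr) {
    if (!length(gr)) return(character(0))
    paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr), ":",
           as.character(strand(gr)))
}

## coordinate key, strand ignored (used for wildcard-strand set logic)
coordKey <- function(gr) {
    if (!length(gr)) return(character(0))
    paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr))
}

strandCompatible <- function(a, b) {
    a == "*" | b == "*" | a == b
}

#' Junction span
#'
#' Genomic length of the intron implied by a junction.
#' @param gr junction `GRanges`.
#' @return integer vector of spans in bp.
#' @export
junctionSpan <- function(gr) width(gr)

## match junctions against a reference junction set allowing the unknown
## strand ("*") on either side to match any strand; returns logical
matchesJunctionSet <- function(gr, ref) {
    if (!length(gr)) return(logical(0))
    if (!length(ref)) return(rep(FALSE, length(gr)))
    refStrand <- split(as.character(strand(ref)), coordKey(ref))
    qs <- as.character(strand(gr))
    qk <- coordKey(gr)
    vapply(seq_along(gr), function(i) {
        s <- refStrand[[qk[i]]]
        !is.null(s) && any(strandCompatible(qs[i], s))
    }, logical(1))
}
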