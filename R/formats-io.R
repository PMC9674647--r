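#' Read a reference genome from FASTA
#'
#' Loads all records, uppercases sequences and maps any character outside
#' {A,C,G,T,N} to N. Record names are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return a `DNAStringSet` with `seqlengths`-compatible names.
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    raw <- tryCatch(readBStringSet(path),
                    error = function(e) stop("malformed FASTA: ",
                                             conditionMessage(e)))
    if (!length(raw)) stop("malformed FASTA: no records in ", path)
    nm <- sub("\\s.*$", "", names(raw))
    if (any(!nzchar(nm))) stop("malformed FASTA: empty record header")
    if (anyDuplicated(nm)) stop("malformed FASTA: duplicate contig names")
    s <- toupper(as.character(raw))
    s <- gsub("[^ACGTN]", "N", s)
    genome <- DNAStringSet(s)
    names(genome) <- nm
    genome
}

#' Read an Ensembl-style GTF into an annotation catalog
#'
#' Uses exon features (1-based closed GTF coordinates) carrying `gene_id`
#' and `transcript_id` attributes. Annotated introns are derived per
#' transcript as the gaps between consecutive exons, then deduplicated.
#'
#' @param path GTF file.
#' @return an [AnnotationCatalog-class] object.
#' @export
readAnnotation <- function(path) {
    if (!file.exists(path)) stop("GTF file not found: ", path)
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) stop("malformed GTF: ",
                                            conditionMessage(e)))
    ex <- gr[gr$type == "exon"]
    if (!length(ex)) stop("malformed GTF: no exon features in ", path)
    if (is.null(ex$transcript_id) || anyNA(ex$transcript_id))
        stop("malformed GTF: exon feature without transcript_id")
    if (is.null(ex$gene_id) || anyNA(ex$gene_id))
        stop("malformed GTF: exon feature without gene_id")
    makeCatalog(ex$gene_id, ex$transcript_id,
                as.character(seqnames(ex)), start(ex), end(ex),
                as.character(strand(ex)))
}

## shared catalog builder; coordinates 1-based closed
makeCatalog <- function(geneId, txId, contig, start, end, strand) {
    ord <- order(txId, start)
    geneId <- geneId[ord]; txId <- txId[ord]; contig <- contig[ord]
    start <- start[ord]; end <- end[ord]; strand <- strand[ord]
    txs <- split(seq_along(txId), txId)
    txGene <- vapply(txs, function(i) unique(geneId[i])[1L], character(1))
    exList <- list(); inList <- list()
    for (tx in names(txs)) {
        i <- txs[[tx]]
        if (length(unique(contig[i])) != 1L ||
            length(unique(strand[i])) != 1L)
            stop("transcript '", tx, "' spans several contigs or strands")
        ex <- GRanges(contig[i][1L], IRanges(start[i], end[i]),
                      strand = strand[i][1L])
        if (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)]))
            stop("overlapping exons within transcript '", tx, "'")
        exList[[tx]] <- ex
        if (length(ex) > 1L) {
            inList[[tx]] <- GRanges(
                contig[i][1L],
                IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1L] - 1L),
                strand = strand[i][1L],
                gene_id = txGene[[tx]])
        }
    }
    introns <- if (length(inList))
        unlist(GRangesList(inList), use.names = FALSE) else GRanges()
    if (length(introns)) {
        introns <- introns[!duplicated(junctionKey(introns))]
        introns <- GenomicRanges::sort(introns, ignore.strand = TRUE)
    }
    perGene <- split(seq_along(geneId), geneId)
    genes <- GRanges(
        vapply(perGene, function(i) contig[i][1L], character(1)),
        IRanges(vapply(perGene, function(i) min(start[i]), numeric(1)),
                vapply(perGene, function(i) max(end[i]), numeric(1))),
        strand = vapply(perGene, function(i) strand[i][1L], character(1)),
        gene_id = names(perGene))
    names(genes) <- NULL
    new("AnnotationCatalog", genes = genes,
        exons = GRangesList(exList), introns = introns, txGene = txGene)
}

#' Read a junction BED12 file (junction-extractor dialect)
#'
#' In this dialect (as emitted by junction extractors such as regtools),
#' `chromStart`/`chromEnd` include the two anchor blocks and the intron is
#' recovered as `[chromStart + blockSize1, chromEnd - blockSize2)` in
#' 0-based half-open coordinates; the score column is the junction read
#' count and strand `"."` marks an unknown strand.
#'
#' @param path BED12 file.
#' @param sampleId sample identifier stored in the `sample` column.
#' @return junction `GRanges` (see [junctions()]).
#' @export
readJunctionBed <- function(path, sampleId) {
    if (!file.exists(path)) stop("BED file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(junctions(character(), integer(), integer())[0])
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf != 12L))
        stop("malformed BED12: expected 12 columns, got ", min(nf))
    m <- matrix(unlist(f), ncol = 12L, byrow = TRUE)
    blockCount <- suppressWarnings(as.integer(m[, 10L]))
    if (anyNA(blockCount) || any(blockCount != 2L))
        stop("malformed BED12: blockCount must be 2 for junction records")
    bs <- strsplit(sub(",$", "", m[, 11L]), ",", fixed = TRUE)
    if (any(lengths(bs) != 2L))
        stop("malformed BED12: blockSizes must have 2 entries")
    bs1 <- suppressWarnings(as.integer(vapply(bs, `[`, character(1), 1L)))
    bs2 <- suppressWarnings(as.integer(vapply(bs, `[`, character(1), 2L)))
    chromStart <- suppressWarnings(as.integer(m[, 2L]))
    chromEnd <- suppressWarnings(as.integer(m[, 3L]))
    score <- suppressWarnings(as.integer(m[, 5L]))
    if (anyNA(chromStart) || anyNA(chromEnd) || anyNA(score) ||
        anyNA(bs1) || anyNA(bs2))
        stop("malformed BED12: non-numeric coordinate, score or block size")
    i0s <- chromStart + bs1        # 0-based first intron base
    i0e <- chromEnd - bs2          # 0-based exclusive intron end
    if (any(i0e <= i0s))
        stop("invalid junction: computed intron is empty")
    strand <- m[, 6L]
    if (!all(strand %in% c("+", "-", ".")))
        stop("malformed BED12: strand must be +, - or .")
    strand[strand == "."] <- "*"
    junctions(m[, 1L], i0s + 1L, i0e, strand, score, sampleId)
}

#' Write junctions to a BED12 file
#'
#' Emits symmetric 1-bp anchors so that [readJunctionBed()] reproduces the
#' intron coordinates, strand and read counts exactly. Unknown strand is
#' written as `"."`.
#'
#' @param gr junction `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeJunctionBed <- function(gr, path) {
    if (!length(gr)) {
        writeLines(character(), path)
        return(invisible(path))
    }
    i0s <- start(gr) - 1L
    i0e <- end(gr)
    strand <- as.character(strand(gr))
    strand[strand == "*"] <- "."
    count <- mcols(gr)$count
    if (is.null(count)) count <- rep(0L, length(gr))
    lines <- paste(
        as.character(seqnames(gr)), i0s - 1L, i0e + 1L,
        sprintf("JUNC%06d", seq_along(gr)), count, strand,
        i0s - 1L, i0e + 1L, "255,0,0", 2L, "1,1",
        paste0("0,", i0e - i0s + 1L),
        sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Read a gene x sample counts table (TSV)
#'
#' First column holds gene ids, the header holds sample ids; all cells
#' must be non-negative integers and labels must be unique.
#'
#' @param path TSV file.
#' @return an integer matrix with gene rownames and sample colnames.
#' @export
readCountsTable <- function(path) {
    if (!file.exists(path)) stop("counts file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("malformed counts table: need gene + sample columns")
    genes <- as.character(df[[1L]])
    if (anyDuplicated(genes)) stop("duplicate gene ids in counts table")
    samples <- colnames(df)[-1L]
    if (anyDuplicated(samples)) stop("duplicate sample ids in counts table")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cell in counts table")
    if (anyNA(m)) stop("missing value in counts table")
    if (any(m < 0)) stop("negative count in counts table")
    if (any(m != round(m))) stop("non-integer count in counts table")
    storage.mode(m) <- "integer"
    rownames(m) <- genes
    colnames(m) <- samples
    m
}

#' Write a gene x sample counts table (TSV)
#'
#' Inverse of [readCountsTable()].
#' @param counts integer matrix with gene rownames and sample colnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCountsTable <- function(counts, path) {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a sample design table (TSV)
#'
#' Columns: `sample_id`, `condition`, `tissue`, `total_reads`.
#' @param path TSV file.
#' @return a `data.frame`.
#' @export
readDesignTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("sample_id", "condition", "tissue", "total_reads")
    if (!all(need %in% names(df)))
        stop("design table needs columns ", paste(need, collapse = ", "))
    if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
    if (any(df$total_reads <= 0)) stop("total_reads must be positive")
    df
}
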