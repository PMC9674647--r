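## Shared toy inputs and independent oracles for the suite. Everything is
## built in code; the heavier default fixture is generated once per run
## and memoized.

.cache <- new.env(parent = emptyenv())

## default mouse-style fixture (the generator's stated study conditions)
defaultFixtureDir <- function() {
    if (is.null(.cache$fixtureDir)) {
        dir <- file.path(tempdir(), "snfixture")
        emitFixture(simulationDesign(seed = 20260901L), dir)
        .cache$fixtureDir <- dir
    }
    .cache$fixtureDir
}

## full pipeline result on the default fixture, memoized
defaultPipelineRun <- function() {
    if (is.null(.cache$pipelineRun)) {
        cfg <- pipelineConfig(defaultFixtureDir(), mode = "mouse",
                              seed = 11L)
        .cache$pipelineRun <- runNoisePipeline(
            cfg, file.path(tempdir(), "snfixture_out"))
    }
    .cache$pipelineRun
}

## a tiny deterministic genome with a readable sequence
toyGenome <- function(len = 400L, seed = 5L) {
    withr::with_seed(seed, {
        g <- Biostrings::DNAStringSet(paste(
            sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""))
        names(g) <- "c1"
        g
    })
}

## write a toy two-exon GTF and read it back as a catalog
toyCatalog <- function(exon1 = c(1L, 100L), exon2 = c(201L, 300L),
                       strand = "+", contig = "c1") {
    path <- tempfile(fileext = ".gtf")
    attr1 <- 'gene_id "g1"; transcript_id "t1";'
    writeLines(c(
        paste(contig, "toy", "exon", exon1[1], exon1[2], ".", strand, ".",
              attr1, sep = "\t"),
        paste(contig, "toy", "exon", exon2[1], exon2[2], ".", strand, ".",
              attr1, sep = "\t")), path)
    readAnnotation(path)
}

## brute-force de novo oracle on plain data.frames, written independently
## of the pipeline's set logic: pools per condition, drops annotated and
## long-span junctions, then keeps identities exclusive to one condition
bruteDenovo <- function(df, annotated, maxSpan = 20000) {
    ## df: contig,start,end,strand,count,sample,condition
    key <- function(d) paste(d$contig, d$start, d$end)
    compat <- function(a, b) a == "*" | b == "*" | a == b
    isAnn <- function(d) {
        vapply(seq_len(nrow(d)), function(i) {
            j <- which(key(annotated) == key(d)[i])
            length(j) > 0 && any(compat(d$strand[i], annotated$strand[j]))
        }, logical(1))
    }
    pools <- lapply(split(df, df$condition), function(d) {
        d <- d[!isAnn(d), , drop = FALSE]
        d <- d[d$end - d$start + 1 <= maxSpan, , drop = FALSE]
        unique(d[c("contig", "start", "end", "strand")])
    })
    stopifnot(length(pools) == 2)
    a <- pools[[1]]; b <- pools[[2]]
    inOther <- function(d, other) {
        vapply(seq_len(nrow(d)), function(i) {
            j <- which(key(other) == key(d)[i])
            length(j) > 0 && any(compat(d$strand[i], other$strand[j]))
        }, logical(1))
    }
    res <- list(a[!inOther(a, b), , drop = FALSE],
                b[!inOther(b, a), , drop = FALSE])
    names(res) <- names(pools)
    res
}

## random toy junction table for oracle comparisons
randomJunctionTable <- function(seed, nJunc = 20L) {
    withr::with_seed(seed, {
        s <- sample(50:500, nJunc) * 10L
        w <- sample(c(50:200, 20500L), nJunc, replace = TRUE)
        data.frame(
            contig = "c1", start = s, end = s + w - 1L,
            strand = sample(c("+", "-", "*"), nJunc, replace = TRUE),
            count = sample(1:5, nJunc, replace = TRUE),
            sample = sample(c("a1", "a2", "b1", "b2"), nJunc, replace = TRUE),
            stringsAsFactors = FALSE)
    })
}
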