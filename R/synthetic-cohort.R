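#' Construct a simulation design
#'
#' The default encodes a mouse-style experiment: two genotypes (reference
#' `WT` with cryptic-usage rate 0.03, perturbed `KO` with rate 0.3), three
#' tissues, three replicates each — 18 samples in total. Use
#' [cohortDesign()] for the many-sample two-group layout.
#'
#' @param seed master seed; every random draw in the generator derives
#'   from it.
#' @param nGenes,exonsPerGene gene structure of the synthetic genome.
#' @param conditions data.frame with `label`, `rho`, `replicates` (first
#'   row = reference condition).
#' @param tissues tissue labels.
#' @param depth mean annotated-junction read count.
#' @param dispersion negative-binomial dispersion of annotated-junction
#'   counts.
#' @param deFraction,deFold fraction and fold change of truly
#'   differentially expressed genes.
#' @param crypticPerGene planted cryptic junctions per gene.
#' @param crypticMean mean read support (zero-truncated Poisson) of an
#'   expressed cryptic junction.
#' @param degradation consensus-degradation probability of cryptic
#'   splice-site windows (0 = annotated-like, 1 = random-like).
#' @param nSharedNoise unannotated junctions shared by both conditions.
#' @param nArtifacts per-sample junctions spanning > 20 kb.
#' @return a [SimulationDesign-class].
#' @export
simulationDesign <- function(seed = 1L, nGenes = 80L, exonsPerGene = 4L,
                             conditions = data.frame(
                                 label = c("WT", "KO"),
                                 rho = c(0.03, 0.3),
                                 replicates = c(3L, 3L)),
                             tissues = c("crypt", "villus", "colon"),
                             depth = 50, dispersion = 0.1,
                             deFraction = 0.1, deFold = 3,
                             crypticPerGene = 3L, crypticMean = 2,
                             degradation = 0.5,
                             nSharedNoise = 20L, nArtifacts = 3L) {
    new("SimulationDesign", seed = as.integer(seed),
        nGenes = as.integer(nGenes), exonsPerGene = as.integer(exonsPerGene),
        conditions = conditions, tissues = tissues, depth = depth,
        dispersion = dispersion, deFraction = deFraction, deFold = deFold,
        crypticPerGene = as.integer(crypticPerGene),
        crypticMean = crypticMean, degradation = degradation,
        nSharedNoise = as.integer(nSharedNoise),
        nArtifacts = as.integer(nArtifacts))
}

#' Cohort-style simulation design
#'
#' Two groups of many samples in a single tissue, emulating a patient
#' cohort (default 20 controls vs 206 cases).
#'
#' @param nControl,nCase group sizes.
#' @param rhoControl,rhoCase cryptic-usage rates.
#' @param ... passed to [simulationDesign()].
#' @inheritParams simulationDesign
#' @return a [SimulationDesign-class].
#' @export
cohortDesign <- function(seed = 1L, nControl = 20L, nCase = 206L,
                         rhoControl = 0.03, rhoCase = 0.3, ...) {
    simulationDesign(
        seed = seed,
        conditions = data.frame(label = c("Cont", "UC"),
                                rho = c(rhoControl, rhoCase),
                                replicates = as.integer(c(nControl, nCase))),
        tissues = "colon", ...)
}

## deterministic sub-seed scheme: master seed + purpose counter; stays
## well below 2^31
subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) %% 1e6) * 1013 + k * 7919 + 17)
}

## strong consensus position profiles (4 x width, rows A,C,G,T).
## Donor: 3 exonic + GT + 4 consensus intronic positions.
donorProfile <- function() {
    p <- cbind(
        c(.34, .36, .18, .12),   # exon -3
        c(.60, .13, .14, .13),   # exon -2
        c(.09, .03, .80, .08),   # exon -1
        c(0, 0, 1, 0),           # intron +1 (G, fixed)
        c(0, 0, 0, 1),           # intron +2 (T, fixed)
        c(.60, .03, .34, .03),   # intron +3
        c(.70, .08, .12, .10),   # intron +4
        c(.07, .06, .82, .05),   # intron +5
        c(.16, .16, .20, .48))   # intron +6
    rownames(p) <- BASES
    p
}

## Acceptor: 18 polypyrimidine positions, fixed AG, 3 exonic.
acceptorProfile <- function() {
    ppt <- c(.08, .32, .10, .50)
    p <- cbind(matrix(rep(ppt, 18), nrow = 4),
               c(1, 0, 0, 0),            # intron -2 (A, fixed)
               c(0, 0, 1, 0),            # intron -1 (G, fixed)
               c(.28, .14, .50, .08),    # exon +1
               c(.25, .25, .25, .25),
               c(.25, .25, .25, .25))
    rownames(p) <- BASES
    p
}

## sample n windows from a profile; with probability `degradation`, each
## non-fixed position is drawn uniformly instead (fixed positions, i.e.
## the GT/AG dinucleotides, are always retained)
sampleWindows <- function(profile, n, degradation = 0) {
    L <- ncol(profile)
    fixed <- apply(profile, 2, max) >= 1 - 1e-12
    m <- matrix("", n, L)
    for (p in seq_len(L)) {
        base <- sample(BASES, n, replace = TRUE, prob = profile[, p])
        if (!fixed[p] && degradation > 0) {
            deg <- stats::runif(n) < degradation
            if (any(deg))
                base[deg] <- sample(BASES, sum(deg), replace = TRUE)
        }
        m[, p] <- base
    }
    apply(m, 1, paste, collapse = "")
}

## place a window (given 5'->3' on the transcribed strand) into the
## contig character vector at genomic positions at..at+n-1
placeWindow <- function(chars, at, window, geneStrand) {
    s <- strsplit(window, "", fixed = TRUE)[[1L]]
    if (geneStrand == "-")
        s <- rev(c(A = "T", C = "G", G = "C", T = "A")[s])
    chars[at:(at + length(s) - 1L)] <- s
    chars
}

## window genomic footprints for an intron [s,e] on `strand`
donorFootprint <- function(s, e, strand)
    if (strand == "+") c(s - 3L, s + 5L) else c(e - 5L, e + 3L)
acceptorFootprint <- function(s, e, strand)
    if (strand == "+") c(e - 19L, e + 3L) else c(s - 3L, s + 19L)

#' Build a synthetic genome and annotation
#'
#' Tiles `nGenes` genes (random strand) on one contig with >= 1 kb
#' spacing. Exons are 100-200 bp, introns 150-600 bp; every annotated
#' intron begins GT and ends AG on its coding strand, with donor and
#' acceptor windows sampled from strong consensus profiles. Deterministic
#' given the design seed.
#'
#' @param design a [SimulationDesign-class].
#' @return list: `genome` (`DNAStringSet`, one contig), `catalog`
#'   ([AnnotationCatalog-class] with one transcript per gene).
#' @export
buildGenomeAnnotation <- function(design) {
    validObject(design)
    withr::with_seed(subSeed(design@seed, 1L), {
        nG <- design@nGenes; nE <- design@exonsPerGene
        exLen <- matrix(sample(100:200, nG * nE, replace = TRUE), nG, nE)
        inLen <- matrix(sample(150:600, nG * (nE - 1L), replace = TRUE),
                        nG, nE - 1L)
        spacing <- 1000L + sample(0:500, nG, replace = TRUE)
        geneStrand <- sample(c("+", "-"), nG, replace = TRUE)
        geneWidth <- rowSums(exLen) + rowSums(inLen)
        geneStart <- cumsum(c(1000L, geneWidth[-nG] + spacing[-nG])) + 1L
        contigLen <- geneStart[nG] + geneWidth[nG] + 30000L
        chars <- sample(BASES, contigLen, replace = TRUE)
        geneId <- sprintf("G%03d", seq_len(nG))
        txId <- sprintf("T%03d", seq_len(nG))
        allG <- character(); allT <- character()
        allS <- integer(); allE <- integer(); allStr <- character()
        for (g in seq_len(nG)) {
            pos <- geneStart[g]
            exS <- integer(nE); exE <- integer(nE)
            for (e in seq_len(nE)) {
                exS[e] <- pos; exE[e] <- pos + exLen[g, e] - 1L
                pos <- exE[e] + 1L
                if (e < nE) pos <- pos + inLen[g, e]
            }
            for (e in seq_len(nE - 1L)) {
                is <- exE[e] + 1L; ie <- exS[e + 1L] - 1L
                dW <- sampleWindows(donorProfile(), 1L)
                aW <- sampleWindows(acceptorProfile(), 1L)
                if (geneStrand[g] == "+") {
                    chars <- placeWindow(chars, donorFootprint(is, ie, "+")[1L],
                                         dW, "+")
                    chars <- placeWindow(chars,
                                         acceptorFootprint(is, ie, "+")[1L],
                                         aW, "+")
                } else {
                    ## transcribed donor sits at the genomic end of the intron
                    chars <- placeWindow(chars, donorFootprint(is, ie, "-")[1L],
                                         dW, "-")
                    chars <- placeWindow(chars,
                                         acceptorFootprint(is, ie, "-")[1L],
                                         aW, "-")
                }
            }
            allG <- c(allG, rep(geneId[g], nE))
            allT <- c(allT, rep(txId[g], nE))
            allS <- c(allS, exS); allE <- c(allE, exE)
            allStr <- c(allStr, rep(geneStrand[g], nE))
        }
        genome <- DNAStringSet(paste(chars, collapse = ""))
        names(genome) <- "chrS"
        catalog <- makeCatalog(allG, allT, rep("chrS", length(allG)),
                               allS, allE, allStr)
        list(genome = genome, catalog = catalog)
    })
}

#' Plant cryptic splice sites
#'
#' Places `crypticPerGene` cryptic junctions per gene inside gene bodies,
#' pairing a weak donor with a weak acceptor: windows are sampled from the
#' consensus profiles with each non-fixed position degraded to a uniform
#' base with probability `degradation` (the GT/AG dinucleotides are always
#' retained), and written into the genome. No planted junction coincides
#' with an annotated intron. Genes without room are skipped with a
#' warning.
#'
#' @param genome `DNAStringSet` from [buildGenomeAnnotation()].
#' @param catalog the matching [AnnotationCatalog-class].
#' @param design a [SimulationDesign-class].
#' @return list: `genome` (modified), `truth` (list with `junctions`
#'   GRanges carrying `gene_id`, `donor_window`, `acceptor_window`;
#'   `geneFold` named per-gene expression fold in the non-reference
#'   condition; `geneBase` named per-gene base expression factor).
#' @export
plantCrypticSites <- function(genome, catalog, design) {
    withr::with_seed(subSeed(design@seed, 2L), {
        chars <- strsplit(as.character(genome[[1L]]), "", fixed = TRUE)[[1L]]
        genes <- catalog@genes
        ann <- catalog@introns
        occupied <- list()  # per-gene list of forbidden [lo,hi] windows
        for (i in seq_along(ann)) {
            gid <- mcols(ann)$gene_id[i]
            st <- as.character(strand(ann))[i]
            d <- donorFootprint(start(ann)[i], end(ann)[i], st)
            a <- acceptorFootprint(start(ann)[i], end(ann)[i], st)
            occupied[[gid]] <- c(occupied[[gid]],
                                 list(c(d[1L] - 5L, d[2L] + 5L),
                                      c(a[1L] - 5L, a[2L] + 5L)))
        }
        annKey <- coordKey(ann)
        out <- list(); skipped <- 0L
        for (g in seq_along(genes)) {
            gid <- mcols(genes)$gene_id[g]
            gs <- start(genes)[g]; ge <- end(genes)[g]
            st <- as.character(strand(genes))[g]
            planted <- 0L; tries <- 0L
            while (planted < design@crypticPerGene && tries < 200L) {
                tries <- tries + 1L
                w <- sample(80:400, 1L)
                if (ge - gs + 1L < w + 60L) break
                cs <- sample(seq(gs + 25L, ge - w - 25L), 1L)
                ce <- cs + w - 1L
                dft <- donorFootprint(cs, ce, st)
                aft <- acceptorFootprint(cs, ce, st)
                clash <- any(vapply(occupied[[gid]] %||% list(), function(iv)
                    (dft[1L] <= iv[2L] && dft[2L] >= iv[1L]) ||
                    (aft[1L] <= iv[2L] && aft[2L] >= iv[1L]), logical(1)))
                if (clash) next
                if (paste0("chrS:", cs, "-", ce) %in% annKey) next
                dW <- sampleWindows(donorProfile(), 1L, design@degradation)
                aW <- sampleWindows(acceptorProfile(), 1L, design@degradation)
                chars <- placeWindow(chars, dft[1L], dW, st)
                chars <- placeWindow(chars, aft[1L], aW, st)
                occupied[[gid]] <- c(occupied[[gid]],
                                     list(c(dft[1L] - 5L, dft[2L] + 5L),
                                          c(aft[1L] - 5L, aft[2L] + 5L)))
                out[[length(out) + 1L]] <- data.frame(
                    start = cs, end = ce, strand = st, gene_id = gid,
                    donor_window = dW, acceptor_window = aW,
                    stringsAsFactors = FALSE)
                planted <- planted + 1L
            }
            if (planted < design@crypticPerGene) skipped <- skipped + 1L
        }
        if (skipped)
            warning(skipped, " gene(s) had no room for all cryptic sites")
        df <- do.call(rbind, out)
        truthGr <- GRanges("chrS", IRanges(df$start, df$end),
                           strand = df$strand, gene_id = df$gene_id,
                           donor_window = df$donor_window,
                           acceptor_window = df$acceptor_window)
        nG <- design@nGenes
        geneIds <- mcols(catalog@genes)$gene_id
        geneBase <- stats::setNames(stats::rlnorm(nG, 0, 0.4), geneIds)
        geneFold <- stats::setNames(rep(1, nG), geneIds)
        nDe <- floor(design@deFraction * nG)
        if (nDe > 0L) {
            de <- sample(geneIds, nDe)
            geneFold[de] <- ifelse(stats::runif(nDe) < 0.5,
                                   design@deFold, 1 / design@deFold)
        }
        genomeOut <- DNAStringSet(paste(chars, collapse = ""))
        names(genomeOut) <- names(genome)
        list(genome = genomeOut,
             truth = list(junctions = truthGr, geneFold = geneFold,
                          geneBase = geneBase))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## zero-truncated Poisson draws
rztpois <- function(n, lambda) {
    u <- stats::runif(n, stats::dpois(0, lambda), 1)
    stats::qpois(u, lambda)
}

#' Simulate the junction calls of one sample
#'
#' Annotated introns receive negative-binomial read counts (mean = depth x
#' gene expression factor x condition fold x mild tissue factor); each
#' planted cryptic junction is expressed with probability `rho(condition)`
#' and, when expressed, receives a zero-truncated Poisson count. Shared
#' unannotated noise junctions and long-span artifact junctions are added
#' per the design. Deterministic given `seed`.
#'
#' @param truth the `truth` element of [plantCrypticSites()].
#' @param catalog an [AnnotationCatalog-class].
#' @param design a [SimulationDesign-class].
#' @param condition condition label (must appear in the design).
#' @param tissue tissue label.
#' @param sampleId sample identifier.
#' @param seed integer seed for this sample.
#' @param genomeLen contig length (bounds the artifact junctions).
#' @return junction `GRanges` with `count` and `sample` columns.
#' @export
simulateSampleJunctions <- function(truth, catalog, design, condition,
                                    tissue, sampleId, seed,
                                    genomeLen = NULL) {
    cond <- design@conditions
    row <- match(condition, cond$label)
    if (is.na(row)) stop("unknown condition label: ", condition)
    rho <- cond$rho[row]
    isRef <- row == 1L
    tissueFactor <- c(0.9, 1.0, 1.1)[
        (match(tissue, design@tissues) - 1L) %% 3L + 1L]
    withr::with_seed(as.integer(seed), {
        ann <- catalog@introns
        gid <- mcols(ann)$gene_id
        mu <- design@depth * truth$geneBase[gid] * tissueFactor *
            (if (isRef) 1 else truth$geneFold[gid])
        annCount <- stats::rnbinom(length(ann), mu = mu,
                                   size = 1 / design@dispersion)
        keep <- annCount >= 1L
        annGr <- ann[keep]
        mcols(annGr) <- NULL
        mcols(annGr)$count <- as.integer(annCount[keep])
        ## planted cryptic junctions
        cj <- truth$junctions
        expressed <- stats::runif(length(cj)) < rho
        cjGr <- cj[expressed]
        mcols(cjGr) <- NULL
        mcols(cjGr)$count <- as.integer(rztpois(sum(expressed),
                                                design@crypticMean))
        ## shared unannotated noise (same coordinates in every sample;
        ## drawn from a design-seeded stream so both conditions share them)
        shared <- sharedNoiseJunctions(design, catalog)
        sharedIn <- stats::runif(length(shared)) < 0.8
        shGr <- shared[sharedIn]
        mcols(shGr)$count <- as.integer(rztpois(sum(sharedIn), 3))
        ## per-sample long-span artifacts (> 20 kb)
        artGr <- GRanges()
        if (design@nArtifacts > 0L && !is.null(genomeLen) &&
            genomeLen > 26000L) {
            as_ <- sample(seq(100L, genomeLen - 26000L),
                          design@nArtifacts, replace = TRUE)
            aw <- sample(20001:25000, design@nArtifacts, replace = TRUE)
            artGr <- GRanges("chrS", IRanges(as_, as_ + aw - 1L),
                             strand = sample(c("+", "-"), design@nArtifacts,
                                             replace = TRUE))
            mcols(artGr)$count <- as.integer(rztpois(design@nArtifacts, 2))
        }
        out <- c(annGr, cjGr, shGr, artGr)
        mcols(out)$sample <- sampleId
        GenomicRanges::sort(out, ignore.strand = TRUE)
    })
}

## fixed set of unannotated junctions present in both conditions; inside
## gene bodies but distinct from annotated introns and planted sites
sharedNoiseJunctions <- function(design, catalog) {
    if (design@nSharedNoise < 1L) return(GRanges())
    withr::with_seed(subSeed(design@seed, 3L), {
        genes <- catalog@genes
        n <- design@nSharedNoise
        gi <- sample(seq_along(genes), n, replace = TRUE)
        w <- sample(90:350, n, replace = TRUE)
        lo <- start(genes)[gi] + 40L
        hi <- end(genes)[gi] - w - 40L
        ok <- hi > lo
        s <- integer(n)
        s[ok] <- lo[ok] + floor(stats::runif(sum(ok)) * (hi - lo)[ok])
        gr <- GRanges("chrS", IRanges(s[ok], s[ok] + w[ok] - 1L),
                      strand = as.character(strand(genes))[gi][ok])
        annKey <- coordKey(catalog@introns)
        gr[!coordKey(gr) %in% annKey]
    })
}

#' Simulate the gene counts table
#'
#' Negative-binomial counts per gene and sample; the design's DE genes
#' change by `deFold` in the non-reference condition.
#'
#' @param truth the `truth` element of [plantCrypticSites()].
#' @param design a [SimulationDesign-class].
#' @param samples data.frame with `sample_id` and `condition`.
#' @return integer matrix genes x samples.
#' @export
simulateCounts <- function(truth, design, samples) {
    withr::with_seed(subSeed(design@seed, 4L), {
        geneIds <- names(truth$geneBase)
        baseMu <- 200 * truth$geneBase
        ref <- design@conditions$label[1L]
        m <- sapply(seq_len(nrow(samples)), function(j) {
            fold <- if (samples$condition[j] == ref) 1 else truth$geneFold
            stats::rnbinom(length(geneIds), mu = baseMu * fold,
                           size = 1 / design@dispersion)
        })
        rownames(m) <- geneIds
        colnames(m) <- samples$sample_id
        storage.mode(m) <- "integer"
        m
    })
}

## sample sheet implied by a design
designSamples <- function(design) {
    cond <- design@conditions
    rows <- list()
    for (ci in seq_len(nrow(cond)))
        for (ts in design@tissues)
            for (r in seq_len(cond$replicates[ci]))
                rows[[length(rows) + 1L]] <- data.frame(
                    sample_id = if (length(design@tissues) > 1L)
                        sprintf("%s_%s_rep%d", cond$label[ci], ts, r)
                    else sprintf("%s_s%03d", cond$label[ci], r),
                    condition = cond$label[ci], tissue = ts,
                    stringsAsFactors = FALSE)
    df <- do.call(rbind, rows)
    df$sub_seed <- subSeed(design@seed, 100L + seq_len(nrow(df)))
    df
}

#' Write a GTF for an annotation catalog
#'
#' Ensembl-style attribute syntax, one gene/transcript/exon feature block
#' per transcript, 1-based closed coordinates.
#'
#' @param catalog an [AnnotationCatalog-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAnnotationGtf <- function(catalog, path) {
    lines <- character()
    genes <- catalog@genes
    gid <- mcols(genes)$gene_id
    for (g in seq_along(genes)) {
        attrs <- sprintf('gene_id "%s";', gid[g])
        lines <- c(lines, paste(as.character(seqnames(genes))[g], "synth",
                                "gene", start(genes)[g], end(genes)[g], ".",
                                as.character(strand(genes))[g], ".", attrs,
                                sep = "\t"))
        txs <- names(catalog@txGene)[catalog@txGene == gid[g]]
        for (tx in txs) {
            ex <- catalog@exons[[tx]]
            a2 <- sprintf('gene_id "%s"; transcript_id "%s";', gid[g], tx)
            lines <- c(lines, paste(as.character(seqnames(ex))[1L], "synth",
                                    "transcript", min(start(ex)), max(end(ex)),
                                    ".", as.character(strand(ex))[1L], ".",
                                    a2, sep = "\t"))
            for (e in seq_along(ex))
                lines <- c(lines, paste(as.character(seqnames(ex))[e],
                                        "synth", "exon", start(ex)[e],
                                        end(ex)[e], ".",
                                        as.character(strand(ex))[e], ".",
                                        a2, sep = "\t"))
        }
    }
    writeLines(lines, path)
    invisible(path)
}

#' Emit a complete synthetic fixture directory
#'
#' Writes `genome.fa`, `annotation.gtf`, `samples/<id>.junctions.bed`, a
#' `design.tsv` sample sheet (with per-sample total mapped reads),
#' `counts.tsv`, `truth.json` (planted cryptic junctions and true gene
#' folds) and `manifest.json` (seed and all design parameters). Byte-
#' identical across runs with the same design.
#'
#' @param design a [SimulationDesign-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emitFixture <- function(design, dir) {
    validObject(design)
    dir.create(file.path(dir, "samples"), recursive = TRUE,
               showWarnings = FALSE)
    ga <- buildGenomeAnnotation(design)
    pl <- plantCrypticSites(ga$genome, ga$catalog, design)
    genome <- pl$genome; truth <- pl$truth; catalog <- ga$catalog
    writeXStringSet(genome, file.path(dir, "genome.fa"))
    writeAnnotationGtf(catalog, file.path(dir, "annotation.gtf"))
    smp <- designSamples(design)
    glen <- Biostrings::width(genome)[1L]
    totalReads <- integer(nrow(smp))
    for (i in seq_len(nrow(smp))) {
        gr <- simulateSampleJunctions(truth, catalog, design,
                                      smp$condition[i], smp$tissue[i],
                                      smp$sample_id[i], smp$sub_seed[i],
                                      genomeLen = glen)
        writeJunctionBed(gr, file.path(dir, "samples",
                                       paste0(smp$sample_id[i],
                                              ".junctions.bed")))
        ## library size: junction reads plus a seeded body-read component
        totalReads[i] <- withr::with_seed(
            subSeed(design@seed, 500L + i),
            as.integer(round(1e6 * stats::rlnorm(1, 0, 0.05))) +
                sum(mcols(gr)$count))
    }
    designDf <- data.frame(sample_id = smp$sample_id,
                           condition = smp$condition, tissue = smp$tissue,
                           total_reads = totalReads,
                           stringsAsFactors = FALSE)
    utils::write.table(designDf, file.path(dir, "design.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    counts <- simulateCounts(truth, design, designDf)
    writeCountsTable(counts, file.path(dir, "counts.tsv"))
    tj <- truth$junctions
    truthOut <- list(
        cryptic_junctions = data.frame(
            contig = as.character(seqnames(tj)), start = start(tj),
            end = end(tj), strand = as.character(strand(tj)),
            gene_id = mcols(tj)$gene_id,
            donor_window = mcols(tj)$donor_window,
            acceptor_window = mcols(tj)$acceptor_window,
            stringsAsFactors = FALSE),
        gene_fold = as.list(truth$geneFold),
        gene_base = as.list(truth$geneBase))
    jsonlite::write_json(truthOut, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(seed = design@seed, n_genes = design@nGenes,
                     exons_per_gene = design@exonsPerGene,
                     conditions = design@conditions,
                     tissues = design@tissues, depth = design@depth,
                     dispersion = design@dispersion,
                     de_fraction = design@deFraction,
                     de_fold = design@deFold,
                     cryptic_per_gene = design@crypticPerGene,
                     cryptic_mean = design@crypticMean,
                     degradation = design@degradation,
                     n_shared_noise = design@nSharedNoise,
                     n_artifacts = design@nArtifacts,
                     n_samples = nrow(designDf))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
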