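#' Pipeline configuration
#'
#' Bundles the fixture/data paths, the analysis mode and all thresholds.
#' Mode presets load the two study defaults (mouse: expression gate and
#' gain fold 2.0, alpha 0.05; cohort: 1.5, alpha 0.01, minimum 10 reads
#' per gene); any field can be overridden. The configuration is echoed
#' into the run's `summary.json`.
#'
#' @param dir fixture/data directory (layout of [emitFixture()]).
#' @param mode `"mouse"` or `"cohort"`.
#' @param maxSpan junction span filter in bp.
#' @param minReads minimum pooled read support per junction.
#' @param modelOrder constraint order of the splice-site models.
#' @param seed seed for the shuffle control.
#' @param ... overrides passed to [geneGateConfig()].
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(dir, mode = c("mouse", "cohort"),
                           maxSpan = 20000L, minReads = 1L,
                           modelOrder = "adjacent2", seed = 1L, ...) {
    mode <- match.arg(mode)
    cfg <- list(dir = dir, mode = mode, maxSpan = maxSpan,
                minReads = minReads, modelOrder = modelOrder,
                seed = as.integer(seed),
                gate = geneGateConfig(mode, ...))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the full splicing-noise pipeline on a fixture directory
#'
#' Stages: read genome/annotation/design/junctions/counts; detect de novo
#' junctions; fit donor and acceptor maximum-entropy models on annotated
#' sites and score the de novo, annotated and shuffled-control classes;
#' per-gene gain analysis gated on stable expression; quartile
#' stratification plus between-quartile differential expression (cohort
#' mode). Writes `noise_report.tsv`, `scores.tsv`, `gene_noise.tsv`,
#' `strata.tsv` (cohort) and `summary.json` into `outDir`; inputs are
#' never mutated.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return (invisibly) a list with all intermediate results: `report`,
#'   `comparison`, `classScores`, `geneGain`, `strata`, `deQuartiles`,
#'   `summary`.
#' @export
runNoisePipeline <- function(config, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    dir <- config$dir
    genome <- readGenome(file.path(dir, "genome.fa"))
    catalog <- readAnnotation(file.path(dir, "annotation.gtf"))
    design <- readDesignTable(file.path(dir, "design.tsv"))
    counts <- readCountsTable(file.path(dir, "counts.tsv"))
    bedFiles <- list.files(file.path(dir, "samples"),
                           pattern = "\\.junctions\\.bed$",
                           full.names = TRUE)
    if (!length(bedFiles))
        stop("no junction BED files under ", file.path(dir, "samples"))
    gr <- do.call(c, lapply(bedFiles, function(f)
        readJunctionBed(f, sub("\\.junctions\\.bed$", "", basename(f)))))
    report <- detectNoise(gr, catalog, design, mode = config$mode,
                          maxSpan = config$maxSpan,
                          minReads = config$minReads)
    comparison <- compareConditions(report,
                                    paired = config$mode == "mouse")
    ## splice-site strength: models fitted on the annotation's own sites
    annWin <- extractWindows(annotatedIntrons(catalog), genome)$windows
    donorModel <- fitMaxEnt(annWin$donor, order = config$modelOrder,
                            kind = "donor")
    acceptorModel <- fitMaxEnt(annWin$acceptor, order = config$modelOrder,
                               kind = "acceptor")
    dnAll <- unlist(report@denovo, use.names = FALSE)
    shuffled <- shuffleJunctions(dnAll, genome, seed = config$seed)
    shWin <- extractWindows(shuffled, genome)$windows
    donorBg <- fitMaxEnt(shWin$donor, order = "order1", kind = "background",
                         minTraining = 10L)
    acceptorBg <- fitMaxEnt(shWin$acceptor, order = "order1",
                            kind = "background", minTraining = 10L)
    classScores <- scoreClasses(dnAll, annotatedIntrons(catalog), shuffled,
                                genome, donorModel, acceptorModel,
                                donorBg, acceptorBg)
    geneGain <- perGeneGain(report, gr, catalog, counts, design,
                            config$gate)
    strata <- NULL; deQ <- NULL
    if (config$mode == "cohort") {
        strata <- stratifyByNoise(report)
        deQ <- deBetweenQuartiles(counts, strata$upper, strata$lower,
                                  fcThreshold = config$gate$maxExpressionFC,
                                  alpha = config$gate$alpha)
    }
    ## outputs
    utils::write.table(sampleCounts(report),
                       file.path(outDir, "noise_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(classScores$scores, file.path(outDir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(geneGain, file.path(outDir, "gene_noise.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(strata))
        utils::write.table(strata$strata, file.path(outDir, "strata.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(
        config = config[c("mode", "maxSpan", "minReads", "modelOrder",
                          "seed")],
        gate = unclass(config$gate),
        filter_log = filterLog(report),
        denovo_per_condition = as.list(vapply(report@denovo, length,
                                              integer(1))),
        condition_means = as.list(comparison$means),
        comparison_p = comparison$p,
        class_means = as.list(classScores$classMeans),
        anova_p = classScores$anova$p,
        ordering_holds = classScores$orderingHolds,
        genes_gaining = sum(geneGain$gain),
        genes_losing = sum(geneGain$loss),
        genes_eligible = nrow(geneGain))
    if (!is.null(deQ)) {
        summary$quartile_up_genes <- length(deQ$up)
        summary$quartile_down_genes <- length(deQ$down)
    }
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    invisible(list(report = report, comparison = comparison,
                   classScores = classScores, geneGain = geneGain,
                   strata = strata, deQuartiles = deQ, summary = summary))
}

#' Simulate a fixture directory (convenience wrapper)
#'
#' @param design a [SimulationDesign-class] (default mouse-style design).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
simulateFixture <- function(design = simulationDesign(), dir) {
    emitFixture(design, dir)
}
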