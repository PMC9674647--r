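test_that("classification is exact identity with a strand wildcard", {
    cat1 <- toyCatalog(c(1L, 100L), c(201L, 300L), "+")  # intron 101..200 (+)
    gr <- junctions(rep("c1", 4),
                    c(101L, 101L, 101L, 101L),
                    c(200L, 180L, 200L, 200L),
                    c("+", "+", "*", "-"),
                    count = 1L, sample = "s")
    cls <- classifyJunctions(gr, cat1)
    ## exact match and unknown-strand match are annotated; a junction
    ## sharing only the donor, or on the wrong strand, is not
    expect_equal(junctionSpan(cls$annotated), c(100L, 100L))
    expect_setequal(as.character(strand(cls$annotated)), c("+", "*"))
    expect_equal(length(cls$unannotated), 2L)
})

test_that("pooling merges identities, sums counts and is idempotent", {
    gr <- junctions(rep("c1", 4), c(101L, 101L, 101L, 501L),
                    c(200L, 200L, 200L, 600L), "+",
                    count = c(1L, 2L, 3L, 4L),
                    sample = c("r1", "r2", "r3", "r1"))
    pool <- poolJunctions(gr)
    expect_equal(length(pool), 2L)
    expect_equal(mcols(pool)$count, c(6L, 4L))
    expect_equal(mcols(pool)$samples[1L], "r1,r2,r3")
    pool2 <- poolJunctions(pool)
    expect_equal(mcols(pool2)$count, mcols(pool)$count)
    expect_equal(junctionKey(pool2), junctionKey(pool))
})

test_that("span filter boundary: exactly 20 kb kept, 20 kb + 1 removed", {
    gr <- junctions("c1", c(1L, 1L, 1L), c(20000L, 20001L, 900L), "+",
                    count = 1L, sample = "s")
    fs <- filterSpan(gr)
    expect_equal(max(junctionSpan(fs$kept)), 20000L)
    expect_equal(fs$removed, 1L)
    expect_equal(length(filterSpan(gr, maxSpan = 0L)$kept), 0L)
    short <- junctions("c1", c(1L, 50L), c(500L, 800L), "+", 1L, "s")
    expect_equal(length(filterSpan(short)$kept), 2L)
})

test_that("exclusivity eliminates junctions shared between conditions", {
    a <- junctions("c1", c(101L, 501L), c(200L, 600L), "+", 2L, "a")
    b <- junctions("c1", c(501L, 901L), c(600L, 990L), c("*", "+"), 2L, "b")
    dn <- callDeNovo(a, b)
    expect_equal(start(dn$A), 101L)
    expect_equal(start(dn$B), 901L)
    expect_equal(dn$sharedRemoved, 2L)
})

test_that("de novo sets equal a brute-force oracle on random toys", {
    cat1 <- toyCatalog(c(1L, 100L), c(201L, 300L), "+")
    ann <- data.frame(contig = "c1", start = 101, end = 200, strand = "+",
                      stringsAsFactors = FALSE)
    design <- data.frame(
        sample_id = c("a1", "a2", "b1", "b2"),
        condition = c("A", "A", "B", "B"),
        tissue = "t", total_reads = 1e6, stringsAsFactors = FALSE)
    for (seed in c(11L, 23L, 37L)) {
        df <- randomJunctionTable(seed)
        df$condition <- ifelse(df$sample %in% c("a1", "a2"), "A", "B")
        ## occasionally inject the annotated intron and a cross-condition
        ## duplicate to exercise every removal path
        df <- rbind(df,
            data.frame(contig = "c1", start = 101, end = 200, strand = "+",
                       count = 9, sample = "a1", condition = "A"),
            data.frame(contig = "c1", start = df$start[1],
                       end = df$end[1], strand = df$strand[1], count = 1,
                       sample = "b1", condition = "B"))
        gr <- junctions(df$contig, df$start, df$end, df$strand,
                        df$count, df$sample)
        report <- detectNoise(gr, cat1, design, mode = "cohort")
        oracle <- bruteDenovo(df, ann)
        dn <- denovoJunctions(report)
        expect_setequal(coordKey(dn[["A"]]),
                        paste0("c1:", oracle$A$start, "-", oracle$A$end))
        expect_setequal(coordKey(dn[["B"]]),
                        paste0("c1:", oracle$B$start, "-", oracle$B$end))
    }
})

test_that("pool-level conservation: every junction is accounted for", {
    cat1 <- toyCatalog(c(1L, 100L), c(201L, 300L), "+")
    df <- randomJunctionTable(7L)
    grA <- junctions(df$contig, df$start, df$end, df$strand, df$count, "a1")
    cls <- classifyJunctions(poolJunctions(grA), cat1)
    sp <- filterSpan(cls$unannotated)
    dn <- callDeNovo(sp$kept, sp$kept[0])
    expect_equal(length(poolJunctions(grA)),
                 length(cls$annotated) + sp$removed + dn$sharedRemoved +
                     length(dn$A))
})

test_that("detection results are invariant to input order", {
    cat1 <- toyCatalog(c(1L, 100L), c(201L, 300L), "+")
    design <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                         condition = c("A", "A", "B", "B"), tissue = "t",
                         total_reads = c(1e6, 2e6, 1e6, 2e6),
                         stringsAsFactors = FALSE)
    df <- randomJunctionTable(3L)
    gr <- junctions(df$contig, df$start, df$end, df$strand, df$count,
                    df$sample)
    r1 <- detectNoise(gr, cat1, design, mode = "cohort")
    perm <- withr::with_seed(1L, sample(length(gr)))
    r2 <- detectNoise(gr[perm], cat1, design, mode = "cohort")
    expect_setequal(junctionKey(denovoJunctions(r1)[[1]]),
                    junctionKey(denovoJunctions(r2)[[1]]))
    expect_equal(sampleCounts(r1)$raw, sampleCounts(r2)$raw)
})

test_that("per-sample normalization is per million mapped reads", {
    cat1 <- toyCatalog(c(1L, 100L), c(201L, 300L), "+")
    design <- data.frame(sample_id = c("a1", "b1", "b2"),
                         condition = c("A", "B", "B"), tissue = "t",
                         total_reads = c(1e7, 1e7, 2e7),
                         stringsAsFactors = FALSE)
    ## 50 junctions exclusive to condition B, observed in both b samples
    s <- seq(1000L, by = 500L, length.out = 50L)
    grB <- c(junctions("c1", s, s + 99L, "+", 2L, "b1"),
             junctions("c1", s, s + 99L, "+", 1L, "b2"))
    grA <- junctions("c1", 70000L, 70100L, "+", 1L, "a1")
    report <- detectNoise(c(grA, grB), cat1, design, mode = "cohort")
    smp <- sampleCounts(report)
    expect_equal(smp$raw[smp$sample_id == "b1"], 50L)
    expect_equal(smp$normalized[smp$sample_id == "b1"], 5.0)
    ## doubled depth with identical junctions -> half the normalized count
    expect_equal(smp$normalized[smp$sample_id == "b2"], 2.5)
    ## a sample with no de novo junction of its own condition reports 0
    expect_equal(smp$raw[smp$sample_id == "a1"], 1L)
})

test_that("condition comparison handles identity and pairing rules", {
    smp <- data.frame(
        sample_id = paste0("s", 1:6),
        condition = rep(c("WT", "KO"), each = 3),
        tissue = rep(c("t1", "t2", "t3"), 2),
        total_reads = 1e6, raw = 5L, normalized = 5)
    rep0 <- new("NoiseReport",
                denovo = GenomicRanges::GRangesList(
                    WT = junctions("c1", 101L, 200L, "+", 1L, "x"),
                    KO = junctions("c1", 501L, 600L, "+", 1L, "x")),
                samples = smp, filterLog = list(),
                params = list(mode = "mouse"))
    cmp <- compareConditions(rep0, paired = TRUE)
    expect_equal(cmp$difference, 0)
    expect_equal(cmp$p, 1)
    ## paired mode with unmatched tissues errors
    smp2 <- smp; smp2$tissue[1:3] <- c("t1", "t2", "t4")
    rep2 <- rep0; rep2@samples <- smp2
    expect_error(compareConditions(rep2, paired = TRUE), "tissue")
})
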