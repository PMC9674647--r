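test_that("window geometry matches hand-computed coordinates", {
    g <- toyGenome(400L)
    seqc <- as.character(g[["c1"]])
    gr <- junctions("c1", 101L, 200L, "+", 1L, "s")
    ew <- extractWindows(gr, g)$windows
    ## + strand: donor = genome[98..106], acceptor = genome[181..203]
    expect_equal(ew$donor, substr(seqc, 98, 106))
    expect_equal(ew$acceptor, substr(seqc, 181, 203))
    expect_equal(nchar(ew$donor), 9L)
    expect_equal(nchar(ew$acceptor), 23L)

    ## - strand: mirrored and reverse-complemented
    grm <- junctions("c1", 101L, 200L, "-", 1L, "s")
    ewm <- extractWindows(grm, g)$windows
    rc <- function(x) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(x)))
    expect_equal(ewm$donor, rc(substr(seqc, 195, 203)))
    expect_equal(ewm$acceptor, rc(substr(seqc, 98, 120)))

    ## unknown strand: both orientations extracted
    gru <- junctions("c1", 101L, 200L, "*", 1L, "s")
    ewu <- extractWindows(gru, g)$windows
    expect_equal(nrow(ewu), 2L)
    expect_setequal(ewu$orientation, c("+", "-"))

    ## donor out of bounds is dropped, acceptor kept
    gr2 <- junctions("c1", 2L, 120L, "+", 1L, "s")
    ew2 <- extractWindows(gr2, g)
    expect_true(is.na(ew2$windows$donor))
    expect_false(is.na(ew2$windows$acceptor))
    expect_equal(ew2$dropped$out_of_bounds, 1L)
})

test_that("order-1 fit reproduces hand-computed frequencies", {
    m <- fitMaxEnt(c("AC", "AC", "AC", "AG"), order = "order1",
                   pseudocount = 0, minTraining = 1L)
    p <- 2^logProb(m, c("AC", "AG"))
    expect_equal(p, c(0.75, 0.25))

    ## degenerate training: the repeated sequence is the modal sequence
    md <- fitMaxEnt(rep("ACG", 60), order = "order1", minTraining = 50L)
    allseq <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 3))[, 3:1],
                    1, paste, collapse = "")
    pr <- 2^logProb(md, allseq)
    expect_equal(allseq[which.max(pr)], "ACG")
    expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("adjacent-constraint closed form equals IPF on toy spaces", {
    for (seed in c(2L, 9L)) {
        w <- withr::with_seed(seed, replicate(150, paste(
            sample(c("A", "C", "G", "T"), 4, TRUE,
                   prob = c(.5, .2, .2, .1)), collapse = "")))
        chain <- fitMaxEnt(w, order = "adjacent2")
        ipf <- maxentIPF(w, pairs = list(c(1, 2), c(2, 3), c(3, 4)))
        allseq <- apply(expand.grid(rep(list(c("A", "C", "G", "T")),
                                        4))[, 4:1], 1, paste, collapse = "")
        pChain <- 2^logProb(chain, allseq)
        pIpf <- ipf$prob[spliceNoise:::seqToIndex(allseq, 4)]
        expect_lt(0.5 * sum(abs(pChain - pIpf)), 1e-8)
        expect_equal(sum(pChain), 1, tolerance = 1e-9)
    }
})

test_that("fitted marginals match their smoothed empirical targets", {
    w <- withr::with_seed(4L, replicate(120, paste(
        sample(c("A", "C", "G", "T"), 5, TRUE, prob = c(.4, .3, .2, .1)),
        collapse = "")))
    m <- fitMaxEnt(w, order = "pairwise2")
    wm <- spliceNoise:::windowMatrix(w, 5L)
    for (pr in list(c(1, 2), c(1, 5), c(2, 4), c(3, 5))) {
        target <- spliceNoise:::pairTargets(wm, list(pr), 0.5)[[1]]
        fitted <- spliceNoise:::modelMarginal(m, pr)
        expect_lt(max(abs(fitted - target)), 1e-6)
    }
    expect_equal(sum(m@jointProb), 1, tolerance = 1e-9)
    expect_error(fitMaxEnt(c("ACGT", "ACG"), order = "order1",
                           minTraining = 1L), "uniform")
})

test_that("log-odds scoring has its closed-form identities", {
    bg <- uniformModel(1L)
    expect_equal(maxentScore(bg, bg, c("A", "C", "G", "T")), rep(0, 4))
    sig <- new("MaxEntModel", kind = "s", width = 1L, order = "order1",
               pseudocount = 0,
               positionProbs = matrix(c(0.5, 1 / 6, 1 / 6, 1 / 6),
                                      4, 1, dimnames = list(
                                          c("A", "C", "G", "T"), NULL)),
               pairProbs = list(), jointProb = numeric(0),
               fitMeta = list(training = 0L))
    expect_equal(maxentScore(sig, bg, "A"), 1.0)  # P_sig = 2 x P_bg
    expect_error(maxentScore(sig, uniformModel(2L), "A"), "width")
})

test_that("strand symmetry: minus-strand scoring equals the plus mirror", {
    g <- toyGenome(600L, seed = 8L)
    n <- Biostrings::width(g)[1]
    rcg <- Biostrings::reverseComplement(g[[1]])
    gRc <- Biostrings::DNAStringSet(as.character(rcg))
    names(gRc) <- "c1"
    grm <- junctions("c1", 201L, 400L, "-", 1L, "s")
    ## mirror junction on the reverse-complemented genome, plus strand
    grp <- junctions("c1", n - 400L + 1L, n - 201L + 1L, "+", 1L, "s")
    wm <- extractWindows(grm, g)$windows
    wp <- extractWindows(grp, gRc)$windows
    expect_equal(wm$donor, wp$donor)
    expect_equal(wm$acceptor, wp$acceptor)
})

test_that("shuffling preserves spans and is seed-deterministic", {
    g <- toyGenome(5000L)
    s <- withr::with_seed(2L, sample(100:4000, 60L))
    gr <- junctions("c1", s, s + rep(c(80L, 200L, 421L), 20L), "+",
                    count = 3L, sample = "x")
    sh1 <- shuffleJunctions(gr, g, seed = 99L)
    sh2 <- shuffleJunctions(gr, g, seed = 99L)
    expect_equal(length(sh1), 60L)
    expect_equal(sort(width(sh1)), sort(width(gr)))
    expect_identical(start(sh1), start(sh2))
    expect_false(identical(start(sh1), start(gr)))
    ## span longer than the contig is skipped with a warning
    big <- junctions("c1", 1L, 4990L, "+", 1L, "x")
    expect_warning(out <- shuffleJunctions(big, g, seed = 1L), "skipped")
    expect_length(out, 0L)
})

test_that("class scoring reports ANOVA and the ordering flag honestly", {
    g <- toyGenome(5000L)
    s <- seq(100L, by = 150L, length.out = 30L)
    gr <- junctions("c1", s, s + 99L, "+", 1L, "x")
    bg <- uniformModel(9L); bga <- uniformModel(23L)
    sig <- uniformModel(9L); siga <- uniformModel(23L)
    ## identical classes under identical models: F ~ 0, ordering FALSE
    res <- scoreClasses(gr, gr, gr, g, sig, siga, bg, bga)
    expect_false(res$orderingHolds)
    expect_true(is.na(res$anova$F) || res$anova$F < 1e-6)
    expect_error(scoreClasses(gr[1], gr, gr, g, sig, siga, bg, bga),
                 "two junctions")
})
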