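BASES <- c("A", "C", "G", "T")

## windows (character vector) -> integer matrix n x L of base codes 1..4;
## rows containing other letters get NA
windowMatrix <- function(windows, width) {
    if (!length(windows))
        return(matrix(integer(0), 0, width))
    if (any(nchar(windows) != width))
        stop("all windows must have width ", width)
    m <- matrix(match(unlist(strsplit(windows, "", fixed = TRUE)), BASES),
                ncol = width, byrow = TRUE)
    m
}

## map ACGT windows to 1-based indices into the enumerated 4^L space
## (first position most significant)
seqToIndex <- function(windows, width) {
    m <- windowMatrix(windows, width)
    idx <- rep(1, nrow(m))
    for (p in seq_len(width)) idx <- idx + (m[, p] - 1) * 4^(width - p)
    idx
}

## base code of position p for all 4^L enumerated sequences
enumPosition <- function(width, p) {
    ((seq_len(4^width) - 1) %/% 4^(width - p)) %% 4 + 1
}

#' Extract donor and acceptor windows for junctions
#'
#' Donor windows cover the last 3 exonic and first 6 intronic nucleotides
#' (9 nt); acceptor windows the last 20 intronic and first 3 exonic
#' nucleotides (23 nt), both read 5'->3' on the transcribed strand (minus
#' strand windows are reverse-complemented). Junctions of unknown strand
#' are extracted in both orientations (`orientation` column) so scoring
#' can retain the higher-scoring one. Windows falling outside contig
#' bounds or containing non-ACGT letters are dropped and tallied.
#'
#' @param gr junction `GRanges`.
#' @param genome `DNAStringSet` from [readGenome()].
#' @return a list with `windows` (data.frame: `key`, `junction` index,
#'   `orientation`, `donor`, `acceptor` sequences, possibly NA when a
#'   single window was dropped) and `dropped` (tally list).
#' @export
extractWindows <- function(gr, genome) {
    donorLen <- 9L; accLen <- 23L
    rows <- list(); nOut <- 0L; nN <- 0L
    lens <- Biostrings::width(genome)
    names(lens) <- names(genome)
    strands <- as.character(strand(gr))
    for (i in seq_along(gr)) {
        chr <- as.character(seqnames(gr))[i]
        if (!chr %in% names(genome)) { nOut <- nOut + 1L; next }
        orientations <- if (strands[i] == "*") c("+", "-") else strands[i]
        for (ori in orientations) {
            s <- start(gr)[i]; e <- end(gr)[i]
            if (ori == "+") {
                dw <- c(s - 3L, s + 5L); aw <- c(e - 19L, e + 3L)
            } else {
                dw <- c(e - 5L, e + 3L); aw <- c(s - 3L, s + 19L)
            }
            getwin <- function(w) {
                if (w[1L] < 1L || w[2L] > lens[[chr]]) return(NA_character_)
                x <- subseq(genome[[chr]], w[1L], w[2L])
                if (ori == "-") x <- reverseComplement(x)
                as.character(x)
            }
            d <- getwin(dw); a <- getwin(aw)
            if (is.na(d) || is.na(a)) nOut <- nOut + 1L
            if (!is.na(d) && grepl("[^ACGT]", d)) { d <- NA_character_; nN <- nN + 1L }
            if (!is.na(a) && grepl("[^ACGT]", a)) { a <- NA_character_; nN <- nN + 1L }
            rows[[length(rows) + 1L]] <- data.frame(
                key = junctionKey(gr[i]), junction = i, orientation = ori,
                donor = d, acceptor = a, stringsAsFactors = FALSE)
        }
    }
    windows <- if (length(rows)) do.call(rbind, rows) else
        data.frame(key = character(), junction = integer(),
                   orientation = character(), donor = character(),
                   acceptor = character(), stringsAsFactors = FALSE)
    list(windows = windows,
         dropped = list(out_of_bounds = nOut, contains_n = nN))
}

## smoothed marginal tables from a window matrix
pairTargets <- function(m, pairs, pseudocount) {
    n <- nrow(m)
    lapply(pairs, function(pr) {
        tab <- matrix(pseudocount, 4, 4, dimnames = list(BASES, BASES))
        t0 <- table(factor(m[, pr[1L]], levels = 1:4),
                    factor(m[, pr[2L]], levels = 1:4))
        (tab + t0) / (n + 16 * pseudocount)
    })
}

singleTargets <- function(m, pseudocount) {
    n <- nrow(m)
    sapply(seq_len(ncol(m)), function(p) {
        (tabulate(m[, p], 4) + pseudocount) / (n + 4 * pseudocount)
    })
}

#' Iterative proportional fitting of a maximum-entropy sequence model
#'
#' Finds the maximum-entropy distribution over the fully enumerated
#' `4^width` sequence space whose pair marginals (and implied singletons)
#' match the smoothed empirical marginals of the training windows, by
#' cyclically rescaling on each constraint until all constrained marginals
#' match within `tol`.
#'
#' @param windows character vector of equal-width ACGT windows.
#' @param pairs list of integer pairs (positions) to constrain; default all
#'   unordered pairs.
#' @param pseudocount smoothing pseudocount per marginal cell.
#' @param tol convergence tolerance on the max absolute marginal residual.
#' @param maxIter maximum IPF sweeps.
#' @return list: `prob` (length `4^width` distribution), `residual`,
#'   `iterations`, `targets`.
#' @export
maxentIPF <- function(windows, pairs = NULL, pseudocount = 0.5,
                      tol = 1e-6, maxIter = 500L) {
    width <- unique(nchar(windows))
    if (length(width) != 1L) stop("windows must have uniform width")
    if (width > 10L) stop("IPF space 4^", width, " is not enumerable here")
    m <- windowMatrix(windows, width)
    if (anyNA(m)) stop("IPF training windows must be pure ACGT")
    if (is.null(pairs)) {
        pairs <- list()
        for (i in seq_len(width - 1L))
            for (j in seq(i + 1L, width)) pairs[[length(pairs) + 1L]] <- c(i, j)
    }
    targets <- pairTargets(m, pairs, pseudocount)
    pos <- lapply(seq_len(width), function(p) enumPosition(width, p))
    groups <- lapply(pairs, function(pr) (pos[[pr[1L]]] - 1L) * 4L + pos[[pr[2L]]])
    tvec <- lapply(targets, function(t) as.vector(t(t)))  # index (a-1)*4+b
    p <- rep(1 / 4^width, 4^width)
    iter <- 0L; residual <- Inf
    while (iter < maxIter) {
        iter <- iter + 1L
        for (k in seq_along(pairs)) {
            cur <- as.vector(rowsum(p, groups[[k]], reorder = TRUE))
            ratio <- tvec[[k]] / cur
            p <- p * ratio[groups[[k]]]
        }
        residual <- max(vapply(seq_along(pairs), function(k) {
            cur <- as.vector(rowsum(p, groups[[k]], reorder = TRUE))
            max(abs(cur - tvec[[k]]))
        }, numeric(1)))
        if (residual < tol) break
    }
    if (residual >= tol)
        stop(sprintf("IPF did not converge: residual %.3g after %d sweeps",
                     residual, iter))
    list(prob = p, residual = residual, iterations = iter, targets = targets)
}

#' Fit a maximum-entropy splice-site model
#'
#' @param windows character vector or `DNAStringSet` of equal-width
#'   training windows (pure ACGT; others rejected).
#' @param order `"order1"` (independent positions), `"adjacent2"`
#'   (singleton + adjacent-pair marginals, closed-form Markov chain) or
#'   `"pairwise2"` (all pairwise marginals via [maxentIPF()]; enumerable
#'   widths only, intended for 9-nt donors).
#' @param pseudocount smoothing pseudocount per marginal cell.
#' @param tol,maxIter IPF convergence controls (pairwise2).
#' @param kind free-text label stored in the model.
#' @param minTraining minimum number of training windows.
#' @return a [MaxEntModel-class] object.
#' @export
fitMaxEnt <- function(windows, order = c("adjacent2", "order1", "pairwise2"),
                      pseudocount = 0.5, tol = 1e-6, maxIter = 500L,
                      kind = "signal", minTraining = 50L) {
    order <- match.arg(order)
    windows <- as.character(windows)
    windows <- windows[!is.na(windows)]
    if (length(windows) < minTraining)
        stop("need at least ", minTraining, " training windows, got ",
             length(windows))
    width <- unique(nchar(windows))
    if (length(width) != 1L) stop("training windows must have uniform width")
    width <- as.integer(width)
    m <- windowMatrix(windows, width)
    if (anyNA(m)) stop("training windows must be pure ACGT")
    posProbs <- singleTargets(m, pseudocount)
    rownames(posProbs) <- BASES
    pairProbs <- list(); jointProb <- numeric(0)
    meta <- list(training = length(windows), tol = tol)
    if (order == "adjacent2") {
        pairs <- lapply(seq_len(width - 1L), function(i) c(i, i + 1L))
        pairProbs <- pairTargets(m, pairs, pseudocount)
        ## chain-consistent position marginals (pseudocount 4*pc per base)
        posProbs <- singleTargets(m, 4 * pseudocount)
        rownames(posProbs) <- BASES
    } else if (order == "pairwise2") {
        fit <- maxentIPF(windows, pseudocount = pseudocount, tol = tol,
                         maxIter = maxIter)
        jointProb <- fit$prob
        meta$iterations <- fit$iterations
        meta$residual <- fit$residual
    }
    new("MaxEntModel", kind = kind, width = width, order = order,
        pseudocount = pseudocount, positionProbs = posProbs,
        pairProbs = pairProbs, jointProb = jointProb, fitMeta = meta)
}

#' Uniform background model
#'
#' @param width window width.
#' @param kind label.
#' @return a [MaxEntModel-class] with equal base probabilities.
#' @export
uniformModel <- function(width, kind = "uniform") {
    new("MaxEntModel", kind = kind, width = as.integer(width),
        order = "order1", pseudocount = 0,
        positionProbs = matrix(0.25, 4, width, dimnames = list(BASES, NULL)),
        pairProbs = list(), jointProb = numeric(0),
        fitMeta = list(training = 0L))
}

#' Log2 probability of windows under a model
#'
#' @param model a [MaxEntModel-class].
#' @param windows character vector of ACGT windows of the model's width.
#' @return numeric vector of log2 probabilities (NA for windows containing
#'   non-ACGT letters).
#' @export
logProb <- function(model, windows) {
    windows <- as.character(windows)
    out <- rep(NA_real_, length(windows))
    ok <- !is.na(windows) & !grepl("[^ACGT]", windows)
    if (!any(ok)) return(out)
    m <- windowMatrix(windows[ok], model@width)
    lp <- switch(model@order,
        order1 = {
            v <- 0
            for (p in seq_len(model@width))
                v <- v + log2(model@positionProbs[m[, p], p])
            v
        },
        adjacent2 = {
            ## P(x) = p12(x1,x2) * prod_{i>=2} p_{i,i+1}(xi,xi+1)/p_i(xi)
            v <- log2(vapply(seq_len(nrow(m)), function(r)
                model@pairProbs[[1L]][m[r, 1L], m[r, 2L]], numeric(1)))
            if (model@width > 2L) {
                for (i in seq(2L, model@width - 1L)) {
                    pij <- model@pairProbs[[i]]
                    rowm <- rowSums(pij)
                    v <- v + log2(vapply(seq_len(nrow(m)), function(r)
                        pij[m[r, i], m[r, i + 1L]], numeric(1))) -
                        log2(rowm[m[, i]])
                }
            }
            v
        },
        pairwise2 = log2(model@jointProb[seqToIndex(windows[ok], model@width)])
    )
    out[ok] <- lp
    out
}

#' Log-odds splice-site score in bits
#'
#' `log2(P_signal(window) / P_background(window))`.
#'
#' @param signal,background [MaxEntModel-class] objects of equal width.
#' @param windows character vector of windows.
#' @return numeric vector of scores in bits (NA where a window was
#'   unusable).
#' @export
maxentScore <- function(signal, background, windows) {
    if (signal@width != background@width)
        stop("signal and background models have different widths")
    if (length(windows) && any(!is.na(windows) &
                               nchar(windows) != signal@width))
        stop("window width does not match the model")
    logProb(signal, windows) - logProb(background, windows)
}

## constrained marginals of a fitted model, for validity checks/tests
modelMarginal <- function(model, positions) {
    if (model@order == "pairwise2") {
        idx <- (enumPosition(model@width, positions[1L]) - 1L) * 4L +
            enumPosition(model@width, positions[2L])
        matrix(as.vector(rowsum(model@jointProb, idx)), 4, 4, byrow = TRUE,
               dimnames = list(BASES, BASES))
    } else if (model@order == "adjacent2" && length(positions) == 2L &&
               positions[2L] == positions[1L] + 1L) {
        model@pairProbs[[positions[1L]]]
    } else {
        model@positionProbs[, positions[1L]]
    }
}

#' Relocate junctions uniformly at random (shuffle control)
#'
#' Each junction is moved to a uniformly random position on its own
#' contig, preserving span, strand and read count, within bounds that
#' allow full donor/acceptor window extraction. Junctions whose span does
#' not fit their contig are skipped with a warning.
#'
#' @param gr junction `GRanges`.
#' @param genome `DNAStringSet`.
#' @param seed integer seed; the shuffle is deterministic given it.
#' @return shuffled junction `GRanges`.
#' @export
shuffleJunctions <- function(gr, genome, seed) {
    lens <- Biostrings::width(genome)
    names(lens) <- names(genome)
    withr::with_seed(as.integer(seed), {
        keep <- logical(length(gr)); newStart <- integer(length(gr))
        for (i in seq_along(gr)) {
            chr <- as.character(seqnames(gr))[i]
            w <- width(gr)[i]
            lo <- 21L                      # room for 20-nt intronic + 3 exonic
            hi <- lens[[chr]] - w + 1L - 20L
            if (is.null(lens[[chr]]) || hi < lo) { keep[i] <- FALSE; next }
            keep[i] <- TRUE
            newStart[i] <- sample.int(hi - lo + 1L, 1L) + lo - 1L
        }
        if (any(!keep))
            warning(sum(!keep), " junction(s) skipped: span exceeds contig")
        out <- gr[keep]
        ranges(out) <- IRanges(newStart[keep], newStart[keep] +
                                   width(gr)[keep] - 1L)
        out
    })
}

#' Score junction classes and test their separation
#'
#' Scores each junction of the de novo, annotated and random classes
#' (donor and acceptor log-odds plus their mean, the consolidated score),
#' then runs an ordinary one-way ANOVA on the consolidated scores across
#' the three classes and reports whether the expected ordering
#' annotated > de novo > random holds for the class means.
#'
#' @param denovo,annotated,random junction `GRanges` per class.
#' @param genome `DNAStringSet`.
#' @param donorModel,acceptorModel signal [MaxEntModel-class] objects.
#' @param donorBg,acceptorBg background models.
#' @return list: `scores` (data.frame with class, donor/acceptor bits,
#'   consolidated), `classMeans`, `anova` (`F`, `p`), `orderingHolds`.
#' @export
scoreClasses <- function(denovo, annotated, random, genome,
                         donorModel, acceptorModel, donorBg, acceptorBg) {
    sets <- list(annotated = annotated, denovo = denovo, random = random)
    if (any(vapply(sets, length, integer(1)) < 2L))
        stop("each class needs at least two junctions")
    tabs <- lapply(names(sets), function(cl) {
        sc <- scoreJunctions(sets[[cl]], genome, donorModel, acceptorModel,
                             donorBg, acceptorBg)
        if (nrow(sc)) sc$class <- cl
        sc
    })
    scores <- do.call(rbind, tabs)
    scores <- scores[is.finite(scores$consolidated), , drop = FALSE]
    if (length(unique(scores$class)) < 3L)
        stop("a class lost all scoreable junctions")
    means <- tapply(scores$consolidated, scores$class, mean)
    av <- stats::oneway.test(consolidated ~ class, data = scores,
                             var.equal = TRUE)
    list(scores = scores,
         classMeans = means,
         anova = list(F = unname(av$statistic), p = av$p.value),
         orderingHolds = isTRUE(means[["annotated"]] > means[["denovo"]] &&
                                means[["denovo"]] > means[["random"]]))
}

#' Score junctions with donor/acceptor models
#'
#' Resolves unknown-strand junctions by scoring both orientations and
#' retaining the one with the higher consolidated score (`flagged = TRUE`).
#'
#' @param gr junction `GRanges`.
#' @param genome `DNAStringSet`.
#' @param donorModel,acceptorModel,donorBg,acceptorBg models.
#' @return data.frame: `key`, `orientation`, `donor`, `acceptor`,
#'   `consolidated` (bits), `flagged`.
#' @export
scoreJunctions <- function(gr, genome, donorModel, acceptorModel,
                           donorBg, acceptorBg) {
    ew <- extractWindows(gr, genome)
    w <- ew$windows
    if (!nrow(w))
        return(data.frame(key = character(), orientation = character(),
                          donor = numeric(), acceptor = numeric(),
                          consolidated = numeric(), flagged = logical(),
                          stringsAsFactors = FALSE))
    w$donorBits <- maxentScore(donorModel, donorBg, w$donor)
    w$acceptorBits <- maxentScore(acceptorModel, acceptorBg, w$acceptor)
    w$consolidated <- (w$donorBits + w$acceptorBits) / 2
    ## pick one orientation per junction: the higher consolidated score
    picked <- lapply(split(w, w$junction), function(d) {
        flagged <- nrow(d) > 1L
        d <- d[order(-ifelse(is.na(d$consolidated), -Inf, d$consolidated)), ,
               drop = FALSE]
        data.frame(key = d$key[1L], orientation = d$orientation[1L],
                   donor = d$donorBits[1L], acceptor = d$acceptorBits[1L],
                   consolidated = d$consolidated[1L], flagged = flagged,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, picked)
    rownames(out) <- NULL
    out
}
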