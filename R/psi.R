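#' Splicing index (delta-psi) of two isoform variants
#'
#' `delta_psi = variant1 / (variant1 + variant2)`. Undefined (NA) when
#' both quantities are zero.
#'
#' @param variant1,variant2 non-negative copy counts or read counts
#'   (vectorized).
#' @param percent return percent instead of a fraction.
#' @return numeric vector in `[0, 1]` (or `[0, 100]`).
#' @examples
#' deltaPsi(3, 1)   # 0.75
#' @export
deltaPsi <- function(variant1, variant2, percent = FALSE) {
    if (any(variant1 < 0, na.rm = TRUE) || any(variant2 < 0, na.rm = TRUE))
        stop("isoform quantities must be non-negative")
    tot <- variant1 + variant2
    out <- ifelse(tot == 0, NA_real_, variant1 / tot)
    if (any(is.na(out) & !is.na(tot)))
        warning("PSI undefined where both variants are zero")
    if (percent) out * 100 else out
}

#' PSI of a variant isoform
#'
#' Variant quantity over total (canonical + variant), e.g. progerin over
#' lamin A plus progerin.
#'
#' @param canonical,variant non-negative quantities (vectorized).
#' @param percent return percent instead of a fraction.
#' @return numeric vector.
#' @examples
#' psiVariant(1566, 2.8)  # ~0.001786
#' @export
psiVariant <- function(canonical, variant, percent = FALSE) {
    deltaPsi(variant, canonical, percent = percent)
}

#' Per-group PSI summary and nonparametric comparison
#'
#' The primary summary is the mean of per-sample PSIs (not the PSI of the
#' summed copies, which is reported separately as `pooled_psi`); groups
#' are compared with a two-sided Mann-Whitney U test.
#'
#' @param measurements data.frame with columns `sample_id`, `group`,
#'   `canonical_copies`, `variant_copies`.
#' @return list: `perSample` (input plus `psi_fraction`, `psi_percent`),
#'   `groups` (data.frame `group`, `n`, `mean_psi`, `sem_psi`,
#'   `pooled_psi`), `p` (Mann-Whitney, two groups only).
#' @export
psiGroupSummary <- function(measurements) {
    need <- c("sample_id", "group", "canonical_copies", "variant_copies")
    if (!all(need %in% names(measurements)))
        stop("measurements needs columns ", paste(need, collapse = ", "))
    m <- measurements
    m$psi_fraction <- psiVariant(m$canonical_copies, m$variant_copies)
    m$psi_percent <- m$psi_fraction * 100
    grp <- split(m, m$group)
    if (any(vapply(grp, nrow, integer(1)) < 3L))
        stop("each group needs at least 3 samples")
    groups <- do.call(rbind, lapply(names(grp), function(g) {
        d <- grp[[g]]
        psi <- d$psi_fraction[!is.na(d$psi_fraction)]
        data.frame(group = g, n = nrow(d), mean_psi = mean(psi),
                   sem_psi = stats::sd(psi) / sqrt(length(psi)),
                   pooled_psi = psiVariant(sum(d$canonical_copies),
                                           sum(d$variant_copies)),
                   stringsAsFactors = FALSE)
    }))
    p <- NA_real_
    if (length(grp) == 2L) {
        x <- grp[[1L]]$psi_fraction; y <- grp[[2L]]$psi_fraction
        p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }
    list(perSample = m, groups = groups, p = p)
}

#' Power simulation for a PSI shift
#'
#' Simulates two groups of `n` samples whose per-sample PSIs are Beta
#' distributed around `psiA` and `psiB` (concentration `conc`), converts
#' them to canonical/variant copy counts, and reports the fraction of
#' seeded replicates in which a two-sided Mann-Whitney U test reaches
#' `alpha`.
#'
#' @param psiA,psiB group mean PSI fractions.
#' @param n samples per group.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param conc Beta concentration (larger = less between-sample spread).
#' @param meanTotal mean total copies per sample.
#' @param alpha significance level.
#' @return list: `power` (fraction of replicates with p < alpha),
#'   `pValues`.
#' @export
psiPowerSim <- function(psiA = 0.04, psiB = 0.20, n = 8L, reps = 500L,
                        seed = 1L, conc = 50, meanTotal = 500,
                        alpha = 0.05) {
    withr::with_seed(as.integer(seed), {
        pv <- vapply(seq_len(reps), function(r) {
            drawGroup <- function(mu) {
                psi <- stats::rbeta(n, mu * conc, (1 - mu) * conc)
                tot <- stats::rpois(n, meanTotal)
                v <- stats::rbinom(n, tot, psi)
                cbind(canonical = tot - v, variant = v)
            }
            a <- drawGroup(psiA); b <- drawGroup(psiB)
            pa <- psiVariant(a[, 1L], a[, 2L])
            pb <- psiVariant(b[, 1L], b[, 2L])
            suppressWarnings(stats::wilcox.test(pa, pb)$p.value)
        }, numeric(1))
        list(power = mean(pv < alpha), pValues = pv)
    })
}
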