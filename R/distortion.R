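#' @include AllClasses.R
NULL

#' Per-site mean ancestry and genome-wide quantile envelope
#'
#' Computes, for each informative site, the mean malinche allele fraction
#' among non-missing calls (\code{sum(calls) / (2 * n)}), together with the
#' central 99\% envelope (0.5\% and 99.5\% empirical quantiles of the
#' per-site means genome wide) used to judge segregation distortion.
#' All-missing sites are excluded and reported.
#'
#' @param x an \linkS4class{AncestryCalls}.
#' @param group optional group label; only individuals with this
#'   \code{group} value enter the summary (e.g. comparing "lagging" versus
#'   "survivor" embryos).
#' @param envelope central probability mass of the envelope (default 0.99).
#' @return A \code{GRanges} with metadata columns \code{meanAncestry} and
#'   \code{n}; the envelope is in \code{metadata()$envelope} and excluded
#'   all-missing sites in \code{metadata()$excludedSites}.
#' @export
siteAncestrySummary <- function(x, group = NULL, envelope = 0.99) {
    stopifnot(is(x, "AncestryCalls"))
    m <- ancestryCalls(x)
    if (!is.null(group)) {
        keep <- !is.na(indivGroup(x)) & indivGroup(x) == group
        if (!any(keep)) stop("no individuals with group '", group, "'")
        m <- m[, keep, drop = FALSE]
    }
    n <- rowSums(!is.na(m))
    mean <- rowSums(m, na.rm = TRUE) / (2 * n)
    gr <- rowRanges(x)
    excluded <- which(n == 0)
    if (length(excluded)) {
        gr <- gr[-excluded]; mean <- mean[-excluded]; n <- n[-excluded]
    }
    mcols(gr)$meanAncestry <- mean
    mcols(gr)$n <- n
    a <- (1 - envelope) / 2
    metadata(gr) <- list(envelope = quantile(mean, c(a, 1 - a), names = FALSE),
                         excludedSites = excluded)
    gr
}

#' Flag regions of extreme segregation distortion
#'
#' Returns maximal runs of contiguous sites whose mean ancestry exceeds the
#' threshold, merging runs separated by fewer than \code{mergeGap}
#' intervening sites (distorted blocks span megabases, so short dips are
#' bridged). The conventional screening rule flags regions above 60\%
#' malinche ancestry in an F2 cross.
#'
#' @param summary the \code{GRanges} from [siteAncestrySummary()].
#' @param threshold ancestry threshold (default 0.60); runs require
#'   \code{meanAncestry > threshold}.
#' @param mergeGap merge runs separated by fewer than this many sites.
#' @return \code{GRanges} of flagged regions with metadata columns
#'   \code{peakMean}, \code{peakPos} and \code{nSites}.
#' @export
findDistortedRegions <- function(summary, threshold = 0.60, mergeGap = 10) {
    above <- mcols(summary)$meanAncestry > threshold
    chr <- as.character(seqnames(summary))
    regions <- list()
    for (ch in unique(chr)) {
        idx <- which(chr == ch)
        hits <- idx[above[idx]]
        if (!length(hits)) next
        # merge across gaps of fewer than mergeGap intervening sites
        brk <- c(0, which(diff(match(hits, idx)) > mergeGap), length(hits))
        for (k in seq_len(length(brk) - 1)) {
            run <- hits[(brk[k] + 1):brk[k + 1]]
            peak <- run[which.max(mcols(summary)$meanAncestry[run])]
            regions[[length(regions) + 1]] <- GRanges(
                ch, IRanges(start(summary)[run[1]], start(summary)[run[length(run)]]),
                peakMean = mcols(summary)$meanAncestry[peak],
                peakPos = start(summary)[peak], nSites = length(run))
        }
    }
    if (!length(regions))
        return(GRanges(peakMean = numeric(), peakPos = integer(),
                       nSites = integer()))
    out <- suppressWarnings(do.call(c, regions))
    GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(summary)
    sort(out)
}

#' Closed-form F2 survivor genotype frequencies
#'
#' The expected genotype frequencies among surviving F2 individuals at a
#' locus under mitonuclear viability selection with selection coefficient
#' \code{s} and dominance \code{h} on a matched mitochondrial background:
#' Mendelian 1:2:1 zygote proportions weighted by fitnesses \code{1 - s}
#' (penalized homozygote), \code{1 - h*s} (heterozygote) and 1, normalized
#' to sum to one. Because F1 individuals are uniformly heterozygous,
#' selection before the F2 generation does not change these frequencies,
#' so this closed form is the full two-generation recursion of the forward
#' simulator.
#'
#' @param s selection coefficient in \code{[0, 1]}.
#' @param h dominance coefficient in \code{[0, 1]}.
#' @return Named numeric: \code{homPenalized}, \code{het}, \code{homOther}.
#' @examples
#' expectedSurvivingFrequencies(0.91, 0.09)   # ~3% penalized homozygotes
#' expectedSurvivingFrequencies(1, 0)         # lethal recessive: 0, 2/3, 1/3
#' @export
expectedSurvivingFrequencies <- function(s, h) {
    stopifnot(s >= 0, s <= 1, h >= 0, h <= 1)
    w <- c(homPenalized = 0.25 * (1 - s),
           het = 0.5 * (1 - h * s),
           homOther = 0.25)
    w / sum(w)
}

#' Exact binomial deficit test
#'
#' One-sided exact lower-tail binomial test for a deficit of a genotype
#' class among survivors: \code{P(X <= k)} under \code{Binomial(n, p)}.
#' The expected count is reported with half-away-from-zero rounding, so an
#' expectation of 18.5 reports as 19.
#'
#' @param k observed count.
#' @param n number of trials.
#' @param p expected proportion (default 0.25, the Mendelian homozygote
#'   expectation).
#' @return List with \code{p.value}, \code{expected} and \code{observed}.
#' @examples
#' binomialDeficitTest(7, 74)  # p ~ 6.6e-4
#' @export
binomialDeficitTest <- function(k, n, p = 0.25) {
    stopifnot(k >= 0, k <= n, p > 0, p < 1)
    list(p.value = pbinom(k, n, p),
         expected = floor(n * p + 0.5),
         observed = k)
}
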