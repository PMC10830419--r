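#' @include AllClasses.R
NULL

# site index of the locus nearest (chrom, pos) in an AncestryCalls object
.siteAt <- function(x, chrom, pos) {
    gr <- rowRanges(x)
    on <- which(as.character(seqnames(gr)) == as.character(chrom))
    if (!length(on)) stop("no sites on chromosome ", chrom)
    on[which.min(abs(start(gr)[on] - pos))]
}

#' Two-locus genotype table among a survivor class
#'
#' Cross-tabulates hard calls at two loci (3x3: 0/1/2 malinche alleles at
#' each) among the individuals selected by \code{subset}, dropping
#' individuals missing at either locus.
#'
#' @param x an \linkS4class{AncestryCalls}.
#' @param chromA,posA,chromB,posB locus coordinates (nearest site used).
#' @param subset optional logical vector over individuals.
#' @return 3x3 integer matrix (rows: locus A genotype; columns: locus B).
#' @export
twoLocusTable <- function(x, chromA, posA, chromB, posB, subset = NULL) {
    a <- ancestryCalls(x)[.siteAt(x, chromA, posA), ]
    b <- ancestryCalls(x)[.siteAt(x, chromB, posB), ]
    if (!is.null(subset)) { a <- a[subset]; b <- b[subset] }
    keep <- !is.na(a) & !is.na(b)
    table(factor(a[keep], 0:2), factor(b[keep], 0:2))
}

#' Pearson chi-squared test of two-locus genotype independence
#'
#' Rows and columns with zero margin are dropped (with a warning) before
#' computing the Pearson statistic \code{sum((O - E)^2 / E)} on the reduced
#' table, with \code{df = (r - 1)(c - 1)}.
#'
#' @param table a genotype contingency table (matrix of counts).
#' @return List with \code{statistic}, \code{df}, \code{p.value} and the
#'   reduced \code{table}.
#' @export
chisqIndependence <- function(table) {
    tab <- as.matrix(table)
    stopifnot(all(tab >= 0), sum(tab) >= 1)
    drop <- list(rows = which(rowSums(tab) == 0), cols = which(colSums(tab) == 0))
    if (length(drop$rows) || length(drop$cols)) {
        warning("dropping ", length(drop$rows), " empty row(s) and ",
                length(drop$cols), " empty column(s)")
        tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    }
    if (nrow(tab) < 2 || ncol(tab) < 2)
        stop("fewer than 2 non-empty rows or columns; independence is undefined")
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- sum((tab - E)^2 / E)
    df <- as.integer((nrow(tab) - 1) * (ncol(tab) - 1))
    list(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE),
         table = tab)
}

#' Permutation test for heterozygote depletion among survivors
#'
#' Tests whether individuals heterozygous at locus B are under-represented
#' among a survivor class defined at locus A (by default, survivors of the
#' locus-A incompatibility: penalized-homozygous individuals on the
#' matching mitochondrial background). The null resamples, \code{nPerm}
#' times, the same number of individuals without replacement from the full
#' cohort's non-missing locus-B genotypes; the one-sided p-value is
#' \code{(1 + #\{null het fraction <= observed\}) / (nPerm + 1)}. If
#' \code{(s, h)} for locus B are supplied, the heterozygote frequency
#' expected under additive selection at that locus is reported as a
#' reference value (not tested).
#'
#' @param x an \linkS4class{AncestryCalls}.
#' @param chromA,posA,chromB,posB locus coordinates.
#' @param survivors logical vector over individuals defining the survivor
#'   class, or \code{NULL} for the default predicate
#'   (\code{calls[locusA] == 0} and malinche mitochondria).
#' @param nPerm number of permutations (>= 100).
#' @param alternative \code{"less"} (depletion, default) or
#'   \code{"two.sided"}.
#' @param shB optional \code{c(s, h)} for the additive-selection reference.
#' @param seed optional integer seed.
#' @return List with \code{p.value}, \code{observedHetFraction},
#'   \code{nullExpectation} (mean null het fraction), \code{nSurvivors}
#'   and \code{additiveExpectedHet} (or NA).
#' @export
hetDepletionPermutation <- function(x, chromA, posA, chromB, posB,
                                    survivors = NULL, nPerm = 10000,
                                    alternative = c("less", "two.sided"),
                                    shB = NULL, seed = NULL) {
    alternative <- match.arg(alternative)
    if (nPerm < 100) stop("nPerm must be at least 100")
    a <- ancestryCalls(x)[.siteAt(x, chromA, posA), ]
    b <- ancestryCalls(x)[.siteAt(x, chromB, posB), ]
    if (is.null(survivors))
        survivors <- !is.na(a) & a == 0L & mitoHaplotype(x) == "malinche"
    stopifnot(length(survivors) == ncol(x))
    bSurv <- b[survivors & !is.na(b)]
    if (!length(bSurv)) stop("no survivors with a locus-B call")
    pool <- b[!is.na(b)]
    k <- length(bSurv)
    obs <- mean(bSurv == 1L)
    null <- withSeed(seed, vapply(seq_len(nPerm), function(i)
        mean(sample(pool, k) == 1L), numeric(1)))
    p <- switch(alternative,
        less = (1 + sum(null <= obs)) / (nPerm + 1),
        two.sided = min(1, 2 * min((1 + sum(null <= obs)) / (nPerm + 1),
                                   (1 + sum(null >= obs)) / (nPerm + 1))))
    list(p.value = p, observedHetFraction = obs,
         nullExpectation = mean(null), nSurvivors = k,
         additiveExpectedHet = if (is.null(shB)) NA_real_ else
             unname(expectedSurvivingFrequencies(shB[1], shB[2])["het"]))
}
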