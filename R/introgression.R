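#' @include AllClasses.R
NULL

#' Pairwise nucleotide divergence with pairwise deletion
#'
#' Per-base divergence between two aligned sequences: mismatches divided by
#' the number of positions where both sequences carry an unambiguous base
#' (gaps and Ns are excluded pairwise).
#'
#' @param seqA,seqB aligned sequences (character or \code{DNAString}) of
#'   equal length.
#' @return Divergence per compared site, with attribute \code{nCompared}.
#' @examples
#' pairwiseDivergence("ACGTACGTAC", "ACGTTCGTAC")  # 0.1
#' @export
pairwiseDivergence <- function(seqA, seqB) {
    a <- strsplit(toupper(as.character(seqA)), "")[[1]]
    b <- strsplit(toupper(as.character(seqB)), "")[[1]]
    if (length(a) != length(b)) stop("sequences differ in length")
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!any(ok)) stop("no comparable sites after pairwise deletion")
    d <- sum(a[ok] != b[ok]) / sum(ok)
    attr(d, "nCompared") <- sum(ok)
    d
}

#' Simulation test of incomplete lineage sorting versus introgression
#'
#' Under a no-gene-flow scenario, the expected divergence between two
#' mitochondrial haplotypes separated for \code{T} generations on two
#' independent lineages is driven by \code{Poisson(2 * mu * T * L)}
#' substitutions over \code{L} sites. Each replicate draws a substitution
#' count and converts it to per-site divergence; the p-value is the
#' add-one-smoothed fraction of replicates with divergence at or below the
#' observed value. A small p indicates the observed divergence is too low
#' for lineage sorting alone, favouring introgression. No within-species
#' coalescent time is added, which is conservative for detecting a
#' divergence deficit.
#'
#' @param dObs observed per-site divergence (e.g. from
#'   [pairwiseDivergence()]).
#' @param T divergence time in generations.
#' @param mu substitution rate per site per generation; run once with the
#'   average and once with the minimum inter-species mitochondrial rate.
#' @param L sequence length in bp.
#' @param nSims number of replicates.
#' @param seed optional integer seed.
#' @return List with \code{p.value}, \code{simulated} (divergence
#'   distribution), \code{expectedDivergence} (\code{2 * mu * T}).
#' @export
ilsSimulation <- function(dObs, T, mu, L, nSims = 10000, seed = NULL) {
    stopifnot(dObs >= 0, T > 0, mu > 0, L > 0, nSims >= 1)
    sim <- withSeed(seed, rpois(nSims, 2 * mu * T * L) / L)
    list(p.value = (1 + sum(sim <= dObs)) / (nSims + 1),
         simulated = sim, expectedDivergence = 2 * mu * T)
}

#' Windowed minor-parent ancestry
#'
#' Mean minor-parent allele fraction in fixed half-open windows tiling each
#' chromosome. A site whose position equals a window boundary belongs to
#' the next window. Windows without sites are flagged (NA mean) and the
#' genome-wide mean is attached as metadata.
#'
#' @param x an \linkS4class{AncestryCalls}.
#' @param windowBp window size in bp (default 250000).
#' @param minorParent the minor-parent label: \code{"birchmanni"} counts
#'   \code{1 - calls/2}, \code{"malinche"} counts \code{calls/2}.
#' @return \code{GRanges} of windows with metadata columns \code{meanAncestry}
#'   and \code{nSites}; \code{metadata()$genomeWideMean} holds the
#'   genome-wide mean minor-parent ancestry.
#' @export
windowAncestry <- function(x, windowBp = 250000, minorParent = "birchmanni") {
    stopifnot(is(x, "AncestryCalls"), minorParent %in% .MITO_LEVELS)
    frac <- ancestryCalls(x) / 2
    if (minorParent == "birchmanni") frac <- 1 - frac
    siteMean <- rowMeans(frac, na.rm = TRUE)
    gr <- rowRanges(x)
    chr <- as.character(seqnames(gr))
    win <- floor(start(gr) / windowBp)
    out <- list()
    for (ch in unique(chr)) {
        idx <- which(chr == ch)
        for (w in 0:max(win[idx])) {
            sel <- idx[win[idx] == w]
            out[[length(out) + 1]] <- GRanges(
                ch, IRanges(w * windowBp, (w + 1) * windowBp - 1),
                meanAncestry = if (length(sel)) mean(siteMean[sel]) else NA_real_,
                nSites = length(sel))
        }
    }
    res <- suppressWarnings(do.call(c, out))
    GenomeInfoDb::seqlevels(res) <- GenomeInfoDb::seqlevels(gr)
    res <- sort(res)
    metadata(res) <- list(genomeWideMean = mean(siteMean, na.rm = TRUE),
                          windowBp = windowBp, minorParent = minorParent)
    res
}

#' Permutation test for replicated ancestry depletion at focal loci
#'
#' Tests whether minor-parent ancestry at the focal loci is lower than
#' expected by chance simultaneously in every population. Each null
#' replicate draws one random genomic window per focal locus -- the same
#' window applied across all populations, preserving the cross-population
#' ancestry correlation -- and succeeds when the drawn windows' ancestry is
#' at or below the observed focal values in every population for every
#' locus. Drawing windows independently per population (anti-conservative)
#' is available via \code{sharedDraw = FALSE}.
#'
#' @param populations list of windowed-ancestry \code{GRanges} from
#'   [windowAncestry()] on a common window grid.
#' @param focalLoci \code{data.frame} with columns \code{chrom} and
#'   \code{pos} (one row per focal locus).
#' @param nPerm number of null draws.
#' @param sharedDraw draw one window position shared across populations
#'   (default) or independent draws per population.
#' @param seed optional integer seed.
#' @return List with \code{p.value}, \code{observed} (loci x populations
#'   matrix of focal-window ancestry) and \code{nWindows}.
#' @export
replicatedDepletionTest <- function(populations, focalLoci, nPerm = 10000,
                                    sharedDraw = TRUE, seed = NULL) {
    stopifnot(length(populations) >= 1, nrow(focalLoci) >= 1)
    keys <- function(w) paste(as.character(seqnames(w)), start(w))
    common <- Reduce(intersect, lapply(populations, function(w)
        keys(w)[!is.na(mcols(w)$meanAncestry)]))
    if (!length(common)) stop("no windows shared across populations")
    anc <- vapply(populations, function(w)
        mcols(w)$meanAncestry[match(common, keys(w))],
        numeric(length(common)))
    anc <- matrix(anc, nrow = length(common))
    w1 <- populations[[1]]
    obsIdx <- vapply(seq_len(nrow(focalLoci)), function(i) {
        hit <- which(as.character(seqnames(w1)) == as.character(focalLoci$chrom[i]) &
                     start(w1) <= focalLoci$pos[i] & end(w1) >= focalLoci$pos[i])
        if (!length(hit)) stop("focal locus ", i, " not covered by the windows")
        j <- match(keys(w1)[hit[1]], common)
        if (is.na(j)) stop("focal window empty in at least one population (locus ", i, ")")
        j
    }, integer(1))
    observed <- anc[obsIdx, , drop = FALSE]
    nW <- length(common)
    nL <- nrow(focalLoci)
    nP <- ncol(anc)
    successes <- withSeed(seed, {
        hits <- 0L
        for (b in seq_len(nPerm)) {
            ok <- TRUE
            for (l in seq_len(nL)) {
                if (sharedDraw) {
                    j <- sample.int(nW, 1)
                    if (any(anc[j, ] > observed[l, ])) { ok <- FALSE; break }
                } else {
                    for (p in seq_len(nP)) {
                        j <- sample.int(nW, 1)
                        if (anc[j, p] > observed[l, p]) { ok <- FALSE; break }
                    }
                    if (!ok) break
                }
            }
            if (ok) hits <- hits + 1L
        }
        hits
    })
    dimnames(observed) <- list(paste0(focalLoci$chrom, ":", focalLoci$pos),
                               names(populations))
    list(p.value = (1 + successes) / (nPerm + 1), observed = observed,
         nWindows = nW)
}
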