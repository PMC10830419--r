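#' @include AllClasses.R
NULL

#' Genome scan result for nuclear-ancestry x mitochondrial-haplotype association
#'
#' Per-site partial correlations, the simulated genome-wide significance
#' threshold (once set), and called peaks.
#'
#' @slot stats \code{GRanges} with metadata columns \code{r} (partial
#'   correlation) and \code{n} (individuals used); sites failing the
#'   preconditions carry \code{NA}.
#' @slot threshold genome-wide threshold on \code{|r|} (NA until set).
#' @slot fpr the false-positive rate the threshold controls.
#' @slot peaks \code{GRanges} of intervals above threshold with apex site.
#' @exportClass AncestryScan
setClass("AncestryScan",
    representation(stats = "GRanges", threshold = "numeric",
                   fpr = "numeric", peaks = "GRanges"))

setValidity("AncestryScan", function(object) {
    r <- mcols(object@stats)$r
    if (!is.null(r) && any(abs(r) > 1 + 1e-8, na.rm = TRUE))
        return("|r| must not exceed 1")
    TRUE
})

setMethod("show", "AncestryScan", function(object) {
    cat("AncestryScan:", length(object@stats), "sites; max |r| =",
        sprintf("%.3f", max(abs(mcols(object@stats)$r), na.rm = TRUE)), "\n")
    if (!is.na(object@threshold))
        cat(sprintf("  threshold |r| >= %.3f (%.0f%% genome-wide FPR); %d peak(s)\n",
                    object@threshold, 100 * object@fpr, length(object@peaks)))
})

#' @describeIn partialCorrelationScan per-site statistics accessor.
#' @param scan an \code{AncestryScan}.
#' @export
scanStats <- function(scan) scan@stats

#' @describeIn partialCorrelationScan called-peaks accessor.
#' @export
scanPeaks <- function(scan) scan@peaks

#' @describeIn partialCorrelationScan threshold accessor.
#' @export
scanThreshold <- function(scan) scan@threshold

#' Partial-correlation admixture scan for mitonuclear association
#'
#' For each informative site, residualizes both the site's malinche allele
#' fraction (\code{calls/2}) and the malinche-mitochondria indicator on the
#' per-individual genome-wide mean ancestry, and reports the Pearson
#' correlation of the residuals. The genome-wide covariate excludes the
#' focal site's chromosome (leave-one-chromosome-out) so that a strong peak
#' cannot dilute its own signal through the covariate. Sites with fewer
#' than \code{minN} complete cases, or no ancestry variation, are flagged
#' with \code{NA} rather than scored.
#'
#' @param x an \linkS4class{AncestryCalls} whose individuals vary in
#'   mitochondrial haplotype.
#' @param covariate optional per-individual covariate overriding the
#'   genome-wide ancestry (disables leave-one-chromosome-out).
#' @param minN minimum complete cases per site (default 3).
#' @return An \linkS4class{AncestryScan} (threshold unset).
#' @export
partialCorrelationScan <- function(x, covariate = NULL, minN = 3) {
    stopifnot(is(x, "AncestryCalls"))
    y <- as.numeric(mitoHaplotype(x) == "malinche")
    if (length(unique(y)) < 2)
        stop("population fixed for one mitochondrial haplotype")
    calls <- ancestryCalls(x)
    gr <- rowRanges(x)
    chr <- as.character(seqnames(gr))
    r <- n <- rep(NA_real_, nrow(calls))
    for (ch in unique(chr)) {
        idx <- which(chr == ch)
        z <- if (is.null(covariate)) genomeWideAncestry(x, excludeChrom = ch)
             else as.numeric(covariate)
        # single-chromosome data: nothing left after leave-one-out
        if (all(!is.finite(z))) z <- genomeWideAncestry(x)
        X <- calls[idx, , drop = FALSE] / 2
        M <- !is.na(X)
        X0 <- X; X0[!M] <- 0
        nS <- rowSums(M)
        Sx <- rowSums(X0);          Sx2 <- rowSums(X0^2)
        Sy <- as.vector(M %*% y);   Sy2 <- as.vector(M %*% y^2)
        Sz <- as.vector(M %*% z);   Sz2 <- as.vector(M %*% z^2)
        Sxy <- as.vector(X0 %*% y); Sxz <- as.vector(X0 %*% z)
        Syz <- as.vector(M %*% (y * z))
        Vx <- Sx2 - Sx^2 / nS; Vy <- Sy2 - Sy^2 / nS; Vz <- Sz2 - Sz^2 / nS
        Cxy <- Sxy - Sx * Sy / nS
        Cxz <- Sxz - Sx * Sz / nS
        Cyz <- Syz - Sy * Sz / nS
        eps <- 1e-12
        rxy <- ifelse(Vx > eps & Vy > eps, Cxy / sqrt(pmax(Vx * Vy, eps)), NA)
        rxz <- ifelse(Vx > eps & Vz > eps, Cxz / sqrt(pmax(Vx * Vz, eps)), 0)
        ryz <- ifelse(Vy > eps & Vz > eps, Cyz / sqrt(pmax(Vy * Vz, eps)), 0)
        den <- (1 - rxz^2) * (1 - ryz^2)
        rp <- ifelse(den > eps, (rxy - rxz * ryz) / sqrt(den), NA)
        rp[nS < minN] <- NA
        rp <- pmin(pmax(rp, -1), 1)
        r[idx] <- rp
        n[idx] <- nS
    }
    mcols(gr)$r <- r
    mcols(gr)$n <- n
    new("AncestryScan", stats = gr, threshold = NA_real_, fpr = NA_real_,
        peaks = GRanges())
}

#' Simulated genome-wide significance threshold for the admixture scan
#'
#' Simulates matched null datasets (hybrid-swarm forward simulations with
#' no incompatibility loci, matching the template's individual count, site
#' grid, mean ancestry and mitochondrial frequency), scans each, and
#' returns the \code{(1 - fpr)} quantile of the per-replicate maximum
#' \code{|r|}. Forward simulation is used rather than permuting
#' mitochondrial labels because permutation would destroy the
#' ancestry-mitochondria covariance the scan covariate is designed to
#' absorb; a permutation mode is provided for comparison.
#'
#' @param template an \linkS4class{AncestryCalls} providing the observed
#'   design (individuals, sites, ancestry and mitochondrial frequencies).
#' @param fpr genome-wide false-positive rate (default 0.10).
#' @param nReps number of null replicates (>= 50).
#' @param generations swarm generations for the null model.
#' @param migration per-generation migrant fraction for the null swarm
#'   (match the value used for the data under test).
#' @param method \code{"swarm"} (default) or \code{"permutation"}.
#' @param map optional \linkS4class{GeneticMap}; by default reconstructed
#'   from the template's site grid at 1 Morgan per chromosome.
#' @param seed optional integer seed.
#' @return Numeric threshold with attributes \code{maxAbsR} (the null
#'   maxima) and \code{fpr}.
#' @export
nullThreshold <- function(template, fpr = 0.10, nReps = 100,
                          generations = 100, migration = 0,
                          method = c("swarm", "permutation"),
                          map = NULL, seed = NULL) {
    method <- match.arg(method)
    stopifnot(is(template, "AncestryCalls"), nReps >= 50, fpr > 0, fpr <= 1)
    N <- ncol(template)
    mhat <- mean(genomeWideAncestry(template))
    mitoHat <- mean(mitoHaplotype(template) == "malinche")
    if (is.null(map)) map <- .mapFromSites(rowRanges(template))
    maxima <- withSeed(seed, vapply(seq_len(nReps), function(i) {
        scan <- if (method == "swarm") {
            null <- simulateSwarm(N, generations = generations, m = mhat,
                                  mitoFreq = mitoHat, map = map,
                                  migration = migration,
                                  requirePolymorphicMito = TRUE)
            partialCorrelationScan(null)
        } else {
            perm <- template
            colData(perm)$mito <- sample(colData(template)$mito)
            partialCorrelationScan(perm)
        }
        max(abs(mcols(scanStats(scan))$r), na.rm = TRUE)
    }, numeric(1)))
    out <- quantile(maxima, 1 - fpr, names = FALSE)
    attr(out, "maxAbsR") <- maxima
    attr(out, "fpr") <- fpr
    out
}

# Reconstruct a GeneticMap (1 Morgan per chromosome) from an observed grid.
.mapFromSites <- function(sites, morgans = 1) {
    chroms <- GenomeInfoDb::seqlevels(sites)
    pos <- split(start(sites), as.character(seqnames(sites)))[chroms]
    bp <- vapply(pos, function(p)
        max(p) + if (length(p) > 1) stats::median(diff(p)) else 1000, numeric(1))
    new("GeneticMap", sites = sites,
        morgans = setNames(rep_len(morgans, length(chroms)), chroms),
        bp = setNames(bp, chroms))
}

#' Call peaks above the genome-wide threshold
#'
#' Maximal runs of contiguous sites with \code{|r| >= threshold}; each
#' peak's interval spans the first to last site of the run and its apex is
#' the maximum-\code{|r|} site.
#'
#' @param scan an \linkS4class{AncestryScan}.
#' @param threshold the genome-wide threshold (e.g. from
#'   [nullThreshold()]).
#' @param fpr optional FPR annotation carried with the threshold.
#' @return The scan with \code{scanPeaks()} filled in: a \code{GRanges}
#'   with metadata columns \code{apexPos}, \code{apexR} and \code{nSites}.
#' @export
callPeaks <- function(scan, threshold, fpr = NA_real_) {
    stopifnot(is(scan, "AncestryScan"), is.finite(threshold))
    gr <- scan@stats
    r <- mcols(gr)$r
    above <- !is.na(r) & abs(r) >= threshold
    chr <- as.character(seqnames(gr))
    peaks <- list()
    for (ch in unique(chr)) {
        idx <- which(chr == ch)
        hits <- idx[above[idx]]
        if (!length(hits)) next
        brk <- c(0, which(diff(match(hits, idx)) > 1), length(hits))
        for (k in seq_len(length(brk) - 1)) {
            run <- hits[(brk[k] + 1):brk[k + 1]]
            apex <- run[which.max(abs(r[run]))]
            peaks[[length(peaks) + 1]] <- GRanges(
                ch, IRanges(start(gr)[run[1]], start(gr)[run[length(run)]]),
                apexPos = start(gr)[apex], apexR = r[apex],
                nSites = length(run))
        }
    }
    pk <- if (length(peaks)) {
        out <- suppressWarnings(do.call(c, peaks))
        GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(gr)
        sort(out)
    } else GRanges(apexPos = integer(), apexR = numeric(), nSites = integer())
    initialize(scan, threshold = as.numeric(threshold),
               fpr = if (is.na(fpr)) attr(threshold, "fpr") %||% NA_real_ else fpr,
               peaks = pk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
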