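#' @include AllClasses.R
NULL

# TSV dialect shared by the readers/writers:
#   main file:    chrom <tab> pos <tab> one column per individual (0/1/2/NA)
#   sidecar file: individual <tab> mito [<tab> group]
# Posterior tables use three columns per individual, <id>.p0/<id>.p1/<id>.p2.

.defaultSidecar <- function(path) paste0(path, ".indiv")

.readSidecar <- function(path) {
    meta <- read.table(path, header = TRUE, sep = "\t",
                       colClasses = "character", check.names = FALSE)
    if (!all(c("individual", "mito") %in% colnames(meta)))
        stop("sidecar '", path, "' needs columns 'individual' and 'mito'")
    if (anyDuplicated(meta$individual))
        stop("duplicated individual id '",
             meta$individual[duplicated(meta$individual)][1], "' in sidecar")
    bad <- !(meta$mito %in% .MITO_LEVELS)
    if (any(bad))
        stop("unknown mito label '", meta$mito[bad][1], "' for individual '",
             meta$individual[bad][1], "'")
    meta
}

.sitesFromColumns <- function(chrom, pos, path) {
    chrom <- as.character(chrom)
    ok <- !is.na(pos)
    bad <- vapply(split(pos, chrom)[unique(chrom)],
                  function(p) is.unsorted(p, strictly = TRUE), logical(1))
    if (any(bad))
        stop("non-increasing positions on chromosome ", names(bad)[bad][1],
             " in '", path, "'")
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    GenomeInfoDb::seqlevels(gr) <- unique(chrom)
    gr
}

#' Read an ancestry hard-call matrix
#'
#' Reads the tab-separated ancestry dialect: a header row of individual ids
#' after the \code{chrom} and \code{pos} columns, one row per
#' ancestry-informative site, cells in \code{{0, 1, 2, NA}} counting
#' malinche-derived alleles; plus a sidecar TSV mapping each individual to
#' its mitochondrial haplotype (and optional group). Cells that parse to
#' anything else become missing and are tallied in the load report attached
#' as \code{metadata(x)$loadReport}.
#'
#' @param path path to the ancestry TSV.
#' @param sidecar path to the individual metadata TSV (default
#'   \code{paste0(path, ".indiv")}).
#' @return An \linkS4class{AncestryCalls}.
#' @seealso [writeAncestryMatrix()]
#' @export
readAncestryMatrix <- function(path, sidecar = .defaultSidecar(path)) {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", na.strings = NULL)
    if (ncol(tab) < 3L || !identical(colnames(tab)[1:2], c("chrom", "pos")))
        stop("'", path, "' must start with columns chrom, pos")
    ids <- colnames(tab)[-(1:2)]
    if (anyDuplicated(ids))
        stop("duplicated individual id '", ids[duplicated(ids)][1], "' in '", path, "'")
    sites <- .sitesFromColumns(tab$chrom, as.integer(tab$pos), path)
    raw <- as.matrix(tab[, -(1:2), drop = FALSE])
    calls <- suppressWarnings(matrix(as.integer(raw), nrow(raw), ncol(raw),
                                     dimnames = list(NULL, ids)))
    calls[!(calls %in% c(0L, 1L, 2L))] <- NA_integer_
    nNA <- sum(raw == "NA")
    nUnparseable <- sum(is.na(calls)) - nNA
    meta <- .readSidecar(sidecar)
    miss <- setdiff(ids, meta$individual)
    if (length(miss))
        stop("no mito haplotype for individual '", miss[1], "'")
    meta <- meta[match(ids, meta$individual), ]
    x <- AncestryCalls(calls, sites, mito = meta$mito,
                       group = if ("group" %in% colnames(meta)) {
                           g <- meta$group; g[g == "NA"] <- NA; g
                       } else NULL)
    metadata(x)$loadReport <- list(nMissing = sum(is.na(calls)),
                                   nUnparseable = nUnparseable)
    x
}

#' Write an ancestry hard-call matrix
#'
#' Writes the TSV dialect read by [readAncestryMatrix()]; the round trip
#' reproduces the object exactly. Missing calls are written as \code{"NA"}.
#'
#' @param x an \linkS4class{AncestryCalls}.
#' @param path output path for the ancestry TSV.
#' @param sidecar output path for the individual metadata TSV.
#' @return \code{path}, invisibly.
#' @export
writeAncestryMatrix <- function(x, path, sidecar = .defaultSidecar(path)) {
    stopifnot(is(x, "AncestryCalls"))
    if (ncol(x) == 0L) stop("empty individual list")
    rr <- rowRanges(x)
    out <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                      ancestryCalls(x), check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    g <- indivGroup(x)
    meta <- data.frame(individual = colnames(x), mito = mitoHaplotype(x),
                       group = ifelse(is.na(g), "NA", g))
    write.table(meta, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an ancestry-posterior table
#'
#' Expects columns \code{chrom}, \code{pos}, then three columns per
#' individual named \code{<id>.p0}, \code{<id>.p1}, \code{<id>.p2}.
#'
#' @inheritParams readAncestryMatrix
#' @return An \linkS4class{AncestryPosteriors}.
#' @export
readPosteriorMatrix <- function(path, sidecar = .defaultSidecar(path)) {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    if (!identical(colnames(tab)[1:2], c("chrom", "pos")))
        stop("'", path, "' must start with columns chrom, pos")
    pcols <- colnames(tab)[-(1:2)]
    ids <- unique(sub("\\.p[012]$", "", pcols))
    need <- as.vector(t(outer(ids, c(".p0", ".p1", ".p2"), paste0)))
    if (!all(need %in% pcols))
        stop("each individual needs three posterior columns <id>.p0/.p1/.p2")
    sites <- .sitesFromColumns(tab$chrom, as.integer(tab$pos), path)
    grab <- function(suf) {
        m <- as.matrix(tab[, paste0(ids, suf), drop = FALSE])
        colnames(m) <- ids
        m
    }
    meta <- .readSidecar(sidecar)
    meta <- meta[match(ids, meta$individual), ]
    if (anyNA(meta$individual))
        stop("no mito haplotype for individual '",
             ids[is.na(meta$individual)][1], "'")
    AncestryPosteriors(grab(".p0"), grab(".p1"), grab(".p2"), sites, meta$mito)
}

#' Convert ancestry posteriors to hard calls
#'
#' The standard post-processing of HMM local-ancestry output: a cell becomes
#' the argmax ancestry state when the maximum posterior reaches the
#' threshold (inclusive), and missing otherwise. Ties in the argmax are
#' declared missing. The default threshold of 0.9 is the conventional
#' hard-call cutoff for this class of pipelines.
#'
#' @param post an \linkS4class{AncestryPosteriors}.
#' @param threshold posterior probability cutoff in \code{(1/3, 1]}.
#' @return An \linkS4class{AncestryCalls}.
#' @examples
#' # a (0.95, 0.04, 0.01) triple calls state 0; (0.5, 0.4, 0.1) is missing
#' @export
hardCallsFromPosteriors <- function(post, threshold = 0.9) {
    stopifnot(is(post, "AncestryPosteriors"),
              threshold > 1/3, threshold <= 1)
    validObject(post)
    p0 <- assay(post, "p0"); p1 <- assay(post, "p1"); p2 <- assay(post, "p2")
    pmaxv <- pmax(p0, p1, p2)
    call <- matrix(NA_integer_, nrow(p0), ncol(p0),
                   dimnames = dimnames(p0))
    call[p0 == pmaxv] <- 0L
    call[p1 == pmaxv] <- 1L
    call[p2 == pmaxv] <- 2L
    ties <- (p0 == pmaxv) + (p1 == pmaxv) + (p2 == pmaxv) > 1L
    call[ties | pmaxv < threshold] <- NA_integer_
    AncestryCalls(call, rowRanges(post), mito = colData(post)$mito)
}
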