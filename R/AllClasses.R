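#' @include mitoscan-package.R
NULL

# ---- GeneticMap -------------------------------------------------------------

#' Genetic map of ancestry-informative sites
#'
#' Holds the informative-site grid (as a \code{GRanges} of width-1 positions)
#' together with per-chromosome genetic lengths in Morgans and physical
#' lengths in base pairs. Positions are 1-based; the declared chromosome
#' order is the \code{seqlevels} of the site ranges.
#'
#' @slot sites \code{GRanges} of width-1 informative sites, sorted.
#' @slot morgans named numeric, genetic length of each chromosome (Morgans).
#' @slot bp named numeric, physical length of each chromosome (bp).
#' @exportClass GeneticMap
setClass("GeneticMap",
    representation(sites = "GRanges", morgans = "numeric", bp = "numeric"))

setValidity("GeneticMap", function(object) {
    msg <- NULL
    chroms <- GenomeInfoDb::seqlevels(object@sites)
    if (!all(chroms %in% names(object@morgans)) ||
        !all(chroms %in% names(object@bp)))
        msg <- c(msg, "every chromosome needs a Morgan and a bp length")
    if (any(object@morgans <= 0) || any(object@bp <= 0))
        msg <- c(msg, "chromosome lengths must be positive")
    pos <- split(GenomicRanges::start(object@sites),
                 as.character(GenomicRanges::seqnames(object@sites)))
    if (any(vapply(pos, function(p) is.unsorted(p, strictly = TRUE), logical(1))))
        msg <- c(msg, "site positions must be strictly increasing within chromosomes")
    if (is.null(msg)) TRUE else msg
})

#' Construct a genetic map
#'
#' The default grid emulates the study design at reduced resolution: 24
#' chromosomes of 25 Mb and 1 Morgan each, with 200 evenly spaced
#' ancestry-informative sites per chromosome (a scaled-down stand-in for the
#' roughly one informative site per kilobase available in real data).
#'
#' @param nChrom number of chromosomes.
#' @param sitesPerChrom informative sites per chromosome.
#' @param morgans genetic length per chromosome (recycled).
#' @param chromBp physical length per chromosome in bp (recycled).
#' @return A \linkS4class{GeneticMap}.
#' @examples
#' map <- geneticMap(nChrom = 2, sitesPerChrom = 10)
#' @export
geneticMap <- function(nChrom = 24, sitesPerChrom = 200, morgans = 1,
                       chromBp = 25e6) {
    stopifnot(nChrom >= 1, sitesPerChrom >= 1)
    chroms <- as.character(seq_len(nChrom))
    morgans <- setNames(rep_len(morgans, nChrom), chroms)
    bp <- setNames(rep_len(chromBp, nChrom), chroms)
    pos <- lapply(chroms, function(c)
        as.integer(round((seq_len(sitesPerChrom) - 0.5) * bp[[c]] / sitesPerChrom)))
    gr <- GRanges(rep(chroms, lengths(pos)),
                  IRanges(unlist(pos), width = 1L))
    GenomeInfoDb::seqlevels(gr) <- chroms
    new("GeneticMap", sites = gr, morgans = morgans, bp = bp)
}

#' @describeIn geneticMap site positions as a \code{GRanges}.
#' @param x,object a \code{GeneticMap}.
#' @export
mapSites <- function(x) x@sites

#' @describeIn geneticMap per-chromosome genetic lengths (Morgans).
#' @export
mapMorgans <- function(x) x@morgans

setMethod("show", "GeneticMap", function(object) {
    cat("GeneticMap:", length(GenomeInfoDb::seqlevels(object@sites)),
        "chromosomes,", length(object@sites), "informative sites,",
        sum(object@morgans), "Morgans total\n")
})

# genetic position (Morgans from chromosome start) of each site, plus the
# flattening used by the C++ simulators: 0-based chromosome start offsets.
.mapFlat <- function(map) {
    chroms <- GenomeInfoDb::seqlevels(map@sites)
    chr <- as.character(GenomicRanges::seqnames(map@sites))
    pos <- GenomicRanges::start(map@sites)
    gpos <- map@morgans[chr] * pos / map@bp[chr]
    counts <- vapply(chroms, function(c) sum(chr == c), integer(1))
    list(chrStart = as.integer(cumsum(c(0L, counts))),
         gpos = as.numeric(gpos),
         morgans = as.numeric(map@morgans[chroms]))
}

# ---- IncompatibilityModel ---------------------------------------------------

#' Mitonuclear incompatibility fitness model
#'
#' One or more nuclear loci, each with a selection coefficient \code{s} and a
#' dominance coefficient \code{h}, a mitochondrial partner haplotype, and the
#' parental ancestry whose homozygote is penalized. Zygote viability is
#' multiplicative across loci: when an individual's mitochondrial haplotype
#' matches a locus's partner, fitness is multiplied by \code{1 - s} for the
#' penalized homozygote and \code{1 - h*s} for the heterozygote. An optional
#' pairwise epistatic term multiplies in \code{1 - e} when locus A is
#' penalized-homozygous and locus B carries at least one penalized allele.
#'
#' @slot loci \code{DataFrame} with columns \code{chrom}, \code{pos},
#'   \code{s}, \code{h}, \code{mitoPartner}, \code{penalizedAncestry}.
#' @slot epistasis \code{list} with elements \code{locusA}, \code{locusB}
#'   (row indices into \code{loci}), \code{mitoPartner} and \code{e}, or an
#'   empty list for no epistasis.
#' @exportClass IncompatibilityModel
setClass("IncompatibilityModel",
    representation(loci = "DataFrame", epistasis = "list"))

setValidity("IncompatibilityModel", function(object) {
    msg <- NULL
    l <- object@loci
    need <- c("chrom", "pos", "s", "h", "mitoPartner", "penalizedAncestry")
    if (!all(need %in% colnames(l)))
        return(paste("loci must have columns", paste(need, collapse = ", ")))
    if (nrow(l)) {
        if (any(l$s < 0 | l$s > 1) || any(l$h < 0 | l$h > 1))
            msg <- c(msg, "s and h must lie in [0, 1]")
        if (!all(l$mitoPartner %in% .MITO_LEVELS) ||
            !all(l$penalizedAncestry %in% .MITO_LEVELS))
            msg <- c(msg, "mitoPartner and penalizedAncestry must be 'malinche' or 'birchmanni'")
    }
    e <- object@epistasis
    if (length(e)) {
        if (!all(c("locusA", "locusB", "mitoPartner", "e") %in% names(e)))
            msg <- c(msg, "epistasis needs locusA, locusB, mitoPartner, e")
        else if (e$e < 0 || e$e > 1)
            msg <- c(msg, "epistatic penalty e must lie in [0, 1]")
        else if (e$locusA > nrow(l) || e$locusB > nrow(l))
            msg <- c(msg, "epistasis indices exceed the locus table")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an incompatibility model
#'
#' @param chrom,pos chromosome labels and 1-based positions of the loci.
#' @param s,h selection and dominance coefficients in \code{[0, 1]}
#'   (recycled across loci).
#' @param mitoPartner mitochondrial haplotype the locus interacts with.
#' @param penalizedAncestry parental ancestry whose homozygote is selected
#'   against (defaults to the classic direction: homozygous birchmanni
#'   ancestry on a malinche mitochondrial background).
#' @param epistasis optional list \code{list(locusA=, locusB=, mitoPartner=,
#'   e=)} adding a multiplicative penalty \code{1 - e}.
#' @return An \linkS4class{IncompatibilityModel}.
#' @examples
#' m <- incompatibilityModel(chrom = "13", pos = 12.5e6, s = 0.996, h = 0.12)
#' @export
incompatibilityModel <- function(chrom = character(), pos = integer(),
                                 s = numeric(), h = numeric(),
                                 mitoPartner = "malinche",
                                 penalizedAncestry = "birchmanni",
                                 epistasis = list()) {
    n <- length(chrom)
    loci <- DataFrame(chrom = as.character(chrom), pos = as.integer(pos),
                      s = rep_len(as.numeric(s), n),
                      h = rep_len(as.numeric(h), n),
                      mitoPartner = rep_len(mitoPartner, n),
                      penalizedAncestry = rep_len(penalizedAncestry, n))
    new("IncompatibilityModel", loci = loci, epistasis = epistasis)
}

#' @describeIn incompatibilityModel locus table accessor.
#' @param x an \code{IncompatibilityModel}.
#' @export
modelLoci <- function(x) x@loci

setMethod("show", "IncompatibilityModel", function(object) {
    cat("IncompatibilityModel:", nrow(object@loci), "locus/loci",
        if (length(object@epistasis)) "+ epistasis" else "", "\n")
    if (nrow(object@loci)) show(object@loci)
})

# Resolve model loci against a map/site grid; returns 0-based site indices
# and integer codings for the C++ layer (mito: 1 = malinche, 0 = birchmanni;
# penalized homozygote call: 2 if malinche ancestry is penalized else 0).
.modelFlat <- function(model, sites) {
    l <- model@loci
    if (nrow(l) == 0L)
        return(list(site = integer(), s = numeric(), h = numeric(),
                    mito = integer(), penHom = integer(),
                    epiA = -1L, epiB = -1L, epiMito = -1L, epiE = 0))
    chr <- as.character(GenomicRanges::seqnames(sites))
    pos <- GenomicRanges::start(sites)
    idx <- vapply(seq_len(nrow(l)), function(i) {
        on <- which(chr == l$chrom[i])
        if (!length(on)) stop("model locus on chromosome ", l$chrom[i],
                              " absent from the site map")
        on[which.min(abs(pos[on] - l$pos[i]))]
    }, integer(1))
    e <- model@epistasis
    list(site = idx - 1L, s = l$s, h = l$h,
         mito = ifelse(l$mitoPartner == "malinche", 1L, 0L),
         penHom = ifelse(l$penalizedAncestry == "malinche", 2L, 0L),
         epiA = if (length(e)) as.integer(e$locusA - 1L) else -1L,
         epiB = if (length(e)) as.integer(e$locusB - 1L) else -1L,
         epiMito = if (length(e)) ifelse(e$mitoPartner == "malinche", 1L, 0L) else -1L,
         epiE = if (length(e)) e$e else 0)
}

# ---- AncestryCalls ----------------------------------------------------------

#' Ancestry hard-call matrix with mitochondrial haplotype labels
#'
#' A \code{RangedSummarizedExperiment} whose single assay \code{"calls"}
#' counts malinche-derived alleles (0 = homozygous birchmanni, 1 =
#' heterozygous, 2 = homozygous malinche, \code{NA} = missing) at each
#' informative site (rows) for each individual (columns). \code{colData}
#' carries the per-individual mitochondrial haplotype (\code{mito}, either
#' \code{"malinche"} or \code{"birchmanni"}) and an optional \code{group}
#' label.
#'
#' @exportClass AncestryCalls
setClass("AncestryCalls", contains = "RangedSummarizedExperiment")

setValidity("AncestryCalls", function(object) {
    msg <- NULL
    if (!"calls" %in% assayNames(object))
        return("assay 'calls' is required")
    m <- assay(object, "calls")
    if (!all(m %in% c(0L, 1L, 2L) | is.na(m)))
        msg <- c(msg, "calls must be 0, 1, 2 or NA")
    if (!"mito" %in% colnames(colData(object)))
        msg <- c(msg, "colData must carry a 'mito' column")
    else {
        mito <- colData(object)$mito
        bad <- !(mito %in% .MITO_LEVELS)
        if (any(bad))
            msg <- c(msg, paste0("unknown mito label '", mito[which(bad)[1]],
                                 "' for individual '",
                                 colnames(object)[which(bad)[1]], "'"))
    }
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated individual ids")
    pos <- split(start(rowRanges(object)),
                 as.character(seqnames(rowRanges(object))))
    if (any(vapply(pos, function(p) is.unsorted(p, strictly = TRUE), logical(1))))
        msg <- c(msg, "site positions must be strictly increasing within chromosomes")
    if (is.null(msg)) TRUE else msg
})

#' Construct an AncestryCalls object
#'
#' @param calls integer matrix, sites x individuals, values 0/1/2/NA counting
#'   malinche-derived alleles. Column names are individual ids.
#' @param sites \code{GRanges} of width-1 site positions (one per row).
#' @param mito character vector of per-individual mitochondrial haplotypes
#'   (\code{"malinche"} or \code{"birchmanni"}).
#' @param group optional per-individual labels (e.g. \code{"lagging"},
#'   \code{"survivor"}).
#' @return An \linkS4class{AncestryCalls}.
#' @examples
#' x <- AncestryCalls(matrix(c(0L, 1L, 2L, 1L), 2,
#'                           dimnames = list(NULL, c("i1", "i2"))),
#'                    GRanges("1", IRanges(c(100, 200), width = 1)),
#'                    mito = c("malinche", "birchmanni"))
#' @export
AncestryCalls <- function(calls, sites, mito, group = NULL) {
    calls <- as.matrix(calls)
    storage.mode(calls) <- "integer"
    if (ncol(calls) == 0L) stop("empty individual list")
    if (is.null(colnames(calls)))
        colnames(calls) <- paste0("indiv", seq_len(ncol(calls)))
    cd <- DataFrame(mito = as.character(mito),
                    group = if (is.null(group)) NA_character_ else as.character(group),
                    row.names = colnames(calls))
    se <- SummarizedExperiment(assays = list(calls = calls),
                               rowRanges = sites, colData = cd)
    new("AncestryCalls", se)
}

#' @describeIn AncestryCalls the calls matrix (sites x individuals).
#' @param x an \code{AncestryCalls}.
#' @export
ancestryCalls <- function(x) assay(x, "calls")

#' @describeIn AncestryCalls per-individual mitochondrial haplotype labels.
#' @export
mitoHaplotype <- function(x) setNames(colData(x)$mito, colnames(x))

#' @describeIn AncestryCalls per-individual group labels (may be NA).
#' @export
indivGroup <- function(x) setNames(colData(x)$group, colnames(x))

#' @describeIn AncestryCalls fraction of missing calls.
#' @export
fractionMissing <- function(x) mean(is.na(ancestryCalls(x)))

#' Per-individual genome-wide mean ancestry
#'
#' Mean malinche allele fraction (\code{calls/2}) per individual over all
#' non-missing sites, optionally excluding one chromosome (used as the
#' leave-one-chromosome-out covariate of the admixture scan).
#'
#' @param x an \linkS4class{AncestryCalls}.
#' @param excludeChrom optional chromosome label to leave out.
#' @return Named numeric vector in \code{[0, 1]}.
#' @export
genomeWideAncestry <- function(x, excludeChrom = NULL) {
    m <- ancestryCalls(x) / 2
    if (!is.null(excludeChrom))
        m <- m[as.character(seqnames(rowRanges(x))) != excludeChrom, , drop = FALSE]
    colMeans(m, na.rm = TRUE)
}

setMethod("show", "AncestryCalls", function(object) {
    cat("AncestryCalls:", nrow(object), "sites x", ncol(object),
        "individuals\n  mito:",
        paste(names(table(colData(object)$mito)),
              table(colData(object)$mito), collapse = ", ", sep = "="),
        "\n  missing:", sprintf("%.2f%%", 100 * fractionMissing(object)), "\n")
})

# ---- AncestryPosteriors -----------------------------------------------------

#' Ancestry-state posterior probabilities
#'
#' A \code{RangedSummarizedExperiment} with assays \code{p0}, \code{p1} and
#' \code{p2} holding the posterior probability of carrying 0, 1 or 2
#' malinche-derived alleles. Each per-cell triple must sum to 1 within 1e-6.
#'
#' @exportClass AncestryPosteriors
setClass("AncestryPosteriors", contains = "RangedSummarizedExperiment")

setValidity("AncestryPosteriors", function(object) {
    if (!all(c("p0", "p1", "p2") %in% assayNames(object)))
        return("assays p0, p1, p2 are required")
    tot <- assay(object, "p0") + assay(object, "p1") + assay(object, "p2")
    bad <- which(abs(tot - 1) > 1e-6, arr.ind = TRUE)
    if (nrow(bad))
        return(sprintf("posterior triple at site %d, individual '%s' sums to %.6f (not 1)",
                       bad[1, 1], colnames(object)[bad[1, 2]], tot[bad[1, , drop = FALSE]]))
    rng <- range(c(assay(object, "p0"), assay(object, "p1"), assay(object, "p2")))
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        return("posteriors must lie in [0, 1]")
    TRUE
})

#' Construct an AncestryPosteriors object
#'
#' @param p0,p1,p2 matrices (sites x individuals) of ancestry-state
#'   posterior probabilities; each cell triple must sum to 1.
#' @param sites \code{GRanges} of site positions.
#' @param mito per-individual mitochondrial haplotype labels.
#' @return An \linkS4class{AncestryPosteriors}.
#' @export
AncestryPosteriors <- function(p0, p1, p2, sites, mito) {
    cd <- DataFrame(mito = as.character(mito), row.names = colnames(p0))
    se <- SummarizedExperiment(assays = list(p0 = as.matrix(p0),
                                             p1 = as.matrix(p1),
                                             p2 = as.matrix(p2)),
                               rowRanges = sites, colData = cd)
    new("AncestryPosteriors", se)
}
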