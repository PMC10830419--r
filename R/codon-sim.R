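#' @include codon-utils.R
NULL

.BRANCHES <- c("birchmanni", "malinche", "internal", "cortezi", "outgroup")

#' Simulate a four-taxon codon alignment with branch-specific substitutions
#'
#' Generates an in-frame codon alignment on the fixed unrooted topology
#' \code{((birchmanni, malinche), cortezi, outgroup)} in which each branch
#' receives exactly the requested numbers of nonsynonymous and synonymous
#' single-nucleotide substitutions, verified against the standard genetic
#' code and never creating stop codons. Substitutions are placed at
#' distinct codons so that parsimony polarization
#' ([polarizeSubstitutions()]) recovers the requested counts exactly.
#'
#' @param nCodons alignment length in codons.
#' @param branchSubs named list of \code{c(N = , S = )} substitution counts;
#'   names among \code{"birchmanni"}, \code{"malinche"}, \code{"internal"},
#'   \code{"cortezi"}, \code{"outgroup"}. Unnamed branches get zero.
#' @param seed optional integer seed; a fixed seed reproduces the alignment
#'   exactly.
#' @return A \code{DNAStringSet} of four sequences named
#'   \code{birchmanni}, \code{malinche}, \code{cortezi}, \code{outgroup}.
#' @examples
#' aln <- simulateCodonAlignment(100, list(birchmanni = c(N = 4, S = 0)),
#'                               seed = 7)
#' @export
simulateCodonAlignment <- function(nCodons, branchSubs = list(), seed = NULL) {
    stopifnot(nCodons >= 1)
    bad <- setdiff(names(branchSubs), .BRANCHES)
    if (length(bad)) stop("unknown branch '", bad[1], "'")
    req <- matrix(0L, length(.BRANCHES), 2,
                  dimnames = list(.BRANCHES, c("N", "S")))
    for (b in names(branchSubs)) {
        v <- branchSubs[[b]]
        req[b, "N"] <- as.integer(v[["N"]])
        req[b, "S"] <- as.integer(v[["S"]])
    }
    if (any(req < 0)) stop("substitution counts must be non-negative")
    total <- sum(req)
    if (total > nCodons)
        stop("cannot place ", total, " substitutions in ", nCodons,
             " codons without overlap")
    tb <- .codonTables()
    synDonors <- tb$sense[vapply(tb$sense, function(cd)
        length(tb$synNeighbors[[cd]]) > 0, logical(1))]
    withSeed(seed, {
        anc <- sample(tb$sense, nCodons, replace = TRUE)
        slots <- if (total) sample.int(nCodons, total) else integer(0)
        # per-branch edit lists: codon index -> replacement codon
        edits <- lapply(.BRANCHES, function(b) list())
        names(edits) <- .BRANCHES
        k <- 0
        for (b in .BRANCHES) for (type in c("N", "S")) {
            for (i in seq_len(req[b, type])) {
                k <- k + 1
                pos <- slots[k]
                pool <- if (type == "S") synDonors else tb$sense
                anc[pos] <- sample(pool, 1)
                nb <- if (type == "S") tb$synNeighbors[[anc[pos]]]
                      else tb$nonsynNeighbors[[anc[pos]]]
                edits[[b]][[as.character(pos)]] <- nb[[sample.int(length(nb), 1)]]
            }
        }
        apply_edits <- function(seq, branches) {
            for (b in branches) for (pos in names(edits[[b]]))
                seq[as.integer(pos)] <- edits[[b]][[pos]]
            seq
        }
        seqs <- c(
            birchmanni = paste(apply_edits(anc, c("internal", "birchmanni")),
                               collapse = ""),
            malinche = paste(apply_edits(anc, c("internal", "malinche")),
                             collapse = ""),
            cortezi = paste(apply_edits(anc, "cortezi"), collapse = ""),
            outgroup = paste(apply_edits(anc, "outgroup"), collapse = ""))
        Biostrings::DNAStringSet(seqs)
    })
}
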