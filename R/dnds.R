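#' @include codon-utils.R
NULL

.seqToCodons <- function(seq, label = "sequence") {
    cds <- .splitCodons(seq)
    tb <- .codonTables()
    aa <- .aa(cds)
    if (length(cds) > 1 && any(aa[-length(aa)] == "*", na.rm = TRUE))
        stop("internal stop codon in ", label)
    if (length(cds) && !is.na(aa[length(aa)]) && aa[length(aa)] == "*")
        cds <- cds[-length(cds)]  # trim terminal stop
    cds
}

#' NG86 pairwise substitution counting and dN/dS
#'
#' Counts synonymous and nonsynonymous sites and differences between two
#' aligned in-frame coding sequences by the Nei-Gojobori (1986) method:
#' sites are counted by degeneracy averaging (per codon position, the
#' fraction of possible changes that are synonymous; changes to stop codons
#' count as nonsynonymous, so each codon contributes 3 sites), and codons
#' differing at several positions are averaged over all minimal mutational
#' paths, excluding paths that pass through stop codons. Jukes-Cantor
#' correction converts the proportions to per-site rates. When \code{dS} is
#' zero with nonsynonymous change present, omega is undefined and displayed
#' as \code{"> 99"}.
#'
#' @param seqA,seqB aligned coding sequences (character or
#'   \code{DNAString}), equal length, multiple of 3. Codons containing
#'   non-ACGT characters in either sequence are excluded pairwise.
#' @return A one-row \code{data.frame} with columns \code{Nd}, \code{Sd}
#'   (nonsynonymous/synonymous differences), \code{Nsites}, \code{Ssites},
#'   \code{pN}, \code{pS}, \code{dN}, \code{dS}, \code{omega} and
#'   \code{omegaDisplay}.
#' @references Nei M, Gojobori T (1986) Mol Biol Evol 3:418-426.
#' @examples
#' ng86Counts("TTTAAA", "TTAAAG")  # one nonsyn, one syn difference
#' @export
ng86Counts <- function(seqA, seqB) {
    a <- .seqToCodons(seqA, "seqA")
    b <- .seqToCodons(seqB, "seqB")
    if (length(a) != length(b)) stop("aligned sequences differ in length")
    tb <- .codonTables()
    keep <- a %in% tb$codons & b %in% tb$codons
    a <- a[keep]; b <- b[keep]
    Ssites <- (sum(tb$synSites[a]) + sum(tb$synSites[b])) / 2
    Nsites <- 3 * length(a) - Ssites
    Nd <- Sd <- 0
    for (i in which(a != b)) {
        cnt <- .ng86PathAverage(a[i], b[i])
        Nd <- Nd + cnt[1]; Sd <- Sd + cnt[2]
    }
    pN <- if (Nsites > 0) Nd / Nsites else 0
    pS <- if (Ssites > 0) Sd / Ssites else 0
    jc <- function(p) if (p >= 3/4) NaN else -3/4 * log(1 - 4/3 * p)
    dN <- jc(pN); dS <- jc(pS)
    omega <- if (is.nan(dN) || is.nan(dS) || dS == 0) NA_real_ else dN / dS
    display <- if (!is.na(omega)) formatC(omega, digits = 4, format = "g")
               else if (!is.nan(dS) && dS == 0 && !is.nan(dN) && dN > 0) "> 99"
               else "undefined"
    data.frame(Nd = Nd, Sd = Sd, Nsites = Nsites, Ssites = Ssites,
               pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
               omegaDisplay = display, stringsAsFactors = FALSE)
}

# Average nonsyn/syn step counts over the minimal mutational paths between
# two codons, dropping paths through stop codons (fall back to all paths,
# counting stop-involving steps as nonsynonymous, if every path is blocked).
.ng86PathAverage <- function(c1, c2) {
    tb <- .codonTables()
    paths <- .codonPaths(c1, c2)
    classify <- function(steps) {
        prev <- c(c1, steps[-length(steps)])
        aa1 <- .aa(prev); aa2 <- .aa(steps)
        if (any(aa2[-length(aa2)] == "*")) return(NULL)  # blocked path
        c(N = sum(aa1 != aa2), S = sum(aa1 == aa2))
    }
    counts <- Filter(Negate(is.null), lapply(paths, classify))
    if (!length(counts)) {
        counts <- lapply(paths, function(steps) {
            prev <- c(c1, steps[-length(steps)])
            aa1 <- .aa(prev); aa2 <- .aa(steps)
            syn <- aa1 == aa2 & aa1 != "*" & aa2 != "*"
            c(N = sum(!syn), S = sum(syn))
        })
    }
    colMeans(do.call(rbind, counts))[c("N", "S")]
}

#' Polarize substitutions onto terminal branches by two-outgroup parsimony
#'
#' For an alignment on the topology \code{((A, B), C, outgroup)}, each
#' nucleotide difference between A and B is assigned to the A branch when
#' B, C and the outgroup agree (and symmetrically to B); sites without
#' two-outgroup agreement are counted as ambiguous and left unassigned.
#' Changes are classified as nonsynonymous or synonymous by comparing the
#' derived codon with the inferred ancestral codon.
#'
#' @param aln a named \code{DNAStringSet} (or named character vector) of
#'   four aligned in-frame sequences.
#' @param taxa named character vector mapping roles \code{A}, \code{B},
#'   \code{C}, \code{out} to sequence names.
#' @return A \code{data.frame} with rows for branches A and B (columns
#'   \code{branch}, \code{taxon}, \code{N}, \code{S}) and an
#'   \code{"ambiguous"} attribute counting unassignable differing sites.
#' @examples
#' aln <- simulateCodonAlignment(50, list(birchmanni = c(N = 2, S = 1)),
#'                               seed = 1)
#' polarizeSubstitutions(aln)
#' @export
polarizeSubstitutions <- function(aln,
                                  taxa = c(A = "birchmanni", B = "malinche",
                                           C = "cortezi", out = "outgroup")) {
    seqs <- setNames(toupper(as.character(aln)), names(aln))
    missing <- setdiff(taxa, names(seqs))
    if (length(missing)) stop("missing taxon '", missing[1], "' in alignment")
    A <- .seqToCodons(seqs[[taxa[["A"]]]], taxa[["A"]])
    B <- .seqToCodons(seqs[[taxa[["B"]]]], taxa[["B"]])
    C <- .seqToCodons(seqs[[taxa[["C"]]]], taxa[["C"]])
    O <- .seqToCodons(seqs[[taxa[["out"]]]], taxa[["out"]])
    if (length(unique(c(length(A), length(B), length(C), length(O)))) != 1)
        stop("aligned sequences differ in length")
    counts <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("N", "S")))
    ambiguous <- 0L
    for (i in which(A != B)) {
        ca <- strsplit(A[i], "")[[1]]; cb <- strsplit(B[i], "")[[1]]
        cc <- strsplit(C[i], "")[[1]]; co <- strsplit(O[i], "")[[1]]
        for (p in which(ca != cb)) {
            if (cb[p] == cc[p] && cc[p] == co[p]) {
                anc <- ca; anc[p] <- cb[p]
                type <- if (.aa(paste(anc, collapse = "")) ==
                            .aa(A[i])) "S" else "N"
                counts["A", type] <- counts["A", type] + 1L
            } else if (ca[p] == cc[p] && cc[p] == co[p]) {
                anc <- cb; anc[p] <- ca[p]
                type <- if (.aa(paste(anc, collapse = "")) ==
                            .aa(B[i])) "S" else "N"
                counts["B", type] <- counts["B", type] + 1L
            } else {
                ambiguous <- ambiguous + 1L
            }
        }
    }
    out <- data.frame(branch = c("A", "B"),
                      taxon = c(taxa[["A"]], taxa[["B"]]),
                      N = counts[, "N"], S = counts[, "S"],
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "ambiguous") <- ambiguous
    out
}

#' Percentile rank of focal genes in a genome-wide dN/dS table
#'
#' Ranks genes by omega among genes with a defined (finite) omega, using
#' mean ranks for ties; genes with undefined omega (\code{dS = 0} with
#' nonsynonymous change) form a right-tail class above all defined values.
#'
#' @param table \code{data.frame} with columns \code{gene} and \code{omega}
#'   (\code{NA} = undefined, as returned by [ng86Counts()]).
#' @param focalGenes character vector of gene names to report.
#' @return \code{data.frame} with columns \code{gene}, \code{omega},
#'   \code{percentile} (of defined-omega genes; \code{NA} for the
#'   undefined right-tail class) and \code{undefinedOmega}.
#' @export
genomewideDndsRank <- function(table, focalGenes) {
    stopifnot(all(c("gene", "omega") %in% colnames(table)))
    defined <- is.finite(table$omega)
    if (sum(defined) < 10)
        stop("need at least 10 genes with defined omega")
    pct <- rep(NA_real_, nrow(table))
    pct[defined] <- 100 * rank(table$omega[defined], ties.method = "average") /
        sum(defined)
    idx <- match(focalGenes, table$gene)
    if (anyNA(idx)) stop("focal gene '", focalGenes[is.na(idx)][1],
                         "' absent from the table")
    data.frame(gene = focalGenes, omega = table$omega[idx],
               percentile = pct[idx], undefinedOmega = !defined[idx],
               row.names = NULL, stringsAsFactors = FALSE)
}
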