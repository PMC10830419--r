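#' @include mitoscan-package.R
NULL

.BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Load replicate structural models from PDB files
#'
#' Reads each file with \code{bio3d::read.pdb}, keeps heavy-atom ATOM
#' records, and checks that chain/residue numbering matches across models
#' (replicate models of one system must be comparable residue by residue).
#'
#' @param paths character vector of PDB file paths.
#' @return List of models; each model is a \code{data.frame} of atoms
#'   (\code{chain}, \code{resno}, \code{resid}, \code{elety}, \code{x},
#'   \code{y}, \code{z}) with the source path as attribute.
#' @export
loadStructures <- function(paths) {
    models <- lapply(paths, function(p) {
        pdb <- bio3d::read.pdb(p, verbose = FALSE)
        at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
        if (nrow(at) == 0) stop("no ATOM records in '", p, "'")
        at <- at[!(at$elety %in% c("H")) & !grepl("^[0-9]*H", at$elety), ]
        out <- at[, c("chain", "resno", "resid", "elety", "x", "y", "z")]
        attr(out, "path") <- p
        out
    })
    key <- function(m) sort(unique(paste(m$chain, m$resno)))
    ref <- key(models[[1]])
    bad <- which(!vapply(models, function(m) identical(key(m), ref), logical(1)))
    if (length(bad))
        stop("chain/residue numbering mismatch between model 1 and model(s) ",
             paste(bad, collapse = ", "))
    models
}

.resAtoms <- function(model, chain, resno) {
    model[model$chain == chain & model$resno == resno, , drop = FALSE]
}

.minDist <- function(a, b) {
    if (!nrow(a) || !nrow(b)) return(Inf)
    d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
          outer(a$z, b$z, "-")^2
    sqrt(min(d2))
}

#' Classify inter-chain residue contacts across model replicates
#'
#' For each pair of substituted residues (one on each chain), a contact is
#' \emph{strong} when the alpha-carbon distance is at most \code{caCutoff}
#' in \emph{every} model, \emph{weak} when the minimum side-chain
#' heavy-atom distance is at most \code{scCutoff} in \emph{at least one}
#' model, and \emph{none} otherwise. Both cutoffs are inclusive. "Side
#' chain" means heavy atoms beyond the backbone (N, CA, C, O, OXT);
#' glycine, having none, falls back to its alpha carbon. Residues lacking
#' a CA atom in some model are excluded from the CA rule (they can only be
#' weak or none) and flagged.
#'
#' @param models list of models from [loadStructures()].
#' @param chainA,chainB chain identifiers.
#' @param residuesA,residuesB integer vectors of substituted residue
#'   numbers on each chain; empty input yields an empty result.
#' @param caCutoff alpha-carbon cutoff in Angstrom (default 10).
#' @param scCutoff side-chain cutoff in Angstrom (default 12).
#' @return \code{data.frame} with one row per residue pair: \code{resA},
#'   \code{resB}, \code{maxCA} (largest CA-CA distance over models),
#'   \code{minSC} (smallest side-chain distance over models),
#'   \code{class} (\code{"strong"}, \code{"weak"} or \code{"none"}) and
#'   \code{caMissing}.
#' @export
contactPairs <- function(models, chainA, residuesA, chainB, residuesB,
                         caCutoff = 10, scCutoff = 12) {
    if (!length(residuesA) || !length(residuesB))
        return(data.frame(resA = integer(), resB = integer(),
                          maxCA = numeric(), minSC = numeric(),
                          class = character(), caMissing = logical(),
                          stringsAsFactors = FALSE))
    for (m in seq_along(models)) {
        have <- function(ch, rs) rs %in% models[[m]]$resno[models[[m]]$chain == ch]
        miss <- c(residuesA[!have(chainA, residuesA)],
                  residuesB[!have(chainB, residuesB)])
        if (length(miss))
            stop("residue ", miss[1], " absent from model ", m)
    }
    pairs <- expand.grid(resA = residuesA, resB = residuesB)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
        ra <- pairs$resA[i]; rb <- pairs$resB[i]
        caD <- scD <- numeric(length(models))
        caMissing <- FALSE
        for (m in seq_along(models)) {
            A <- .resAtoms(models[[m]], chainA, ra)
            B <- .resAtoms(models[[m]], chainB, rb)
            caA <- A[A$elety == "CA", ]; caB <- B[B$elety == "CA", ]
            if (!nrow(caA) || !nrow(caB)) { caMissing <- TRUE; caD[m] <- Inf }
            else caD[m] <- .minDist(caA, caB)
            scA <- A[!(A$elety %in% .BACKBONE), ]
            scB <- B[!(B$elety %in% .BACKBONE), ]
            if (!nrow(scA)) scA <- caA  # glycine fallback
            if (!nrow(scB)) scB <- caB
            scD[m] <- .minDist(scA, scB)
        }
        class <- if (!caMissing && all(caD <= caCutoff)) "strong"
                 else if (any(scD <= scCutoff)) "weak"
                 else "none"
        data.frame(resA = ra, resB = rb, maxCA = max(caD), minSC = min(scD),
                   class = class, caMissing = caMissing,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
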