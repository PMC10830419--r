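suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# small AncestryCalls with explicit values
makeCalls <- function(calls, mito, chrom = "1", pos = NULL, group = NULL) {
    calls <- as.matrix(calls)
    if (is.null(pos)) pos <- seq_len(nrow(calls)) * 1000L
    gr <- GRanges(rep(chrom, length.out = nrow(calls)), IRanges(pos, width = 1))
    AncestryCalls(calls, gr, mito = mito, group = group)
}

# random matrix exercising missing data and both mito labels
randomCalls <- function(nSites = 12, nInd = 6, pMissing = 0.1) {
    calls <- matrix(sample(c(0:2, NA), nSites * nInd, replace = TRUE,
                           prob = c((1 - pMissing) / 3, (1 - pMissing) / 3,
                                    (1 - pMissing) / 3, pMissing)),
                    nSites, nInd,
                    dimnames = list(NULL, paste0("ind", seq_len(nInd))))
    chrom <- rep(c("1", "2"), each = ceiling(nSites / 2))[seq_len(nSites)]
    pos <- unlist(lapply(split(seq_len(nSites), chrom)[unique(chrom)],
                         function(i) sort(sample.int(1e6, length(i)))))
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1))
    AncestryCalls(calls, gr,
                  mito = sample(c("malinche", "birchmanni"), nInd, TRUE),
                  group = sample(c("survivor", "lagging", NA), nInd, TRUE))
}

# three-model toy structure set with controlled CA and side-chain distances:
# residue pair (A1, B1) has per-model CA distances caD and side-chain (CB)
# distances scD
writeControlledModels <- function(caD, scD, dir = tempfile()) {
    dir.create(dir)
    vapply(seq_along(caD), function(m) {
        mk <- function(chain, resno, xCA, xCB) {
            data.frame(chain = chain, resno = resno, resid = "ALA",
                       elety = c("N", "CA", "C", "O", "CB"),
                       x = c(xCA - 1.2, xCA, xCA + 1.2, xCA + 2.2, xCB),
                       y = c(0, 0, 0, 0, 5), z = 0)
        }
        # CA atoms on y=0 line separated by caD; CB atoms on y=5 line
        # separated horizontally by scD
        atoms <- rbind(mk("A", 1, 0, 0), mk("B", 1, caD[m], scD[m]))
        f <- file.path(dir, sprintf("model%d.pdb", m))
        writeToyStructure(atoms, f)
        f
    }, character(1))
}

# brute-force NG86 path enumeration, written independently of the package:
# recursive enumeration of orderings with stop-path exclusion
oracleNG86Paths <- function(c1, c2) {
    code <- Biostrings::GENETIC_CODE
    aa <- function(cd) unname(code[cd])
    rec <- function(cur, target) {
        diffs <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
        if (!length(diffs)) return(list(c(N = 0, S = 0, blocked = 0)))
        out <- list()
        for (p in diffs) {
            nxt <- strsplit(cur, "")[[1]]
            nxt[p] <- strsplit(target, "")[[1]][p]
            nxt <- paste(nxt, collapse = "")
            step <- if (aa(nxt) == "*" && nxt != target) c(N = 0, S = 0, blocked = 1)
                    else if (aa(cur) == aa(nxt)) c(N = 0, S = 1, blocked = 0)
                    else c(N = 1, S = 0, blocked = 0)
            for (restpath in rec(nxt, target))
                out[[length(out) + 1]] <- step + restpath
        }
        out
    }
    paths <- do.call(rbind, rec(c1, c2))
    ok <- paths[, "blocked"] == 0
    if (any(ok)) colMeans(paths[ok, c("N", "S"), drop = FALSE])
    else {
        # fall back to all paths, stop-involving steps as nonsynonymous
        # (recompute without exclusion)
        recAll <- function(cur, target) {
            diffs <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
            if (!length(diffs)) return(list(c(N = 0, S = 0)))
            out <- list()
            for (p in diffs) {
                nxt <- strsplit(cur, "")[[1]]
                nxt[p] <- strsplit(target, "")[[1]][p]
                nxt <- paste(nxt, collapse = "")
                syn <- aa(cur) == aa(nxt) && aa(cur) != "*" && aa(nxt) != "*"
                step <- if (syn) c(N = 0, S = 1) else c(N = 1, S = 0)
                for (restpath in recAll(nxt, target))
                    out[[length(out) + 1]] <- step + restpath
            }
            out
        }
        colMeans(do.call(rbind, recAll(c1, c2)))
    }
}

senseCodons <- function() {
    code <- Biostrings::GENETIC_CODE
    names(code)[code != "*"]
}
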