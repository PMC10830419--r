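#' @include mitoscan-package.R
NULL

# Standard genetic code tables shared by the alignment simulator and the
# substitution-counting code. Built once at load time from
# Biostrings::GENETIC_CODE.

.codonTables <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        code <- Biostrings::GENETIC_CODE
        codons <- names(code)
        sense <- codons[code != "*"]
        nts <- c("A", "C", "G", "T")
        # single-nucleotide neighbours of each codon, split syn / nonsyn / stop
        neigh <- lapply(codons, function(cd) {
            ch <- strsplit(cd, "")[[1]]
            out <- character(0)
            for (p in 1:3) for (n in setdiff(nts, ch[p])) {
                alt <- ch; alt[p] <- n
                out <- c(out, paste(alt, collapse = ""))
            }
            out
        })
        names(neigh) <- codons
        synN <- lapply(codons, function(cd)
            Filter(function(x) code[[x]] != "*" && code[[x]] == code[[cd]],
                   neigh[[cd]]))
        nonsynN <- lapply(codons, function(cd)
            Filter(function(x) code[[x]] != "*" && code[[x]] != code[[cd]],
                   neigh[[cd]]))
        names(synN) <- names(nonsynN) <- codons
        # NG86 site counts: per position, the fraction of the three possible
        # changes that are synonymous; stop-creating changes count as
        # non-synonymous, so syn + nonsyn sites = 3 for every codon.
        synSites <- vapply(codons, function(cd) length(synN[[cd]]) / 3,
                           numeric(1))
        cache <<- list(code = code, codons = codons, sense = sense,
                       synNeighbors = synN, nonsynNeighbors = nonsynN,
                       synSites = synSites)
        cache
    }
})

.splitCodons <- function(seq) {
    s <- toupper(as.character(seq))
    if (nchar(s) %% 3 != 0)
        stop("sequence length ", nchar(s), " is not a multiple of 3")
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

.aa <- function(codon) {
    tb <- .codonTables()
    ifelse(codon %in% tb$codons, unname(tb$code[codon]), NA_character_)
}

# All orderings of the differing positions between two codons; each path is
# a sequence of single-nucleotide steps. Used by NG86 path averaging.
.codonPaths <- function(c1, c2) {
    a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
    diffs <- which(a != b)
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        do.call(c, lapply(seq_along(v), function(i)
            lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    lapply(perms(diffs), function(ord) {
        cur <- a
        steps <- character(length(ord))
        for (k in seq_along(ord)) {
            cur[ord[k]] <- b[ord[k]]
            steps[k] <- paste(cur, collapse = "")
        }
        steps  # codons visited after each step (last one is c2)
    })
}
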