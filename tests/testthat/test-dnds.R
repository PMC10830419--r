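test_that("single-codon differences are classified against the genetic code", {
    same <- ng86Counts("ATGGCT", "ATGGCT")
    expect_identical(c(same$Nd, same$Sd), c(0, 0))
    expect_identical(same$omegaDisplay, "undefined")
    syn <- ng86Counts("AAA", "AAG")   # Lys -> Lys
    expect_identical(c(syn$Nd, syn$Sd), c(0, 1))
    nonsyn <- ng86Counts("TTT", "TTA")  # Phe -> Leu
    expect_identical(c(nonsyn$Nd, nonsyn$Sd), c(1, 0))
    expect_identical(nonsyn$omegaDisplay, "> 99")
})

test_that("site counting matches brute-force enumeration of the nine mutations", {
    tb <- mitoscan:::.codonTables()
    code <- Biostrings::GENETIC_CODE
    nts <- c("A", "C", "G", "T")
    for (cd in senseCodons()) {
        syn <- 0
        ch <- strsplit(cd, "")[[1]]
        for (p in 1:3) for (nt in setdiff(nts, ch[p])) {
            alt <- ch; alt[p] <- nt
            alt <- paste(alt, collapse = "")
            if (code[[alt]] != "*" && code[[alt]] == code[[cd]])
                syn <- syn + 1
        }
        expect_equal(unname(tb$synSites[cd]), syn / 3)
    }
    expect_equal(unname(tb$synSites["TTT"]), 1 / 3)
    # site-counting conservation: every codon contributes exactly 3 sites
    expect_equal(sum(tb$synSites[senseCodons()]) +
                 sum(3 - tb$synSites[senseCodons()]), 3 * 61)
})

test_that("path averaging agrees with an independent recursive enumeration", {
    set.seed(12)
    sense <- senseCodons()
    pairs <- cbind(sample(sense, 60, TRUE), sample(sense, 60, TRUE))
    for (i in seq_len(nrow(pairs))) {
        res <- ng86Counts(pairs[i, 1], pairs[i, 2])
        oracle <- oracleNG86Paths(pairs[i, 1], pairs[i, 2])
        expect_equal(c(res$Nd, res$Sd), unname(oracle[c("N", "S")]),
                     tolerance = 1e-10)
    }
})

test_that("counting is symmetric and validates its inputs", {
    set.seed(2)
    sense <- senseCodons()
    a <- paste(sample(sense, 30, TRUE), collapse = "")
    b <- paste(sample(sense, 30, TRUE), collapse = "")
    ab <- ng86Counts(a, b); ba <- ng86Counts(b, a)
    expect_equal(ab[, c("Nd", "Sd", "Nsites", "Ssites")],
                 ba[, c("Nd", "Sd", "Nsites", "Ssites")])
    expect_error(ng86Counts("ATGTAAGCT", "ATGAAAGCT"), "stop codon")
    expect_error(ng86Counts("ATGAAA", "ATG"), "length")
    expect_error(ng86Counts("ATGA", "ATGA"), "multiple of 3")
})

test_that("polarization assigns derived changes by strict two-outgroup agreement", {
    aln <- c(birchmanni = "ATGAAA", malinche = "ATGAAG",
             cortezi = "ATGAAG", outgroup = "ATGAAG")
    res <- polarizeSubstitutions(aln)
    expect_identical(res$S[res$taxon == "birchmanni"], 1L)
    expect_identical(res$N[res$taxon == "birchmanni"], 0L)
    expect_identical(sum(res$N) + sum(res$S), 1L)
    same <- polarizeSubstitutions(c(birchmanni = "ATG", malinche = "ATG",
                                    cortezi = "ATG", outgroup = "ATG"))
    expect_identical(sum(same$N) + sum(same$S), 0L)
    # discordant outgroups leave the site ambiguous
    amb <- polarizeSubstitutions(c(birchmanni = "AAA", malinche = "AAG",
                                   cortezi = "AAA", outgroup = "AAG"))
    expect_identical(sum(amb$N) + sum(amb$S), 0L)
    expect_identical(attr(amb, "ambiguous"), 1L)
    expect_error(polarizeSubstitutions(aln[1:3]), "missing taxon")
})

test_that("simulated branch substitutions are recovered exactly, including the N=4 S=0 pattern", {
    aln <- simulateCodonAlignment(100, list(birchmanni = c(N = 4, S = 0)),
                                  seed = 71)
    res <- polarizeSubstitutions(aln)
    expect_identical(c(res$N[res$taxon == "birchmanni"],
                       res$S[res$taxon == "birchmanni"]), c(4L, 0L))
    expect_identical(c(res$N[res$taxon == "malinche"],
                       res$S[res$taxon == "malinche"]), c(0L, 0L))
    expect_identical(ng86Counts(as.character(aln[["birchmanni"]]),
                                as.character(aln[["malinche"]]))$omegaDisplay,
                     "> 99")
    # both terminal branches at once
    set.seed(81)
    for (i in 1:3) {
        want <- list(birchmanni = c(N = sample(0:3, 1), S = sample(0:3, 1)),
                     malinche = c(N = sample(0:3, 1), S = sample(0:3, 1)))
        aln2 <- simulateCodonAlignment(120, want)
        res2 <- polarizeSubstitutions(aln2)
        expect_identical(res2$N[res2$taxon == "birchmanni"],
                         as.integer(want$birchmanni[["N"]]))
        expect_identical(res2$S[res2$taxon == "birchmanni"],
                         as.integer(want$birchmanni[["S"]]))
        expect_identical(res2$N[res2$taxon == "malinche"],
                         as.integer(want$malinche[["N"]]))
        expect_identical(res2$S[res2$taxon == "malinche"],
                         as.integer(want$malinche[["S"]]))
    }
})

test_that("genome-wide ranking places focal genes and undefined omegas correctly", {
    tab <- data.frame(gene = sprintf("g%02d", 1:20),
                      omega = c(seq(0.05, 0.9, length.out = 19), NA))
    tab$omega[10] <- 5  # implanted high-omega gene
    rk <- genomewideDndsRank(tab, c("g10", "g20", "g01"))
    expect_equal(rk$percentile[1], 100)
    expect_true(rk$undefinedOmega[2])
    expect_true(is.na(rk$percentile[2]))
    expect_equal(rk$percentile[3], 100 * 1 / 19)
    allEq <- data.frame(gene = letters[1:12], omega = rep(0.5, 12))
    rkEq <- genomewideDndsRank(allEq, c("a", "b"))
    expect_equal(rkEq$percentile, rep(100 * 6.5 / 12, 2))  # mean rank of a 12-way tie
    expect_error(genomewideDndsRank(tab[1:5, ], "g01"), "at least 10")
    expect_error(genomewideDndsRank(tab, "nope"), "absent")
})
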