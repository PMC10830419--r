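test_that("pairwise divergence uses pairwise deletion of ambiguous sites", {
    a <- paste(rep("A", 1000), collapse = "")
    expect_equal(as.numeric(pairwiseDivergence(a, a)), 0)
    b <- paste(c(rep("A", 990), rep("C", 10)), collapse = "")
    expect_equal(as.numeric(pairwiseDivergence(a, b)), 0.01)
    bn <- paste(c(rep("N", 5), rep("A", 985), rep("C", 10)), collapse = "")
    d <- pairwiseDivergence(a, bn)
    expect_identical(attr(d, "nCompared"), 995L)
    expect_equal(as.numeric(d), 10 / 995)
    expect_error(pairwiseDivergence("NNN", "ACG"), "no comparable sites")
    expect_error(pairwiseDivergence("ACGT", "ACG"), "differ in length")
})

test_that("ILS simulation p-values match the analytic Poisson lower tail", {
    for (pars in list(c(T = 250000, mu = 5e-8, L = 16500, dObs = 0.01),
                      c(T = 100000, mu = 2e-8, L = 16500, dObs = 0.003),
                      c(T = 500000, mu = 1e-8, L = 10000, dObs = 0.008))) {
        sim <- ilsSimulation(pars[["dObs"]], pars[["T"]], pars[["mu"]],
                             pars[["L"]], nSims = 20000, seed = 19)
        analytic <- ppois(floor(pars[["dObs"]] * pars[["L"]]),
                          2 * pars[["mu"]] * pars[["T"]] * pars[["L"]])
        mcse <- sqrt(analytic * (1 - analytic) / 20000) + 1 / 20001
        expect_lt(abs(sim$p.value - analytic), 3 * mcse + 1e-4)
    }
})

test_that("an extreme divergence deficit reports the add-one floor and a surplus does not", {
    # expected 100 substitutions, observed 10: analytic tail ~ 1e-28
    deficit <- ilsSimulation(10 / 1000, T = 1e6, mu = 5e-8, L = 1000,
                             nSims = 2000, seed = 4)
    expect_equal(deficit$p.value, 1 / 2001)
    surplus <- ilsSimulation(0.12, T = 1e6, mu = 5e-8, L = 1000,
                             nSims = 2000, seed = 4)
    expect_gt(surplus$p.value, 0.3)
    expect_identical(ilsSimulation(0.01, 1e5, 1e-8, 500, 100, seed = 8)$p.value,
                     ilsSimulation(0.01, 1e5, 1e-8, 500, 100, seed = 8)$p.value)
})

test_that("window means tile half-open windows and match site-level restriction", {
    x <- makeCalls(matrix(rep(c(1L, 2L, 0L), 4), 4, 3, byrow = TRUE,
                          dimnames = list(NULL, c("a", "b", "c"))),
                   mito = rep("malinche", 3),
                   pos = c(100L, 200L, 250000L, 300000L))
    w <- windowAncestry(x, windowBp = 250000, minorParent = "birchmanni")
    expect_length(w, 2)
    # site at exactly 250000 belongs to the second window (half-open rule)
    expect_identical(mcols(w)$nSites, c(2L, 2L))
    siteMean <- mean(1 - c(1, 2, 0) / 2)
    expect_equal(mcols(w)$meanAncestry, rep(siteMean, 2))
    expect_equal(metadata(w)$genomeWideMean, siteMean)
    # malinche orientation flips the fraction
    wm <- windowAncestry(x, windowBp = 250000, minorParent = "malinche")
    expect_equal(mcols(wm)$meanAncestry, rep(1 - siteMean, 2))
})

test_that("window means equal the site-level mean restricted to the window", {
    set.seed(9)
    x <- randomCalls(nSites = 30, nInd = 10, pMissing = 0)
    w <- windowAncestry(x, windowBp = 200000)
    frac <- 1 - ancestryCalls(x) / 2
    gr <- rowRanges(x)
    for (i in seq_along(w)) {
        sel <- as.character(seqnames(gr)) == as.character(seqnames(w))[i] &
            floor(start(gr) / 200000) == floor(start(w)[i] / 200000)
        if (!any(sel)) { expect_true(is.na(mcols(w)$meanAncestry[i])); next }
        expect_equal(mcols(w)$meanAncestry[i], mean(rowMeans(frac[sel, , drop = FALSE])))
    }
})

test_that("replicated depletion p matches brute-force window enumeration", {
    # one population, one locus sitting at a known rank of the window means
    nW <- 40
    set.seed(33)
    calls <- matrix(sample(0:2, nW * 4, TRUE), nW, 4,
                    dimnames = list(NULL, paste0("i", 1:4)))
    x <- makeCalls(calls, mito = rep("malinche", 4),
                   pos = seq_len(nW) * 250000L + 10L)
    w <- windowAncestry(x, windowBp = 250000)
    anc <- mcols(w)$meanAncestry
    for (locusIdx in c(which.min(anc), order(anc)[4], order(anc)[10])) {
        loci <- data.frame(chrom = "1", pos = start(w)[locusIdx] + 100)
        res <- replicatedDepletionTest(list(p1 = w), loci, nPerm = 20000,
                                       seed = 3)
        # brute-force enumeration over the non-empty windows the test draws from
        exact <- mean(anc[!is.na(anc)] <= anc[locusIdx])
        mcse <- sqrt(exact * (1 - exact) / 20000)
        expect_lt(abs(res$p.value - exact), 3 * mcse + 1e-3)
    }
})

test_that("a median focal locus gives p near its rank and population order is irrelevant", {
    set.seed(44)
    nW <- 41
    mk <- function() {
        calls <- matrix(sample(0:2, nW * 6, TRUE), nW, 6,
                        dimnames = list(NULL, paste0("i", 1:6)))
        x <- makeCalls(calls, mito = rep("birchmanni", 6),
                       chrom = rep(c("1", "2"), c(21, 20)),
                       pos = c(seq_len(21), seq_len(20)) * 250000L + 5L)
        windowAncestry(x, windowBp = 250000)
    }
    w <- mk()
    anc <- mcols(w)$meanAncestry
    med1 <- which(!is.na(anc) &
                  rank(anc, ties.method = "first", na.last = "keep") == 21)[1]
    loci <- data.frame(chrom = as.character(seqnames(w))[med1],
                       pos = start(w)[med1] + 10)
    # single population, single median locus: p ~ P(draw <= median)
    res1 <- replicatedDepletionTest(list(a = w), loci, nPerm = 20000, seed = 9)
    exact <- mean(anc[!is.na(anc)] <= anc[med1])
    expect_lt(abs(res1$p.value - exact), 0.02)
    # exchangeability across population order (shared draws keyed to windows)
    w2 <- mk()
    resAB <- replicatedDepletionTest(list(a = w, b = w2), loci,
                                     nPerm = 5000, seed = 13)
    resBA <- replicatedDepletionTest(list(b = w2, a = w), loci,
                                     nPerm = 5000, seed = 13)
    expect_equal(resAB$p.value, resBA$p.value)
})

test_that("uncovered or empty focal windows are an error", {
    x <- makeCalls(matrix(0:2, 3, 2, dimnames = list(NULL, c("a", "b"))),
                   mito = rep("malinche", 2), pos = c(1000L, 2000L, 3000L))
    w <- windowAncestry(x, windowBp = 1000)
    expect_error(replicatedDepletionTest(list(w), data.frame(chrom = "9", pos = 1)),
                 "not covered")
})
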