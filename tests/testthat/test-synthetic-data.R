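test_that("neutral F2 cross is Mendelian: per-site means near 0.5, genotypes near 1:2:1", {
    map <- geneticMap(nChrom = 3, sitesPerChrom = 20)
    x <- simulateCross(10000, map = map, seed = 101)
    calls <- ancestryCalls(x)
    se <- sqrt(0.5 * 0.5 / (2 * 10000))
    means <- rowMeans(calls) / 2
    expect_lt(abs(mean(means) - 0.5), 3 * se)
    expect_lt(max(abs(means - 0.5)), 5 * se)  # 60 sites, allow multiplicity
    props <- table(factor(calls, 0:2)) / length(calls)
    expect_lt(max(abs(props - c(0.25, 0.5, 0.25))), 0.01)
    expect_true(all(mitoHaplotype(x) == "malinche"))  # maternal transmission
})

test_that("a lethal recessive (s=1, h=0) leaves no penalized homozygotes and a 2:1 ratio", {
    map <- geneticMap(nChrom = 1, sitesPerChrom = 5)
    model <- incompatibilityModel("1", 12.5e6, s = 1, h = 0)
    x <- simulateCross(6000, model, map, seed = 7)
    locus <- ancestryCalls(x)[3, ]
    expect_identical(sum(locus == 0), 0L)
    ratio <- sum(locus == 1) / sum(locus == 2)
    expect_lt(abs(ratio - 2), 0.15)
})

test_that("simulators are deterministic under a fixed seed", {
    map <- geneticMap(nChrom = 2, sitesPerChrom = 10)
    model <- incompatibilityModel("1", 1e6, s = 0.5, h = 0.2)
    expect_identical(ancestryCalls(simulateCross(50, model, map, seed = 3)),
                     ancestryCalls(simulateCross(50, model, map, seed = 3)))
    expect_identical(ancestryCalls(simulateSwarm(40, 10, model = model,
                                                 map = map, seed = 4)),
                     ancestryCalls(simulateSwarm(40, 10, model = model,
                                                 map = map, seed = 4)))
    expect_identical(simulateGametes(20, map, seed = 5),
                     simulateGametes(20, map, seed = 5))
})

test_that("neutral F2 genotype counts are Binomial(2, 1/2): chi-square p-values are uniform", {
    # 1,000 unlinked loci from independent crosses of 200 offspring
    map <- geneticMap(nChrom = 10, sitesPerChrom = 1)
    pvals <- unlist(lapply(1:100, function(i) {
        x <- simulateCross(200, map = map, seed = 5000 + i)
        apply(ancestryCalls(x), 1, function(g) {
            obs <- tabulate(g + 1L, 3)
            suppressWarnings(chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value)
        })
    }))
    expect_length(pvals, 1000)
    ks <- suppressWarnings(ks.test(pvals, "punif"))
    expect_gt(ks$p.value, 0.001)
})

test_that("ancestry tract lengths are exponential with mean 1 Morgan (Haldane)", {
    # one 40-Morgan chromosome sampled at 2e-3 Morgan resolution; keep only
    # interior tracts that start in the first half so that right-censoring
    # by the chromosome end is negligible (P ~ exp(-20))
    map <- geneticMap(nChrom = 1, sitesPerChrom = 20000, morgans = 40)
    res <- 40 / 20000
    tracts <- c()
    for (batch in 1:2) {
        g <- simulateGametes(400, map, seed = 40 + batch)
        for (j in seq_len(ncol(g))) {
            runs <- rle(g[, j])$lengths
            if (length(runs) < 3) next
            starts <- cumsum(c(0, runs[-length(runs)]))
            keep <- seq_along(runs)[-c(1, length(runs))]
            keep <- keep[starts[keep] * res < 20]
            tracts <- c(tracts, runs[keep])
        }
    }
    tracts <- tracts * res
    expect_gt(length(tracts), 9000)
    expect_lt(abs(mean(tracts) - 1), 0.05)
    ks <- suppressWarnings(ks.test(tracts, "pexp", 1))
    expect_gt(ks$p.value, 0.001)
})

test_that("selection never increases the penalized genotype frequency (monotone in s)", {
    map <- geneticMap(nChrom = 1, sitesPerChrom = 3)
    freq <- vapply(c(0, 0.25, 0.5, 0.75, 0.95, 1), function(s) {
        model <- incompatibilityModel("1", 12.5e6, s = s, h = 0.1)
        x <- simulateCross(4000, model, map, seed = 99)
        mean(ancestryCalls(x)[2, ] == 0)
    }, numeric(1))
    expect_true(all(diff(freq) <= 0.01))   # common seed; small MC slack
    expect_identical(freq[6], 0)           # s = 1 exact
})

test_that("neutral swarm stays near founder admixture with uncorrelated mito", {
    map <- geneticMap(nChrom = 8, sitesPerChrom = 25)
    x <- simulateSwarm(1000, generations = 30, m = 0.5, mitoFreq = 0.5,
                       map = map, seed = 21)
    anc <- genomeWideAncestry(x)
    expect_lt(abs(mean(anc) - 0.5), 0.08)
    mito <- as.numeric(mitoHaplotype(x) == "malinche")
    expect_lt(abs(cor(anc, mito)), 0.15)
})

test_that("fixed founder mito frequency yields a monomorphic swarm", {
    map <- geneticMap(nChrom = 2, sitesPerChrom = 5)
    x <- simulateSwarm(50, 5, mitoFreq = 1, map = map, seed = 2)
    expect_true(all(mitoHaplotype(x) == "malinche"))
    y <- simulateSwarm(50, 5, mitoFreq = 0, map = map, seed = 2)
    expect_true(all(mitoHaplotype(y) == "birchmanni"))
})

test_that("swarm selection depletes penalized homozygotes only on the matched mito background", {
    map <- geneticMap(nChrom = 2, sitesPerChrom = 10)
    model <- incompatibilityModel("1", 12.5e6, s = 1, h = 0)
    x <- simulateSwarm(600, generations = 8, model = model, map = map,
                       seed = 31, requirePolymorphicMito = TRUE)
    locus <- ancestryCalls(x)[5, ]
    mito <- mitoHaplotype(x)
    # matched background: zygote fitness zero, so no penalized homozygotes
    expect_identical(sum(locus[mito == "malinche"] == 0), 0L)
    # unmatched background: single-generation recursion oracle predicts
    # Hardy-Weinberg q^2 from the parental allele frequency
    bm <- locus[mito == "birchmanni"]
    q <- mean(2 - bm) / 2
    nB <- length(bm)
    expect_gt(nB, 30)
    se <- sqrt(q^2 * (1 - q^2) / nB)
    expect_lt(abs(mean(bm == 0) - q^2), 5 * se + 0.02)
})

test_that("population extinction under selection reports the generation", {
    map <- geneticMap(nChrom = 1, sitesPerChrom = 3)
    # on the malinche background every genotype at the locus is lethal
    # (both homozygotes penalized, h = 1); with all-malinche mitochondria
    # no zygote can survive
    model <- incompatibilityModel(c("1", "1"), c(1e6, 1e6), s = 1, h = 1,
                                  mitoPartner = "malinche",
                                  penalizedAncestry = c("birchmanni", "malinche"))
    expect_error(simulateSwarm(20, 5, mitoFreq = 1, model = model, map = map,
                               seed = 3, maxTriesPerIndiv = 50),
                 "extinct.*generation")
})

test_that("codon alignment simulator places exactly the requested substitutions", {
    aln <- simulateCodonAlignment(60, list(), seed = 1)
    expect_identical(length(unique(as.character(aln))), 1L)  # all-zero request
    expect_identical(as.character(simulateCodonAlignment(80,
                         list(malinche = c(N = 2, S = 3)), seed = 9)),
                     as.character(simulateCodonAlignment(80,
                         list(malinche = c(N = 2, S = 3)), seed = 9)))
    expect_error(simulateCodonAlignment(3, list(birchmanni = c(N = 3, S = 2))),
                 "cannot place")
    expect_error(simulateCodonAlignment(10, list(cortez = c(N = 1, S = 0))),
                 "unknown branch")
    # no stop codons anywhere, length as requested
    aln <- simulateCodonAlignment(50, list(birchmanni = c(N = 3, S = 2),
                                           outgroup = c(N = 1, S = 1)), seed = 4)
    expect_true(all(Biostrings::width(aln) == 150))
    for (s in as.character(aln)) {
        aas <- strsplit(as.character(Biostrings::translate(
            Biostrings::DNAString(s))), "")[[1]]
        expect_false(any(aas == "*"))
    }
})
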