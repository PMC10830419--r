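#' @include AllClasses.R
NULL

#' Simulate an F2 intercross under mitonuclear viability selection
#'
#' Emulates the mapping design: F1 hybrids from malinche mothers and
#' birchmanni fathers are intercrossed, so every offspring inherits the
#' malinche mitochondria maternally. Gametes are formed with Poisson
#' crossovers (Haldane model, no interference) at a rate equal to each
#' chromosome's map length; zygote viability follows the multiplicative
#' fitness model of \code{\link{incompatibilityModel}}. Because every F1 is
#' heterozygous genome wide, viability selection on the F1 generation only
#' rescales brood size, so a single selected F2 generation reproduces the
#' two-generation scheme's genotype frequencies.
#'
#' @param n number of surviving offspring to return.
#' @param model an \linkS4class{IncompatibilityModel} (default: no loci,
#'   i.e. neutral Mendelian segregation).
#' @param map a \linkS4class{GeneticMap} (default [geneticMap()]).
#' @param seed optional integer seed recorded in the output metadata.
#' @param resample if \code{TRUE} (default) zygotes are redrawn until
#'   \code{n} survivors are obtained; if \code{FALSE} exactly \code{n}
#'   zygotes are drawn and only survivors are returned.
#' @param maxTries cap on zygote draws when resampling.
#' @return An \linkS4class{AncestryCalls} of survivors (all with malinche
#'   mitochondria); \code{metadata(x)$seed} and \code{metadata(x)$zygotes}
#'   record the seed and the number of zygotes drawn.
#' @examples
#' x <- simulateCross(50, map = geneticMap(nChrom = 2, sitesPerChrom = 20),
#'                    seed = 1)
#' @export
simulateCross <- function(n, model = incompatibilityModel(),
                          map = geneticMap(), seed = NULL,
                          resample = TRUE, maxTries = 1000 * n + 1000) {
    stopifnot(n > 0, is(model, "IncompatibilityModel"), is(map, "GeneticMap"))
    validObject(model)
    fm <- .mapFlat(map)
    fl <- .modelFlat(model, map@sites)
    res <- withSeed(seed, .cpp_simulate_cross(
        fm$chrStart, fm$gpos, fm$morgans, as.integer(n),
        fl$site, fl$s, fl$h, fl$mito, fl$penHom,
        fl$epiA, fl$epiB, fl$epiMito, fl$epiE,
        resample, as.numeric(maxTries)))
    calls <- res$calls
    colnames(calls) <- sprintf("F2_%04d", seq_len(ncol(calls)))
    x <- AncestryCalls(calls, map@sites,
                       mito = rep("malinche", ncol(calls)))
    metadata(x) <- list(seed = seed, zygotes = res$zygotes,
                        scheme = "F1 intercross (malinche female founder)")
    x
}

#' Simulate a multigeneration hybrid swarm
#'
#' Wright-Fisher random mating for \code{generations} generations from a
#' founding event in which each founder is a pure parental individual
#' (malinche with probability \code{m}). Mitochondria are transmitted
#' maternally; the founder mitochondrial frequency is controlled separately
#' and malinche mitochondria are allocated to malinche founders first, so
#' that founders are cytonuclear-matched whenever possible (as when a
#' hybrid population is seeded by pure individuals of both species).
#' Viability selection uses the same zygote fitness model as
#' [simulateCross()].
#'
#' @param N population size (constant).
#' @param generations number of generations of random mating (default 100,
#'   the age of the natural hybrid zones this emulates).
#' @param m founder admixture proportion (probability a founder is
#'   malinche).
#' @param mitoFreq founder frequency of the malinche mitochondrial
#'   haplotype.
#' @param model an \linkS4class{IncompatibilityModel}.
#' @param map a \linkS4class{GeneticMap}.
#' @param migration per-generation probability that an individual slot is
#'   filled by a pure parental migrant (malinche with probability \code{m},
#'   carrying its own species' mitochondria) instead of an offspring; 0
#'   (default) gives a closed swarm. Ongoing migration keeps both
#'   ancestries and mitochondrial haplotypes segregating, as in natural
#'   hybrid zones that receive parental migrants.
#' @param seed optional integer seed.
#' @param requirePolymorphicMito if \code{TRUE}, re-simulate (up to
#'   \code{maxRestarts} times) until both mitochondrial haplotypes survive
#'   to the final generation, mirroring the choice of study populations
#'   that still segregate for both; applies only when the founders were
#'   polymorphic.
#' @param maxRestarts restart cap for \code{requirePolymorphicMito}.
#' @param maxTriesPerIndiv per-individual zygote draw cap before declaring
#'   the population extinct under selection.
#' @return An \linkS4class{AncestryCalls} for the final generation.
#' @export
simulateSwarm <- function(N, generations = 100, m = 0.5, mitoFreq = 0.5,
                          model = incompatibilityModel(), map = geneticMap(),
                          migration = 0, seed = NULL,
                          requirePolymorphicMito = FALSE,
                          maxRestarts = 100, maxTriesPerIndiv = 10000) {
    stopifnot(N > 0, generations >= 1, m > 0, m < 1,
              mitoFreq >= 0, mitoFreq <= 1, migration >= 0, migration < 1,
              is(model, "IncompatibilityModel"), is(map, "GeneticMap"))
    validObject(model)
    fm <- .mapFlat(map)
    fl <- .modelFlat(model, map@sites)
    run <- function() {
        species <- as.integer(runif(N) < m)
        nMal <- rbinom(1L, N, mitoFreq)
        mito <- integer(N)
        ord <- order(species, decreasing = TRUE)  # malinche founders first
        if (nMal > 0) mito[ord[seq_len(min(nMal, N))]] <- 1L
        .cpp_simulate_swarm(fm$chrStart, fm$gpos, fm$morgans,
                            species, mito, as.integer(generations),
                            fl$site, fl$s, fl$h, fl$mito, fl$penHom,
                            fl$epiA, fl$epiB, fl$epiMito, fl$epiE,
                            migration, m, as.numeric(maxTriesPerIndiv))
    }
    res <- withSeed(seed, {
        out <- run()
        if (requirePolymorphicMito && mitoFreq > 0 && mitoFreq < 1) {
            tries <- 0
            while (length(unique(out$mito)) < 2L) {
                if ((tries <- tries + 1) > maxRestarts)
                    stop("mitochondrial haplotype fixed in every restart")
                out <- run()
            }
        }
        out
    })
    calls <- res$calls
    colnames(calls) <- sprintf("H%04d", seq_len(ncol(calls)))
    x <- AncestryCalls(calls, map@sites,
                       mito = .MITO_LEVELS[2L - res$mito])
    metadata(x) <- list(seed = seed, generations = generations,
                        m = m, mitoFreq = mitoFreq, migration = migration)
    x
}

# Raw F1 gametes over the site grid (1 = malinche haplotype); used to
# study the crossover process itself (ancestry tract lengths).
#' Simulate F1 gametes
#'
#' Returns the raw gamete haplotypes (sites x n, 1 = malinche-derived) an F1
#' individual transmits, exposing the Haldane crossover process directly.
#'
#' @inheritParams simulateCross
#' @return Integer 0/1 matrix, sites x \code{n}.
#' @export
simulateGametes <- function(n, map = geneticMap(), seed = NULL) {
    fm <- .mapFlat(map)
    withSeed(seed, .cpp_simulate_gametes(fm$chrStart, fm$gpos, fm$morgans,
                                         as.integer(n)))
}
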