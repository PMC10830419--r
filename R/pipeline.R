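#' @include AllClasses.R
NULL

.STAGES <- c("simulate", "distortion", "abc", "admixscan", "epistasis",
             "ils", "depletion", "dnds", "contacts")

.defaultConfig <- function() list(
    seed = 1,
    stages = .STAGES,
    map = list(nChrom = 4, sitesPerChrom = 60, morgans = 1, chromBp = 25e6),
    model = list(chromA = "2", posA = 8e6, sA = 0.996, hA = 0.12,
                 chromB = "4", posB = 16e6, sB = 0.91, hB = 0.09,
                 epistasisE = 0.5),
    cross = list(n = 400),
    swarm = list(N = 150, generations = 60, m = 0.5, mitoFreq = 0.5),
    abc = list(nSims = 200000, tolerance = 0.05),
    admixscan = list(fpr = 0.10, nReps = 50),
    epistasis = list(nPerm = 2000),
    ils = list(T = 250000, muAverage = 5e-8, muMinimum = 2e-8, L = 16500,
               nSims = 5000),
    depletion = list(windowBp = 250000, nPerm = 5000),
    dnds = list(nGenes = 40, nCodons = 120),
    contacts = list(caCutoff = 10, scCutoff = 12))

# deep merge of user config over defaults
.mergeConfig <- function(base, user) {
    for (k in names(user)) {
        base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
            .mergeConfig(base[[k]], user[[k]]) else user[[k]]
    }
    base
}

#' Run the end-to-end demonstration pipeline
#'
#' Simulates an F2 cross and two hybrid swarms under a two-locus
#' mitonuclear incompatibility model, then runs every analysis stage —
#' distortion scan, ABC selection inference, admixture scan with simulated
#' threshold, epistasis tests, ILS simulation, replicated-depletion test,
#' dN/dS counting and contact classification — writing per-stage artifacts
#' under \code{outDir} (\code{data/}, \code{scans/}, \code{abc/},
#' \code{tests/}) and an aggregate \code{report.json}. All randomness is
#' keyed from the root \code{seed} with fixed per-stage offsets, so a rerun
#' with the same configuration is reproducible; the configuration's MD5
#' hash is recorded in the report.
#'
#' @param config a configuration list, a YAML file path, or \code{NULL}
#'   for the built-in demo configuration. Unknown stage names are rejected
#'   before any computation.
#' @param outDir output directory (created if needed).
#' @return The report, invisibly (also written to
#'   \code{file.path(outDir, "report.json")}).
#' @export
runPipeline <- function(config = NULL, outDir = tempfile("mitoscan_run_")) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- .mergeConfig(.defaultConfig(), if (is.null(config)) list() else config)
    bad <- setdiff(cfg$stages, .STAGES)
    if (length(bad)) stop("unknown stage name '", bad[1], "'")
    for (d in c("", "data", "scans", "abc", "tests"))
        dir.create(file.path(outDir, d), recursive = TRUE, showWarnings = FALSE)
    cfgFile <- file.path(outDir, "config.yaml")
    yaml::write_yaml(cfg, cfgFile)
    cfgHash <- unname(tools::md5sum(cfgFile))
    seed <- cfg$seed
    report <- list(configHash = cfgHash, seed = seed, stages = list())
    saveReport <- function() jsonlite::write_json(
        report, file.path(outDir, "report.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
    runStage <- function(name, fun) {
        if (!(name %in% cfg$stages)) return()
        res <- tryCatch(fun(), error = function(e) {
            saveReport()
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
        report$stages[[name]] <<- res
        saveReport()
    }

    map <- geneticMap(cfg$map$nChrom, cfg$map$sitesPerChrom,
                      cfg$map$morgans, cfg$map$chromBp)
    mc <- cfg$model
    model <- incompatibilityModel(
        chrom = c(mc$chromA, mc$chromB), pos = c(mc$posA, mc$posB),
        s = c(mc$sA, mc$sB), h = c(mc$hA, mc$hB),
        epistasis = list(locusA = 2, locusB = 1, mitoPartner = "malinche",
                         e = mc$epistasisE))
    env <- new.env()

    runStage("simulate", function() {
        env$cross <- simulateCross(cfg$cross$n, model, map, seed = seed + 1)
        env$swarm1 <- simulateSwarm(cfg$swarm$N, cfg$swarm$generations,
                                    cfg$swarm$m, cfg$swarm$mitoFreq,
                                    model, map, seed = seed + 2,
                                    requirePolymorphicMito = TRUE)
        env$swarm2 <- simulateSwarm(cfg$swarm$N, cfg$swarm$generations,
                                    cfg$swarm$m, cfg$swarm$mitoFreq,
                                    model, map, seed = seed + 3,
                                    requirePolymorphicMito = TRUE)
        writeAncestryMatrix(env$cross, file.path(outDir, "data", "cross.tsv"))
        writeAncestryMatrix(env$swarm1, file.path(outDir, "data", "swarm1.tsv"))
        writeAncestryMatrix(env$swarm2, file.path(outDir, "data", "swarm2.tsv"))
        list(cross = ncol(env$cross), swarm = ncol(env$swarm1))
    })

    runStage("distortion", function() {
        s <- siteAncestrySummary(env$cross)
        regions <- findDistortedRegions(s)
        out <- data.frame(chrom = as.character(seqnames(s)), pos = start(s),
                          meanAncestry = mcols(s)$meanAncestry, n = mcols(s)$n)
        write.table(out, file.path(outDir, "scans", "distortion_sites.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        bed <- data.frame(chrom = as.character(seqnames(regions)),
                          start = start(regions), end = end(regions),
                          peakMean = mcols(regions)$peakMean)
        write.table(bed, file.path(outDir, "scans", "distortion_regions.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        list(envelope = metadata(s)$envelope, nRegions = length(regions),
             regions = bed)
    })

    runStage("abc", function() {
        calls <- ancestryCalls(env$cross)[.siteAt(env$cross, mc$chromA, mc$posA), ]
        obs <- c(sum(calls == 0, na.rm = TRUE), sum(calls == 1, na.rm = TRUE),
                 sum(calls == 2, na.rm = TRUE))
        fit <- abcFit(obs, nSims = cfg$abc$nSims,
                      tolerance = cfg$abc$tolerance, seed = seed + 4)
        write.table(acceptedDraws(fit),
                    file.path(outDir, "abc", "accepted.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        sm <- posteriorSummary(fit)
        out <- list(observed = obs, map = as.list(sm$map),
                    ci = list(s = unname(sm$ci["s", ]), h = unname(sm$ci["h", ])),
                    acceptanceRate = sm$acceptanceRate)
        jsonlite::write_json(out, file.path(outDir, "abc", "summary.json"),
                             auto_unbox = TRUE, digits = NA)
        out
    })

    runStage("admixscan", function() {
        scan <- partialCorrelationScan(env$swarm1)
        thr <- nullThreshold(env$swarm1, fpr = cfg$admixscan$fpr,
                             nReps = cfg$admixscan$nReps,
                             generations = cfg$swarm$generations,
                             map = map, seed = seed + 5)
        scan <- callPeaks(scan, thr)
        st <- scanStats(scan)
        write.table(data.frame(chrom = as.character(seqnames(st)),
                               pos = start(st), r = mcols(st)$r),
                    file.path(outDir, "scans", "admixscan.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        pk <- scanPeaks(scan)
        peaks <- data.frame(chrom = as.character(seqnames(pk)),
                            start = start(pk), end = end(pk),
                            apexPos = mcols(pk)$apexPos,
                            apexR = mcols(pk)$apexR)
        write.table(peaks, file.path(outDir, "scans", "peaks.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(list(threshold = as.numeric(thr),
                                  fpr = cfg$admixscan$fpr),
                             file.path(outDir, "scans", "threshold.json"),
                             auto_unbox = TRUE, digits = NA)
        list(threshold = as.numeric(thr), peaks = peaks)
    })

    runStage("epistasis", function() {
        tab <- twoLocusTable(env$cross, mc$chromA, mc$posA, mc$chromB, mc$posB)
        chi <- tryCatch(suppressWarnings(chisqIndependence(tab)), error = function(e)
            list(statistic = NA, df = NA, p.value = NA))
        perm <- hetDepletionPermutation(env$cross, mc$chromB, mc$posB,
                                        mc$chromA, mc$posA,
                                        nPerm = cfg$epistasis$nPerm,
                                        shB = c(mc$sA, mc$hA),
                                        seed = seed + 6)
        out <- list(chisq = list(statistic = chi$statistic, df = chi$df,
                                 p.value = chi$p.value),
                    hetDepletion = perm[c("p.value", "observedHetFraction",
                                          "nullExpectation", "nSurvivors")])
        jsonlite::write_json(out, file.path(outDir, "tests", "epistasis.json"),
                             auto_unbox = TRUE, digits = NA)
        out
    })

    runStage("ils", function() {
        ic <- cfg$ils
        dObs <- 0.2 * 2 * ic$muAverage * ic$T  # introgressed: far below expectation
        res <- lapply(c(average = ic$muAverage, minimum = ic$muMinimum),
                      function(mu) ilsSimulation(dObs, ic$T, mu, ic$L,
                                                 ic$nSims, seed = seed + 7))
        out <- list(dObs = dObs,
                    pAverage = res$average$p.value,
                    pMinimum = res$minimum$p.value)
        jsonlite::write_json(out, file.path(outDir, "tests", "ils.json"),
                             auto_unbox = TRUE, digits = NA)
        out
    })

    runStage("depletion", function() {
        pops <- list(pop1 = windowAncestry(env$swarm1, cfg$depletion$windowBp),
                     pop2 = windowAncestry(env$swarm2, cfg$depletion$windowBp))
        loci <- data.frame(chrom = c(mc$chromA, mc$chromB),
                           pos = c(mc$posA, mc$posB))
        res <- replicatedDepletionTest(pops, loci,
                                       nPerm = cfg$depletion$nPerm,
                                       seed = seed + 8)
        out <- list(p.value = res$p.value, observed = res$observed,
                    nWindows = res$nWindows)
        jsonlite::write_json(out, file.path(outDir, "tests", "depletion.json"),
                             auto_unbox = TRUE, digits = NA)
        out
    })

    runStage("dnds", function() {
        dc <- cfg$dnds
        withSeed(seed + 9, {
            genes <- lapply(seq_len(dc$nGenes), function(g) {
                aln <- simulateCodonAlignment(dc$nCodons, list(
                    birchmanni = c(N = rpois(1, 1), S = rpois(1, 2)),
                    malinche = c(N = rpois(1, 1), S = rpois(1, 2))))
                cbind(gene = sprintf("gene%02d", g),
                      ng86Counts(as.character(aln[["birchmanni"]]),
                                 as.character(aln[["malinche"]])))
            })
            focal <- simulateCodonAlignment(dc$nCodons,
                                            list(birchmanni = c(N = 4, S = 0)))
            genes[[dc$nGenes + 1]] <- cbind(gene = "ndufs5_like",
                ng86Counts(as.character(focal[["birchmanni"]]),
                           as.character(focal[["malinche"]])))
            tab <- do.call(rbind, genes)
            write.table(tab, file.path(outDir, "tests", "dnds.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            pol <- polarizeSubstitutions(focal)
            list(focalOmegaDisplay = tab$omegaDisplay[tab$gene == "ndufs5_like"],
                 focalBranchCounts = pol[pol$taxon == "birchmanni",
                                         c("N", "S")])
        })
    })

    runStage("contacts", function() {
        paths <- vapply(1:2, function(m) {
            f <- file.path(outDir, "data", sprintf("toy_model%d.pdb", m))
            writeToyStructure(.toyComplexAtoms(jitter = (m - 1) * 0.5), f)
            f
        }, character(1))
        models <- loadStructures(paths)
        res <- contactPairs(models, "A", c(1, 2), "B", c(1, 2),
                            cfg$contacts$caCutoff, cfg$contacts$scCutoff)
        write.table(res, file.path(outDir, "tests", "contacts.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        list(nStrong = sum(res$class == "strong"),
             nWeak = sum(res$class == "weak"))
    })

    saveReport()
    invisible(report)
}

# small two-chain system: residue A1-B1 close, A2-B2 distant
.toyComplexAtoms <- function(jitter = 0) {
    res <- function(chain, resno, ox, oy) {
        data.frame(chain = chain, resno = resno, resid = "ALA",
                   elety = c("N", "CA", "C", "O", "CB"),
                   x = ox + c(-1.2, 0, 1.2, 2.2, 0) + jitter,
                   y = oy + c(0, 0, 0, 0, 1.5), z = 0)
    }
    rbind(res("A", 1, 0, 0), res("A", 2, 0, 30),
          res("B", 1, 6, 0), res("B", 2, 40, 30))
}
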