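test_that("PDB loading validates ATOM records and cross-model numbering", {
    paths <- writeControlledModels(caD = c(5, 5), scD = c(5, 5))
    models <- loadStructures(paths)
    expect_length(models, 2)
    expect_setequal(unique(models[[1]]$chain), c("A", "B"))
    # HETATM-only file
    f <- tempfile(fileext = ".pdb")
    writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00",
                 "END"), f)
    expect_error(loadStructures(f), "no ATOM records")
    # mismatched numbering across models
    bad <- writeControlledModels(caD = c(5), scD = c(5))
    atoms <- data.frame(chain = "A", resno = 9, resid = "ALA",
                        elety = c("N", "CA", "C", "O", "CB"),
                        x = 0:4, y = 0, z = 0)
    f2 <- tempfile(fileext = ".pdb")
    writeToyStructure(atoms, f2)
    expect_error(loadStructures(c(bad, f2)), "numbering mismatch")
})

test_that("contact classes follow the all-models CA rule and any-model side-chain rule", {
    # CA 5 A in all three models -> strong
    strong <- loadStructures(writeControlledModels(c(5, 5, 5), c(20, 20, 20)))
    expect_identical(contactPairs(strong, "A", 1, "B", 1)$class, "strong")
    # CA (9, 9, 11): fails "all models"; side chain 11.5 in model 1 -> weak
    weak <- loadStructures(writeControlledModels(c(9, 9, 11), c(11.5, 30, 30)))
    res <- contactPairs(weak, "A", 1, "B", 1)
    expect_identical(res$class, "weak")
    # inclusive boundaries: CA exactly 10.0 everywhere -> strong;
    # side chain exactly 12.0 in one model -> weak
    expect_identical(contactPairs(loadStructures(
        writeControlledModels(c(10, 10), c(30, 30))), "A", 1, "B", 1)$class,
        "strong")
    expect_identical(contactPairs(loadStructures(
        writeControlledModels(c(11, 11), c(12, 30))), "A", 1, "B", 1)$class,
        "weak")
    # beyond both cutoffs -> none
    expect_identical(contactPairs(loadStructures(
        writeControlledModels(c(15, 15), c(20, 20))), "A", 1, "B", 1)$class,
        "none")
    # adding a distant model can demote strong but never promote
    demoted <- loadStructures(writeControlledModels(c(5, 5, 25), c(30, 30, 30)))
    expect_identical(contactPairs(demoted, "A", 1, "B", 1)$class, "none")
})

test_that("classification is symmetric in chains and empty inputs give empty output", {
    models <- loadStructures(writeControlledModels(c(8, 8), c(9, 9)))
    ab <- contactPairs(models, "A", 1, "B", 1)
    ba <- contactPairs(models, "B", 1, "A", 1)
    expect_identical(ab$class, ba$class)
    expect_equal(ab$maxCA, ba$maxCA)
    expect_identical(nrow(contactPairs(models, "A", integer(), "B", 1)), 0L)
    expect_error(contactPairs(models, "A", 99, "B", 1), "absent from model")
})

test_that("glycine residues fall back to CA for the side-chain rule", {
    mk <- function(dir) {
        # glycine on chain A (no CB), alanine on chain B 11 A away
        a <- data.frame(chain = "A", resno = 1, resid = "GLY",
                        elety = c("N", "CA", "C", "O"),
                        x = c(-1.2, 0, 1.2, 2.2), y = 0, z = 0)
        b <- data.frame(chain = "B", resno = 1, resid = "ALA",
                        elety = c("N", "CA", "C", "O", "CB"),
                        x = c(9.8, 11, 12.2, 13.2, 11), y = c(0, 0, 0, 0, 1.5),
                        z = 0)
        f <- tempfile(fileext = ".pdb")
        writeToyStructure(rbind(a, b), f)
        f
    }
    models <- loadStructures(c(mk(), mk()))
    res <- contactPairs(models, "A", 1, "B", 1)
    # CA-CA = 11 > 10 (not strong); glycine side chain = CA at distance
    # 11 to B's CB at sqrt(11^2+...)... min(CA->CB, CA->?) <= 12 -> weak
    expect_identical(res$class, "weak")
})

test_that("classification matches an all-atom brute-force oracle on random structures", {
    set.seed(61)
    backbone <- c("N", "CA", "C", "O", "OXT")
    for (rep in 1:4) {
        mkModel <- function(jit) {
            rows <- list()
            for (chain in c("A", "B")) for (resno in 1:3) {
                base <- c(runif(1, 0, 25), runif(1, 0, 25), runif(1, 0, 25))
                nAtoms <- sample(3:6, 1)
                elety <- c("CA", sample(c("N", "C", "O", "CB", "CG", "CD1"),
                                        nAtoms - 1))
                rows[[length(rows) + 1]] <- data.frame(
                    chain = chain, resno = resno, resid = "LEU", elety = elety,
                    x = base[1] + runif(nAtoms, -1.5, 1.5) + jit,
                    y = base[2] + runif(nAtoms, -1.5, 1.5),
                    z = base[3] + runif(nAtoms, -1.5, 1.5))
            }
            do.call(rbind, rows)
        }
        set.seed(100 + rep)
        m1 <- mkModel(0)
        set.seed(100 + rep)
        m2 <- mkModel(0.8)
        dir <- tempfile(); dir.create(dir)
        f1 <- file.path(dir, "m1.pdb"); f2 <- file.path(dir, "m2.pdb")
        writeToyStructure(m1, f1); writeToyStructure(m2, f2)
        models <- loadStructures(c(f1, f2))
        res <- contactPairs(models, "A", 1:3, "B", 1:3)
        # independent brute-force double loop over atoms
        for (i in seq_len(nrow(res))) {
            caAll <- c(); scAny <- FALSE
            for (mm in list(m1, m2)) {
                A <- mm[mm$chain == "A" & mm$resno == res$resA[i], ]
                B <- mm[mm$chain == "B" & mm$resno == res$resB[i], ]
                dist <- function(p, q)
                    sqrt((p$x - q$x)^2 + (p$y - q$y)^2 + (p$z - q$z)^2)
                caAll <- c(caAll, dist(A[A$elety == "CA", ], B[B$elety == "CA", ]))
                scA <- A[!(A$elety %in% backbone), ]
                scB <- B[!(B$elety %in% backbone), ]
                if (nrow(scA) == 0) scA <- A[A$elety == "CA", ]
                if (nrow(scB) == 0) scB <- B[B$elety == "CA", ]
                mind <- Inf
                for (ii in seq_len(nrow(scA))) for (jj in seq_len(nrow(scB)))
                    mind <- min(mind, dist(scA[ii, ], scB[jj, ]))
                if (mind <= 12) scAny <- TRUE
            }
            want <- if (all(caAll <= 10)) "strong" else if (scAny) "weak" else "none"
            expect_identical(res$class[i], want)
        }
    }
})
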