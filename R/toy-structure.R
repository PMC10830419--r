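#' @include mitoscan-package.R
NULL

#' Write a synthetic multi-chain structure in PDB format
#'
#' Serializes an atom table to minimal PDB ATOM records readable by
#' \code{bio3d::read.pdb}. Used to build small synthetic coordinate sets
#' for exercising the contact classifier; not a general PDB writer.
#'
#' @param atoms \code{data.frame} with columns \code{chain}, \code{resno},
#'   \code{resid} (3-letter code), \code{elety} (atom name) and
#'   \code{x}, \code{y}, \code{z} in Angstrom.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @examples
#' atoms <- data.frame(chain = "A", resno = 1, resid = "ALA",
#'                     elety = c("N", "CA", "C", "O", "CB"),
#'                     x = c(0, 1.5, 2.5, 3.5, 1.5), y = 0, z = 0:4)
#' writeToyStructure(atoms, tempfile(fileext = ".pdb"))
#' @export
writeToyStructure <- function(atoms, path) {
    need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
    stopifnot(all(need %in% colnames(atoms)))
    lines <- vapply(seq_len(nrow(atoms)), function(i) {
        a <- atoms[i, ]
        sprintf("ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                i, a$elety, a$resid, a$chain, as.integer(a$resno),
                a$x, a$y, a$z, 1, 0)
    }, character(1))
    writeLines(c(lines, "END"), path)
    invisible(path)
}
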