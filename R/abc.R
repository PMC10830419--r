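#' @include distortion.R
NULL

#' ABC posterior for selection and dominance coefficients
#'
#' Accepted \code{(s, h)} draws from rejection ABC, with the maximum a
#' posteriori point estimate (mode of a boundary-reflected 2-D kernel
#' density over the accepted draws) and marginal 95\% credible intervals.
#'
#' @slot accepted \code{data.frame} of accepted draws (\code{s}, \code{h},
#'   \code{distance}).
#' @slot map named numeric \code{(s, h)} MAP estimate (NA if not computed).
#' @slot ci 2x2 matrix of marginal credible bounds (rows \code{s},
#'   \code{h}; columns \code{lower}, \code{upper}).
#' @slot nSims,tolerance,mode ABC settings used.
#' @slot observed observed genotype counts the fit targeted.
#' @exportClass ABCPosterior
setClass("ABCPosterior",
    representation(accepted = "data.frame", map = "numeric", ci = "matrix",
                   nSims = "numeric", tolerance = "numeric",
                   mode = "character", observed = "numeric"))

setValidity("ABCPosterior", function(object) {
    msg <- NULL
    if (identical(object@mode, "fraction") &&
        nrow(object@accepted) != ceiling(object@tolerance * object@nSims))
        msg <- c(msg, "accepted count must equal ceiling(tolerance * nSims)")
    if (!all(is.na(object@map)) &&
        (any(object@map < 0) || any(object@map > 1)))
        msg <- c(msg, "MAP must lie in the prior support [0, 1]^2")
    if (any(object@ci < 0 - 1e-12) || any(object@ci > 1 + 1e-12))
        msg <- c(msg, "credible bounds must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "ABCPosterior", function(object) {
    cat("ABCPosterior:", nrow(object@accepted), "accepted of",
        object@nSims, "simulations (tolerance", object@tolerance, ")\n")
    if (!all(is.na(object@map)))
        cat(sprintf("  MAP: s = %.3f, h = %.3f\n",
                    object@map["s"], object@map["h"]))
    cat(sprintf("  95%% CI: s = %.3f-%.3f, h = %.3f-%.3f\n",
                object@ci["s", 1], object@ci["s", 2],
                object@ci["h", 1], object@ci["h", 2]))
})

#' @describeIn abcFit accepted draws accessor.
#' @export
acceptedDraws <- function(posterior) posterior@accepted

#' @describeIn abcFit MAP accessor (named numeric \code{s}, \code{h}).
#' @export
abcMAP <- function(posterior) posterior@map

#' @describeIn abcFit credible-interval accessor (2x2 matrix of marginal
#'   equal-tailed 2.5\%/97.5\% quantiles of the accepted draws).
#' @export
abcCI <- function(posterior) posterior@ci

#' @describeIn abcFit highest-posterior-density credible intervals from a
#'   boundary-reflected 1-D KDE per parameter. Unlike equal-tailed sample
#'   quantiles, the HPD interval closes onto the prior boundary when the
#'   posterior piles against it (e.g. a fully recessive \code{h = 0} or a
#'   lethal \code{s = 1}), which equal-tailed intervals can never cover.
#' @param level credible level for the HPD interval.
#' @export
abcHPD <- function(posterior, level = 0.95) {
    acc <- acceptedDraws(posterior)
    rbind(s = .hpdInterval(acc$s, level),
          h = .hpdInterval(acc$h, level))
}

# 95% highest-density region of a boundary-reflected KDE on [0, 1];
# returns the interval hull of the selected grid cells.
.hpdInterval <- function(x, level = 0.95, gridSize = 512) {
    if (length(unique(x)) == 1L) return(c(lower = x[1], upper = x[1]))
    bw <- max(tryCatch(bw.nrd0(x), error = function(e) 0),
              1 / (gridSize - 1), 1e-6)
    est <- KernSmooth::bkde(c(x, -x, 2 - x), bandwidth = bw,
                            gridsize = gridSize, range.x = c(0, 1))
    f <- pmax(est$y, 0)
    f <- f / sum(f)
    ord <- order(f, decreasing = TRUE)
    keep <- ord[seq_len(which(cumsum(f[ord]) >= level)[1])]
    c(lower = min(est$x[keep]), upper = max(est$x[keep]))
}

#' Simulate F2 survivor genotype counts at one locus
#'
#' One multinomial draw of \code{n} survivors from the closed-form survivor
#' frequencies [expectedSurvivingFrequencies()]; the ABC simulation kernel.
#'
#' @param s,h selection and dominance coefficients.
#' @param n number of surviving offspring.
#' @param seed optional integer seed.
#' @return Named integer counts \code{homPenalized}, \code{het},
#'   \code{homOther}.
#' @export
simulateF2Counts <- function(s, h, n, seed = NULL) {
    f <- expectedSurvivingFrequencies(s, h)
    withSeed(seed, setNames(as.integer(rmultinom(1, n, f)), names(f)))
}

#' Rejection-ABC fit of selection and dominance at a focal locus
#'
#' Estimates the strength and dominance of viability selection against one
#' genotype class from observed F2 survivor genotype counts on a matched
#' mitochondrial background. Draws \code{(s, h)} from independent
#' Uniform(0, 1) priors and simulates multinomial survivor counts from the
#' closed-form survivor model. Two acceptance rules are offered. The
#' default, \code{mode = "relative"}, accepts a simulation when every
#' simulated genotype frequency lies within \code{tolerance} (relative) of
#' its observed value; because the acceptance band around a rare genotype
#' class is proportionally narrow, this retains the information carried by
#' rare penalized homozygotes and concentrates the posterior sharply (a
#' raw-distance rule lets the two common classes dominate and flattens the
#' posterior over a wide range of \code{s}). \code{mode = "fraction"}
#' instead keeps the fraction \code{tolerance} of draws closest to the
#' observed genotype-frequency vector in Euclidean distance; an absolute
#' distance cutoff is available via \code{absoluteTolerance}. The MAP is
#' the mode of a 2-D Gaussian kernel density over accepted draws on a
#' 200x200 grid, with draws reflected at the \code{[0, 1]} boundaries so
#' modes at the edge of the support (e.g. near-lethal \code{s}) are not
#' biased inward.
#'
#' @param observed observed genotype counts, in the order
#'   (penalized homozygote, heterozygote, other homozygote); a named
#'   vector as from [simulateF2Counts()] also works.
#' @param nSims number of prior draws (default 500,000).
#' @param tolerance relative acceptance band (\code{mode = "relative"}) or
#'   acceptance fraction (\code{mode = "fraction"}); default 0.05.
#' @param mode acceptance rule, \code{"relative"} (default) or
#'   \code{"fraction"}.
#' @param seed optional integer seed.
#' @param computeMAP compute the KDE MAP (set \code{FALSE} to fit many
#'   replicates quickly when only credible intervals are needed).
#' @param gridSize KDE grid resolution per axis.
#' @param absoluteTolerance if non-\code{NULL}, accept all draws with
#'   distance below this value instead of the closest fraction.
#' @return An \linkS4class{ABCPosterior}.
#' @examples
#' fit <- abcFit(c(28, 610, 305), nSims = 20000, seed = 1)
#' abcMAP(fit)
#' @export
abcFit <- function(observed, nSims = 500000, tolerance = 0.05,
                   mode = c("relative", "fraction"), seed = NULL,
                   computeMAP = TRUE, gridSize = 200,
                   absoluteTolerance = NULL) {
    mode <- match.arg(mode)
    observed <- as.numeric(observed)
    stopifnot(length(observed) == 3, all(observed >= 0), nSims >= 1000,
              tolerance > 0, tolerance < 1)
    n <- sum(observed)
    if (n == 0) stop("observed counts sum to zero")
    obsFreq <- observed / n
    if (!is.null(absoluteTolerance)) mode <- "absolute"
    res <- withSeed(seed, {
        s <- runif(nSims); h <- runif(nSims)
        w1 <- 0.25 * (1 - s); w2 <- 0.5 * (1 - h * s); w3 <- 0.25
        z <- w1 + w2 + w3
        k1 <- rbinom(nSims, n, w1 / z)
        k2 <- rbinom(nSims, n - k1, w2 / (w2 + w3))
        k3 <- n - k1 - k2
        d <- sqrt((k1 / n - obsFreq[1])^2 + (k2 / n - obsFreq[2])^2 +
                  (k3 / n - obsFreq[3])^2)
        keep <- switch(mode,
            relative = {
                band <- tolerance * pmax(obsFreq, 1 / n)
                which(abs(k1 / n - obsFreq[1]) <= band[1] &
                      abs(k2 / n - obsFreq[2]) <= band[2] &
                      abs(k3 / n - obsFreq[3]) <= band[3])
            },
            fraction = order(d)[seq_len(ceiling(tolerance * nSims))],
            absolute = which(d <= absoluteTolerance))
        data.frame(s = s[keep], h = h[keep], distance = d[keep])
    })
    if (nrow(res) == 0)
        stop("no simulations accepted; widen the tolerance or check the counts")
    ci <- rbind(s = quantile(res$s, c(0.025, 0.975), names = FALSE),
                h = quantile(res$h, c(0.025, 0.975), names = FALSE))
    colnames(ci) <- c("lower", "upper")
    map <- c(s = NA_real_, h = NA_real_)
    if (computeMAP) map <- .abcMAP(res$s, res$h, gridSize)
    new("ABCPosterior", accepted = res, map = map, ci = ci,
        nSims = nSims, tolerance = tolerance, mode = mode,
        observed = observed)
}

# Mode of a boundary-reflected 2-D Gaussian KDE over [0,1]^2. Bandwidths
# follow Silverman's rule per axis, floored at one grid cell so the mode
# search is not dominated by discretization noise; draws are reflected
# through all four edges (and corners) before binning.
.abcMAP <- function(s, h, gridSize = 200) {
    if (length(unique(s)) == 1L && length(unique(h)) == 1L)
        return(c(s = s[1], h = h[1]))
    bw <- function(v) {
        b <- tryCatch(bw.nrd0(v), error = function(e) 0)
        max(b, 1 / (gridSize - 1), 1e-6)
    }
    sAll <- rep(c(s, -s, 2 - s), times = 3)
    hAll <- c(rep(h, 3), rep(-h, 3), rep(2 - h, 3))
    est <- KernSmooth::bkde2D(cbind(sAll, hAll),
                              bandwidth = c(bw(s), bw(h)),
                              gridsize = c(gridSize, gridSize),
                              range.x = list(c(0, 1), c(0, 1)))
    peak <- which(est$fhat == max(est$fhat), arr.ind = TRUE)[1, ]
    c(s = est$x1[peak[1]], h = est$x2[peak[2]])
}

#' Summarize an ABC posterior
#'
#' @param posterior an \linkS4class{ABCPosterior} with at least 100
#'   accepted draws.
#' @param bins histogram bins per axis for the prior-posterior overlap
#'   coefficient.
#' @return List with \code{map}, \code{ci}, \code{acceptanceRate},
#'   \code{nAccepted} and \code{priorOverlap} (per-parameter overlap
#'   coefficient between the Uniform(0,1) prior and the posterior
#'   histogram; 1 means the data were uninformative).
#' @export
posteriorSummary <- function(posterior, bins = 20) {
    acc <- acceptedDraws(posterior)
    if (nrow(acc) < 100)
        stop("only ", nrow(acc),
             " accepted draws; increase nSims (need >= 100)")
    overlap <- function(v) {
        p <- tabulate(pmin(pmax(ceiling(v * bins), 1L), bins), bins) / length(v)
        sum(pmin(p, 1 / bins))
    }
    map <- abcMAP(posterior)
    if (all(is.na(map))) map <- .abcMAP(acc$s, acc$h)
    list(map = map, ci = abcCI(posterior),
         acceptanceRate = nrow(acc) / posterior@nSims,
         nAccepted = nrow(acc),
         priorOverlap = c(s = overlap(acc$s), h = overlap(acc$h)))
}
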