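## Synthetic-data generators. Every generator is a pure function of its
## arguments plus a seed, so any downstream result is reproducible from
## the call alone. The linear generator emulates the statistical shape of
## a VSA-descriptor QSAR table: non-negative columns on O(100) Angstrom^2
## scales and a linear pIC50 signal with Gaussian noise in pIC50 units.

#' Generate a linear-signal descriptor dataset
#'
#' Columns of X are independent uniforms on [0, s_j] with per-column scales
#' s_j drawn once from \code{scaleRange}; the response is
#' y = beta0 + X beta + N(0, noiseSd^2). When \code{pic50Range} is given
#' the noiseless signal is mapped linearly onto that range first (the
#' returned \code{beta}/\code{beta0} are adjusted accordingly, so they stay
#' the ground truth of the returned data).
#'
#' @param n compounds.
#' @param p descriptors.
#' @param beta true coefficient vector (length p); default alternating
#'   small weights on a VSA-like scale.
#' @param beta0 true intercept.
#' @param scaleRange range the per-column scales are drawn from
#'   (Angstrom^2-like magnitudes).
#' @param noiseSd Gaussian noise standard deviation in pIC50 units.
#' @param pic50Range optional target range for the noiseless signal,
#'   e.g. \code{c(5.38, 7.60)}.
#' @param seed integer seed.
#' @return list with \code{X} (with column names \code{d1..dp}), \code{y},
#'   true \code{beta}, \code{beta0} and the generating \code{spec}.
#' @examples
#' d <- genLinearDataset(n = 10, p = 3, noiseSd = 0, seed = 1)
#' max(abs(d$y - (d$beta0 + d$X %*% d$beta)))   # exactly linear
#' @export
genLinearDataset <- function(n, p, beta = NULL, beta0 = 6,
                             scaleRange = c(20, 200), noiseSd = 0.1,
                             pic50Range = NULL, seed = 1L) {
    if (n < 1L || p < 1L || noiseSd < 0)
        ck2_error("invalid synthetic spec (need n >= 1, p >= 1, noiseSd >= 0)",
                  "ck2qsar_synthetic_error")
    if (is.null(beta)) beta <- rep_len(c(0.02, -0.01, 0.015, -0.005), p)
    if (length(beta) != p)
        ck2_error("beta must have length p", "ck2qsar_synthetic_error")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    scales <- stats::runif(p, scaleRange[1], scaleRange[2])
    X <- vapply(seq_len(p), function(j) stats::runif(n, 0, scales[j]),
                numeric(n))
    X <- matrix(X, nrow = n, dimnames = list(NULL, paste0("d", seq_len(p))))
    ylin <- as.numeric(beta0 + X %*% beta)
    if (!is.null(pic50Range)) {
        rng <- range(ylin)
        if (diff(rng) > 0) {
            b <- diff(pic50Range) / diff(rng)
            a <- pic50Range[1] - b * rng[1]
            beta <- beta * b
            beta0 <- a + b * beta0
            ylin <- a + b * ylin
        }
    }
    y <- ylin + stats::rnorm(n, 0, noiseSd)
    list(X = X, y = y, beta = stats::setNames(beta, colnames(X)),
         beta0 = beta0,
         spec = list(n = n, p = p, scaleRange = scaleRange,
                     noiseSd = noiseSd, pic50Range = pic50Range, seed = seed))
}

#' Generate toy carbon-skeleton graphs with known topology
#'
#' Builds a single-bonded carbon skeleton in the requested topology; these
#' have analytically known Wiener path numbers (path: (n^3 - n)/6; cycle-6:
#' 27; star on n atoms: (n - 1)^2) and serve as oracles for the
#' distance-matrix machinery. Valence limits carbon to 4 neighbours, so
#' stars are capped at n = 5 and complete graphs at n = 5.
#'
#' @param family one of \code{"path"}, \code{"cycle"}, \code{"star"},
#'   \code{"complete"}.
#' @param n atom count (\code{n >= 1}; \code{>= 3} for cycles).
#' @return a \linkS4class{MolecularGraph}.
#' @examples
#' wienerPathNumber(genToyGraphs("path", 4))   # 10
#' @export
genToyGraphs <- function(family = c("path", "cycle", "star", "complete"), n) {
    family <- match.arg(family)
    n <- as.integer(n)
    if (n < 1L) ck2_error("n must be >= 1", "ck2qsar_synthetic_error")
    edges <- switch(family,
        path = if (n == 1L) cbind(integer(), integer())
               else cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
        cycle = {
            if (n < 3L) ck2_error("a cycle needs n >= 3", "ck2qsar_synthetic_error")
            rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), c(n, 1L))
        },
        star = {
            if (n > 5L)
                ck2_error("carbon valence caps star arms at 4 (n <= 5)",
                          "ck2qsar_synthetic_error")
            if (n == 1L) cbind(integer(), integer())
            else cbind(rep(1L, n - 1L), seq_len(n - 1L) + 1L)
        },
        complete = {
            if (n > 5L)
                ck2_error("carbon valence caps complete graphs at n <= 5",
                          "ck2qsar_synthetic_error")
            if (n == 1L) cbind(integer(), integer())
            else t(utils::combn(n, 2L))
        })
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
    atoms <- data.frame(element = rep("C", n), charge = 0L, aromatic = FALSE,
                        hcount = 4L - deg)
    bonds <- data.frame(i = as.integer(edges[, 1]), j = as.integer(edges[, 2]),
                        order = rep(1, nrow(edges)))
    bonds$korder <- rep(1, nrow(edges))
    MolecularGraph(atoms, bonds)
}

#' Generate a synthetic activity table
#'
#' IC50 values are drawn log-uniformly within the requested nM range
#' (mirroring the typical spread of a kinase-inhibitor training set) and
#' transformed to pIC50.
#'
#' @param n number of compounds (0 allowed: empty table).
#' @param ic50Range nM interval, default \code{c(25, 4100)}.
#' @param seed integer seed.
#' @return data.frame with columns \code{id}, \code{ic50_nM}, \code{pic50}.
#' @export
genActivityTable <- function(n, ic50Range = c(25, 4100), seed = 1L) {
    if (any(ic50Range <= 0) || ic50Range[2] < ic50Range[1])
        ck2_error("invalid IC50 range", "ck2qsar_synthetic_error")
    if (n == 0L)
        return(data.frame(id = character(), ic50_nM = numeric(),
                          pic50 = numeric()))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    ic50 <- exp(stats::runif(n, log(ic50Range[1]), log(ic50Range[2])))
    data.frame(id = sprintf("synth%03d", seq_len(n)), ic50_nM = ic50,
               pic50 = toPIC50(ic50))
}
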