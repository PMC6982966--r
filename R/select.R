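## Descriptor selection: relative importance of fitted coefficients and
## contingency-table association statistics between quantile-binned
## descriptors and the binned response.

#' Relative importance of descriptors in a fitted model
#'
#' Importance of descriptor i is |b_i| * sigma_i scaled by the largest such
#' product, where sigma_i is the training-column standard deviation; the
#' measure is invariant to rescaling any column by a positive constant.
#' Descriptors scoring below the cutoff are flagged for removal.
#'
#' @param model a \linkS4class{PLSModel}.
#' @param X training descriptor matrix (defaults to the scaling recorded in
#'   the model).
#' @param cutoff retention threshold on the [0, 1] importance scale
#'   (default 0.1).
#' @return data.frame with columns \code{descriptor}, \code{importance},
#'   \code{retained}, ordered by decreasing importance.
#' @export
relativeImportance <- function(model, X = NULL, cutoff = 0.1) {
    b <- model@coefficients
    sds <- if (is.null(X)) {
        s <- model@xScales
        s[names(b)]
    } else apply(as.matrix(X)[, names(b), drop = FALSE], 2, stats::sd)
    raw <- abs(b) * sds
    if (max(raw) == 0)
        ck2_error("all coefficients are zero; importance undefined",
                  "ck2qsar_model_error")
    imp <- raw / max(raw)
    out <- data.frame(descriptor = names(b), importance = as.numeric(imp),
                      retained = as.numeric(imp) >= cutoff)
    out[order(-out$importance), , drop = FALSE]
}

.entropy <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
}

## quantile binning into at most B non-degenerate bins
.qbin <- function(x, B) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = B + 1)))
    if (length(br) < 2L) return(NULL)
    cut(x, breaks = br, include.lowest = TRUE)
}

#' Contingency-based descriptor screening
#'
#' Each descriptor and the response are binned into B quantile bins; the
#' resulting contingency table yields the chi-square statistic, Cramer's V,
#' the contingency coefficient C and the uncertainty coefficient U
#' (fraction of response entropy explained). A descriptor is retained when
#' Cramer's V or U meets its threshold. Constant descriptors score zero
#' and are dropped with a log entry.
#'
#' @param X descriptor matrix (compounds x descriptors).
#' @param y response vector.
#' @param bins number of quantile bins B (default 4); requires
#'   \code{n >= 2 * bins}.
#' @param vThreshold,uThreshold retention thresholds (defaults 0.3, 0.2).
#' @return data.frame with one row per descriptor: \code{chisq},
#'   \code{cramers_v}, \code{contingency_c}, \code{uncertainty},
#'   \code{retained}.
#' @export
contingencySelect <- function(X, y, bins = 4L, vThreshold = 0.3,
                              uThreshold = 0.2) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (n < 2L * bins)
        ck2_error(sprintf("need at least %d observations for %d bins",
                          2L * bins, bins), "ck2qsar_model_error")
    yb <- .qbin(y, bins)
    if (is.null(yb))
        ck2_error("response is constant", "ck2qsar_model_error")
    hy <- .entropy(table(yb))
    res <- lapply(colnames(X), function(d) {
        xb <- .qbin(X[, d], bins)
        if (is.null(xb)) {
            message("contingencySelect: descriptor '", d,
                    "' is constant; dropped")
            return(data.frame(descriptor = d, chisq = 0, cramers_v = 0,
                              contingency_c = 0, uncertainty = 0,
                              retained = FALSE))
        }
        tab <- table(xb, yb)
        exp_ <- outer(rowSums(tab), colSums(tab)) / n
        chisq <- sum((tab - exp_)^2 / exp_, na.rm = TRUE)
        k <- min(nrow(tab), ncol(tab))
        v <- if (k > 1) sqrt(chisq / (n * (k - 1))) else 0
        cc <- sqrt(chisq / (chisq + n))
        hx <- .entropy(rowSums(tab)); hxy <- .entropy(tab)
        u <- if (hy > 0) (hx + hy - hxy) / hy else 0
        data.frame(descriptor = d, chisq = chisq, cramers_v = v,
                   contingency_c = cc, uncertainty = u,
                   retained = v >= vThreshold || u >= uThreshold)
    })
    do.call(rbind, res)
}
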