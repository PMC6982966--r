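## Partial least squares regression (single response, NIPALS algorithm) on
## column-autoscaled data, with leave-one-out cross-validation and export
## of the latent model as one linear equation on the raw descriptor scale.

.check_xy <- function(X, y) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (nrow(X) != length(y))
        ck2_error("X and y dimensions disagree", "ck2qsar_model_error")
    if (nrow(X) < 3L)
        ck2_error("at least 3 observations are required", "ck2qsar_model_error")
    if (anyNA(X) || anyNA(y))
        ck2_error("missing values are not allowed", "ck2qsar_model_error")
    if (stats::sd(y) == 0)
        ck2_error("response is constant", "ck2qsar_model_error")
    sds <- apply(X, 2, stats::sd)
    if (all(sds == 0))
        ck2_error("all descriptor columns are constant", "ck2qsar_model_error")
    list(X = X, y = as.numeric(y), sds = sds)
}

## Core NIPALS on already-scaled matrices. Constant (zero-sd) columns are
## carried with zero scores and get zero coefficients.
.nipals_pls1 <- function(Xs, ys, ncomp) {
    n <- nrow(Xs); p <- ncol(Xs)
    W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
    Tm <- matrix(0, n, ncomp)
    E <- Xs; f <- ys
    for (a in seq_len(ncomp)) {
        w <- crossprod(E, f)                  # p x 1
        wn <- sqrt(sum(w^2))
        if (wn < 1e-12) { ncomp <- a - 1L; break }
        w <- w / wn
        t <- E %*% w
        tt <- sum(t^2)
        if (tt < 1e-12) { ncomp <- a - 1L; break }
        pvec <- crossprod(E, t) / tt
        qa <- sum(f * t) / tt
        E <- E - t %*% t(pvec)
        f <- f - qa * t
        W[, a] <- w; P[, a] <- pvec; q[a] <- qa; Tm[, a] <- t
    }
    if (ncomp < 1L)
        ck2_error("no usable latent component (degenerate data)",
                  "ck2qsar_model_error")
    W <- W[, seq_len(ncomp), drop = FALSE]
    P <- P[, seq_len(ncomp), drop = FALSE]
    q <- q[seq_len(ncomp)]
    ## regression vector in scaled space: b = W (P'W)^-1 q
    b <- W %*% solve(crossprod(P, W), q)
    list(b = as.numeric(b), W = W, P = P, q = q, ncomp = ncomp)
}

.fit_pls_fixed <- function(X, y, ncomp) {
    ck <- .check_xy(X, y)
    X <- ck$X; y <- ck$y
    mx <- colMeans(X); sx <- apply(X, 2, stats::sd)
    sx[sx == 0] <- 1                           # constant columns: centred only
    my <- mean(y); sy <- stats::sd(y)
    Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
    ys <- (y - my) / sy
    ncomp <- as.integer(min(ncomp, nrow(X) - 1L, ncol(X)))
    fit <- .nipals_pls1(Xs, ys, ncomp)
    ## back-transform to raw scale
    braw <- fit$b * sy / sx
    b0 <- my - sum(braw * mx)
    yhat <- as.numeric(X %*% braw + b0)
    stats <- FitStatistics(r2 = stats::cor(y, yhat)^2,
                           rmse = sqrt(mean((y - yhat)^2)),
                           n = length(y))
    new("PLSModel", ncomp = fit$ncomp,
        coefficients = stats::setNames(braw, colnames(X)),
        intercept = b0, xMeans = mx, xScales = sx, yMean = my, yScale = sy,
        weights = fit$W, loadings = fit$P, yloadings = fit$q,
        fitted = yhat, stats = stats)
}

#' Fit a PLS regression model
#'
#' Columns are autoscaled (centred, unit variance) before the NIPALS
#' decomposition; the fitted latent model is exported as raw-scale
#' coefficients plus intercept, which predict identically. With
#' \code{ncomp = "auto"} the number of latent components maximizing the
#' leave-one-out q2 is chosen (ties break to the smaller model).
#'
#' @param X descriptor matrix (compounds x descriptors) or a
#'   \linkS4class{QSARDataset}.
#' @param y response vector (pIC50); taken from the dataset when \code{X}
#'   is a \linkS4class{QSARDataset}.
#' @param ncomp number of latent components, or \code{"auto"}.
#' @param cv whether to attach the LOO q2 of the final model.
#' @return a \linkS4class{PLSModel}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 2 * X[, 1] - X[, 2] + 3
#' coef(fitPLS(X, y, ncomp = 3))
#' @export
fitPLS <- function(X, y = NULL, ncomp = "auto", cv = TRUE) {
    if (is(X, "QSARDataset")) {
        if (is.null(y)) y <- activities(X)$pic50
        X <- descriptorMatrix(X)
    }
    X <- as.matrix(X)
    maxA <- min(nrow(X) - 1L, ncol(X))
    if (identical(ncomp, "auto")) {
        q2s <- vapply(seq_len(maxA), function(a)
            looQ2(X, y, ncomp = a), numeric(1))
        A <- which.max(q2s)                    # which.max takes the first tie
        model <- .fit_pls_fixed(X, y, A)
        model@stats@q2 <- q2s[A]
        return(model)
    }
    model <- .fit_pls_fixed(X, y, as.integer(ncomp))
    if (cv) model@stats@q2 <- looQ2(X, y, ncomp = as.integer(ncomp))
    model
}

#' @describeIn fitPLS raw-scale coefficients of a fitted model
#' @param object a \linkS4class{PLSModel}.
#' @param ... unused.
#' @export
setMethod("modelCoefficients", "PLSModel", function(object) object@coefficients)

#' @rdname modelCoefficients
#' @export
setMethod("modelCoefficients", "QSAREquation", function(object) object@coefficients)

#' @rdname modelIntercept
#' @export
setMethod("modelIntercept", "PLSModel", function(object) object@intercept)

#' @rdname modelIntercept
#' @export
setMethod("modelIntercept", "QSAREquation", function(object) object@intercept)

#' @export
#' @rdname fitPLS
setMethod("coef", "PLSModel", function(object, ...)
    c("(Intercept)" = object@intercept, object@coefficients))

.predict_linear <- function(intercept, coefs, X) {
    X <- as.matrix(X)
    need <- names(coefs)
    missing_cols <- setdiff(need, colnames(X))
    if (length(missing_cols))
        ck2_error(paste("descriptor column(s) missing from newdata:",
                        paste(missing_cols, collapse = ", ")),
                  "ck2qsar_predict_error")
    as.numeric(X[, need, drop = FALSE] %*% coefs + intercept)
}

#' Predict activities from a model or frozen equation
#'
#' Predictions are formed with the raw-scale linear equation
#' \eqn{\hat y = b_0 + \sum_i b_i x_i}; the corresponding IC50 in nM is
#' the inverse pIC50 transform.
#'
#' @param object a \linkS4class{PLSModel} or \linkS4class{QSAREquation}.
#' @param newdata matrix or data.frame containing every descriptor the
#'   model names (extra columns are ignored).
#' @param ... unused.
#' @return data.frame with columns \code{pic50} and \code{ic50_nM}.
#' @rdname predictActivity
#' @export
setMethod("predictActivity", "PLSModel", function(object, newdata, ...) {
    p <- .predict_linear(object@intercept, object@coefficients, newdata)
    data.frame(pic50 = p, ic50_nM = fromPIC50(p))
})

#' @rdname predictActivity
#' @export
setMethod("predictActivity", "QSAREquation", function(object, newdata, ...) {
    p <- .predict_linear(object@intercept, object@coefficients, newdata)
    data.frame(pic50 = p, ic50_nM = fromPIC50(p))
})

#' @rdname predictActivity
#' @param object fitted model.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
    if (missing(newdata)) return(object@fitted)
    predictActivity(object, newdata)$pic50
})

#' @rdname predictActivity
#' @export
setMethod("predict", "QSAREquation", function(object, newdata, ...) {
    predictActivity(object, newdata)$pic50
})

#' Squared Pearson correlation of observed vs predicted
#'
#' @param observed,predicted equal-length numeric vectors (>= 3, both
#'   non-constant).
#' @return r2 in [0, 1].
#' @examples
#' rSquared(1:5, c(1.1, 2.2, 2.9, 4.1, 5.3))
#' @export
rSquared <- function(observed, predicted) {
    if (length(observed) != length(predicted) || length(observed) < 3L)
        ck2_error("need equal-length vectors of length >= 3",
                  "ck2qsar_model_error")
    if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
        ck2_error("constant input has no defined correlation",
                  "ck2qsar_model_error")
    stats::cor(observed, predicted)^2
}

#' Root mean square error
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return sqrt(mean squared residual).
#' @export
rmse <- function(observed, predicted) {
    if (length(observed) != length(predicted) || length(observed) < 1L)
        ck2_error("need equal-length non-empty vectors", "ck2qsar_model_error")
    sqrt(mean((observed - predicted)^2))
}

#' Leave-one-out cross-validated q2
#'
#' q2 = 1 - PRESS/SS, where PRESS sums the squared errors of predictions
#' from n full refits (autoscaling redone inside every fold) and SS is the
#' total sum of squares about the mean. q2 can be negative; 1 is a perfect
#' cross-validated fit.
#'
#' @param X descriptor matrix.
#' @param y response vector.
#' @param ncomp number of latent components for every fold.
#' @return q2 (scalar).
#' @export
looQ2 <- function(X, y, ncomp) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (n < 4L)
        ck2_error("leave-one-out validation needs at least 4 observations",
                  "ck2qsar_model_error")
    press <- 0
    for (i in seq_len(n)) {
        fit <- .fit_pls_fixed(X[-i, , drop = FALSE], y[-i],
                              min(ncomp, n - 2L, ncol(X)))
        yhat <- .predict_linear(fit@intercept, fit@coefficients,
                                X[i, , drop = FALSE])
        press <- press + (y[i] - yhat)^2
    }
    1 - press / sum((y - mean(y))^2)
}
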