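test_that("noiseless linear signals are recovered exactly", {
    set.seed(11)
    X <- matrix(runif(40, 0, 10), 20, 2, dimnames = list(NULL, c("x1", "x2")))
    y <- 2 * X[, 1] - X[, 2] + 3
    fit <- fitPLS(X, y, ncomp = 2, cv = FALSE)
    expect_equal(unname(modelCoefficients(fit)), c(2, -1), tolerance = 1e-6)
    expect_equal(modelIntercept(fit), 3, tolerance = 1e-6)
    expect_equal(predict(fit, X), y, tolerance = 1e-8)
})

test_that("full-component PLS equals the least-squares solution", {
    # normal-equations oracle on random full-rank problems
    set.seed(202)
    for (rep in 1:10) {
        n <- sample(12:25, 1); p <- sample(2:6, 1)
        X <- matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("v", seq_len(p))))
        y <- rnorm(n)
        fit <- fitPLS(X, y, ncomp = p, cv = FALSE)
        Xa <- cbind(1, X)
        beta <- solve(crossprod(Xa), crossprod(Xa, y))
        expect_equal(unname(modelCoefficients(fit)), unname(beta[-1]),
                     tolerance = 1e-6)
        expect_equal(modelIntercept(fit), beta[1], tolerance = 1e-6)
    }
})

test_that("single-descriptor PLS equals simple linear regression", {
    set.seed(5)
    x <- matrix(rnorm(15), dimnames = list(NULL, "d"))
    y <- 1.5 * x[, 1] + rnorm(15, 0, 0.3)
    fit <- fitPLS(x, y, ncomp = 1, cv = FALSE)
    sl <- stats::lm(y ~ x)
    expect_equal(unname(modelCoefficients(fit)), unname(coef(sl)[2]),
                 tolerance = 1e-8)
    expect_equal(modelIntercept(fit), unname(coef(sl)[1]), tolerance = 1e-8)
})

test_that("latent-space and exported linear predictions coincide", {
    set.seed(31)
    X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("d", 1:5)))
    y <- X %*% c(1, -2, 0.5, 0, 1) + rnorm(20, 0, 0.2)
    for (A in c(1L, 2L, 4L)) {
        fit <- fitPLS(X, y, ncomp = A, cv = FALSE)
        Xs <- sweep(sweep(X, 2, fit@xMeans), 2, fit@xScales, "/")
        Tm <- Xs %*% fit@weights %*%
            solve(crossprod(fit@loadings, fit@weights))
        latent <- as.numeric(Tm %*% fit@yloadings) * fit@yScale + fit@yMean
        expect_equal(latent, predict(fit, X), tolerance = 1e-8)
    }
})

test_that("LOO q2 equals an explicit n-refit loop", {
    set.seed(77)
    X <- matrix(rnorm(36), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- X %*% c(1, 0.5, -1) + rnorm(12, 0, 0.3)
    for (A in 1:3) {
        press <- 0
        for (i in seq_len(nrow(X))) {
            f <- fitPLS(X[-i, , drop = FALSE], y[-i], ncomp = A, cv = FALSE)
            press <- press + (y[i] - predict(f, X[i, , drop = FALSE]))^2
        }
        expect_equal(looQ2(X, y, A), 1 - press / sum((y - mean(y))^2),
                     tolerance = 1e-10)
    }
})

test_that("cross-validation never flatters the training fit", {
    # q2 <= r2 at equal component count, across random datasets
    set.seed(400)
    for (rep in 1:8) {
        n <- 15; p <- 4
        X <- matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("d", 1:p)))
        y <- X %*% runif(p, -1, 1) + rnorm(n, 0, 0.5)
        A <- sample(p, 1)
        fit <- fitPLS(X, y, ncomp = A)
        expect_lte(fit@stats@q2, fit@stats@r2 + 1e-12)
    }
    # exact linear data cross-validates almost perfectly
    X <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- X %*% c(1, 2, 3) + 1
    expect_gt(looQ2(X, y, 3), 0.999)
})

test_that("pure-noise responses yield non-positive q2 in expectation", {
    set.seed(900)
    q2s <- replicate(40, {
        X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("d", 1:5)))
        looQ2(X, rnorm(20), 2)
    })
    expect_lt(mean(q2s), 0)
})

test_that("degenerate inputs raise typed model errors", {
    X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
    expect_error(fitPLS(X, rep(1, 10)), class = "ck2qsar_model_error")
    expect_error(fitPLS(X[1:2, ], rnorm(2), ncomp = 1),
                 class = "ck2qsar_model_error")
    Xc <- matrix(1, 10, 2, dimnames = list(NULL, c("a", "b")))
    expect_error(fitPLS(Xc, rnorm(10), ncomp = 1),
                 class = "ck2qsar_model_error")
    fit <- fitPLS(X, rnorm(10), ncomp = 1, cv = FALSE)
    expect_error(predictActivity(fit, matrix(0, 1, 1, dimnames = list(NULL, "zz"))),
                 class = "ck2qsar_predict_error")
})

test_that("automatic component choice maximizes cross-validated q2", {
    set.seed(321)
    X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("d", 1:4)))
    y <- X[, 1] - X[, 2] + rnorm(20, 0, 0.1)
    fit <- fitPLS(X, y, ncomp = "auto")
    q2s <- vapply(1:4, function(a) looQ2(X, y, a), numeric(1))
    expect_equal(fit@stats@q2, max(q2s))
    expect_equal(fit@ncomp, which.max(q2s))
})

test_that("r-squared and RMSE behave on published-style pairs", {
    expect_equal(rSquared(1:10, 1:10), 1.0)
    expect_equal(rmse(c(1, 2), c(2, 1)), 1.0)
    expect_equal(rmse(1:5, 1:5), 0)
    expect_error(rSquared(rep(1, 5), 1:5), class = "ck2qsar_model_error")
    expect_error(rmse(1:3, 1:4), class = "ck2qsar_model_error")
    tp <- ck2TrainingPairs()
    ms <- mean((tp$tested_pic50 - tp$predicted_pic50)^2)
    expect_equal(rmse(tp$tested_pic50, tp$predicted_pic50), sqrt(ms),
                 tolerance = 1e-6)
})
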