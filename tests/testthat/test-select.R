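test_that("relative importance scales coefficients by column spread", {
    set.seed(8)
    n <- 40
    X <- cbind(s1 = rnorm(n), s2 = rnorm(n))   # standardized-scale columns
    y <- 1.0 * X[, 1] + 0.05 * X[, 2] + rnorm(n, 0, 0.01)
    fit <- fitPLS(X, y, ncomp = 2, cv = FALSE)
    ri <- relativeImportance(fit, X)
    expect_equal(ri$importance[ri$descriptor == "s1"], 1.0)
    expect_lt(ri$importance[ri$descriptor == "s2"], 0.1)
    expect_false(ri$retained[ri$descriptor == "s2"])
    expect_true(ri$retained[ri$descriptor == "s1"])
})

test_that("duplicated top descriptors share the top importance", {
    set.seed(9)
    x <- rnorm(30)
    X <- cbind(a = x, b = x, c = rnorm(30))
    y <- x + rnorm(30, 0, 0.05)
    fit <- fitPLS(X, y, ncomp = 2, cv = FALSE)
    ri <- relativeImportance(fit, X)
    expect_equal(ri$importance[ri$descriptor == "a"],
                 ri$importance[ri$descriptor == "b"], tolerance = 1e-6)
})

test_that("importance is invariant to positive rescaling of a column", {
    set.seed(10)
    X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- X %*% c(1, -0.5, 0.2) + rnorm(20, 0, 0.1)
    ri1 <- relativeImportance(fitPLS(X, y, ncomp = 3, cv = FALSE), X)
    X2 <- X; X2[, "b"] <- X2[, "b"] * 1000
    ri2 <- relativeImportance(fitPLS(X2, y, ncomp = 3, cv = FALSE), X2)
    o1 <- ri1[order(ri1$descriptor), "importance"]
    o2 <- ri2[order(ri2$descriptor), "importance"]
    expect_equal(o1, o2, tolerance = 1e-6)
})

test_that("contingency statistics saturate for a perfectly informative descriptor", {
    set.seed(12)
    y <- rnorm(200)
    X <- cbind(same = y, noise = rnorm(200))
    cs <- contingencySelect(X, y)
    expect_equal(cs$cramers_v[cs$descriptor == "same"], 1, tolerance = 1e-12)
    expect_equal(cs$uncertainty[cs$descriptor == "same"], 1, tolerance = 1e-12)
    expect_true(cs$retained[cs$descriptor == "same"])
})

test_that("independent descriptors rarely reach the association thresholds", {
    set.seed(13)
    vs <- replicate(100, {
        y <- rnorm(200)
        x <- matrix(runif(200), dimnames = list(NULL, "u"))
        contingencySelect(x, y)$cramers_v
    })
    expect_gte(mean(vs < 0.2), 0.95)
})

test_that("constant descriptors are dropped with a log entry", {
    y <- rnorm(50)
    X <- cbind(flat = rep(1, 50), ok = y + rnorm(50, 0, 0.1))
    expect_message(cs <- contingencySelect(X, y), "constant")
    expect_false(cs$retained[cs$descriptor == "flat"])
    expect_equal(cs$cramers_v[cs$descriptor == "flat"], 0)
})

test_that("selection respects its preconditions", {
    X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
    expect_error(contingencySelect(X, rnorm(5), bins = 4),
                 class = "ck2qsar_model_error")
})
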