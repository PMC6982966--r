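test_that("generators are pure functions of spec and seed", {
    d1 <- genLinearDataset(15, 4, seed = 99)
    d2 <- genLinearDataset(15, 4, seed = 99)
    expect_identical(d1, d2)
    d3 <- genLinearDataset(15, 4, seed = 100)
    expect_false(identical(d1$X, d3$X))
    a1 <- genActivityTable(10, seed = 4)
    a2 <- genActivityTable(10, seed = 4)
    expect_identical(a1, a2)
})

test_that("noiseless synthetic data is fit exactly", {
    d <- genLinearDataset(20, 5, noiseSd = 0, seed = 2)
    fit <- fitPLS(d$X, d$y, ncomp = 5, cv = FALSE)
    expect_equal(modelCoefficients(fit), d$beta, tolerance = 1e-6)
    expect_equal(modelIntercept(fit), d$beta0, tolerance = 1e-6)
})

test_that("the pIC50 range constraint brackets the signal", {
    d <- genLinearDataset(50, 6, noiseSd = 0, pic50Range = c(5.38, 7.60),
                          seed = 3)
    expect_equal(range(d$y), c(5.38, 7.60), tolerance = 1e-9)
    # returned beta/beta0 remain the ground truth after the mapping
    expect_equal(as.numeric(d$beta0 + d$X %*% d$beta), d$y, tolerance = 1e-9)
})

test_that("fitted r2 concentrates near the generating signal strength", {
    set.seed(1000)
    hits <- replicate(30, {
        seed <- sample.int(1e6, 1)
        d <- genLinearDataset(20, 10, noiseSd = 0, seed = seed)
        signal_sd <- sd(d$y)
        d <- genLinearDataset(20, 10, noiseSd = signal_sd / 3, seed = seed)
        fit <- fitPLS(d$X, d$y, ncomp = 10, cv = FALSE)
        r2 <- fit@stats@r2
        r2 >= 0.8 && r2 <= 0.995
    })
    expect_gte(mean(hits), 0.9)
})

test_that("toy graphs honour topology and carbon valence", {
    expect_equal(wienerPathNumber(genToyGraphs("path", 4)), 10)
    expect_equal(wienerPathNumber(genToyGraphs("cycle", 6)), 27)
    expect_equal(wienerPathNumber(genToyGraphs("star", 5)), 16)
    g <- genToyGraphs("complete", 4)
    expect_equal(numBonds(g), 6L)
    expect_true(all(atoms(g)$hcount >= 0))
    expect_error(genToyGraphs("star", 6), class = "ck2qsar_synthetic_error")
    expect_error(genToyGraphs("cycle", 2), class = "ck2qsar_synthetic_error")
    expect_error(genToyGraphs("complete", 6), class = "ck2qsar_synthetic_error")
})

test_that("synthetic activity tables stay inside the requested range", {
    tab <- genActivityTable(200, ic50Range = c(25, 4100), seed = 17)
    expect_true(all(tab$ic50_nM >= 25 & tab$ic50_nM <= 4100))
    expect_true(all(tab$pic50 >= toPIC50(4100) & tab$pic50 <= toPIC50(25)))
    expect_equal(nrow(genActivityTable(0)), 0L)
    expect_error(genActivityTable(5, ic50Range = c(-1, 10)),
                 class = "ck2qsar_synthetic_error")
})

test_that("signal descriptors outrank null descriptors end to end", {
    set.seed(55)
    ok <- replicate(40, {
        seed <- sample.int(1e6, 1)
        beta <- c(rep(0.02, 5), rep(0, 5))
        d <- genLinearDataset(20, 10, beta = beta, noiseSd = 0.1, seed = seed)
        fit <- fitPLS(d$X, d$y, ncomp = "auto")
        ri <- relativeImportance(fit, d$X)
        strength <- abs(d$beta) * apply(d$X, 2, sd)
        top <- names(sort(strength, decreasing = TRUE))[1:3]
        null_d <- names(d$beta)[d$beta == 0]
        min(ri$importance[ri$descriptor %in% top]) >
            max(ri$importance[ri$descriptor %in% null_d])
    })
    expect_gte(mean(ok), 0.9)
})

test_that("contingency selection separates signal from null at scale", {
    set.seed(56)
    ok <- replicate(30, {
        seed <- sample.int(1e6, 1)
        d <- genLinearDataset(200, 2, beta = c(0.03, 0), noiseSd = 0.1,
                              seed = seed)
        cs <- contingencySelect(d$X, d$y)
        cs$retained[1] && !cs$retained[2]
    })
    expect_gte(mean(ok), 0.9)
})
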