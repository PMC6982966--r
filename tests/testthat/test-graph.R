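test_that("distance matrix equals brute-force BFS and rejects disconnection", {
    g <- parseSmiles("CCCC")
    d <- distanceMatrix(g)
    expect_equal(max(d), 3L)
    expect_equal(rowSums(d), c(6, 4, 4, 6))
    expect_true(isSymmetric(d))
    expect_true(all(diag(d) == 0))

    d3 <- distanceMatrix(parseSmiles("C1CC1"))
    expect_true(all(d3[upper.tri(d3)] == 1))

    for (smi in c("CC(C)(C)C", "c1ccc2ccccc2c1", "CC(=O)Nc1ccc(O)cc1"))
        expect_equal(distanceMatrix(parseSmiles(smi)),
                     unname(bfs_distances(parseSmiles(smi))),
                     ignore_attr = TRUE, label = smi)

    expect_error(distanceMatrix(parseSmiles("CCCC.O")),
                 class = "ck2qsar_disconnected_error")
})

test_that("Wiener path number matches closed forms and brute-force BFS", {
    # paths: W = (n^3 - n) / 6
    for (n in 2:12) {
        smi <- paste(rep("C", n), collapse = "")
        w <- wienerPathNumber(parseSmiles(smi))
        expect_equal(w, (n^3 - n) / 6, label = paste("path", n))
        expect_equal(w, bfs_wiener(parseSmiles(smi)))
    }
    # cycles and stars via generated toy graphs
    expect_equal(wienerPathNumber(genToyGraphs("cycle", 6)), 27)
    expect_equal(wienerPathNumber(genToyGraphs("cycle", 6)),
                 bfs_wiener(genToyGraphs("cycle", 6)))
    for (n in 2:5) {
        g <- genToyGraphs("star", n)
        expect_equal(wienerPathNumber(g), (n - 1)^2, label = paste("star", n))
        expect_equal(wienerPathNumber(g), bfs_wiener(g))
    }
    # specific molecules
    expect_equal(wienerPathNumber(parseSmiles("CCCC")), 10)
    expect_equal(wienerPathNumber(parseSmiles("C1CC1")), 3)
    expect_equal(wienerPathNumber(parseSmiles("CC(C)(C)C")), 16)
    expect_equal(wienerPathNumber(parseSmiles("c1ccccc1")), 27)
    expect_equal(wienerPathNumber(parseSmiles("Cc1ccccc1")), 42)
    # hydrogens are suppressed
    expect_equal(wienerPathNumber(expandHydrogens(parseSmiles("CCCC"))), 10)
})

test_that("growing a molecule never decreases Wiener index or volume", {
    chains <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC")
    w <- vapply(chains, function(s) wienerPathNumber(parseSmiles(s)), numeric(1))
    v <- vapply(chains, function(s) vdwVolume(parseSmiles(s)), numeric(1))
    expect_true(all(diff(w) > 0))
    expect_true(all(diff(v) > 0))
    expect_gt(vdwVolume(parseSmiles("Cc1ccccc1")), vdwVolume(parseSmiles("c1ccccc1")))
    expect_gt(wienerPathNumber(parseSmiles("Cc1ccccc1")),
              wienerPathNumber(parseSmiles("c1ccccc1")))
})
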