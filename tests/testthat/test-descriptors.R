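test_that("the descriptor vector has exactly the ten named keys and is deterministic", {
    v1 <- computeDescriptors("CC(=O)Nc1ccc(O)cc1")
    v2 <- computeDescriptors("CC(=O)Nc1ccc(O)cc1")
    expect_identical(names(v1), descriptorNames())
    expect_identical(v1, v2)
    expect_true(all(v1[1:8] >= 0))
    expect_gt(v1["vdw_vol"], 0)
    expect_equal(v1["weinerPath"], round(v1["weinerPath"]), ignore_attr = TRUE)
})

test_that("PEOE bins partition the total molecular surface", {
    for (smi in c("CCO", "CC(=O)O", "Nc1ccccc1", "CC(=O)Nc1ccc(O)cc1")) {
        v <- binnedVSADescriptors(parseSmiles(smi), full = TRUE)
        expect_equal(sum(attr(v, "peoeBins")), attr(v, "totalVSA"),
                     tolerance = 1e-8, label = smi)
    }
})

test_that("hydrophobic and polar surfaces partition the total", {
    for (smi in c("CCO", "CC(=O)O", "c1ccncc1", "CC(=O)Nc1ccc(O)cc1")) {
        v <- binnedVSADescriptors(parseSmiles(smi), full = TRUE)
        q <- attr(v, "charges")
        vsa_all <- attr(v, "totalVSA")
        ppos <- vsa_all - v[["Q_VSA_HYD"]] - v[["Q_VSA_PNEG"]] # positive polar
        expect_equal(v[["Q_VSA_HYD"]] + v[["Q_VSA_PNEG"]] + ppos, vsa_all,
                     tolerance = 1e-8)
        # recompute the split directly from charges as a cross-check
        gx <- attr(q, "graph")
        vsa <- atomicVSA(gx)
        expect_equal(v[["Q_VSA_HYD"]], sum(vsa[abs(q) <= 0.2]), tolerance = 1e-8)
        expect_equal(v[["Q_VSA_PNEG"]], sum(vsa[q < -0.2]), tolerance = 1e-8)
    }
})

test_that("molecules whose logP contributions stay below 0.25 zero the SlogP bins", {
    cc <- crippenContribs(parseSmiles("CC"))
    expect_true(all(cc$logp <= 0.25))
    v <- computeDescriptors("CC")
    expect_equal(unname(v[c("SlogP_VSA7", "SlogP_VSA8", "SlogP_VSA9")]),
                 c(0, 0, 0))
})

test_that("toluene exceeds benzene in volume and Wiener index", {
    vb <- computeDescriptors("c1ccccc1")
    vt <- computeDescriptors("Cc1ccccc1")
    expect_equal(unname(vb["weinerPath"]), 27)
    expect_equal(unname(vt["weinerPath"]), 42)
    expect_gt(vt["vdw_vol"], vb["vdw_vol"])
})

test_that("descriptor tables respect the failure policy", {
    mols <- list(ok1 = "CCO", bad = "C(", ok2 = "CCN")
    expect_error(descriptorTable(mols, onError = "stop"),
                 class = "ck2qsar_descriptor_error")
    m <- descriptorTable(mols, onError = "skip")
    expect_equal(rownames(m), c("ok1", "ok2"))
    expect_match(attr(m, "failures"), "bad")
})

test_that("descriptor CSV export uses the canonical header", {
    m <- descriptorTable(list(a = "CCO"))
    f <- withr::local_tempfile(fileext = ".csv")
    writeDescriptorCSV(m, f)
    header <- readLines(f, n = 1L)
    expect_equal(header, paste(c("id", descriptorNames()), collapse = ","))
})
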