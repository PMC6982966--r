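test_that("QSARDataset enforces its activity invariants", {
    m <- matrix(rnorm(12), 3, 4,
                dimnames = list(c("a", "b", "c"), paste0("d", 1:4)))
    act <- data.frame(id = c("a", "b", "c"), ic50_nM = c(100, 200, 400),
                      set = c("train", "train", "test"))
    ds <- QSARDataset(m, act)
    expect_s4_class(ds, "QSARDataset")
    expect_equal(descriptorMatrix(ds), m)
    expect_equal(activities(ds)$pic50, toPIC50(act$ic50_nM))
    expect_equal(unname(setLabels(ds)), act$set)
    # invalid activities are rejected by the validity method
    bad <- act; bad$ic50_nM[1] <- -5
    expect_error(QSARDataset(m, bad))
    bad2 <- act; bad2$set[1] <- "unknown"
    expect_error(QSARDataset(m, bad2))
})

test_that("compound tables read with unit conversion", {
    f <- withr::local_tempfile(fileext = ".csv")
    write.csv(data.frame(id = c("x", "y"), smiles = c("CC", "CCO"),
                         ic50 = c(2.33, 0.11)), f, row.names = FALSE)
    tab <- readCompoundTable(f, units = "uM")
    expect_equal(tab$ic50_nM, c(2330, 110))
    expect_equal(tab$pic50, toPIC50(c(2330, 110)))
    expect_equal(tab$set, c("train", "train"))
    tab2 <- readCompoundTable(f, units = "nM")
    expect_equal(tab2$ic50_nM, c(2.33, 0.11))
})

test_that("SMILES files parse ids and skip comments", {
    f <- withr::local_tempfile(fileext = ".smi")
    writeLines(c("# header", "CCO mol1", "", "c1ccccc1 mol2", "CC"), f)
    tab <- readSmilesFile(f)
    expect_equal(tab$id, c("mol1", "mol2", "3"))
    expect_equal(tab$smiles, c("CCO", "c1ccccc1", "CC"))
})

test_that("SDF connection tables convert to molecular graphs", {
    skip_if_not_installed("ChemmineR")
    # minimal V2000 ethanol record, coordinates irrelevant
    sdf <- c("ethanol", "  test", "",
             "  3  2  0  0  0  0  0  0  0  0999 V2000",
             "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
             "    2.2000    1.2000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
             "  1  2  1  0", "  2  3  1  0",
             "M  END", "$$$$")
    f <- withr::local_tempfile(fileext = ".sdf")
    writeLines(sdf, f)
    mols <- suppressWarnings(readSDFMolecules(f))
    expect_length(mols, 1L)
    g <- mols[[1]]
    expect_equal(atoms(g)$element, c("C", "C", "O"))
    expect_equal(atoms(g)$hcount, c(3L, 2L, 1L))
    # descriptors from SDF match descriptors from SMILES
    expect_equal(computeDescriptors(g), computeDescriptors("CCO"),
                 tolerance = 1e-9)
})

test_that("dataset building computes the full descriptor block", {
    comp <- data.frame(id = c("a", "b", "c"),
                       smiles = c("CCO", "CCC", "c1ccccc1"),
                       ic50_nM = c(100, 1000, 50),
                       pic50 = toPIC50(c(100, 1000, 50)),
                       set = "train")
    ds <- buildQSARDataset(comp)
    expect_equal(dim(descriptorMatrix(ds)), c(3L, 10L))
    expect_identical(colnames(descriptorMatrix(ds)), descriptorNames())
})
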