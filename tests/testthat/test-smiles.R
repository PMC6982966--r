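test_that("valence rules assign implicit hydrogens on simple molecules", {
    g <- parseSmiles("CC")
    expect_equal(numAtoms(g), 2L)
    expect_equal(atoms(g)$hcount, c(3L, 3L))

    cases <- list(
        C = 4L, N = 3L, O = 2L, "CO" = c(3L, 1L), "C=C" = c(2L, 2L),
        "C#N" = c(1L, 0L), "CC(=O)O" = c(3L, 0L, 0L, 1L),
        "[NH4+]" = 4L, "[O-]C" = c(0L, 3L), "S(=O)(=O)(O)O" = c(0L, 0L, 0L, 1L, 1L))
    for (smi in names(cases))
        expect_equal(atoms(parseSmiles(smi))$hcount, cases[[smi]], label = smi)
})

test_that("aromatic rings are perceived and kekulized consistently", {
    g <- parseSmiles("c1ccccc1")
    expect_equal(numAtoms(g), 6L)
    expect_true(all(atoms(g)$aromatic))
    expect_equal(numBonds(g), 6L)
    expect_equal(atoms(g)$hcount, rep(1L, 6))
    expect_equal(sort(unique(bonds(g)$order)), 1.5)
    expect_equal(sort(bonds(g)$korder), c(1, 1, 1, 2, 2, 2))

    # pyridine N takes a ring double bond, pyrrole N does not
    pyr <- parseSmiles("c1ccncc1")
    ndx <- which(atoms(pyr)$element == "N")
    b <- bonds(pyr)
    expect_equal(sum(b$korder[b$i == ndx | b$j == ndx] == 2), 1L)
    pyl <- parseSmiles("c1cc[nH]c1")
    ndx <- which(atoms(pyl)$element == "N")
    b <- bonds(pyl)
    expect_equal(sum(b$korder[b$i == ndx | b$j == ndx] == 2), 0L)
    expect_equal(atoms(pyl)$hcount[ndx], 1L)

    # fused aromatic system
    naph <- parseSmiles("c1ccc2ccccc2c1")
    expect_equal(numAtoms(naph), 10L)
    expect_equal(numBonds(naph), 11L)
    expect_equal(sum(bonds(naph)$korder == 2), 5L)
})

test_that("charges, brackets and ring-closure variants parse", {
    g <- parseSmiles("[NH3+]CC(=O)[O-]")
    expect_equal(netCharge(g), 0L)
    expect_equal(atoms(g)$charge, c(1L, 0L, 0L, 0L, -1L))
    expect_equal(numAtoms(parseSmiles("C%12CC%12")), 3L)
    expect_equal(numBonds(parseSmiles("C1CC1")), 3L)
    # disconnected components parse (rejection happens downstream)
    expect_equal(numAtoms(parseSmiles("CCCC.O")), 5L)
})

test_that("malformed SMILES raise typed parse errors naming the position", {
    expect_error(parseSmiles("C("), class = "ck2qsar_parse_error")
    expect_error(parseSmiles("C1CC"), class = "ck2qsar_parse_error")
    expect_error(parseSmiles("C)"), class = "ck2qsar_parse_error")
    expect_error(parseSmiles("C=#C"), class = "ck2qsar_parse_error")
    expect_error(parseSmiles("C[Qq]C"), class = "ck2qsar_parse_error")
    expect_error(parseSmiles(""), class = "ck2qsar_parse_error")
    expect_error(parseSmiles("C(C)(C)(C)(C)C"), class = "ck2qsar_valence_error")
    err <- tryCatch(parseSmiles("CC)C"), error = identity)
    expect_match(conditionMessage(err), "position 3")
})

test_that("hydrogen expansion is explicit, order-preserving and idempotent", {
    g <- expandHydrogens(parseSmiles("C"))
    expect_equal(numAtoms(g), 5L)
    expect_equal(numBonds(g), 4L)
    expect_equal(sum(atoms(g)$element == "H"), 4L)

    bz <- expandHydrogens(parseSmiles("c1ccccc1"))
    expect_equal(numAtoms(bz), 12L)
    expect_equal(numBonds(bz), 12L)

    # idempotence and preservation of the heavy-atom subgraph
    again <- expandHydrogens(bz)
    expect_identical(atoms(again), atoms(bz))
    expect_identical(bonds(again), bonds(bz))
    g0 <- parseSmiles("CCO")
    expect_identical(atoms(heavyAtomGraph(expandHydrogens(g0)))$element,
                     atoms(g0)$element)
})

test_that("molecular graph validity catches inconsistent structures", {
    expect_error(MolecularGraph(
        data.frame(element = "C", charge = 0L, aromatic = FALSE, hcount = 4L),
        data.frame(i = 1L, j = 2L, order = 1)), "valid atoms")
    expect_error(MolecularGraph(
        data.frame(element = c("C", "C"), charge = 0L, aromatic = FALSE,
                   hcount = 3L),
        data.frame(i = c(1L, 1L), j = c(2L, 2L), order = 1)), "duplicate")
    expect_error(MolecularGraph(
        data.frame(element = "C", charge = 0L, aromatic = FALSE, hcount = 4L),
        data.frame(i = 1L, j = 1L, order = 1)), "self-bonds")
})
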