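# Component CIF / SDF reading and writing, and the admission filter.

minimalDiatomicCIF <- c(
  "data_XX",
  "_chem_comp.id XX",
  "_chem_comp.name 'toy diatomic'",
  "_chem_comp.type non-polymer",
  "loop_",
  "_chem_comp_atom.atom_id",
  "_chem_comp_atom.type_symbol",
  "_chem_comp_atom.charge",
  "_chem_comp_atom.model_Cartn_x",
  "_chem_comp_atom.model_Cartn_y",
  "_chem_comp_atom.model_Cartn_z",
  "C1 C 0 0.0 0.0 0.0",
  "O1 O 0 1.2 0.0 0.0",
  "loop_",
  "_chem_comp_bond.atom_id_1",
  "_chem_comp_bond.atom_id_2",
  "_chem_comp_bond.value_order",
  "C1 O1 DOUB")

test_that("component CIF reading handles minimal and degenerate inputs", {
  cc <- readComponentCIF(minimalDiatomicCIF)
  expect_s4_class(cc, "Component")
  expect_equal(nrow(atomTable(cc)), 2L)
  expect_equal(nrow(bondTable(cc)), 1L)
  expect_equal(bondTable(cc)$order, "double")
  expect_true(hasCoords(cc))

  nocoord <- minimalDiatomicCIF[!grepl("Cartn", minimalDiatomicCIF)]
  nocoord <- nocoord[!grepl("^C1 C 0 0", nocoord) &
                       !grepl("^O1 O 0 1", nocoord)]
  nocoord <- c(nocoord[1:8], "C1 C 0", "O1 O 0", nocoord[9:12])
  cc2 <- readComponentCIF(nocoord)
  expect_false(hasCoords(cc2))
  expect_equal(nrow(atomTable(cc2)), 2L)

  # single-row key-value form (no loop_) must parse too
  kv <- c("data_YY",
          "_chem_comp.id YY",
          "_chem_comp_atom.atom_id MG1",
          "_chem_comp_atom.type_symbol MG",
          "_chem_comp_atom.charge 2")
  cc3 <- readComponentCIF(kv)
  expect_equal(atomTable(cc3)$name, "MG1")
  expect_equal(netCharge(cc3), 2L)
})

test_that("component CIF errors name the problem", {
  bad <- c(minimalDiatomicCIF, "loop_")  # loop without tags
  expect_error(readComponentCIF(bad), "loop_")
  badbond <- sub("^C1 O1 DOUB$", "C1 OZ DOUB", minimalDiatomicCIF)
  expect_error(readComponentCIF(badbond), "unknown atom")
  badorder <- sub("DOUB$", "QUAD", minimalDiatomicCIF)
  expect_error(readComponentCIF(badorder), "value_order")
})

test_that("write/read CIF round-trips every fixture field-for-field", {
  for (kind in FIXTURE_KINDS) {
    cc <- fixtureComponent(kind)
    cc2 <- readComponentCIF(writeComponentCIF(cc))
    expect_identical(componentId(cc2), componentId(cc))
    expect_identical(atomTable(cc2)$name, atomTable(cc)$name)
    expect_identical(atomTable(cc2)$element, atomTable(cc)$element)
    expect_identical(atomTable(cc2)$charge, atomTable(cc)$charge)
    expect_identical(bondTable(cc2), bondTable(cc))
    expect_equal(atomCoords(cc2), atomCoords(cc))
    expect_identical(compClass(cc2), compClass(cc))
    expect_identical(smilesString(cc2), smilesString(cc))
    expect_identical(netCharge(cc2), netCharge(cc))
  }
})

test_that("acetic acid fixture matches its chemical description", {
  cc <- readComponentCIF(writeComponentCIF(makeComponent("acetic_acid")))
  expect_equal(nrow(atomTable(cc)), 8L)
  expect_equal(nrow(bondTable(cc)), 7L)
  expect_equal(netCharge(cc), 0L)
  # C(=O)OH substructure: one C with a double-bonded O and a single O
  # that carries an H
  b <- bondTable(cc)
  dbl <- b[b$order == "double", ]
  expect_equal(nrow(dbl), 1L)
  carboxylC <- intersect(c(dbl$atom1, dbl$atom2),
                         atomTable(cc)$name[atomTable(cc)$element == "C"])
  singleO <- b$atom2[b$atom1 == carboxylC & b$order == "single" &
                       grepl("^O", b$atom2)]
  expect_length(singleO, 1L)
  expect_true(any((b$atom1 == singleO & grepl("^H", b$atom2)) |
                    (b$atom2 == singleO & grepl("^H", b$atom1))))
})

test_that("five-character IDs and empty bond loops survive a round trip", {
  cc <- fixtureComponent("benzene")
  cc@id <- "A1B2C"
  cc2 <- readComponentCIF(writeComponentCIF(cc))
  expect_identical(componentId(cc2), "A1B2C")

  lone <- makeComponent("custom", id = "AR",
                        atoms = data.frame(name = "AR1", element = "C",
                                           charge = 0L,
                                           is_hydrogen = FALSE,
                                           legacy_name = NA_character_),
                        bonds = data.frame(atom1 = character(0),
                                           atom2 = character(0),
                                           order = character(0)),
                        coords = matrix(0, 1, 3,
                                        dimnames = list("AR1", NULL)))
  cc3 <- readComponentCIF(writeComponentCIF(lone))
  expect_equal(nrow(bondTable(cc3)), 0L)
})

test_that("SDF reading synthesizes names and propagates charges", {
  one <- c("methane-ish", "", "",
           "  1  0  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0",
           "M  END", "$$$$")
  cc <- readSDF(one)
  expect_equal(nrow(atomTable(cc)), 1L)
  expect_equal(nrow(bondTable(cc)), 0L)

  eth <- c("ethane", "", "",
           "  8  7  0  0  0  0  0  0  0  0999 V2000",
           sprintf("%10.4f%10.4f%10.4f %-3s 0  0",
                   c(0, 1.53, -0.36, -0.36, -0.36, 1.89, 1.89, 1.89),
                   c(0, 0, 1.02, -0.51, -0.51, -1.02, 0.51, 0.51),
                   c(0, 0, 0, 0.88, -0.88, 0, 0.88, -0.88),
                   c("C", "C", "H", "H", "H", "H", "H", "H")),
           "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
           "  2  6  1  0", "  2  7  1  0", "  2  8  1  0",
           "M  END", "$$$$")
  cc2 <- readSDF(eth)
  expect_identical(atomTable(cc2)$name,
                   c("C1", "C2", paste0("H", 1:6)))
  expect_equal(nrow(bondTable(cc2)), 7L)

  chg <- c("oxide", "", "",
           "  2  1  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0",
           "    1.3000    0.0000    0.0000 O   0  0",
           "  1  2  1  0",
           "M  CHG  1   2  -1",
           "M  END", "$$$$")
  cc3 <- readSDF(chg)
  expect_equal(atomTable(cc3)$charge, c(0L, -1L))
  expect_equal(netCharge(cc3), -1L)

  badcount <- sub("  8  7", "  9  7", eth[4])
  expect_error(readSDF(c(eth[1:3], badcount, eth[-(1:4)])), "mismatch")
})

test_that("filter applies exclusions in fixed precedence order", {
  mg <- makeComponent("custom", id = "MG",
                      atoms = data.frame(name = "MG", element = "Mg",
                                         charge = 2L, is_hydrogen = FALSE,
                                         legacy_name = NA_character_),
                      bonds = data.frame(atom1 = character(0),
                                         atom2 = character(0),
                                         order = character(0)))
  d <- filterComponent(mg)
  expect_false(d@kept)
  expect_identical(d@reason, "single_atom")

  hemelike <- makeComponent("custom", id = "HMX",
                            atoms = data.frame(
                              name = c("FE", "N1", "N2"),
                              element = c("Fe", "N", "N"), charge = 0L,
                              is_hydrogen = FALSE,
                              legacy_name = NA_character_),
                            bonds = data.frame(atom1 = c("FE", "FE"),
                                               atom2 = c("N1", "N2"),
                                               order = "single"))
  expect_identical(filterComponent(hemelike)@reason, "contains_metal")

  # obsolete outranks single_atom
  mg@obsolete <- TRUE
  expect_identical(filterComponent(mg)@reason, "obsolete")

  ala <- fixtureComponent("alanine_like")
  ala@id <- "ALA"
  expect_identical(filterComponent(ala)@reason, "standard_residue")
  expect_identical(
    filterComponent(fixtureComponent("benzene"),
                    FilterPolicy(skipIds = "BNZ"))@reason,
    "manually_curated")

  ok <- filterComponent(fixtureComponent("benzene"))
  expect_true(ok@kept)
  expect_identical(ok@reason, "kept")
})

test_that("filter decisions are invariant to policy list order", {
  pol1 <- FilterPolicy(skipIds = c("AAA", "BNZ", "ZZZ"))
  pol2 <- FilterPolicy(skipIds = c("ZZZ", "AAA", "BNZ"),
                       standardResidueIds =
                         rev(pol1@standardResidueIds),
                       allowedElements = rev(pol1@allowedElements))
  for (kind in FIXTURE_KINDS) {
    cc <- fixtureComponent(kind)
    expect_identical(filterComponent(cc, pol1)@reason,
                     filterComponent(cc, pol2)@reason)
  }
})

test_that("metal filter equals a brute-force element scan", {
  pol <- FilterPolicy()
  for (kind in FIXTURE_KINDS) {
    cc <- fixtureComponent(kind)
    passes <- all(toupper(atomTable(cc)$element) %in% pol@allowedElements)
    expect_identical(filterComponent(cc, pol)@reason != "contains_metal",
                     passes)
  }
})
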