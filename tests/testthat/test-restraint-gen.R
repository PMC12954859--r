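# Internal-coordinate measurement, restraint assignment, dictionary
# generation, restraint CIF serialization.

test_that("measured bonds/angles/torsions match brute-force recomputation", {
  for (kind in FIXTURE_KINDS) {
    cc <- fixtureComponent(kind, n = 4)
    g <- fixtureGraph(cc)
    m <- measureGeometry(cc, g)
    expect_equal(m@bonds$value, oracleBonds(cc), tolerance = 1e-9)
    x <- atomCoords(cc)
    for (i in seq_len(nrow(m@angles)))
      expect_equal(m@angles$value[i],
                   oracleAngle(x, m@angles$atom1[i], m@angles$atom2[i],
                               m@angles$atom3[i]),
                   tolerance = 1e-9)
    for (i in seq_len(nrow(m@torsions)))
      expect_lt(angularDiff(m@torsions$value[i],
                            oracleDihedral(x, m@torsions$atom1[i],
                                           m@torsions$atom2[i],
                                           m@torsions$atom3[i],
                                           m@torsions$atom4[i])),
                1e-9)
  }
})

test_that("measurement handles simple hand-computable geometries", {
  pair <- makeComponent("custom", id = "PR",
                        atoms = data.frame(name = c("C1", "C2"),
                                           element = "C", charge = 0L,
                                           is_hydrogen = FALSE,
                                           legacy_name = NA_character_),
                        bonds = data.frame(atom1 = "C1", atom2 = "C2",
                                           order = "single"),
                        coords = matrix(c(0, 0, 0, 1.5, 0, 0), 2, 3,
                                        byrow = TRUE,
                                        dimnames = list(c("C1", "C2"))))
  g <- fixtureGraph(pair)
  expect_equal(measureGeometry(pair, g)@bonds$value, 1.5)

  tri <- makeComponent("custom", id = "TRI",
                       atoms = data.frame(name = c("C1", "C2", "C3"),
                                          element = "C", charge = 0L,
                                          is_hydrogen = FALSE,
                                          legacy_name = NA_character_),
                       bonds = data.frame(atom1 = c("C1", "C2"),
                                          atom2 = c("C2", "C3"),
                                          order = "single"),
                       coords = matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3,
                                       byrow = TRUE,
                                       dimnames = list(c("C1", "C2",
                                                         "C3"))))
  m <- measureGeometry(tri, fixtureGraph(tri))
  expect_equal(m@angles$value, 90)

  # trans butane backbone torsion
  but <- fixtureComponent("alkane_chain", n = 4)
  m4 <- measureGeometry(but, fixtureGraph(but))
  backbone <- m4@torsions[m4@torsions$central1 == "C2" &
                            m4@torsions$central2 == "C3", ]
  main <- backbone[!backbone$h_positioning, ]
  expect_equal(abs(main$value), 180, tolerance = 1e-6)
})

test_that("degenerate and incomplete coordinates are errors", {
  cc <- fixtureComponent("alkane_chain", n = 2)
  g <- fixtureGraph(cc)
  cc2 <- cc
  cc2@coords["H1", ] <- cc2@coords["C1", ] + c(0.01, 0, 0)
  expect_error(measureGeometry(cc2, g), "degenerate")
  cc3 <- cc
  cc3@coords <- matrix(numeric(0), 0, 3)
  expect_error(measureGeometry(cc3, g), "no coordinates")
})

test_that("torsion periods follow hybridization of the central bond", {
  eth <- fixtureComponent("alkane_chain", n = 2)
  m <- measureGeometry(eth, fixtureGraph(eth))
  tor <- assignTorsionRestraints(fixtureGraph(eth), m)
  main <- m@torsions[!m@torsions$h_positioning, ]
  expect_equal(nrow(main), 1L)           # one eligible central bond
  expect_true(all(tor$period == 3L))
  expect_equal(abs(tor$ideal[1]), 60, tolerance = 1e-6)  # staggered

  ene <- makeEthene()
  ge <- fixtureGraph(ene)
  te <- assignTorsionRestraints(ge, measureGeometry(ene, ge))
  expect_true(all(te$period == 2L))
  expect_true(all(te$ideal %in% c(0, 180)))  # snapped

  bz <- fixtureComponent("benzene")
  gb <- fixtureGraph(bz)
  tb <- measureGeometry(bz, gb)@torsions
  ring <- paste0("C", 1:6)
  expect_false(any(tb$central1 %in% ring & tb$central2 %in% ring))

  # sp2-sp3 bond gets period 6
  ach <- fixtureComponent("acetic_acid")
  ta <- measureGeometry(ach, fixtureGraph(ach))@torsions
  cc_bond <- ta[ta$central1 == "C1" & ta$central2 == "C2" |
                  ta$central1 == "C2" & ta$central2 == "C1", ]
  expect_true(all(cc_bond$period == 6L))
})

test_that("exactly one non-positioning torsion per eligible central bond", {
  for (kind in FIXTURE_KINDS) {
    cc <- fixtureComponent(kind, n = 4)
    m <- measureGeometry(cc, fixtureGraph(cc))
    main <- m@torsions[!m@torsions$h_positioning, ]
    key <- paste(pmin(main$central1, main$central2),
                 pmax(main$central1, main$central2))
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("plane detection groups aromatic rings and sp2 centres", {
  bz <- fixtureComponent("benzene")
  pb <- detectPlanes(fixtureGraph(bz), bz)
  expect_equal(length(unique(pb$plane_id)), 1L)
  expect_equal(nrow(pb), 12L)

  meth <- fixtureComponent("alkane_chain", n = 1)
  expect_equal(nrow(detectPlanes(fixtureGraph(meth), meth)), 0L)

  act <- fixtureComponent("acetate")
  pa <- detectPlanes(fixtureGraph(act), act)
  expect_setequal(pa$atom_id, c("C1", "C2", "O1", "O2"))
})

test_that("chirality restraints flip sign under mirror inversion", {
  ala <- fixtureComponent("alanine_like")
  g <- fixtureGraph(ala)
  ch <- assignChirality(g, ala)
  expect_equal(nrow(ch), 1L)
  expect_identical(ch$center, "CA")
  expect_true(ch$sign %in% c("positive", "negative"))

  mir <- ala
  mir@coords[, 1] <- -mir@coords[, 1]
  ch2 <- assignChirality(fixtureGraph(mir), mir)
  expect_identical(ch2$sign,
                   ifelse(ch$sign == "positive", "negative", "positive"))

  ene <- makeEthene()
  expect_equal(nrow(assignChirality(fixtureGraph(ene), ene)), 0L)
})

test_that("e.s.d. policy floors then doubles reference s.d. values", {
  cc <- fixtureComponent("alkane_chain", n = 2)
  g <- fixtureGraph(cc)
  m <- measureGeometry(cc, g)
  ccKey <- typeKey(c("C1", "C2"), "bond", g)

  tabOf <- function(sd) {
    new("ReferenceTable",
        bonds = data.frame(type_key = ccKey, ideal = 1.53, sd = sd,
                           n_obs = 10L),
        angles = data.frame(type_key = character(0), ideal = numeric(0),
                            sd = numeric(0), n_obs = integer(0)))
  }
  pickCC <- function(d) {
    b <- bondRestraints(d)
    b$esd[b$atom1 == "C1" & b$atom2 == "C2"]
  }
  expect_equal(pickCC(buildDictionary(cc, m, graph = g,
                                      table = tabOf(0.009))), 0.018)
  expect_equal(pickCC(buildDictionary(cc, m, graph = g,
                                      table = tabOf(0.001))), 0.010)
  # type absent from table: configured default
  d0 <- buildDictionary(cc, m, graph = g)
  expect_true(all(bondRestraints(d0)$esd == 0.02))
  expect_true(all(angleRestraints(d0)$esd == 1.5))
})

test_that("every hydrogen is restrained in every fixture dictionary", {
  for (kind in FIXTURE_KINDS) {
    cc <- fixtureComponent(kind, n = 3)
    d <- fixtureDictionary(cc)
    hs <- atomTable(cc)$name[atomTable(cc)$is_hydrogen]
    expect_true(all(hs %in% c(d@bonds$atom1, d@bonds$atom2)))
    expect_true(all(hs %in% c(d@angles$atom1, d@angles$atom2,
                              d@angles$atom3)))
  }
})

test_that("restraint CIF write/read is an exact round trip", {
  for (kind in c("benzene", "alanine_like", "phosphate_like")) {
    cc <- fixtureComponent(kind)
    d <- fixtureDictionary(cc)
    d2 <- readRestraintCIF(writeRestraintCIF(d))
    expect_identical(componentId(d2), componentId(d))
    expect_identical(variantLabel(d2), variantLabel(d))
    expect_equal(bondRestraints(d2), bondRestraints(d))
    expect_equal(angleRestraints(d2), angleRestraints(d))
    expect_equal(torsionRestraints(d2)$ideal, torsionRestraints(d)$ideal)
    expect_equal(torsionRestraints(d2)$period,
                 torsionRestraints(d)$period)
    expect_identical(chiralityRestraints(d2)$sign,
                     chiralityRestraints(d)$sign)
    expect_equal(planeRestraints(d2), planeRestraints(d))
  }
})

test_that("discrete-ideal torsions round-trip through the period-0 form", {
  cc <- fixtureComponent("alkane_chain", n = 2)
  d <- fixtureDictionary(cc)
  d@torsions$period[1] <- 0L
  d@torsions$alt_ideals[[1]] <- c(-60, 180)
  validObject(d)
  d2 <- readRestraintCIF(writeRestraintCIF(d))
  expect_equal(d2@torsions$period[1], 0L)
  expect_equal(d2@torsions$alt_ideals[[1]], c(-60, 180))
  expect_equal(d2@torsions$ideal[1], d@torsions$ideal[1])
})

test_that("restraint CIF reading enforces schema and invariants", {
  cc <- fixtureComponent("alkane_chain", n = 1)
  d <- fixtureDictionary(cc)    # methane: no chirality
  txt <- writeRestraintCIF(d)
  expect_false(any(grepl("chem_comp_chir", txt)))
  d2 <- readRestraintCIF(txt)
  expect_equal(nrow(chiralityRestraints(d2)), 0L)

  minimal <- c("data_comp_ZZ",
               "_chem_comp.id ZZ",
               "loop_",
               "_chem_comp_bond.comp_id",
               "_chem_comp_bond.atom_id_1",
               "_chem_comp_bond.atom_id_2",
               "_chem_comp_bond.value_dist",
               "_chem_comp_bond.value_dist_esd",
               "ZZ A1 A2 1.5 0.02")
  d3 <- readRestraintCIF(minimal)
  expect_equal(nrow(bondRestraints(d3)), 1L)
  expect_equal(nrow(angleRestraints(d3)), 0L)

  badEsd <- sub("1.5 0.02", "1.5 0.0", minimal)
  expect_error(readRestraintCIF(badEsd), "esd")

  noCol <- minimal
  noCol[8] <- "_chem_comp_bond.value_other"  # value_dist column missing
  expect_error(readRestraintCIF(noCol), "mandatory")

  unknown <- c(minimal, "loop_", "_mystery_cat.a", "1")
  expect_warning(readRestraintCIF(unknown), "unknown")
})
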