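# Restraint energy, analytic gradients, minimization, Kabsch RMSD,
# round-trip verification.

twoAtomDict <- function(ideal = 1.5, esd = 0.1) {
  new("RestraintDictionary", componentId = "PR", variantLabel = "in_situ",
      bonds = data.frame(atom1 = "A1", atom2 = "A2", ideal = ideal,
                         esd = esd, stringsAsFactors = FALSE),
      angles = data.frame(atom1 = character(0), atom2 = character(0),
                          atom3 = character(0), ideal = numeric(0),
                          esd = numeric(0)),
      torsions = LigandForge:::emptyTorsionFrame(),
      chirality = data.frame(id = character(0), center = character(0),
                             n1 = character(0), n2 = character(0),
                             n3 = character(0), sign = character(0)),
      planes = data.frame(plane_id = character(0), atom_id = character(0),
                          esd = numeric(0)),
      provenance = "test")
}

test_that("energy is zero at the ideal geometry and counts unit residuals", {
  for (kind in c("alkane_chain", "benzene", "alanine_like")) {
    cc <- fixtureComponent(kind)
    d <- fixtureDictionary(cc)
    en <- restraintEnergy(atomCoords(cc), d, elements = elementsOf(cc))
    expect_lt(en$energy, 1e-12)
    expect_lt(max(abs(en$gradient)), 1e-6)
  }
  # one bond stretched by +1 esd contributes exactly weight x 1
  d <- twoAtomDict(ideal = 1.5, esd = 0.1)
  x <- matrix(c(0, 0, 0, 1.6, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("A1", "A2")))
  mdl <- EnergyModel(weights = c(bond = 2, angle = 1, torsion = 1,
                                 chirality = 1, plane = 1, repulsion = 0))
  expect_equal(restraintEnergy(x, d, mdl)$energy, 2 * 1.0)
})

test_that("the mirror image of a chiral fixture is penalized", {
  ala <- fixtureComponent("alanine_like")
  d <- fixtureDictionary(ala)
  mir <- atomCoords(ala)
  mir[, 1] <- -mir[, 1]
  mdl <- EnergyModel(weights = c(bond = 0, angle = 0, torsion = 0,
                                 chirality = 1, plane = 0, repulsion = 0))
  expect_gt(restraintEnergy(mir, d, mdl,
                            elements = elementsOf(ala))$energy, 0)
  expect_equal(restraintEnergy(atomCoords(ala), d, mdl,
                               elements = elementsOf(ala))$energy, 0)
})

test_that("analytic gradients match central finite differences", {
  for (kind in c("alkane_chain", "acetic_acid", "alanine_like",
                 "phosphate_like")) {
    for (seed in c(7, 23)) {
      cc <- fixtureComponent(kind)
      d <- fixtureDictionary(cc)
      x <- atomCoords(perturbComponent(cc, 0.08, seed = seed))
      el <- elementsOf(cc)
      en <- restraintEnergy(x, d, elements = el)
      h <- 1e-5
      gfd <- x * 0
      for (i in seq_len(nrow(x))) for (j in 1:3) {
        xp <- x; xp[i, j] <- xp[i, j] + h
        xm <- x; xm[i, j] <- xm[i, j] - h
        gfd[i, j] <- (restraintEnergy(xp, d, elements = el)$energy -
                        restraintEnergy(xm, d, elements = el)$energy) /
          (2 * h)
      }
      expect_lt(max(abs(en$gradient - gfd)) / max(abs(gfd)), 1e-4)
    }
  }
})

test_that("energy is invariant under rigid motion of the coordinates", {
  cc <- fixtureComponent("alanine_like")
  d <- fixtureDictionary(cc)
  x <- atomCoords(perturbComponent(cc, 0.05, seed = 3))
  el <- elementsOf(cc)
  e0 <- restraintEnergy(x, d, elements = el)$energy
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  x2 <- sweep(x %*% t(R), 2L, c(3.2, -1.1, 0.5), `+`)
  expect_equal(restraintEnergy(x2, d, elements = el)$energy, e0,
               tolerance = 1e-9)
})

test_that("Kabsch RMSD matches identity, rigid motion, and a grid oracle", {
  x <- atomCoords(fixtureComponent("acetate"))
  expect_equal(kabschRMSD(x, x), 0)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  x2 <- sweep(x %*% t(R), 2L, c(1, 2, 3), `+`)
  expect_lt(kabschRMSD(x, x2), 1e-9)

  sq <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3, byrow = TRUE,
               dimnames = list(paste0("P", 1:4)))
  sq2 <- sq
  sq2["P3", 1] <- sq2["P3", 1] + 0.1
  expect_equal(kabschRMSD(sq, sq2), oracleKabschRMSD(sq, sq2),
               tolerance = 1e-3)
  # larger asymmetric set against the oracle
  set.seed(5)
  a <- matrix(rnorm(18), 6, 3, dimnames = list(paste0("Q", 1:6)))
  b <- a + matrix(rnorm(18, sd = 0.05), 6, 3)
  expect_equal(kabschRMSD(a, b), oracleKabschRMSD(a, b),
               tolerance = 1e-3)
  expect_error(kabschRMSD(sq[1:2, ], sq2[1:2, ]), "3 atoms")
})

test_that("minimization honors convergence, determinism and zero weights", {
  cc <- fixtureComponent("alkane_chain", n = 2)
  d <- fixtureDictionary(cc)
  el <- elementsOf(cc)
  r0 <- minimizeGeometry(atomCoords(cc), d, elements = el)
  expect_true(r0@converged)
  expect_lt(r0@rmsdToStart, 0.01)

  # gaussian-perturbed start returns to the unperturbed geometry
  pc <- perturbComponent(cc, 0.1, seed = 42)
  r1 <- minimizeGeometry(atomCoords(pc), d, elements = el)
  expect_true(r1@converged)
  expect_lt(kabschRMSD(r1@finalCoords, atomCoords(cc)), 0.05)

  # determinism: identical runs are bit-identical
  r2 <- minimizeGeometry(atomCoords(pc), d, elements = el)
  expect_identical(r1@finalCoords, r2@finalCoords)
  expect_identical(r1@nIterations, r2@nIterations)

  zero <- EnergyModel(weights = c(bond = 0, angle = 0, torsion = 0,
                                  chirality = 0, plane = 0,
                                  repulsion = 0))
  rz <- minimizeGeometry(atomCoords(pc), d, model = zero, elements = el)
  expect_true(rz@converged)
  expect_equal(rz@rmsdToStart, 0, tolerance = 1e-12)
})

test_that("dictionaries minimize back to their source geometry", {
  for (kind in FIXTURE_KINDS) {
    cc <- fixtureComponent(kind, n = 4)
    d <- fixtureDictionary(cc)
    rt <- roundtripCheck(d, cc)
    expect_true(rt@converged)
    expect_lt(rt@rmsdToStart, 0.01)
  }
  # rigid aromatic ring: planar minimum stays planar
  bz <- fixtureComponent("benzene")
  rtb <- roundtripCheck(fixtureDictionary(bz), bz)
  expect_lt(rtb@rmsdToStart, 0.01)
  fit <- LigandForge:::bestFitPlane(rtb@finalCoords)
  expect_lt(fit$rms, 0.005)
})

test_that("a corrupted ideal value is detected by the round trip", {
  cc <- fixtureComponent("alkane_chain", n = 4)
  d <- fixtureDictionary(cc)
  i <- which(d@bonds$atom1 == "C2" & d@bonds$atom2 == "C3")
  d@bonds$ideal[i] <- d@bonds$ideal[i] + 0.5
  rt <- roundtripCheck(d, cc)
  expect_gt(rt@rmsdToStart, 0.05)
})
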