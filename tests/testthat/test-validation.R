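# Z-scores, s.d. floors, maximum-Z classification, reference tables.

test_that("type keys are canonical and symmetric", {
  eth <- fixtureComponent("alkane_chain", n = 2)
  g <- fixtureGraph(eth)
  expect_identical(typeKey(c("C1", "C2"), "bond", g), "C.sp3-C.sp3")
  expect_identical(typeKey(c("C2", "C1"), "bond", g),
                   typeKey(c("C1", "C2"), "bond", g))
  bz <- fixtureComponent("benzene")
  gb <- fixtureGraph(bz)
  expect_identical(typeKey(c("C1", "C2", "C3"), "angle", gb),
                   "C.sp2.ar|C.sp2.ar|C.sp2.ar")
  expect_identical(typeKey(c("C3", "C2", "C1"), "angle", gb),
                   typeKey(c("C1", "C2", "C3"), "angle", gb))
})

test_that("Z-scores reproduce the phosphorus-outlier worked example", {
  # observed P-O bond 1.681 A against strict reference 1.623 +/- 0.009:
  # just beyond the satisfactory band
  expect_equal(zscore(1.681, 1.623, 0.009), (1.681 - 1.623) / 0.009)
  expect_gt(zscore(1.681, 1.623, 0.009), 6)
  # 1.674 A lies within the satisfactory band
  expect_equal(zscore(1.674, 1.623, 0.009), (1.674 - 1.623) / 0.009)
  expect_lt(zscore(1.674, 1.623, 0.009), 6)
  # the organometal-inclusive reference is far more permissive
  expect_lt(zscore(1.681, 1.608, 0.043), 2)
  expect_equal(zscore(1.7, 1.7, 0.5), 0)
  expect_error(zscore(1.5, 1.5, 0), "positive")
})

test_that("s.d. floors replace deficient values", {
  cfg <- ValidationConfig()
  r <- applySdFloor(0, "bond", cfg)
  expect_equal(r$sd, 0.005)
  expect_true(r$floored)
  r2 <- applySdFloor(0.5, "angle", cfg)
  expect_equal(r2$sd, 0.75)
  expect_true(r2$floored)
  r3 <- applySdFloor(0.02, "bond", cfg)
  expect_equal(r3$sd, 0.02)
  expect_false(r3$floored)
  expect_error(applySdFloor(-0.1, "bond", cfg), ">= 0")
})

test_that("classification bands are strict at 2, 4, 6", {
  cls <- function(z, fl = FALSE)
    classifyMaxZ(z, usedFloor = fl)$classification
  expect_identical(cls(1.2), "awesome")
  expect_identical(cls(6.44), "fail")
  expect_identical(cls(3.9), "superior")
  expect_identical(cls(5.99), "satisfactory")
  # boundary values belong to the worse class
  expect_identical(cls(2), "superior")
  expect_identical(cls(4), "satisfactory")
  expect_identical(cls(6), "fail")
  # floored s.d. overrides the band
  v <- classifyMaxZ(1.2, usedFloor = TRUE)
  expect_identical(v$classification, "satisfactory")
  expect_true("reasonable_std" %in% v$flags)
  expect_identical(classifyMaxZ(7, usedFloor = TRUE)$classification,
                   "fail")
  expect_true("side_chain" %in%
                classifyMaxZ(1, sideChain = TRUE)$flags)
})

test_that("classification change points located by bisection are 2/4/6", {
  locate <- function(lo, hi) {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (identical(classifyMaxZ(mid)$classification,
                    classifyMaxZ(lo)$classification)) lo <- mid
      else hi <- mid
    }
    hi
  }
  expect_equal(locate(1, 3), 2, tolerance = 1e-12)
  expect_equal(locate(3, 5), 4, tolerance = 1e-12)
  expect_equal(locate(5, 7), 6, tolerance = 1e-12)
})

scoredFixture <- function(kind = "acetate", ...) {
  cc <- fixtureComponent(kind)
  g <- fixtureGraph(cc)
  m <- measureGeometry(cc, g)
  d <- buildDictionary(cc, m, graph = g)
  list(cc = cc, g = g, m = m,
       tab = makeReferenceTable(d, g, ...))
}

test_that("a geometry identical to the table ideals is awesome", {
  f <- scoredFixture()
  rep <- validateGeometry(f$m, f$g, f$tab)
  expect_identical(classification(rep), "awesome")
  expect_equal(maxAbsZ(rep), 0)
  expect_equal(rep@nUnmatched, 0L)
  expect_length(reportFlags(rep), 0L)
})

test_that("a single outlier bond drives the maximum-Z verdict", {
  f <- scoredFixture("alkane_chain")
  # push one measured bond 7 sd away from its reference ideal
  m <- f$m
  i <- which(m@bonds$atom1 == "C1" & m@bonds$atom2 == "C2")
  key <- typeKey(c("C1", "C2"), "bond", f$g)
  sd <- f$tab@bonds$sd[f$tab@bonds$type_key == key]
  m@bonds$value[i] <- m@bonds$value[i] + 7 * sd
  rep <- validateGeometry(m, f$g, f$tab)
  expect_identical(classification(rep), "fail")
  # 5 sd away: satisfactory
  m@bonds$value[i] <- f$m@bonds$value[i] + 5 * sd
  expect_identical(classification(validateGeometry(m, f$g, f$tab)),
                   "satisfactory")
})

test_that("increasing a single deviation never improves the verdict", {
  f <- scoredFixture("acetic_acid")
  key <- typeKey(c("C1", "C2"), "bond", f$g)
  sd <- f$tab@bonds$sd[f$tab@bonds$type_key == key]
  i <- which(f$m@bonds$atom1 == "C1" & f$m@bonds$atom2 == "C2")
  last <- 1L
  for (dz in c(0, 1, 3, 5, 7, 20)) {
    m <- f$m
    m@bonds$value[i] <- m@bonds$value[i] + dz * sd
    r <- classificationRank(
      classification(validateGeometry(m, f$g, f$tab)))
    expect_gte(r, last)
    last <- r
  }
})

test_that("rmsZ equals the brute-force quadratic mean; Z is scale-free", {
  f <- scoredFixture("acetate", bias = 0.004)
  rep <- validateGeometry(f$m, f$g, f$tab)
  s <- termScores(rep)
  for (kind in c("bond", "angle")) {
    z <- s$z[s$matched & s$kind == kind]
    expect_equal(unname(rmsZ(rep)[if (kind == "bond") "bonds"
                                  else "angles"]),
                 sqrt(mean(z^2)))
  }
  k <- 3.7
  expect_equal(zscore(1.54 * k, 1.53 * k, 0.01 * k),
               zscore(1.54, 1.53, 0.01))
})

test_that("zero-s.d. reference entries engage the floored second pass", {
  f <- scoredFixture("alkane_chain")
  key <- typeKey(c("C1", "C2"), "bond", f$g)
  tab0 <- makeReferenceTable(
    fixtureDictionary(fixtureComponent("alkane_chain")), f$g,
    sdOverrides = stats::setNames(0, key))
  rep <- validateGeometry(f$m, f$g, tab0)
  expect_identical(classification(rep), "satisfactory")
  expect_true("reasonable_std" %in% reportFlags(rep))
  s <- termScores(rep)
  expect_true(any(s$floored[s$type_key == key]))

  # with all s.d. above the floors the pass-2 path is never taken and
  # a raw pass never earns reasonable_std
  rep2 <- validateGeometry(f$m, f$g, f$tab)
  expect_false("reasonable_std" %in% reportFlags(rep2))
})

test_that("side-chain scope drops all-backbone terms and flags the report", {
  ala <- fixtureComponent("alanine_like")
  g <- fixtureGraph(ala)
  m <- measureGeometry(ala, g)
  tab <- makeReferenceTable(buildDictionary(ala, m, graph = g), g)
  rep <- validateGeometry(m, g, tab, sideChainOnly = TRUE)
  expect_true("side_chain" %in% reportFlags(rep))
  s <- termScores(rep)
  backbone <- ValidationConfig()@sideChainBackboneNames
  backboneOnly <- vapply(strsplit(s$atoms, "-", fixed = TRUE),
                         function(a) all(a %in% backbone),
                         logical(1))
  expect_false(any(backboneOnly))
  # the full-scope report has strictly more terms
  repFull <- validateGeometry(m, g, tab)
  expect_gt(nrow(termScores(repFull)), nrow(s))
})

test_that("an empty reference table fails with everything unmatched", {
  f <- scoredFixture("acetate")
  empty <- new("ReferenceTable",
               bonds = LigandForge:::emptyRefFrame(),
               angles = LigandForge:::emptyRefFrame())
  expect_message(rep <- validateGeometry(f$m, f$g, empty), "empty")
  expect_identical(classification(rep), "fail")
  expect_equal(rep@nUnmatched, nrow(termScores(rep)))
  expect_true(is.na(maxAbsZ(rep)))
})

test_that("reference tables read from delimited text", {
  two <- c("kind\ttype_key\tideal\tsd\tn_obs",
           "bond\tC.sp3-C.sp3\t1.53\t0.012\t40",
           "angle\tC.sp3|C.sp3|C.sp3\t111.2\t1.3\t25")
  tab <- readReferenceTable(two)
  expect_equal(nrow(tab@bonds), 1L)
  expect_equal(nrow(tab@angles), 1L)
  expect_equal(tab@bonds$ideal, 1.53)

  csv <- gsub("\t", ",", two)
  expect_equal(readReferenceTable(csv)@bonds$sd, 0.012)

  zero <- c(two, "bond\tO.sp3-P.sp3\t1.59\t0\t1")
  expect_equal(min(readReferenceTable(zero)@bonds$sd), 0)

  neg <- c(two, "bond\tX-Y\t1.5\t-0.01\t3")
  expect_error(readReferenceTable(neg), "negative sd")

  dup <- c(two, "bond\tC.sp3-C.sp3\t1.54\t0.02\t10")
  expect_warning(tb <- readReferenceTable(dup), "last wins")
  expect_equal(tb@bonds$ideal, 1.54)

  expect_equal(nrow(readReferenceTable(character(0))@bonds), 0L)

  # write/read round trip
  rt <- readReferenceTable(writeReferenceTable(tab))
  expect_equal(rt@bonds, tab@bonds)
  expect_equal(rt@angles, tab@angles)
})
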