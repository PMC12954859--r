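# Shared fixtures and independent oracles used across the suite.

FIXTURE_KINDS <- c("alkane_chain", "benzene", "acetic_acid", "acetate",
                   "alanine_like", "phosphate_like")

fixtureComponent <- function(kind, n = 3L) makeComponent(kind, n = n)

fixtureGraph <- function(component)
  assignHybridization(buildGraph(component), component)

fixtureDictionary <- function(component, graph = fixtureGraph(component),
                              table = NULL) {
  buildDictionary(component, measureGeometry(component, graph),
                  graph = graph, table = table)
}

elementsOf <- function(component)
  stats::setNames(atomTable(component)$element, atomTable(component)$name)

# --- custom small molecules not in the fixture generator ---------------

customComponent <- function(id, spec, bonds, orders = NULL,
                            compClass = "non_polymer") {
  atoms <- data.frame(name = names(spec),
                      element = vapply(spec, function(s) s$el, ""),
                      charge = vapply(spec, function(s)
                        as.integer(s$q %||% 0L), 0L),
                      is_hydrogen = toupper(vapply(spec, function(s)
                        s$el, "")) %in% c("H", "D"),
                      legacy_name = NA_character_,
                      stringsAsFactors = FALSE)
  bdf <- data.frame(atom1 = vapply(bonds, `[[`, "", 1L),
                    atom2 = vapply(bonds, `[[`, "", 2L),
                    order = if (is.null(orders)) "single" else orders,
                    stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(spec, function(s) s$xyz))
  rownames(xyz) <- names(spec)
  makeComponent("custom", id = id, atoms = atoms, bonds = bdf,
                coords = xyz, compClass = compClass)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

makeEthanol <- function() {
  cc <- makeComponent("alkane_chain", n = 2)  # start from ethane
  a <- atomTable(cc); x <- atomCoords(cc)
  # replace H4 (on C2) by an O-H group
  keep <- setdiff(a$name, "H4")
  dirO <- (x["H4", ] - x["C2", ]) / sqrt(sum((x["H4", ] - x["C2", ])^2))
  spec <- lapply(keep, function(nm)
    list(el = a$element[a$name == nm], xyz = x[nm, ]))
  names(spec) <- keep
  spec$O1 <- list(el = "O", xyz = x["C2", ] + 1.43 * dirO)
  spec$HO <- list(el = "H", xyz = x["C2", ] + 1.43 * dirO +
                    0.98 * c(0.9, 0.3, 0.3) / sqrt(0.99))
  bonds <- list(c("C1", "C2"), c("C1", "H1"), c("C1", "H2"),
                c("C1", "H3"), c("C2", "H5"), c("C2", "H6"),
                c("C2", "O1"), c("O1", "HO"))
  customComponent("ETO", spec, bonds)
}

makeAcetonitrile <- function() {
  spec <- list(
    C1 = list(el = "C", xyz = c(0, 0, 0)),
    C2 = list(el = "C", xyz = c(1.46, 0, 0)),
    N1 = list(el = "N", xyz = c(2.62, 0, 0)),
    H1 = list(el = "H", xyz = c(-0.36, 1.03, 0)),
    H2 = list(el = "H", xyz = c(-0.36, -0.51, 0.89)),
    H3 = list(el = "H", xyz = c(-0.36, -0.51, -0.89)))
  customComponent("ACN", spec,
                  list(c("C1", "C2"), c("C2", "N1"), c("C1", "H1"),
                       c("C1", "H2"), c("C1", "H3")),
                  orders = c("single", "triple", "single", "single",
                             "single"))
}

makeEthene <- function() {
  s <- sin(60 / 180 * pi); c2 <- cos(60 / 180 * pi)
  spec <- list(
    C1 = list(el = "C", xyz = c(0, 0, 0)),
    C2 = list(el = "C", xyz = c(1.33, 0, 0)),
    H1 = list(el = "H", xyz = c(-1.09 * c2, 1.09 * s, 0)),
    H2 = list(el = "H", xyz = c(-1.09 * c2, -1.09 * s, 0)),
    H3 = list(el = "H", xyz = c(1.33 + 1.09 * c2, 1.09 * s, 0)),
    H4 = list(el = "H", xyz = c(1.33 + 1.09 * c2, -1.09 * s, 0)))
  customComponent("ETN", spec,
                  list(c("C1", "C2"), c("C1", "H1"), c("C1", "H2"),
                       c("C2", "H3"), c("C2", "H4")),
                  orders = c("double", "single", "single", "single",
                             "single"))
}

# --- brute-force oracles -----------------------------------------------

# naive recomputation of bond lengths and angles, tuple by tuple
oracleBonds <- function(component) {
  x <- atomCoords(component); b <- bondTable(component)
  vapply(seq_len(nrow(b)), function(i)
    sqrt(sum((x[b$atom1[i], ] - x[b$atom2[i], ])^2)), numeric(1))
}

oracleAngle <- function(x, a1, a2, a3) {
  u <- x[a1, ] - x[a2, ]; v <- x[a3, ] - x[a2, ]
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# dihedral by projecting the outer bonds onto the plane normal to the
# central bond (independent of the normal-vector cross-product route)
oracleDihedral <- function(x, a1, a2, a3, a4) {
  axis <- x[a3, ] - x[a2, ]; axis <- axis / sqrt(sum(axis^2))
  u <- x[a1, ] - x[a2, ]; v <- x[a4, ] - x[a3, ]
  up <- u - sum(u * axis) * axis
  vp <- v - sum(v * axis) * axis
  cr <- c(up[2] * vp[3] - up[3] * vp[2], up[3] * vp[1] - up[1] * vp[3],
          up[1] * vp[2] - up[2] * vp[1])
  atan2(sum(cr * axis), sum(up * vp)) * 180 / pi
}

# smallest angular separation in degrees (so +180 and -180 agree)
angularDiff <- function(a, b) {
  d <- (a - b) %% 360
  min(d, 360 - d)
}

# grid + simplex search over rotations (no SVD): independent Kabsch
# oracle for small point sets
oracleKabschRMSD <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A)); B <- sweep(B, 2L, colMeans(B))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rotmat(ang)) - B)^2)))
  grid <- seq(0, 2 * pi, length.out = 13L)[-13L]
  best <- NULL; bestv <- Inf
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt$value
}

classificationRank <- function(cls)
  match(cls, c("awesome", "superior", "satisfactory", "fail"))
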