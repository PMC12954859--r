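# Synthetic fixture components with idealized geometries, coordinate
# perturbation, and self-consistent reference tables.  Geometry
# constants are conventional textbook values: C-C 1.53 A, aromatic C-C
# 1.39 A, C-H 1.09 A, C=O 1.21-1.25 A, C-O(H) 1.34 A, O-H 0.98 A,
# N-H 1.01 A, P-O 1.48-1.60 A, tetrahedral angle 109.47 deg, trigonal
# 120 deg.

TET <- 109.4712206344907  # tetrahedral angle, degrees

rotAbout <- function(v, axis, angleDeg) {
  # Rodrigues rotation of v about unit axis
  th <- angleDeg / RAD2DEG
  k <- unitv(axis)
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

perpUnit <- function(u) {
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  unitv(ref - sum(ref * u) * u)
}

# directions at TET degrees from u (the unit direction from the centre
# toward its existing neighbour), spaced 120 degrees in azimuth
tripodDirections <- function(u, n = 3L, az0 = 0) {
  u <- unitv(u)
  e1 <- perpUnit(u); e2 <- cross3(u, e1)
  az <- (az0 + 120 * (seq_len(n) - 1L)) / RAD2DEG
  ct <- cos(TET / RAD2DEG); st <- sin(TET / RAD2DEG)
  lapply(az, function(a) ct * u + st * (cos(a) * e1 + sin(a) * e2))
}

# two directions completing a tetrahedral centre with existing bond
# directions u1, u2
bisectorDirections <- function(u1, u2) {
  a <- -unitv(unitv(u1) + unitv(u2))
  pv <- unitv(cross3(u1, u2))
  g <- (TET / 2) / RAD2DEG
  list(cos(g) * a + sin(g) * pv, cos(g) * a - sin(g) * pv)
}

alkaneFixture <- function(n) {
  L <- 1.53; LH <- 1.09
  s <- L * sin(TET / 2 / RAD2DEG); cz <- L * cos(TET / 2 / RAD2DEG)
  cpos <- t(vapply(seq_len(n), function(i)
    c((i - 1) * s, 0, ((i - 1) %% 2) * cz), numeric(3)))
  cn <- paste0("C", seq_len(n))
  rownames(cpos) <- cn
  atoms <- list(); coords <- list(); bonds <- list()
  for (i in seq_len(n)) {
    atoms[[length(atoms) + 1L]] <- c(cn[i], "C")
    coords[[cn[i]]] <- cpos[i, ]
    if (i > 1L)
      bonds[[length(bonds) + 1L]] <- c(cn[i - 1L], cn[i])
  }
  hserial <- 0L
  addH <- function(carbon, dirs) {
    for (d in dirs) {
      hserial <<- hserial + 1L
      nm <- paste0("H", hserial)
      atoms[[length(atoms) + 1L]] <<- c(nm, "H")
      coords[[nm]] <<- coords[[carbon]] + LH * d
      bonds[[length(bonds) + 1L]] <<- c(carbon, nm)
    }
  }
  if (n == 1L) {
    d <- tripodDirections(c(0, 0, -1), 3L)
    addH("C1", c(list(c(0, 0, -1)), d))
  } else {
    for (i in seq_len(n)) {
      if (i == 1L) {
        u <- unitv(cpos[2L, ] - cpos[1L, ])
        addH(cn[i], tripodDirections(u, 3L, az0 = 0))
      } else if (i == n) {
        u <- unitv(cpos[n - 1L, ] - cpos[n, ])
        addH(cn[i], tripodDirections(u, 3L, az0 = 60))
      } else {
        u1 <- unitv(cpos[i - 1L, ] - cpos[i, ])
        u2 <- unitv(cpos[i + 1L, ] - cpos[i, ])
        addH(cn[i], bisectorDirections(u1, u2))
      }
    }
  }
  assembleFixture(if (n == 1L) "MTH" else c("ETH", "PRP", "BUT",
                                            "PNT")[min(n - 1L, 4L)],
                  atoms, bonds, coords)
}

assembleFixture <- function(id, atoms, bonds, coords, charge = NULL,
                            compClass = "non_polymer",
                            smiles = character(0)) {
  am <- do.call(rbind, atoms)
  nm <- am[, 1L]
  chg <- integer(length(nm))
  if (!is.null(charge)) chg[match(names(charge), nm)] <- charge
  adf <- atomFrame(nm, am[, 2L], chg)
  bm <- do.call(rbind, bonds)
  bdf <- data.frame(atom1 = bm[, 1L], atom2 = bm[, 2L],
                    order = rep("single", nrow(bm)),
                    stringsAsFactors = FALSE)
  xyz <- do.call(rbind, coords[nm])
  rownames(xyz) <- nm
  newComponent(id = id, atoms = adf, bonds = bdf, coords = xyz,
               compClass = compClass, smiles = smiles,
               coordSource = "synthetic")
}

benzeneFixture <- function() {
  atoms <- list(); bonds <- list(); coords <- list()
  for (k in 1:6) {
    a <- (k - 1) * 60 / RAD2DEG
    cn <- paste0("C", k); hn <- paste0("H", k)
    atoms[[length(atoms) + 1L]] <- c(cn, "C")
    atoms[[length(atoms) + 1L]] <- c(hn, "H")
    coords[[cn]] <- c(1.39 * cos(a), 1.39 * sin(a), 0)
    coords[[hn]] <- c(2.48 * cos(a), 2.48 * sin(a), 0)
    bonds[[length(bonds) + 1L]] <- c(cn, hn)
    bonds[[length(bonds) + 1L]] <- c(cn, paste0("C", k %% 6 + 1L))
  }
  cc <- assembleFixture("BNZ", atoms, bonds, coords,
                        smiles = "c1ccccc1")
  cc@bonds$order[cc@bonds$atom1 %in% paste0("C", 1:6) &
                   cc@bonds$atom2 %in% paste0("C", 1:6)] <- "aromatic"
  validObject(cc)
  cc
}

aceticFixture <- function(protonated = TRUE) {
  rotZ <- function(v, a) rotAbout(v, c(0, 0, 1), a)
  C2 <- c(0, 0, 0)
  C1 <- c(-1.50, 0, 0)
  dCO <- if (protonated) c(1.21, 1.34) else c(1.25, 1.25)
  O1 <- dCO[1L] * c(cos(60 / RAD2DEG), sin(60 / RAD2DEG), 0)
  O2 <- dCO[2L] * c(cos(-60 / RAD2DEG), sin(-60 / RAD2DEG), 0)
  atoms <- list(c("C1", "C"), c("C2", "C"), c("O1", "O"), c("O2", "O"))
  coords <- list(C1 = C1, C2 = C2, O1 = O1, O2 = O2)
  bonds <- list(c("C1", "C2"), c("C2", "O1"), c("C2", "O2"))
  hm <- tripodDirections(unitv(C2 - C1), 3L, az0 = 90)
  for (k in 1:3) {
    nm <- paste0("H", k)
    atoms[[length(atoms) + 1L]] <- c(nm, "H")
    coords[[nm]] <- C1 + 1.09 * hm[[k]]
    bonds[[length(bonds) + 1L]] <- c("C1", nm)
  }
  if (protonated) {
    u <- unitv(C2 - O2)
    cand <- list(rotZ(u, 106), rotZ(u, -106))
    d <- cand[[which.max(vapply(cand, function(x)
      vnorm(O2 + 0.98 * x - O1), numeric(1)))]]
    atoms[[length(atoms) + 1L]] <- c("H4", "H")
    coords[["H4"]] <- O2 + 0.98 * d
    bonds[[length(bonds) + 1L]] <- c("O2", "H4")
  }
  cc <- assembleFixture(if (protonated) "ACH" else "ACT", atoms, bonds,
                        coords,
                        charge = if (protonated) NULL else c(O2 = -1L),
                        smiles = if (protonated) "CC(=O)O"
                                 else "CC(=O)[O-]")
  cc@bonds$order[cc@bonds$atom1 == "C2" & cc@bonds$atom2 == "O1"] <-
    "double"
  validObject(cc)
  cc
}

alanineFixture <- function() {
  t1 <- c(1, 1, 1) / sqrt(3); t2 <- c(1, -1, -1) / sqrt(3)
  t3 <- c(-1, 1, -1) / sqrt(3); t4 <- c(-1, -1, 1) / sqrt(3)
  CA <- c(0, 0, 0)
  N <- CA + 1.47 * t1
  C <- CA + 1.52 * t2
  CB <- CA + 1.53 * t3
  HA <- CA + 1.09 * t4
  u <- unitv(CA - C)                     # sp2 plane about C
  axis <- unitv(cross3(u, t1))
  O <- C + 1.23 * rotAbout(u, axis, 120)
  OXT <- C + 1.32 * rotAbout(u, axis, -120)
  uo <- unitv(C - OXT)
  HXT <- OXT + 0.98 * rotAbout(uo, axis, 110)
  hn <- tripodDirections(unitv(CA - N), 2L, az0 = 0)
  H <- N + 1.01 * hn[[1L]]
  H2 <- N + 1.01 * hn[[2L]]
  hb <- tripodDirections(unitv(CA - CB), 3L, az0 = 30)
  atoms <- list(c("N", "N"), c("CA", "C"), c("C", "C"), c("O", "O"),
                c("OXT", "O"), c("CB", "C"), c("H", "H"), c("H2", "H"),
                c("HA", "H"), c("HXT", "H"))
  coords <- list(N = N, CA = CA, C = C, O = O, OXT = OXT, CB = CB,
                 H = H, H2 = H2, HA = HA, HXT = HXT)
  bonds <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"),
                c("CA", "CB"), c("N", "H"), c("N", "H2"), c("CA", "HA"),
                c("OXT", "HXT"))
  for (k in 1:3) {
    nm <- paste0("HB", k)
    atoms[[length(atoms) + 1L]] <- c(nm, "H")
    coords[[nm]] <- CB + 1.09 * hb[[k]]
    bonds[[length(bonds) + 1L]] <- c("CB", nm)
  }
  cc <- assembleFixture("ALX", atoms, bonds, coords,
                        compClass = "amino_acid",
                        smiles = "CC(N)C(=O)O")
  cc@bonds$order[cc@bonds$atom1 == "C" & cc@bonds$atom2 == "O"] <- "double"
  validObject(cc)
  cc
}

phosphateFixture <- function() {
  t1 <- c(1, 1, 1) / sqrt(3); t2 <- c(1, -1, -1) / sqrt(3)
  t3 <- c(-1, 1, -1) / sqrt(3); t4 <- c(-1, -1, 1) / sqrt(3)
  P1 <- c(0, 0, 0)
  O1 <- P1 + 1.60 * t1    # bridging ester O
  O2 <- P1 + 1.48 * t2    # P=O
  O3 <- P1 + 1.57 * t3    # P-OH
  O4 <- P1 + 1.57 * t4    # P-OH
  C1 <- O1 + 1.44 * tripodDirections(unitv(P1 - O1), 1L, az0 = 0)[[1L]]
  atoms <- list(c("P1", "P"), c("O1", "O"), c("O2", "O"), c("O3", "O"),
                c("O4", "O"), c("C1", "C"))
  coords <- list(P1 = P1, O1 = O1, O2 = O2, O3 = O3, O4 = O4, C1 = C1)
  bonds <- list(c("P1", "O1"), c("P1", "O2"), c("P1", "O3"),
                c("P1", "O4"), c("O1", "C1"))
  hm <- tripodDirections(unitv(O1 - C1), 3L, az0 = 60)
  for (k in 1:3) {
    nm <- paste0("H1", k)
    atoms[[length(atoms) + 1L]] <- c(nm, "H")
    coords[[nm]] <- C1 + 1.09 * hm[[k]]
    bonds[[length(bonds) + 1L]] <- c("C1", nm)
  }
  for (o in c("O3", "O4")) {
    nm <- paste0("H", o)
    atoms[[length(atoms) + 1L]] <- c(nm, "H")
    coords[[nm]] <- coords[[o]] +
      0.98 * tripodDirections(unitv(P1 - coords[[o]]), 1L, az0 = 40)[[1L]]
    bonds[[length(bonds) + 1L]] <- c(o, nm)
  }
  cc <- assembleFixture("MPH", atoms, bonds, coords,
                        smiles = "COP(=O)(O)O")
  cc@bonds$order[cc@bonds$atom1 == "P1" & cc@bonds$atom2 == "O2"] <-
    "double"
  validObject(cc)
  cc
}

#' Make a synthetic fixture component
#'
#' Chemically sensible toy components with idealized hard-coded
#' geometries, full hydrogen sets and correct formal charges, so the
#' whole pipeline can run without external databases.  Kinds:
#' \code{alkane_chain} (n carbons, staggered), \code{benzene},
#' \code{acetic_acid} (protonated acid, 8 atoms), \code{acetate}
#' (deprotonated, 7 atoms, net charge -1), \code{alanine_like} (an
#' amino acid with H2/OXT/HXT termini and a chiral CA),
#' \code{phosphate_like} (a methyl phosphate diester with two acidic
#' protons), and \code{custom} (caller-supplied atoms/bonds/coords).
#'
#' @param kind fixture kind (see above).
#' @param n chain length for \code{alkane_chain}.
#' @param seed random seed used when \code{noiseSigma > 0}.
#' @param noiseSigma Gaussian coordinate noise applied after
#'   construction, in Angstrom (0 = exact idealized geometry).
#' @param ... for \code{kind = "custom"}: \code{id}, \code{atoms}
#'   (data.frame as in \code{\linkS4class{Component}}), \code{bonds},
#'   \code{coords}, optional \code{compClass}.
#' @return a \code{\linkS4class{Component}}.
#' @examples
#' makeComponent("acetate")
#' @export
makeComponent <- function(kind = c("alkane_chain", "benzene",
                                   "acetic_acid", "acetate",
                                   "alanine_like", "phosphate_like",
                                   "custom"),
                          n = 3L, seed = 1L, noiseSigma = 0, ...) {
  kind <- match.arg(kind)
  cc <- switch(kind,
    alkane_chain = { stopifnot(n >= 1L); alkaneFixture(n) },
    benzene = benzeneFixture(),
    acetic_acid = aceticFixture(TRUE),
    acetate = aceticFixture(FALSE),
    alanine_like = alanineFixture(),
    phosphate_like = phosphateFixture(),
    custom = {
      args <- list(...)
      need <- setdiff(c("id", "atoms", "bonds"), names(args))
      if (length(need))
        stop("custom fixture needs: ", paste(need, collapse = ", "),
             call. = FALSE)
      newComponent(id = args$id, atoms = args$atoms, bonds = args$bonds,
                   coords = args$coords,
                   compClass = args$compClass %||% "non_polymer",
                   coordSource = "synthetic")
    })
  validObject(cc)
  if (noiseSigma > 0) cc <- perturbComponent(cc, noiseSigma, seed)
  cc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Perturb a component's coordinates
#'
#' Adds independent Gaussian noise (standard deviation \code{sigma} per
#' Cartesian component) to every atom.  Deterministic per seed; the
#' global RNG state is left untouched.
#'
#' @param component a component with coordinates.
#' @param sigma noise s.d. in Angstrom.
#' @param seed integer seed.
#' @return the perturbed component.
#' @export
perturbComponent <- function(component, sigma, seed = 1L) {
  if (!hasCoords(component))
    stop("component has no coordinates", call. = FALSE)
  if (sigma == 0) return(component)
  xyz <- component@coords
  noise <- withLocalSeed(seed,
    matrix(stats::rnorm(length(xyz), sd = sigma), nrow(xyz), 3L))
  component@coords <- xyz + noise
  component
}

#' Make a reference table consistent with a dictionary
#'
#' Builds a synthetic reference table (a stand-in for CSD/Mogul output)
#' from a dictionary: one entry per distinct bond/angle type key, with
#' ideal equal to the mean of that key's dictionary ideals plus an
#' optional bias, a stated s.d., and pseudo-random observation counts.
#' With zero bias the table is exactly consistent with the dictionary,
#' so the source geometry validates as "awesome"; a bias of b with s.d.
#' s induces a known Z-score of b/s on the biased key.
#'
#' @param dictionary a \code{\linkS4class{RestraintDictionary}}.
#' @param graph the matching graph with hybridization (for type keys).
#' @param sdBond,sdAngle s.d. assigned to bond / angle entries.
#' @param bias offset added to the ideal of the biased keys.
#' @param biasKeys type keys to bias (default: all).
#' @param sdOverrides optional named vector type_key -> s.d. (e.g. to
#'   exercise the zero-s.d. floor path).
#' @param seed seed for the synthetic observation counts.
#' @return a \code{\linkS4class{ReferenceTable}}.
#' @export
makeReferenceTable <- function(dictionary, graph, sdBond = 0.01,
                               sdAngle = 1.0, bias = 0, biasKeys = NULL,
                               sdOverrides = NULL, seed = 1L) {
  entries <- function(df, kind, sd0) {
    if (!nrow(df)) return(emptyRefFrame())
    keys <- vapply(seq_len(nrow(df)), function(i)
      typeKey(unlist(df[i, grep("^atom", names(df))]), kind, graph), "")
    agg <- tapply(df$ideal, keys, mean)
    out <- data.frame(type_key = names(agg), ideal = as.numeric(agg),
                      sd = sd0, n_obs = 0L, stringsAsFactors = FALSE)
    sel <- if (is.null(biasKeys)) rep(TRUE, nrow(out))
           else out$type_key %in% biasKeys
    out$ideal[sel] <- out$ideal[sel] + bias
    if (!is.null(sdOverrides)) {
      hit <- match(out$type_key, names(sdOverrides))
      out$sd[!is.na(hit)] <- sdOverrides[hit[!is.na(hit)]]
    }
    rownames(out) <- NULL
    out
  }
  bonds <- entries(dictionary@bonds, "bond", sdBond)
  angles <- entries(dictionary@angles, "angle", sdAngle)
  nobs <- withLocalSeed(seed,
    sample(3:50, nrow(bonds) + nrow(angles), replace = TRUE))
  if (nrow(bonds)) bonds$n_obs <- nobs[seq_len(nrow(bonds))]
  if (nrow(angles)) angles$n_obs <- nobs[nrow(bonds) + seq_len(nrow(angles))]
  new("ReferenceTable", bonds = bonds, angles = angles)
}
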