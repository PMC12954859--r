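# Restraint energy function with analytic gradients.

# hydrogen uses the reduced radius conventional in restraint
# minimizers, so ordinary 1-5 H...X contacts are not penalized
VDW_RADII <- c(H = 1.00, D = 1.00, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
               F = 1.47, SI = 2.10, P = 1.80, S = 1.80, CL = 1.75,
               SE = 1.90, BR = 1.85, I = 1.98)

# chirality flat-bottom: penalize signed volume on the wrong side of
# +/- CHIR_VMIN; zero force at any correctly-signed tetrahedral volume
CHIR_VMIN <- 0.5
CHIR_ESD <- 0.2

guessElements <- function(atomNames) {
  two <- toupper(substr(gsub("[0-9'\"]", "", atomNames), 1L, 2L))
  one <- substr(two, 1L, 1L)
  el <- ifelse(two %in% names(VDW_RADII), two,
               ifelse(one %in% names(VDW_RADII), one, NA_character_))
  stats::setNames(el, atomNames)
}

# nonbonded pair list: atoms >= 4 bonds apart (or disconnected), with
# per-pair cutoffs from scaled van der Waals radii
repulsionPairs <- function(atomNames, dictBonds, model, elements) {
  n <- length(atomNames)
  if (n < 2L) return(NULL)
  g <- igraph::graph_from_data_frame(
    dictBonds[, c("atom1", "atom2")], directed = FALSE,
    vertices = data.frame(name = atomNames))
  d <- igraph::distances(g)
  d <- d[atomNames, atomNames]
  idx <- which(upper.tri(d) & (d >= 4 | is.infinite(d)), arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  r <- VDW_RADII[elements[atomNames[idx[, 1L]]]] +
    VDW_RADII[elements[atomNames[idx[, 2L]]]]
  cutoff <- ifelse(is.na(r), model@repulsionCutoff, model@vdwScale * r)
  list(i = idx[, 1L], j = idx[, 2L], cutoff = unname(cutoff))
}

#' Restraint energy and gradient
#'
#' Evaluates the weighted restraint pseudo-energy of a coordinate set
#' under a dictionary: squared (value - ideal)/esd residuals for bonds
#' and angles, wrap-aware periodic (or nearest-discrete-ideal) residuals
#' for torsions, a one-sided penalty on wrongly-signed chiral volumes, a
#' best-fit-plane deviation term, and a repulsive-only nonbonded term --
#' a one-sided quadratic penalty for pairs at least four bonds apart
#' that approach closer than a scaled sum of van der Waals radii.  The
#' gradient is analytic throughout.
#'
#' @param coords numeric matrix (atoms x 3) with rownames covering every
#'   atom named in the dictionary.
#' @param dictionary a \code{\linkS4class{RestraintDictionary}}.
#' @param model an \code{\linkS4class{EnergyModel}}.
#' @param elements optional named element vector for van der Waals
#'   radii; guessed from atom names when omitted.
#' @return list(energy, gradient) with gradient an atoms x 3 matrix.
#' @export
restraintEnergy <- function(coords, dictionary, model = EnergyModel(),
                            elements = NULL) {
  atomNames <- rownames(coords)
  dictAtoms <- unique(c(dictionary@bonds$atom1, dictionary@bonds$atom2,
                        dictionary@angles$atom1, dictionary@angles$atom2,
                        dictionary@angles$atom3,
                        unlist(dictionary@torsions[c("atom1", "atom2",
                                                     "atom3", "atom4")]),
                        unlist(dictionary@chirality[c("center", "n1", "n2",
                                                      "n3")]),
                        dictionary@planes$atom_id))
  missing <- setdiff(dictAtoms, atomNames)
  if (length(missing))
    stop("missing coordinates for atom(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(elements)) elements <- guessElements(atomNames)
  w <- model@weights
  E <- 0
  G <- matrix(0, nrow(coords), 3L, dimnames = dimnames(coords))
  p <- function(a) coords[a, ]

  b <- dictionary@bonds
  for (i in seq_len(nrow(b))) {
    v <- p(b$atom1[i]) - p(b$atom2[i])
    d <- vnorm(v)
    r <- (d - b$ideal[i]) / b$esd[i]
    E <- E + w[["bond"]] * r^2
    gv <- 2 * w[["bond"]] * r / b$esd[i] * v / d
    G[b$atom1[i], ] <- G[b$atom1[i], ] + gv
    G[b$atom2[i], ] <- G[b$atom2[i], ] - gv
  }

  a <- dictionary@angles
  for (i in seq_len(nrow(a))) {
    p1 <- p(a$atom1[i]); p2 <- p(a$atom2[i]); p3 <- p(a$atom3[i])
    u <- p1 - p2; v <- p3 - p2
    lu <- vnorm(u); lv <- vnorm(v)
    cth <- max(-1, min(1, sum(u * v) / (lu * lv)))
    sth <- sqrt(max(0, 1 - cth^2))
    th <- acos(cth) * RAD2DEG
    r <- (th - a$ideal[i]) / a$esd[i]
    E <- E + w[["angle"]] * r^2
    if (sth > 1e-8) {
      pref <- 2 * w[["angle"]] * r / a$esd[i] * RAD2DEG
      d1 <- (cth * u / lu - v / lv) / (lu * sth)
      d3 <- (cth * v / lv - u / lu) / (lv * sth)
      G[a$atom1[i], ] <- G[a$atom1[i], ] + pref * d1
      G[a$atom3[i], ] <- G[a$atom3[i], ] + pref * d3
      G[a$atom2[i], ] <- G[a$atom2[i], ] - pref * (d1 + d3)
    }
  }

  tor <- dictionary@torsions
  for (i in seq_len(nrow(tor))) {
    p1 <- p(tor$atom1[i]); p2 <- p(tor$atom2[i])
    p3 <- p(tor$atom3[i]); p4 <- p(tor$atom4[i])
    phi <- dihedralDeg(p1, p2, p3, p4)
    if (tor$period[i] >= 1L) {
      step <- 360 / tor$period[i]
      delta <- wrapDeg(phi - tor$ideal[i])
      r <- delta - step * round(delta / step)
    } else {
      cand <- wrapDeg(phi - c(tor$ideal[i], tor$alt_ideals[[i]]))
      r <- cand[which.min(abs(cand))]
    }
    r <- r / tor$esd[i]
    E <- E + w[["torsion"]] * r^2
    # Blondel-Karplus dihedral derivatives
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    ln1 <- sum(n1 * n1); ln2 <- sum(n2 * n2); lb2 <- vnorm(b2)
    if (ln1 > 1e-12 && ln2 > 1e-12) {
      t1 <- -lb2 / ln1 * n1
      t4 <- lb2 / ln2 * n2
      t2 <- -(1 + sum(b1 * b2) / lb2^2) * t1 + sum(b3 * b2) / lb2^2 * t4
      t3 <- -t1 - t2 - t4
      pref <- 2 * w[["torsion"]] * r / tor$esd[i] * RAD2DEG
      G[tor$atom1[i], ] <- G[tor$atom1[i], ] + pref * t1
      G[tor$atom2[i], ] <- G[tor$atom2[i], ] + pref * t2
      G[tor$atom3[i], ] <- G[tor$atom3[i], ] + pref * t3
      G[tor$atom4[i], ] <- G[tor$atom4[i], ] + pref * t4
    }
  }

  ch <- dictionary@chirality
  for (i in seq_len(nrow(ch))) {
    if (ch$sign[i] == "both") next
    pc <- p(ch$center[i])
    a1 <- p(ch$n1[i]) - pc; a2 <- p(ch$n2[i]) - pc; a3 <- p(ch$n3[i]) - pc
    V <- sum(a1 * cross3(a2, a3))
    target <- if (ch$sign[i] == "positive") CHIR_VMIN else -CHIR_VMIN
    viol <- if (ch$sign[i] == "positive") V < target else V > target
    if (!viol) next
    r <- (V - target) / CHIR_ESD
    E <- E + w[["chirality"]] * r^2
    pref <- 2 * w[["chirality"]] * r / CHIR_ESD
    g1 <- cross3(a2, a3); g2 <- cross3(a3, a1); g3 <- cross3(a1, a2)
    G[ch$n1[i], ] <- G[ch$n1[i], ] + pref * g1
    G[ch$n2[i], ] <- G[ch$n2[i], ] + pref * g2
    G[ch$n3[i], ] <- G[ch$n3[i], ] + pref * g3
    G[ch$center[i], ] <- G[ch$center[i], ] - pref * (g1 + g2 + g3)
  }

  pl <- dictionary@planes
  for (pid in unique(pl$plane_id)) {
    sub <- pl[pl$plane_id == pid, , drop = FALSE]
    pts <- coords[sub$atom_id, , drop = FALSE]
    wt <- 1 / sub$esd^2
    ctr <- colSums(pts * wt) / sum(wt)
    x <- sweep(pts, 2L, ctr)
    M <- crossprod(x * sqrt(wt))
    nrm <- eigen(M, symmetric = TRUE)$vectors[, 3L]
    dists <- drop(x %*% nrm)
    E <- E + w[["plane"]] * sum(wt * dists^2)
    # envelope theorem: the weighted best-fit plane minimizes this sum,
    # so the gradient holds the plane parameters fixed
    gd <- 2 * w[["plane"]] * wt * dists
    G[sub$atom_id, ] <- G[sub$atom_id, ] + outer(gd, nrm)
  }

  if (w[["repulsion"]] > 0) {
    rp <- repulsionPairs(atomNames, dictionary@bonds, model, elements)
    if (!is.null(rp)) {
      for (k in seq_along(rp$i)) {
        v <- coords[rp$i[k], ] - coords[rp$j[k], ]
        d <- vnorm(v)
        if (d >= rp$cutoff[k]) next
        E <- E + w[["repulsion"]] * model@repulsionStrength *
          (rp$cutoff[k] - d)^2
        gv <- -2 * w[["repulsion"]] * model@repulsionStrength *
          (rp$cutoff[k] - d) * v / d
        G[rp$i[k], ] <- G[rp$i[k], ] + gv
        G[rp$j[k], ] <- G[rp$j[k], ] - gv
      }
    }
  }
  list(energy = unname(E), gradient = G)
}
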