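# Internal-coordinate measurement: bonds, angles, torsions, chiral
# volumes, plane groups.

vnorm <- function(v) sqrt(sum(v * v))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
RAD2DEG <- 180 / pi

angleDeg <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cosv <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, cosv))) * RAD2DEG
}

# dihedral about p2-p3, in (-180, 180]
dihedralDeg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  d <- atan2(y, x) * RAD2DEG
  if (d <= -180) d + 360 else d
}

# signed volume of the tetrahedron spanned by three neighbours about a
# centre: (n1-c) . ((n2-c) x (n3-c))
signedVolume <- function(pc, p1, p2, p3) {
  sum((p1 - pc) * cross3(p2 - pc, p3 - pc))
}

# wrap an angle difference into (-180, 180]
wrapDeg <- function(d) {
  d <- d %% 360
  d[d > 180] <- d[d > 180] - 360
  d[d <= -180] <- d[d <= -180] + 360
  d
}

# best-fit plane of a point set: centroid + eigenvector of the smallest
# eigenvalue of the centered second-moment matrix
bestFitPlane <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  normal <- ev$vectors[, 3L]
  dists <- drop(x %*% normal)
  list(centroid = ctr, normal = normal, dists = dists,
       rms = sqrt(mean(dists^2)))
}

ATOMIC_NUMBER_TABLE <- local({
  tbl <- setdiff(PERIODIC_TABLE, "D")
  stats::setNames(c(seq_along(tbl), 1L), c(tbl, "D"))
})
atomicNumber <- function(element) {
  unname(ATOMIC_NUMBER_TABLE[normElement(element)])
}

# neighbour priority: heaviest element first, ties by atom name
orderByPriority <- function(names, elements) {
  names[order(-atomicNumber(elements[names]), names)]
}

bondInRing <- function(graph, a, b) {
  any(vapply(graph@rings, function(r) {
    i <- match(a, r); j <- match(b, r)
    if (is.na(i) || is.na(j)) return(FALSE)
    n <- length(r)
    abs(i - j) == 1L || abs(i - j) == n - 1L
  }, logical(1)))
}

# Torsion selection: one representative torsion per eligible central
# bond, classified by end-atom hybridization, plus extra torsions so
# every hydrogen with a non-degenerate 4-atom path is positioned.
selectTorsions <- function(graph, component) {
  if (!all(nzchar(graph@hybridization)))
    stop("hybridization not assigned; call assignHybridization() first",
         call. = FALSE)
  adj <- graph@adjacency
  hy <- graph@hybridization
  el <- graph@elements
  b <- component@bonds
  rows <- list()
  centralKey <- character(0)

  classifyBond <- function(a1, a2) {
    # returns list(period, snap) or NULL for no restraint
    if (hy[[a1]] == "sp" || hy[[a2]] == "sp") return(NULL)
    aromatic_internal <- a1 %in% graph@aromaticAtoms &&
      a2 %in% graph@aromaticAtoms && bondInRing(graph, a1, a2)
    if (aromatic_internal) return(NULL)
    if (bondInRing(graph, a1, a2)) return(list(period = 1L, snap = FALSE))
    h1 <- hy[[a1]]; h2 <- hy[[a2]]
    if (h1 == "sp2" && h2 == "sp2") return(list(period = 2L, snap = TRUE))
    if (h1 == "sp3" && h2 == "sp3") return(list(period = 3L, snap = FALSE))
    if ((h1 == "sp2" && h2 == "sp3") || (h1 == "sp3" && h2 == "sp2"))
      return(list(period = 6L, snap = FALSE))
    NULL  # 'other' / terminal ends carry no torsion restraint
  }

  for (i in seq_len(nrow(b))) {
    a2 <- b$atom1[i]; a3 <- b$atom2[i]
    n2 <- setdiff(adj[[a2]], a3); n3 <- setdiff(adj[[a3]], a2)
    if (!length(n2) || !length(n3)) next
    cls <- classifyBond(a2, a3)
    if (is.null(cls)) next
    a1 <- orderByPriority(n2, el)[1L]
    a4 <- orderByPriority(n3, el)[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      atom1 = a1, atom2 = a2, atom3 = a3, atom4 = a4,
      central1 = a2, central2 = a3, period = cls$period,
      snap = cls$snap, in_ring = cls$period == 1L,
      h_positioning = FALSE, stringsAsFactors = FALSE)
    centralKey <- c(centralKey, paste(min(a2, a3), max(a2, a3)))
  }

  # hydrogens needing a positioning torsion
  hnames <- names(el)[el %in% c("H", "D")]
  for (h in hnames) {
    x <- adj[[h]][1L]
    ys <- setdiff(adj[[x]], h)
    placed <- FALSE
    for (r in rows) if (r$atom1 == h || r$atom4 == h) placed <- TRUE
    if (placed) next
    for (y in orderByPriority(ys, el)) {
      cls <- classifyBond(x, y)
      if (is.null(cls)) next
      zs <- setdiff(adj[[y]], x)
      if (!length(zs)) next
      z <- orderByPriority(zs, el)[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        atom1 = h, atom2 = x, atom3 = y, atom4 = z,
        central1 = x, central2 = y, period = cls$period,
        snap = cls$snap, in_ring = cls$period == 1L,
        h_positioning = TRUE, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
  }
  if (!length(rows))
    return(data.frame(atom1 = character(0), atom2 = character(0),
                      atom3 = character(0), atom4 = character(0),
                      central1 = character(0), central2 = character(0),
                      period = integer(0), snap = logical(0),
                      in_ring = logical(0), h_positioning = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Measure the internal coordinates of a component
#'
#' From Cartesian coordinates, measures every bond length, every bonded
#' angle triple (each pair of distinct neighbours about a central atom),
#' one representative torsion per restrainable central bond (plus
#' hydrogen-positioning torsions), the signed chiral volume of every
#' tetrahedral centre with at least three heavy neighbours, and the
#' r.m.s. deviation of every detected plane group.
#'
#' @param component a \code{\linkS4class{Component}} with coordinates.
#' @param graph its \code{\linkS4class{MolecularGraph}} with
#'   hybridization assigned.
#' @return a \code{\linkS4class{MeasuredGeometry}}.
#' @examples
#' cc <- makeComponent("alkane_chain", n = 2)
#' g <- assignHybridization(buildGraph(cc), cc)
#' measureGeometry(cc, g)
#' @export
measureGeometry <- function(component, graph) {
  if (!hasCoords(component))
    stop("component has no coordinates", call. = FALSE)
  xyz <- component@coords
  missing <- setdiff(component@atoms$name, rownames(xyz))
  if (length(missing))
    stop("missing coordinates for atom(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  if (any(d < 0.1)) {
    pair <- which(d < 0.1, arr.ind = TRUE)[1L, ]
    stop("degenerate geometry: atoms ", rownames(xyz)[pair[1L]], " and ",
         rownames(xyz)[pair[2L]], " closer than 0.1 A", call. = FALSE)
  }
  b <- component@bonds
  bonds <- data.frame(atom1 = b$atom1, atom2 = b$atom2,
                      value = d[cbind(b$atom1, b$atom2)],
                      stringsAsFactors = FALSE)

  adj <- graph@adjacency
  ang <- list()
  for (ctr in names(adj)) {
    nb <- adj[[ctr]]
    if (length(nb) < 2L) next
    pairs <- utils::combn(nb, 2L)
    for (k in seq_len(ncol(pairs)))
      ang[[length(ang) + 1L]] <- data.frame(
        atom1 = pairs[1L, k], atom2 = ctr, atom3 = pairs[2L, k],
        value = angleDeg(xyz[pairs[1L, k], ], xyz[ctr, ],
                         xyz[pairs[2L, k], ]),
        stringsAsFactors = FALSE)
  }
  angles <- if (length(ang)) do.call(rbind, ang) else
    data.frame(atom1 = character(0), atom2 = character(0),
               atom3 = character(0), value = numeric(0))

  tor <- selectTorsions(graph, component)
  tor$value <- if (nrow(tor))
    vapply(seq_len(nrow(tor)), function(i)
      dihedralDeg(xyz[tor$atom1[i], ], xyz[tor$atom2[i], ],
                  xyz[tor$atom3[i], ], xyz[tor$atom4[i], ]),
      numeric(1)) else numeric(0)
  tor <- tor[, c("atom1", "atom2", "atom3", "atom4", "value", "central1",
                 "central2", "period", "snap", "in_ring", "h_positioning")]

  chir <- list()
  el <- graph@elements
  for (ctr in names(adj)) {
    if (graph@hybridization[[ctr]] != "sp3") next
    heavies <- adj[[ctr]][!el[adj[[ctr]]] %in% c("H", "D")]
    if (length(heavies) < 3L) next
    nb <- orderByPriority(heavies, el)[1:3]
    chir[[length(chir) + 1L]] <- data.frame(
      center = ctr, n1 = nb[1L], n2 = nb[2L], n3 = nb[3L],
      volume = signedVolume(xyz[ctr, ], xyz[nb[1L], ], xyz[nb[2L], ],
                            xyz[nb[3L], ]),
      stringsAsFactors = FALSE)
  }
  chirals <- if (length(chir)) do.call(rbind, chir) else
    data.frame(center = character(0), n1 = character(0), n2 = character(0),
               n3 = character(0), volume = numeric(0))

  groups <- planeGroups(graph)
  planes <- lapply(seq_along(groups), function(i) {
    fit <- bestFitPlane(xyz[groups[[i]], , drop = FALSE])
    list(id = paste0("plan-", i), atoms = groups[[i]], rms = fit$rms)
  })

  new("MeasuredGeometry", bonds = bonds, angles = angles, torsions = tor,
      chirals = chirals, planes = planes)
}

# Plane groups: each aromatic ring with its first-shell substituents;
# each non-ring sp2 centre with all its neighbours; groups sharing >= 3
# atoms merged; groups of < 4 atoms dropped.  Deterministic order.
planeGroups <- function(graph) {
  adj <- graph@adjacency
  hy <- graph@hybridization
  ringAtoms <- unique(unlist(graph@rings))
  groups <- list()
  for (ring in graph@rings) {
    if (!all(ring %in% graph@aromaticAtoms)) next
    groups[[length(groups) + 1L]] <-
      sort(unique(c(ring, unlist(adj[ring]))))
  }
  sp2 <- names(hy)[hy == "sp2"]
  for (ctr in sort(setdiff(sp2, ringAtoms))) {
    g <- sort(unique(c(ctr, adj[[ctr]])))
    groups[[length(groups) + 1L]] <- g
  }
  # merge overlapping groups (>= 3 shared atoms) to a fixed point
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        if (length(intersect(groups[[i]], groups[[j]])) >= 3L) {
          groups[[i]] <- sort(union(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups <- groups[lengths(groups) >= 4L]
  groups[order(vapply(groups, paste, "", collapse = "|"))]
}
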