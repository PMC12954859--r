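# Molecular-graph perception: adjacency, rings (SSSR), aromaticity,
# hybridization.

igraphFromComponent <- function(component) {
  igraph::graph_from_data_frame(
    component@bonds[, c("atom1", "atom2")], directed = FALSE,
    vertices = data.frame(name = component@atoms$name))
}

# Smallest set of smallest rings: for every edge, the shortest cycle
# through it (edge + shortest path between its endpoints with the edge
# removed), deduplicated and greedily reduced to a GF(2)-independent
# basis of the cycle space, smallest rings first; ties broken by
# lexicographic order of the sorted atom names.
findRings <- function(component) {
  g <- igraphFromComponent(component)
  nEdges <- igraph::ecount(g)
  dimCycle <- nEdges - igraph::vcount(g) +
    igraph::components(g)$no
  if (dimCycle <= 0L) return(list())
  candidates <- list()
  for (e in seq_len(nEdges)) {
    ends <- igraph::ends(g, e)
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, ends[1L], ends[2L],
                                                  output = "vpath"))
    vp <- sp$vpath[[1L]]
    if (length(vp) < 3L) next
    candidates[[length(candidates) + 1L]] <- names(vp)
  }
  if (!length(candidates)) return(list())
  key <- vapply(candidates, function(r) paste(sort(r), collapse = "|"), "")
  candidates <- candidates[!duplicated(key)]
  sizes <- lengths(candidates)
  tiekey <- vapply(candidates, function(r) paste(sort(r), collapse = "|"), "")
  candidates <- candidates[order(sizes, tiekey)]

  edgeId <- function(a, b) paste(pmin(a, b), pmax(a, b))
  allEdges <- edgeId(component@bonds$atom1, component@bonds$atom2)
  ringVec <- function(ring) {
    nxt <- c(ring[-1L], ring[1L])
    as.integer(allEdges %in% edgeId(ring, nxt))
  }
  basis <- matrix(integer(0), nrow = nEdges, ncol = 0L)
  chosen <- list()
  for (r in candidates) {
    v <- ringVec(r)
    red <- v
    if (ncol(basis)) {
      # GF(2) reduction against pivots of current basis
      for (j in seq_len(ncol(basis))) {
        p <- which(basis[, j] == 1L)[1L]
        if (red[p] == 1L) red <- (red + basis[, j]) %% 2L
      }
    }
    if (any(red == 1L)) {
      basis <- cbind(basis, red)
      chosen[[length(chosen) + 1L]] <- r
      if (length(chosen) == dimCycle) break
    }
  }
  chosen
}

#' Build the molecular graph of a component
#'
#' Derives adjacency from the bond list, perceives rings (smallest set
#' of smallest rings) and marks aromatic atoms: atoms on bonds flagged
#' aromatic, plus atoms of planar-prototype 6-rings of alternating
#' single/double bonds (no full Hueckel electron counting).
#' Hybridization is left unassigned until
#' \code{\link{assignHybridization}}.
#'
#' @param component a \code{\linkS4class{Component}}.
#' @return a \code{\linkS4class{MolecularGraph}}.
#' @examples
#' g <- buildGraph(makeComponent("benzene"))
#' @export
buildGraph <- function(component) {
  validObject(component)
  a <- component@atoms; b <- component@bonds
  adjacency <- stats::setNames(
    lapply(a$name, function(nm)
      sort(unique(c(b$atom2[b$atom1 == nm], b$atom1[b$atom2 == nm])))),
    a$name)
  lonely_h <- a$name[a$is_hydrogen & lengths(adjacency[a$name]) == 0L]
  if (length(lonely_h))
    stop("disconnected hydrogen atom(s): ",
         paste(lonely_h, collapse = ", "), call. = FALSE)
  rings <- findRings(component)

  aromatic <- unique(c(b$atom1[b$order == "aromatic"],
                       b$atom2[b$order == "aromatic"]))
  bondOrder <- function(x, y) {
    hit <- (b$atom1 == x & b$atom2 == y) | (b$atom1 == y & b$atom2 == x)
    b$order[hit][1L]
  }
  for (ring in rings) {
    if (length(ring) != 6L) next
    nxt <- c(ring[-1L], ring[1L])
    orders <- mapply(bondOrder, ring, nxt)
    if (all(orders %in% c("single", "double")) &&
        sum(orders == "double") == 3L &&
        all(orders != c(orders[-1L], orders[1L])))
      aromatic <- unique(c(aromatic, ring))
  }
  el <- stats::setNames(normElement(a$element), a$name)
  new("MolecularGraph", componentId = component@id, adjacency = adjacency,
      elements = el,
      hybridization = stats::setNames(rep("", nrow(a)), a$name),
      aromaticAtoms = sort(aromatic), rings = rings)
}

#' Assign per-atom hybridization
#'
#' Simple empirical rules on the bonded structure: an atom carrying a
#' triple bond or two cumulated double bonds is sp; an aromatic atom or
#' an atom carrying exactly one double bond is sp2; any other heavy atom
#' is sp3; hydrogens are "terminal".  Exotic valences fall back to
#' "other".
#'
#' @param graph a \code{\linkS4class{MolecularGraph}} from
#'   \code{\link{buildGraph}}.
#' @param component the source \code{\linkS4class{Component}}.
#' @return the graph with its \code{hybridization} slot populated.
#' @export
assignHybridization <- function(graph, component) {
  a <- component@atoms; b <- component@bonds
  hy <- stats::setNames(rep("sp3", nrow(a)), a$name)
  nDouble <- nTriple <- stats::setNames(integer(nrow(a)), a$name)
  for (i in seq_len(nrow(b))) {
    if (b$order[i] == "double") {
      nDouble[b$atom1[i]] <- nDouble[b$atom1[i]] + 1L
      nDouble[b$atom2[i]] <- nDouble[b$atom2[i]] + 1L
    } else if (b$order[i] == "triple") {
      nTriple[b$atom1[i]] <- nTriple[b$atom1[i]] + 1L
      nTriple[b$atom2[i]] <- nTriple[b$atom2[i]] + 1L
    }
  }
  hy[nTriple >= 1L | nDouble >= 2L] <- "sp"
  hy[nTriple == 0L & nDouble == 1L] <- "sp2"
  hy[nTriple == 0L & nDouble == 0L &
       a$name %in% graph@aromaticAtoms] <- "sp2"
  # hypervalent centres (phosphate P, sulfone/sulfate S): four sigma
  # neighbours means tetrahedral regardless of formal double bonds
  deg4 <- lengths(graph@adjacency[a$name]) >= 4L
  hy[deg4] <- "sp3"
  hy[a$is_hydrogen] <- "terminal"
  # valence sanity: more than 4 neighbours on C/N/O is outside the rules
  deg <- lengths(graph@adjacency[a$name])
  odd <- !a$is_hydrogen & deg > 4L &
    stats::setNames(normElement(a$element), a$name) %in% c("C", "N", "O")
  if (any(odd)) {
    hy[odd] <- "other"
    message("hybridization fallback 'other' for: ",
            paste(a$name[odd], collapse = ", "))
  }
  graph@hybridization <- hy
  validObject(graph)
  graph
}
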