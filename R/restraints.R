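# Restraint assignment and dictionary generation.

emptyTorsionFrame <- function() {
  data.frame(id = character(0), atom1 = character(0), atom2 = character(0),
             atom3 = character(0), atom4 = character(0),
             ideal = numeric(0), esd = numeric(0), period = integer(0),
             alt_ideals = I(list()), stringsAsFactors = FALSE)
}

torsionEsdFor <- function(policy, period) {
  key <- as.character(period)
  esd <- policy@torsionEsdByPeriod[key]
  ifelse(is.na(esd), policy@torsionEsdByPeriod[["1"]], esd)
}

#' Assign torsion restraints
#'
#' Converts the measured torsions into restraint rows.  Period follows
#' the hybridization of the central-bond atoms (sp3--sp3 threefold,
#' sp2--sp2 twofold with the ideal snapped to the nearer of 0/180
#' degrees, sp2--sp3 sixfold, non-aromatic ring bonds period 1 at the
#' measured value); bonds with an sp end or internal to an aromatic ring
#' carry no torsion restraint (the latter are covered by planes).
#' Hydrogen-positioning torsions keep the period of their central bond.
#'
#' @param graph a \code{\linkS4class{MolecularGraph}} with hybridization.
#' @param measured a \code{\linkS4class{MeasuredGeometry}} from
#'   \code{\link{measureGeometry}} on the same graph.
#' @param policy an \code{\linkS4class{EsdPolicy}} supplying per-period
#'   e.s.d. defaults.
#' @return a data.frame in the \code{torsions} layout of
#'   \code{\linkS4class{RestraintDictionary}}.
#' @export
assignTorsionRestraints <- function(graph, measured, policy = EsdPolicy()) {
  tor <- measured@torsions
  if (!nrow(tor)) return(emptyTorsionFrame())
  ideal <- tor$value
  snap <- tor$snap
  ideal[snap] <- ifelse(abs(wrapDeg(ideal[snap])) < 90, 0, 180)
  out <- data.frame(
    id = sprintf("tor-%d", seq_len(nrow(tor))),
    atom1 = tor$atom1, atom2 = tor$atom2, atom3 = tor$atom3,
    atom4 = tor$atom4, ideal = ideal,
    esd = unname(torsionEsdFor(policy, tor$period)),
    period = as.integer(tor$period), stringsAsFactors = FALSE)
  out$alt_ideals <- rep(list(numeric(0)), nrow(out))
  out
}

#' Detect plane restraints
#'
#' One plane per aromatic ring (ring atoms plus first-shell
#' substituents) and one per non-ring sp2 centre with its neighbours;
#' groups sharing three or more atoms are merged and groups of fewer
#' than four atoms dropped.
#'
#' @param graph a \code{\linkS4class{MolecularGraph}} with aromaticity
#'   and hybridization assigned.
#' @param component the source component (unused beyond validation; the
#'   grouping is purely topological).
#' @param policy an \code{\linkS4class{EsdPolicy}} supplying the plane
#'   e.s.d.
#' @return a long-form data.frame (plane_id, atom_id, esd).
#' @export
detectPlanes <- function(graph, component, policy = EsdPolicy()) {
  groups <- planeGroups(graph)
  if (!length(groups))
    return(data.frame(plane_id = character(0), atom_id = character(0),
                      esd = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(groups), function(i)
    data.frame(plane_id = paste0("plan-", i), atom_id = groups[[i]],
               esd = policy@defaultPlaneEsd, stringsAsFactors = FALSE)))
}

#' Assign chirality restraints
#'
#' For each sp3 atom with at least three heavy neighbours, orders the
#' neighbours deterministically (descending atomic number, ties by atom
#' name) and restrains the sign of the signed volume of the three
#' neighbour vectors: positive above +0.1 cubic Angstrom, negative
#' below -0.1, "both" in the degenerate band between.
#'
#' @param graph a \code{\linkS4class{MolecularGraph}} with hybridization.
#' @param component a \code{\linkS4class{Component}} with coordinates.
#' @return a data.frame (id, center, n1, n2, n3, sign).
#' @export
assignChirality <- function(graph, component) {
  if (!hasCoords(component))
    stop("component has no coordinates", call. = FALSE)
  xyz <- component@coords
  adj <- graph@adjacency
  el <- graph@elements
  rows <- list()
  for (ctr in names(adj)) {
    if (graph@hybridization[[ctr]] != "sp3") next
    heavies <- adj[[ctr]][!el[adj[[ctr]]] %in% c("H", "D")]
    if (length(heavies) < 3L) next
    nb <- orderByPriority(heavies, el)[1:3]
    v <- signedVolume(xyz[ctr, ], xyz[nb[1L], ], xyz[nb[2L], ],
                      xyz[nb[3L], ])
    s <- if (v > 0.1) "positive" else if (v < -0.1) "negative" else "both"
    rows[[length(rows) + 1L]] <- data.frame(
      id = sprintf("chir-%d", length(rows) + 1L), center = ctr,
      n1 = nb[1L], n2 = nb[2L], n3 = nb[3L], sign = s,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(id = character(0), center = character(0),
                      n1 = character(0), n2 = character(0),
                      n3 = character(0), sign = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# e.s.d. from a reference entry: floor the s.d., then multiply
restraintEsd <- function(sd, floor_val, multiplier) {
  multiplier * pmax(sd, floor_val)
}

#' Build a restraint dictionary
#'
#' Assembles the full dictionary for one component geometry: ideal
#' values are the measured values; bond and angle e.s.d. values are the
#' policy multiplier (default 2) times the reference s.d. for the term's
#' type, floored at the ad hoc minima (0.005 Angstrom / 0.75 degrees)
#' beforehand, or the policy defaults when the type is absent from the
#' reference table; torsion e.s.d. values come from the per-period
#' defaults.  Generation fails if any hydrogen lacks a bond restraint,
#' an angle restraint, or (when a non-degenerate four-atom path exists)
#' a positioning torsion -- completeness that riding-hydrogen refinement
#' depends on.
#'
#' @param component a \code{\linkS4class{Component}}.
#' @param measured its \code{\linkS4class{MeasuredGeometry}}.
#' @param policy an \code{\linkS4class{EsdPolicy}}.
#' @param table optional \code{\linkS4class{ReferenceTable}} supplying
#'   per-type s.d. values.
#' @param graph the component's graph with hybridization; rebuilt when
#'   omitted.
#' @param variantLabel protonation-variant label recorded in the
#'   dictionary.
#' @param provenance free-text geometry source label.
#' @return a \code{\linkS4class{RestraintDictionary}}.
#' @examples
#' cc <- makeComponent("acetate")
#' g <- assignHybridization(buildGraph(cc), cc)
#' m <- measureGeometry(cc, g)
#' buildDictionary(cc, m, graph = g)
#' @export
buildDictionary <- function(component, measured, policy = EsdPolicy(),
                            table = NULL, graph = NULL,
                            variantLabel = "in_situ",
                            provenance = "measured geometry") {
  if (is.null(graph))
    graph <- assignHybridization(buildGraph(component), component)
  mb <- measured@bonds
  bondEsd <- rep(policy@defaultBondEsd, nrow(mb))
  if (!is.null(table) && nrow(mb)) {
    keys <- vapply(seq_len(nrow(mb)), function(i)
      typeKey(c(mb$atom1[i], mb$atom2[i]), "bond", graph), "")
    hit <- match(keys, table@bonds$type_key)
    ok <- !is.na(hit)
    bondEsd[ok] <- restraintEsd(table@bonds$sd[hit[ok]],
                                policy@bondFloor, policy@esdMultiplier)
  }
  bonds <- data.frame(atom1 = mb$atom1, atom2 = mb$atom2,
                      ideal = mb$value, esd = bondEsd,
                      stringsAsFactors = FALSE)

  ma <- measured@angles
  angleEsd <- rep(policy@defaultAngleEsd, nrow(ma))
  if (!is.null(table) && nrow(ma)) {
    keys <- vapply(seq_len(nrow(ma)), function(i)
      typeKey(c(ma$atom1[i], ma$atom2[i], ma$atom3[i]), "angle", graph), "")
    hit <- match(keys, table@angles$type_key)
    ok <- !is.na(hit)
    angleEsd[ok] <- restraintEsd(table@angles$sd[hit[ok]],
                                 policy@angleFloor, policy@esdMultiplier)
  }
  angles <- data.frame(atom1 = ma$atom1, atom2 = ma$atom2,
                       atom3 = ma$atom3, ideal = ma$value, esd = angleEsd,
                       stringsAsFactors = FALSE)

  torsions <- assignTorsionRestraints(graph, measured, policy)
  chirality <- measuredChirality(measured)
  planes <- detectPlanes(graph, component, policy)

  dict <- new("RestraintDictionary", componentId = component@id,
              variantLabel = variantLabel, bonds = bonds, angles = angles,
              torsions = torsions, chirality = chirality, planes = planes,
              provenance = provenance)
  checkHydrogenCompleteness(dict, component, graph)
  validObject(dict)
  dict
}

# chirality rows from the measured volumes (same convention as
# assignChirality, but reusing the volumes already measured)
measuredChirality <- function(measured) {
  ch <- measured@chirals
  if (!nrow(ch))
    return(data.frame(id = character(0), center = character(0),
                      n1 = character(0), n2 = character(0),
                      n3 = character(0), sign = character(0),
                      stringsAsFactors = FALSE))
  s <- ifelse(ch$volume > 0.1, "positive",
              ifelse(ch$volume < -0.1, "negative", "both"))
  data.frame(id = sprintf("chir-%d", seq_len(nrow(ch))),
             center = ch$center, n1 = ch$n1, n2 = ch$n2, n3 = ch$n3,
             sign = s, stringsAsFactors = FALSE)
}

# every hydrogen must have >= 1 bond restraint, >= 1 angle restraint and
# a positioning torsion whenever a non-degenerate 4-atom path exists
checkHydrogenCompleteness <- function(dict, component, graph) {
  hnames <- component@atoms$name[component@atoms$is_hydrogen]
  if (!length(hnames)) return(invisible(TRUE))
  inBond <- hnames %in% c(dict@bonds$atom1, dict@bonds$atom2)
  inAngle <- hnames %in% c(dict@angles$atom1, dict@angles$atom2,
                           dict@angles$atom3)
  placeable <- selectTorsions(graph, component)
  needTor <- hnames %in% c(placeable$atom1[placeable$h_positioning],
                           placeable$atom1, placeable$atom4)
  hasTor <- hnames %in% c(dict@torsions$atom1, dict@torsions$atom4)
  bad <- hnames[!inBond | !inAngle | (needTor & !hasTor)]
  if (length(bad))
    stop("incomplete hydrogen restraints for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
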