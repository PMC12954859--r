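# S4 classes for components, restraints, validation reports and configs.

PERIODIC_TABLE <- c(
  "H", "D", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG",
  "AL", "SI", "P", "S", "CL", "AR", "K", "CA", "SC", "TI", "V", "CR", "MN",
  "FE", "CO", "NI", "CU", "ZN", "GA", "GE", "AS", "SE", "BR", "KR", "RB",
  "SR", "Y", "ZR", "NB", "MO", "TC", "RU", "RH", "PD", "AG", "CD", "IN",
  "SN", "SB", "TE", "I", "XE", "CS", "BA", "LA", "CE", "PR", "ND", "PM",
  "SM", "EU", "GD", "TB", "DY", "HO", "ER", "TM", "YB", "LU", "HF", "TA",
  "W", "RE", "OS", "IR", "PT", "AU", "HG", "TL", "PB", "BI", "PO", "AT",
  "RN", "FR", "RA", "AC", "TH", "PA", "U", "NP", "PU")

BOND_ORDERS <- c("single", "double", "triple", "aromatic")
COMP_CLASSES <- c("non_polymer", "amino_acid", "nucleic_acid", "saccharide",
                  "other_polymer")
FILTER_REASONS <- c("kept", "single_atom", "contains_metal", "obsolete",
                    "standard_residue", "manually_curated")
VARIANT_LABELS <- c("in_situ", "in_notitia")
CLASSIFICATIONS <- c("awesome", "superior", "satisfactory", "fail")

# canonical upper-case element lookup; returns NA for unknown symbols
normElement <- function(x) {
  up <- toupper(x)
  ifelse(up %in% PERIODIC_TABLE, up, NA_character_)
}

#' Chemical component
#'
#' A chemical component in the sense of the PDB Chemical Component
#' Dictionary: a named set of atoms, an explicit bond list, optional
#' Cartesian coordinates, and bookkeeping metadata (SMILES string, polymer
#' class, obsolete flag).  All restraint generation and validation in this
#' package operates on \code{Component} objects.
#'
#' @slot id component identifier, 1--5 alphanumeric characters (the PDB now
#'   issues five-character IDs).
#' @slot name free-text component name.
#' @slot atoms \code{data.frame} with columns \code{name}, \code{element},
#'   \code{charge} (formal charge, integer), \code{is_hydrogen} and
#'   \code{legacy_name} (prior atom naming, \code{NA} when none).
#' @slot bonds \code{data.frame} with columns \code{atom1}, \code{atom2}
#'   and \code{order} (one of single/double/triple/aromatic).
#' @slot coords numeric matrix with one row per atom (rownames are atom
#'   names) and columns x, y, z in Angstrom; a 0-row matrix when the
#'   component carries no coordinates.
#' @slot smiles canonical SMILES string, retained as metadata
#'   (\code{character(0)} when absent).
#' @slot compClass polymer class, one of \code{non_polymer},
#'   \code{amino_acid}, \code{nucleic_acid}, \code{saccharide},
#'   \code{other_polymer}.
#' @slot obsolete whether the source entry is flagged obsolete.
#' @slot coordSource which coordinate set was taken from the source file
#'   ("ideal", "model", "sdf", "synthetic" or "none").
#' @exportClass Component
setClass("Component", representation(
  id = "character", name = "character", atoms = "data.frame",
  bonds = "data.frame", coords = "matrix", smiles = "character",
  compClass = "character", obsolete = "logical", coordSource = "character"))

setValidity("Component", function(object) {
  msg <- character(0)
  a <- object@atoms; b <- object@bonds
  if (length(object@id) != 1L || !grepl("^[A-Za-z0-9]{1,5}$", object@id))
    msg <- c(msg, "id must be 1-5 alphanumeric characters")
  req <- c("name", "element", "charge", "is_hydrogen", "legacy_name")
  if (!all(req %in% names(a)))
    return(paste("atoms must have columns:", paste(req, collapse = ", ")))
  if (anyDuplicated(a$name) || any(!nzchar(a$name)))
    msg <- c(msg, "atom names must be nonempty and unique")
  if (any(is.na(normElement(a$element))))
    msg <- c(msg, paste("unknown element symbol(s):",
                        paste(unique(a$element[is.na(normElement(a$element))]),
                              collapse = ", ")))
  hyd <- normElement(a$element) %in% c("H", "D")
  if (!all(a$is_hydrogen == hyd))
    msg <- c(msg, "is_hydrogen must match element H/D")
  if (nrow(b)) {
    if (!all(c("atom1", "atom2", "order") %in% names(b)))
      return("bonds must have columns atom1, atom2, order")
    if (any(b$atom1 == b$atom2))
      msg <- c(msg, "bond with identical endpoints")
    unknown <- setdiff(c(b$atom1, b$atom2), a$name)
    if (length(unknown))
      msg <- c(msg, paste("bond references unknown atom(s):",
                          paste(unknown, collapse = ", ")))
    key <- paste(pmin(b$atom1, b$atom2), pmax(b$atom1, b$atom2))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate bond (unordered pair)")
    if (!all(b$order %in% BOND_ORDERS))
      msg <- c(msg, "bond order must be single/double/triple/aromatic")
  }
  if (nrow(object@coords)) {
    if (ncol(object@coords) != 3L)
      msg <- c(msg, "coords must have 3 columns")
    else if (!setequal(rownames(object@coords), a$name) ||
             nrow(object@coords) != nrow(a))
      msg <- c(msg, "coords rownames must match atom names exactly")
    else if (any(!is.finite(object@coords)))
      msg <- c(msg, "coords must be finite")
  }
  if (!object@compClass %in% COMP_CLASSES)
    msg <- c(msg, "invalid compClass")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Component filtering policy
#'
#' Which components are admitted to the restraint pipeline.  Components
#' are excluded when obsolete, single-atom (mostly metal ions or inert
#' gases), containing elements outside the allowed set (metals and metal
#' clusters), standard residues (amino acids / nucleic acids, whose
#' restraints are already established), or on a manually curated skip
#' list.
#'
#' @slot skipIds manually curated component IDs to skip.
#' @slot standardResidueIds IDs of standard amino acids and nucleic acids.
#' @slot allowedElements element symbols that do not trigger the metal
#'   filter.
#' @exportClass FilterPolicy
setClass("FilterPolicy", representation(
  skipIds = "character", standardResidueIds = "character",
  allowedElements = "character"))

#' @describeIn FilterPolicy-class Constructor with the package defaults:
#'   the 20 standard amino acids plus standard nucleotides, an empty skip
#'   list, and allowed elements {H, D, B, C, N, O, F, Si, P, S, Cl, Se,
#'   Br, I}.
#' @param skipIds,standardResidueIds,allowedElements see slots.
#' @export
FilterPolicy <- function(skipIds = character(0),
                         standardResidueIds = STANDARD_RESIDUE_IDS,
                         allowedElements = ALLOWED_ELEMENTS) {
  new("FilterPolicy", skipIds = toupper(skipIds),
      standardResidueIds = toupper(standardResidueIds),
      allowedElements = toupper(allowedElements))
}

STANDARD_RESIDUE_IDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DI", "DU")

ALLOWED_ELEMENTS <- c("H", "D", "B", "C", "N", "O", "F", "SI", "P", "S",
                      "CL", "SE", "BR", "I")

#' Filter decision
#'
#' Verdict of \code{\link{filterComponent}} for one component; \code{kept}
#' is \code{TRUE} iff \code{reason == "kept"}.
#'
#' @slot componentId component identifier.
#' @slot kept logical.
#' @slot reason one of kept, single_atom, contains_metal, obsolete,
#'   standard_residue, manually_curated.
#' @exportClass FilterDecision
setClass("FilterDecision", representation(
  componentId = "character", kept = "logical", reason = "character"))

setValidity("FilterDecision", function(object) {
  if (!object@reason %in% FILTER_REASONS) return("invalid reason")
  if (object@kept != (object@reason == "kept"))
    return("kept must agree with reason")
  TRUE
})

#' Molecular graph
#'
#' Connectivity-derived perception of a component: adjacency, per-atom
#' hybridization, aromatic atoms and ring memberships (smallest set of
#' smallest rings).  Built by \code{\link{buildGraph}} and refined by
#' \code{\link{assignHybridization}}.
#'
#' @slot componentId component identifier.
#' @slot adjacency named list; for each atom, the character vector of its
#'   bonded neighbours.
#' @slot elements named character vector of canonical element symbols.
#' @slot hybridization named character vector with values sp, sp2, sp3,
#'   terminal or other ("" until assigned).
#' @slot aromaticAtoms atom names flagged aromatic.
#' @slot rings list of character vectors, each one ring (SSSR).
#' @exportClass MolecularGraph
setClass("MolecularGraph", representation(
  componentId = "character", adjacency = "list", elements = "character",
  hybridization = "character", aromaticAtoms = "character",
  rings = "list"))

setValidity("MolecularGraph", function(object) {
  adj <- object@adjacency
  for (a in names(adj)) for (b in adj[[a]])
    if (!a %in% adj[[b]]) return("adjacency not symmetric")
  hyd <- names(object@elements)[object@elements %in% c("H", "D")]
  for (h in hyd) if (length(adj[[h]]) > 1L)
    return(paste("hydrogen", h, "is not terminal"))
  ringAtoms <- unique(unlist(object@rings))
  if (!all(object@aromaticAtoms %in% ringAtoms))
    return("aromatic atom outside any ring")
  TRUE
})

#' Measured internal coordinates
#'
#' Raw internal-coordinate measurements taken from a component's Cartesian
#' geometry by \code{\link{measureGeometry}}: one row per bond, bonded
#' angle triple, selected torsion, tetrahedral chiral centre and plane
#' group.
#'
#' @slot bonds data.frame(atom1, atom2, value) -- lengths in Angstrom.
#' @slot angles data.frame(atom1, atom2, atom3, value) -- degrees, atom2
#'   is the vertex.
#' @slot torsions data.frame(atom1..atom4, value, central1, central2,
#'   period, in_ring, h_positioning) -- degrees in (-180, 180].
#' @slot chirals data.frame(center, n1, n2, n3, volume) -- signed volume
#'   in cubic Angstrom.
#' @slot planes list of list(id, atoms, rms) -- plane groups with their
#'   current r.m.s. deviation from the best-fit plane in Angstrom.
#' @exportClass MeasuredGeometry
setClass("MeasuredGeometry", representation(
  bonds = "data.frame", angles = "data.frame", torsions = "data.frame",
  chirals = "data.frame", planes = "list"))

setValidity("MeasuredGeometry", function(object) {
  if (nrow(object@bonds) && any(object@bonds$value <= 0))
    return("bond length must be positive")
  if (nrow(object@angles) &&
      any(object@angles$value <= 0 | object@angles$value >= 180))
    return("angles must lie in (0, 180)")
  if (nrow(object@torsions) &&
      any(object@torsions$value <= -180 | object@torsions$value > 180))
    return("torsions must lie in (-180, 180]")
  TRUE
})

#' Restraint dictionary
#'
#' The primary output artifact: ideal values plus estimated standard
#' deviations (e.s.d.) for every bond, angle, selected torsion, chiral
#' centre and plane group of one protonation variant of a component.
#' Serialized to and from Monomer-Library-style restraint CIF by
#' \code{\link{writeRestraintCIF}} / \code{\link{readRestraintCIF}}.
#'
#' @slot componentId component identifier.
#' @slot variantLabel "in_situ" or "in_notitia".
#' @slot bonds data.frame(atom1, atom2, ideal, esd) -- Angstrom.
#' @slot angles data.frame(atom1, atom2, atom3, ideal, esd) -- degrees.
#' @slot torsions data.frame(id, atom1..atom4, ideal, esd, period) with a
#'   list column \code{alt_ideals}; period 0 marks a discrete-ideal
#'   torsion whose allowed values are listed in \code{alt_ideals}.
#' @slot chirality data.frame(id, center, n1, n2, n3, sign) with sign in
#'   positive/negative/both.
#' @slot planes data.frame(plane_id, atom_id, esd) -- long form, one row
#'   per atom per plane.
#' @slot provenance free-text label of the geometry source.
#' @exportClass RestraintDictionary
setClass("RestraintDictionary", representation(
  componentId = "character", variantLabel = "character",
  bonds = "data.frame", angles = "data.frame", torsions = "data.frame",
  chirality = "data.frame", planes = "data.frame",
  provenance = "character"))

setValidity("RestraintDictionary", function(object) {
  msg <- character(0)
  if (!object@variantLabel %in% VARIANT_LABELS)
    msg <- c(msg, "variantLabel must be in_situ or in_notitia")
  if (nrow(object@bonds) && any(object@bonds$esd <= 0))
    msg <- c(msg, "bond esd must be positive")
  if (nrow(object@angles)) {
    if (any(object@angles$esd <= 0)) msg <- c(msg, "angle esd must be positive")
    if (any(object@angles$ideal <= 0 | object@angles$ideal >= 180))
      msg <- c(msg, "angle ideal must lie in (0, 180)")
  }
  tor <- object@torsions
  if (nrow(tor)) {
    if (any(tor$esd <= 0)) msg <- c(msg, "torsion esd must be positive")
    discrete <- vapply(tor$alt_ideals, function(v) length(v) > 0, logical(1))
    if (any(tor$period[discrete] != 0L))
      msg <- c(msg, "torsions with alt_ideals must have period 0")
    if (any(tor$period[!discrete] < 1L))
      msg <- c(msg, "torsions without alt_ideals must have period >= 1")
    bad <- unlist(tor$alt_ideals[discrete])
    if (length(bad) && any(bad <= -180 | bad > 180))
      msg <- c(msg, "alt_ideals must lie in (-180, 180]")
  }
  if (nrow(object@chirality) &&
      !all(object@chirality$sign %in% c("positive", "negative", "both")))
    msg <- c(msg, "chirality sign must be positive/negative/both")
  if (nrow(object@planes) && any(object@planes$esd <= 0))
    msg <- c(msg, "plane esd must be positive")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Reference table of ideal geometry values
#'
#' Bond- and angle-type keyed table of (ideal, s.d., n_obs) standing in
#' for CSD/Mogul-derived statistics; the ground truth used by
#' \code{\link{validateGeometry}}.
#'
#' @slot bonds data.frame(type_key, ideal, sd, n_obs) -- Angstrom.
#' @slot angles data.frame(type_key, ideal, sd, n_obs) -- degrees.
#' @exportClass ReferenceTable
setClass("ReferenceTable", representation(
  bonds = "data.frame", angles = "data.frame"))

setValidity("ReferenceTable", function(object) {
  for (kind in c("bonds", "angles")) {
    d <- slot(object, kind)
    if (!nrow(d)) next
    if (any(d$sd < 0)) return("sd must be >= 0")
    if (any(d$n_obs < 1)) return("n_obs must be >= 1")
    if (anyDuplicated(d$type_key)) return("duplicate type_key")
    if (kind == "bonds" && any(d$ideal <= 0))
      return("bond ideals must be positive")
    if (kind == "angles" && any(d$ideal <= 0 | d$ideal >= 180))
      return("angle ideals must lie in (0, 180)")
  }
  TRUE
})

#' Z-score validation report
#'
#' Per-term Z-scores of a measured geometry against a reference table,
#' the maximum |Z|, r.m.s. Z over bonds and angles, and the maximum-Z
#' classification (awesome / superior / satisfactory / fail at max |Z|
#' thresholds 2 / 4 / 6) with its flags.
#'
#' @slot componentId component identifier.
#' @slot variantLabel protonation-variant label.
#' @slot scores data.frame(kind, atoms, type_key, observed, ideal,
#'   sd_used, floored, z, matched).
#' @slot maxAbsZ maximum |Z| over matched terms (NA when none matched).
#' @slot rmszBonds,rmszAngles root-mean-square Z over matched bond /
#'   angle terms.
#' @slot nUnmatched number of terms without a usable reference entry.
#' @slot classification one of awesome, superior, satisfactory, fail.
#' @slot flags subset of c("reasonable_std", "side_chain").
#' @exportClass ZscoreReport
setClass("ZscoreReport", representation(
  componentId = "character", variantLabel = "character",
  scores = "data.frame", maxAbsZ = "numeric", rmszBonds = "numeric",
  rmszAngles = "numeric", nUnmatched = "integer",
  classification = "character", flags = "character"))

setValidity("ZscoreReport", function(object) {
  if (!object@classification %in% CLASSIFICATIONS)
    return("invalid classification")
  if (!all(object@flags %in% c("reasonable_std", "side_chain")))
    return("invalid flag")
  TRUE
})

#' Validation configuration
#'
#' Thresholds of the maximum-Z classification scheme and the ad hoc
#' s.d. floors applied when reference s.d. values are deficient.
#'
#' @slot zAwesome,zSuperior,zSatisfactory classification band edges
#'   (defaults 2, 4, 6; strict less-than).
#' @slot bondFloor minimum usable bond s.d. in Angstrom (default 0.005).
#' @slot angleFloor minimum usable angle s.d. in degrees (default 0.75).
#' @slot sideChainBackboneNames atom names counted as polymer backbone
#'   when validating side-chain-only.
#' @exportClass ValidationConfig
setClass("ValidationConfig", representation(
  zAwesome = "numeric", zSuperior = "numeric", zSatisfactory = "numeric",
  bondFloor = "numeric", angleFloor = "numeric",
  sideChainBackboneNames = "character"))

BACKBONE_ATOM_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "H2", "HA", "HXT")

#' @describeIn ValidationConfig-class Constructor with package defaults.
#' @param zAwesome,zSuperior,zSatisfactory,bondFloor,angleFloor,sideChainBackboneNames see slots.
#' @export
ValidationConfig <- function(zAwesome = 2, zSuperior = 4, zSatisfactory = 6,
                             bondFloor = 0.005, angleFloor = 0.75,
                             sideChainBackboneNames = BACKBONE_ATOM_NAMES) {
  obj <- new("ValidationConfig", zAwesome = zAwesome, zSuperior = zSuperior,
             zSatisfactory = zSatisfactory, bondFloor = bondFloor,
             angleFloor = angleFloor,
             sideChainBackboneNames = sideChainBackboneNames)
  obj
}

setValidity("ValidationConfig", function(object) {
  if (!(0 < object@zAwesome && object@zAwesome < object@zSuperior &&
        object@zSuperior < object@zSatisfactory))
    return("need 0 < zAwesome < zSuperior < zSatisfactory")
  if (object@bondFloor <= 0 || object@angleFloor <= 0)
    return("floors must be positive")
  TRUE
})

#' E.s.d. policy for dictionary generation
#'
#' How reference s.d. values become restraint e.s.d. values: floor the
#' s.d. at the ad hoc minimum, then multiply (default 2x, the refinement
#' convention); defaults when no reference entry matches a term's type.
#'
#' @slot esdMultiplier multiplier applied to the (floored) reference s.d.
#' @slot bondFloor,angleFloor ad hoc s.d. floors (0.005 A, 0.75 deg).
#' @slot defaultBondEsd,defaultAngleEsd,defaultPlaneEsd fallbacks when a
#'   term's type is absent from the reference table.
#' @slot torsionEsdByPeriod named numeric: e.s.d. per torsion period;
#'   name "0" covers discrete-ideal torsions.
#' @exportClass EsdPolicy
setClass("EsdPolicy", representation(
  esdMultiplier = "numeric", bondFloor = "numeric", angleFloor = "numeric",
  defaultBondEsd = "numeric", defaultAngleEsd = "numeric",
  defaultPlaneEsd = "numeric", torsionEsdByPeriod = "numeric"))

#' @describeIn EsdPolicy-class Constructor with package defaults.
#' @param esdMultiplier,bondFloor,angleFloor,defaultBondEsd,defaultAngleEsd,defaultPlaneEsd,torsionEsdByPeriod see slots.
#' @export
EsdPolicy <- function(esdMultiplier = 2, bondFloor = 0.005,
                      angleFloor = 0.75, defaultBondEsd = 0.02,
                      defaultAngleEsd = 1.5, defaultPlaneEsd = 0.02,
                      torsionEsdByPeriod = c("0" = 10, "1" = 10, "2" = 20,
                                             "3" = 30, "6" = 30)) {
  new("EsdPolicy", esdMultiplier = esdMultiplier, bondFloor = bondFloor,
      angleFloor = angleFloor, defaultBondEsd = defaultBondEsd,
      defaultAngleEsd = defaultAngleEsd, defaultPlaneEsd = defaultPlaneEsd,
      torsionEsdByPeriod = torsionEsdByPeriod)
}

setValidity("EsdPolicy", function(object) {
  vals <- c(object@esdMultiplier, object@bondFloor, object@angleFloor,
            object@defaultBondEsd, object@defaultAngleEsd,
            object@defaultPlaneEsd, object@torsionEsdByPeriod)
  if (any(vals <= 0)) return("all policy values must be positive")
  TRUE
})

#' Energy model for restraint minimization
#'
#' Weights and nonbonded parameters of the restraint energy function: a
#' weighted sum of squared (value - ideal)/esd residuals per restraint
#' kind plus a repulsive-only nonbonded term (quadratic one-sided
#' penalty inside a per-element-pair cutoff).
#'
#' @slot weights named numeric with entries bond, angle, torsion,
#'   chirality, plane, repulsion.
#' @slot vdwScale scale on the sum of van der Waals radii giving the
#'   per-pair repulsion cutoff (default 0.8).
#' @slot repulsionCutoff fallback pair cutoff in Angstrom when an element
#'   has no tabulated radius.
#' @slot repulsionStrength prefactor of the repulsive penalty.
#' @exportClass EnergyModel
setClass("EnergyModel", representation(
  weights = "numeric", vdwScale = "numeric", repulsionCutoff = "numeric",
  repulsionStrength = "numeric"))

#' @describeIn EnergyModel-class Constructor with package defaults.
#' @param weights,vdwScale,repulsionCutoff,repulsionStrength see slots.
#' @export
EnergyModel <- function(weights = c(bond = 1, angle = 1, torsion = 1,
                                    chirality = 1, plane = 1, repulsion = 1),
                        vdwScale = 0.8, repulsionCutoff = 2.2,
                        repulsionStrength = 100) {
  new("EnergyModel", weights = weights, vdwScale = vdwScale,
      repulsionCutoff = repulsionCutoff,
      repulsionStrength = repulsionStrength)
}

setValidity("EnergyModel", function(object) {
  need <- c("bond", "angle", "torsion", "chirality", "plane", "repulsion")
  if (!all(need %in% names(object@weights)))
    return(paste("weights must name:", paste(need, collapse = ", ")))
  if (any(object@weights < 0)) return("weights must be >= 0")
  if (object@repulsionCutoff <= 0 || object@vdwScale <= 0)
    return("cutoffs must be positive")
  TRUE
})

#' Minimization result
#'
#' Outcome of a restraint-driven geometry minimization: start and final
#' coordinates, superposition RMSD between them, and convergence
#' diagnostics.
#'
#' @slot startCoords,finalCoords coordinate matrices (rownames = atoms).
#' @slot rmsdToStart Kabsch-superposed RMSD between start and final, in
#'   Angstrom.
#' @slot nIterations number of gradient evaluations used by the
#'   optimizer.
#' @slot finalGradNorm Euclidean norm of the gradient at the final
#'   coordinates.
#' @slot converged whether the gradient tolerance was met (or the
#'   optimizer reported convergence) within the iteration budget.
#' @exportClass MinimizationResult
setClass("MinimizationResult", representation(
  startCoords = "matrix", finalCoords = "matrix", rmsdToStart = "numeric",
  nIterations = "integer", finalGradNorm = "numeric",
  converged = "logical"))

#' Pipeline outcome for one component
#'
#' @slot componentId component identifier.
#' @slot records list of per-variant records, each a list with elements
#'   variant_label, accepted_method (NULL when failed), classification,
#'   flags, dictionary (NULL when failed), roundtrip_rmsd (NA when not
#'   run) and filter_reason.
#' @exportClass ComponentOutcome
setClass("ComponentOutcome", representation(
  componentId = "character", records = "list"))

setValidity("ComponentOutcome", function(object) {
  labs <- vapply(object@records, `[[`, "", "variant_label")
  if ("in_notitia" %in% labs && !"in_situ" %in% labs)
    return("in_notitia record requires an in_situ record")
  for (r in object@records) {
    if (!is.null(r$accepted_method) != (r$classification != "fail"))
      return("accepted_method present iff classification != fail")
  }
  TRUE
})

#' Summary counts over pipeline outcomes
#'
#' Cross-tabulation of validation classifications (with reasonable_std
#' and side-chain flags) per accepted method column and variant, in the
#' layout of a per-category results table.
#'
#' @slot counts data.frame(method, variant, category, n).
#' @slot totals named numeric, per-method column totals.
#' @exportClass SummaryCounts
setClass("SummaryCounts", representation(
  counts = "data.frame", totals = "numeric"))
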