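# Protonation-state variants and polymer-terminus trimming.

#' Protonation variant
#'
#' One protonation state of a component.  The state recorded in the
#' source database (typically protonated acids) is labelled
#' \emph{in notitia}; the state most likely inside a protein model
#' (acids deprotonated) is labelled \emph{in situ}.
#'
#' @slot label "in_situ" or "in_notitia".
#' @slot component the \code{\linkS4class{Component}} in this state.
#' @slot removedAtoms names of the acidic protons removed (empty for the
#'   in notitia state).
#' @slot deltaCharge net-charge change relative to the source component.
#' @exportClass ProtonationVariant
setClass("ProtonationVariant", representation(
  label = "character", component = "Component",
  removedAtoms = "character", deltaCharge = "integer"))

setValidity("ProtonationVariant", function(object) {
  if (!object@label %in% VARIANT_LABELS) return("invalid label")
  if (object@label == "in_notitia" &&
      (length(object@removedAtoms) || object@deltaCharge != 0L))
    return("in_notitia variant must be unchanged")
  if (object@label == "in_situ" &&
      object@deltaCharge != -length(object@removedAtoms))
    return("in_situ deltaCharge must be -(removed protons)")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("variantLabel", "ProtonationVariant", function(x) x@label)
#' @rdname accessors
#' @export
setGeneric("variantComponent", function(x) standardGeneric("variantComponent"))
#' @rdname accessors
#' @export
setMethod("variantComponent", "ProtonationVariant", function(x) x@component)
#' @rdname accessors
#' @export
setGeneric("removedAtoms", function(x) standardGeneric("removedAtoms"))
#' @rdname accessors
#' @export
setMethod("removedAtoms", "ProtonationVariant", function(x) x@removedAtoms)

setMethod("show", "ProtonationVariant", function(object) {
  cat(sprintf("ProtonationVariant %s [%s]: %d proton(s) removed, dQ %+d\n",
              object@component@id, object@label,
              length(object@removedAtoms), object@deltaCharge))
})

# H atoms on O bound to an acid group: O single-bonded to C carrying a
# C=O, to S carrying >= 2 S=O, or to P carrying >= 1 P=O.
findAcidicProtons <- function(component, graph = buildGraph(component)) {
  a <- component@atoms; b <- component@bonds
  el <- stats::setNames(normElement(a$element), a$name)
  doubleO <- function(x) {
    nb <- graph@adjacency[[x]]
    sum(vapply(nb, function(y) {
      hit <- (b$atom1 == x & b$atom2 == y) | (b$atom1 == y & b$atom2 == x)
      el[[y]] == "O" && b$order[hit][1L] == "double"
    }, logical(1)))
  }
  out <- list()
  for (h in a$name[a$is_hydrogen]) {
    nb <- graph@adjacency[[h]]
    if (length(nb) != 1L || el[[nb]] != "O") next
    o <- nb
    heavies <- setdiff(graph@adjacency[[o]], h)
    acidic <- any(vapply(heavies, function(x) {
      switch(el[[x]],
             C = doubleO(x) >= 1L,
             S = doubleO(x) >= 2L,
             P = doubleO(x) >= 1L,
             FALSE)
    }, logical(1)))
    if (acidic) out[[length(out) + 1L]] <- c(h = h, o = o)
  }
  out
}

removeAtoms <- function(component, drop) {
  a <- component@atoms[!component@atoms$name %in% drop, , drop = FALSE]
  rownames(a) <- NULL
  b <- component@bonds
  b <- b[!(b$atom1 %in% drop | b$atom2 %in% drop), , drop = FALSE]
  rownames(b) <- NULL
  component@atoms <- a
  component@bonds <- b
  if (hasCoords(component))
    component@coords <- component@coords[a$name, , drop = FALSE]
  component
}

#' Enumerate protonation variants of a component
#'
#' Identifies acidic protons (H on O of carboxylic, sulfonic/sulfate or
#' phosphate/phosphonate groups).  When any are present two variants are
#' returned: the unchanged \emph{in notitia} state and the \emph{in
#' situ} state with every acidic proton removed and the bearing oxygen's
#' formal charge decreased by one.  With no acidic protons the component
#' is its own in situ state and a single variant is returned.
#'
#' @param component a \code{\linkS4class{Component}}.
#' @param graph optional pre-built \code{\linkS4class{MolecularGraph}}.
#' @return a list of \code{\linkS4class{ProtonationVariant}} objects,
#'   in situ first.
#' @examples
#' v <- enumerateProtonationVariants(makeComponent("acetic_acid"))
#' vapply(v, variantLabel, "")
#' @export
enumerateProtonationVariants <- function(component,
                                         graph = buildGraph(component)) {
  validObject(component)
  hits <- findAcidicProtons(component, graph)
  if (!length(hits)) {
    return(list(new("ProtonationVariant", label = "in_situ",
                    component = component, removedAtoms = character(0),
                    deltaCharge = 0L)))
  }
  drop_h <- vapply(hits, `[[`, "", "h")
  bearer_o <- vapply(hits, `[[`, "", "o")
  situ <- removeAtoms(component, drop_h)
  idx <- match(bearer_o, situ@atoms$name)
  for (i in idx) situ@atoms$charge[i] <- situ@atoms$charge[i] - 1L
  validObject(situ)
  list(new("ProtonationVariant", label = "in_situ", component = situ,
           removedAtoms = drop_h, deltaCharge = -length(drop_h)),
       new("ProtonationVariant", label = "in_notitia",
           component = component, removedAtoms = character(0),
           deltaCharge = 0L))
}

#' Trim polymer-terminus atoms
#'
#' For amino-acid components, removes the superfluous terminus atoms
#' involved in polymerization -- H2, OXT and HXT -- together with their
#' bonds, so the restraints suit the in-chain form.  Formal charges are
#' left untouched.  Components of any other polymer class pass through
#' unchanged.
#'
#' @param component a \code{\linkS4class{Component}}.
#' @return a new \code{\linkS4class{Component}}.
#' @export
trimPolymerTermini <- function(component) {
  validObject(component)
  if (component@compClass != "amino_acid") {
    message("trimPolymerTermini: ", component@id, " is ",
            component@compClass, "; unchanged")
    return(component)
  }
  drop <- intersect(c("H2", "OXT", "HXT"), component@atoms$name)
  if (!length(drop)) return(component)
  out <- removeAtoms(component, drop)
  validObject(out)
  out
}
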