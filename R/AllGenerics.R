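# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for LigandForge objects
#' @description Slot accessors; user code should use these rather than
#'   \code{@} access.
#' @param x an object.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("componentId", function(x) standardGeneric("componentId"))
#' @rdname accessors
#' @export
setMethod("componentId", "Component", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("componentId", "RestraintDictionary", function(x) x@componentId)
#' @rdname accessors
#' @export
setMethod("componentId", "ZscoreReport", function(x) x@componentId)
#' @rdname accessors
#' @export
setMethod("componentId", "ComponentOutcome", function(x) x@componentId)

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "Component", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))
#' @rdname accessors
#' @export
setMethod("bondTable", "Component", function(x) x@bonds)

#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setMethod("atomCoords", "Component", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("hasCoords", function(x) standardGeneric("hasCoords"))
#' @rdname accessors
#' @export
setMethod("hasCoords", "Component", function(x) nrow(x@coords) > 0L)

#' @rdname accessors
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))
#' @rdname accessors
#' @export
setMethod("netCharge", "Component",
          function(x) as.integer(sum(x@atoms$charge)))

#' @rdname accessors
#' @export
setGeneric("compClass", function(x) standardGeneric("compClass"))
#' @rdname accessors
#' @export
setMethod("compClass", "Component", function(x) x@compClass)

#' @rdname accessors
#' @export
setGeneric("isObsolete", function(x) standardGeneric("isObsolete"))
#' @rdname accessors
#' @export
setMethod("isObsolete", "Component", function(x) x@obsolete)

#' @rdname accessors
#' @export
setGeneric("smilesString", function(x) standardGeneric("smilesString"))
#' @rdname accessors
#' @export
setMethod("smilesString", "Component", function(x) x@smiles)

#' @rdname accessors
#' @export
setGeneric("variantLabel", function(x) standardGeneric("variantLabel"))
#' @rdname accessors
#' @export
setMethod("variantLabel", "RestraintDictionary", function(x) x@variantLabel)
#' @rdname accessors
#' @export
setMethod("variantLabel", "ZscoreReport", function(x) x@variantLabel)

#' @rdname accessors
#' @export
setGeneric("bondRestraints", function(x) standardGeneric("bondRestraints"))
#' @rdname accessors
#' @export
setMethod("bondRestraints", "RestraintDictionary", function(x) x@bonds)

#' @rdname accessors
#' @export
setGeneric("angleRestraints", function(x) standardGeneric("angleRestraints"))
#' @rdname accessors
#' @export
setMethod("angleRestraints", "RestraintDictionary", function(x) x@angles)

#' @rdname accessors
#' @export
setGeneric("torsionRestraints",
           function(x) standardGeneric("torsionRestraints"))
#' @rdname accessors
#' @export
setMethod("torsionRestraints", "RestraintDictionary", function(x) x@torsions)

#' @rdname accessors
#' @export
setGeneric("chiralityRestraints",
           function(x) standardGeneric("chiralityRestraints"))
#' @rdname accessors
#' @export
setMethod("chiralityRestraints", "RestraintDictionary",
          function(x) x@chirality)

#' @rdname accessors
#' @export
setGeneric("planeRestraints", function(x) standardGeneric("planeRestraints"))
#' @rdname accessors
#' @export
setMethod("planeRestraints", "RestraintDictionary", function(x) x@planes)

#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))
#' @rdname accessors
#' @export
setMethod("classification", "ZscoreReport", function(x) x@classification)

#' @rdname accessors
#' @export
setGeneric("maxAbsZ", function(x) standardGeneric("maxAbsZ"))
#' @rdname accessors
#' @export
setMethod("maxAbsZ", "ZscoreReport", function(x) x@maxAbsZ)

#' @rdname accessors
#' @export
setGeneric("reportFlags", function(x) standardGeneric("reportFlags"))
#' @rdname accessors
#' @export
setMethod("reportFlags", "ZscoreReport", function(x) x@flags)

#' @rdname accessors
#' @export
setGeneric("termScores", function(x) standardGeneric("termScores"))
#' @rdname accessors
#' @export
setMethod("termScores", "ZscoreReport", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("rmsZ", function(x) standardGeneric("rmsZ"))
#' @rdname accessors
#' @export
setMethod("rmsZ", "ZscoreReport",
          function(x) c(bonds = x@rmszBonds, angles = x@rmszAngles))

#' @rdname accessors
#' @export
setGeneric("outcomeRecords", function(x) standardGeneric("outcomeRecords"))
#' @rdname accessors
#' @export
setMethod("outcomeRecords", "ComponentOutcome", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("summaryCounts", function(x) standardGeneric("summaryCounts"))
#' @rdname accessors
#' @export
setMethod("summaryCounts", "SummaryCounts", function(x) x@counts)

setMethod("show", "Component", function(object) {
  nh <- sum(!object@atoms$is_hydrogen)
  cat(sprintf("Component %s (%s): %d atoms (%d heavy), %d bonds, charge %+d\n",
              object@id, object@compClass, nrow(object@atoms), nh,
              nrow(object@bonds), netCharge(object)))
  cat(sprintf("  coordinates: %s%s\n",
              if (hasCoords(object)) "present" else "absent",
              if (hasCoords(object))
                paste0(" (", object@coordSource, ")") else ""))
  if (length(object@smiles)) cat("  SMILES:", object@smiles, "\n")
  if (object@obsolete) cat("  flagged obsolete\n")
})

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph of %s: %d atoms, %d rings, %d aromatic atoms\n",
              object@componentId, length(object@adjacency),
              length(object@rings), length(object@aromaticAtoms)))
  hy <- object@hybridization
  if (any(nzchar(hy)))
    cat("  hybridization:",
        paste(sprintf("%s=%d", names(table(hy[nzchar(hy)])),
                      as.integer(table(hy[nzchar(hy)]))), collapse = " "),
        "\n")
})

setMethod("show", "RestraintDictionary", function(object) {
  cat(sprintf(
    "RestraintDictionary %s [%s]: %d bonds, %d angles, %d torsions, %d chiral, %d plane atoms\n",
    object@componentId, object@variantLabel, nrow(object@bonds),
    nrow(object@angles), nrow(object@torsions), nrow(object@chirality),
    nrow(object@planes)))
  if (length(object@provenance) && nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "ZscoreReport", function(object) {
  flg <- if (length(object@flags))
    paste0(" (", paste(object@flags, collapse = ", "), ")") else ""
  cat(sprintf("ZscoreReport %s [%s]: %s%s\n", object@componentId,
              object@variantLabel, object@classification, flg))
  cat(sprintf("  max|Z| = %s, rmsZ(bonds) = %.3f, rmsZ(angles) = %.3f, unmatched = %d\n",
              if (is.na(object@maxAbsZ)) "NA" else
                sprintf("%.3f", object@maxAbsZ),
              object@rmszBonds, object@rmszAngles, object@nUnmatched))
})

setMethod("show", "MinimizationResult", function(object) {
  cat(sprintf(
    "MinimizationResult: rmsd to start %.4f A, %d iterations, |grad| %.2e, %s\n",
    object@rmsdToStart, object@nIterations, object@finalGradNorm,
    if (object@converged) "converged" else "not converged"))
})

setMethod("show", "FilterDecision", function(object) {
  cat(sprintf("FilterDecision %s: %s (%s)\n", object@componentId,
              if (object@kept) "kept" else "excluded", object@reason))
})

setMethod("show", "SummaryCounts", function(object) {
  cat("SummaryCounts:\n")
  print(object@counts, row.names = FALSE)
  cat("totals:", paste(sprintf("%s=%d", names(object@totals),
                               as.integer(object@totals)), collapse = " "),
      "\n")
})
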