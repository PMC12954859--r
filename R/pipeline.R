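# End-to-end orchestration: variants, candidate-geometry cascade,
# generation, validation, round-trip, summaries.

candidateList <- function(method_label, coords) {
  list(method_label = method_label, coords = coords)
}

# default candidates: the component's own coordinates, restricted to the
# variant's atoms (approximate for the deprotonated variant, logged)
defaultCandidates <- function(variant) {
  vc <- variant@component
  if (!hasCoords(vc)) return(list())
  if (length(variant@removedAtoms))
    message("variant ", variant@label, " of ", vc@id,
            " reuses the source geometry with acidic protons removed",
            " (approximate)")
  list(candidateList("method-1", vc@coords))
}

processVariant <- function(variant, candidates, table, policy, vconfig,
                           model, minConfig) {
  vc <- variant@component
  label <- variant@label
  sideChainOnly <- vc@compClass == "amino_acid"
  record <- list(variant_label = label, accepted_method = NULL,
                 classification = "fail", flags = character(0),
                 dictionary = NULL, roundtrip_rmsd = NA_real_,
                 filter_reason = NULL, max_abs_z = NA_real_,
                 no_geometry = length(candidates) == 0L)
  if (!length(candidates)) {
    message(vc@id, " [", label, "]: no candidate geometry")
    return(record)
  }
  graph <- assignHybridization(buildGraph(vc), vc)
  for (cand in candidates) {
    missing <- setdiff(vc@atoms$name, rownames(cand$coords))
    if (length(missing))
      stop("candidate geometry ", cand$method_label,
           " lacks coordinates for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    geom <- vc
    geom@coords <- cand$coords[vc@atoms$name, , drop = FALSE]
    measured <- measureGeometry(geom, graph)
    report <- validateGeometry(measured, graph, table, vconfig,
                               sideChainOnly = sideChainOnly,
                               componentId = vc@id, variantLabel = label)
    message(sprintf("%s [%s] %s: %s max|Z|=%s", vc@id, label,
                    cand$method_label, report@classification,
                    if (is.na(report@maxAbsZ)) "NA"
                    else sprintf("%.2f", report@maxAbsZ)))
    if (report@classification != "fail") {
      dictComp <- geom
      dictGraph <- graph
      dictMeasured <- measured
      if (vc@compClass == "amino_acid") {
        dictComp <- trimPolymerTermini(geom)
        dictGraph <- assignHybridization(buildGraph(dictComp), dictComp)
        dictMeasured <- measureGeometry(dictComp, dictGraph)
      }
      dict <- buildDictionary(dictComp, dictMeasured, policy, table,
                              graph = dictGraph, variantLabel = label,
                              provenance = cand$method_label)
      rt <- roundtripCheck(dict, dictComp, model, minConfig)
      record$accepted_method <- cand$method_label
      record$classification <- report@classification
      record$flags <- report@flags
      record$dictionary <- dict
      record$roundtrip_rmsd <- rt@rmsdToStart
      record$max_abs_z <- report@maxAbsZ
      return(record)
    }
    record$classification <- report@classification
    record$flags <- report@flags
    record$max_abs_z <- report@maxAbsZ
  }
  record
}

#' Process one component end-to-end
#'
#' Runs the full per-component procedure: protonation variants are
#' enumerated; for the in situ variant the candidate geometries are
#' validated in order and the first that does not fail is accepted, its
#' dictionary built and round-trip checked; amino-acid components are
#' validated side-chain-only and their termini trimmed before
#' dictionary emission; the in notitia variant is processed only after
#' the in situ variant passed validation.
#'
#' @param component a component that already passed
#'   \code{\link{filterComponent}}.
#' @param geometries named list (by variant label) of ordered candidate
#'   geometry lists, each candidate a \code{list(method_label, coords)}.
#'   When omitted, the component's own coordinates serve as the single
#'   candidate for every variant (acidic protons dropped for the in
#'   situ variant).
#' @param table a \code{\linkS4class{ReferenceTable}}.
#' @param policy an \code{\linkS4class{EsdPolicy}}.
#' @param vconfig a \code{\linkS4class{ValidationConfig}}.
#' @param model an \code{\linkS4class{EnergyModel}} for the round-trip
#'   check.
#' @param minConfig minimizer configuration list.
#' @return a \code{\linkS4class{ComponentOutcome}}.
#' @export
processComponent <- function(component, geometries = NULL, table,
                             policy = EsdPolicy(),
                             vconfig = ValidationConfig(),
                             model = EnergyModel(), minConfig = list()) {
  validObject(component)
  variants <- enumerateProtonationVariants(component)
  labels <- vapply(variants, variantLabel, "")
  records <- list()
  situ <- variants[[which(labels == "in_situ")]]
  cand <- if (!is.null(geometries)) geometries[["in_situ"]] %||% list()
          else defaultCandidates(situ)
  situRec <- processVariant(situ, cand, table, policy, vconfig, model,
                            minConfig)
  records[[1L]] <- situRec
  if ("in_notitia" %in% labels) {
    if (situRec$classification != "fail") {
      notitia <- variants[[which(labels == "in_notitia")]]
      cand <- if (!is.null(geometries))
        geometries[["in_notitia"]] %||% list()
      else defaultCandidates(notitia)
      records[[2L]] <- processVariant(notitia, cand, table, policy,
                                      vconfig, model, minConfig)
    } else {
      message(component@id,
              ": in_situ failed validation; in_notitia not attempted")
    }
  }
  new("ComponentOutcome", componentId = component@id, records = records)
}

categoryLabel <- function(classification, flags) {
  lab <- if ("reasonable_std" %in% flags)
    "satisfactory (reasonable std)"
  else classification
  if ("side_chain" %in% flags) lab <- paste(lab, "(side chain)")
  lab
}

#' Summarize pipeline outcomes
#'
#' Cross-tabulates outcomes by accepted method, variant and category
#' (classification with reasonable-std and side-chain designations) and
#' computes per-method totals, in the layout of a per-category results
#' table.  Records that failed validation are tabulated under method
#' "none".
#'
#' @param outcomes list of \code{\linkS4class{ComponentOutcome}}.
#' @return a \code{\linkS4class{SummaryCounts}}.
#' @export
summarizeOutcomes <- function(outcomes) {
  rows <- list()
  for (oc in outcomes) for (r in oc@records) {
    rows[[length(rows) + 1L]] <- data.frame(
      method = r$accepted_method %||% "none",
      variant = r$variant_label,
      category = categoryLabel(r$classification, r$flags),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(new("SummaryCounts",
               counts = data.frame(method = character(0),
                                   variant = character(0),
                                   category = character(0),
                                   n = integer(0)),
               totals = stats::setNames(numeric(0), character(0))))
  }
  df <- do.call(rbind, rows)
  counts <- stats::aggregate(list(n = rep(1L, nrow(df))),
                             df[c("method", "variant", "category")],
                             FUN = sum)
  counts <- counts[order(counts$method, counts$variant,
                         counts$category), , drop = FALSE]
  rownames(counts) <- NULL
  totals <- tapply(counts$n, counts$method, sum)
  new("SummaryCounts", counts = counts,
      totals = stats::setNames(as.numeric(totals), names(totals)))
}

#' Write summary counts as TSV
#'
#' @param summary a \code{\linkS4class{SummaryCounts}}.
#' @param file optional output path.
#' @return the lines, invisibly when \code{file} is given.
#' @export
writeSummaryTSV <- function(summary, file = NULL) {
  df <- summary@counts
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                            list(sep = "\t"))),
             paste0("# totals\t",
                    paste(sprintf("%s=%d", names(summary@totals),
                                  as.integer(summary@totals)),
                          collapse = "\t")))
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}

#' Show all configuration defaults
#'
#' Prints the default filter policy, e.s.d. policy, validation
#' configuration and energy model.
#'
#' @return invisibly, a list of the four default objects.
#' @export
showConfig <- function() {
  fp <- FilterPolicy(); ep <- EsdPolicy(); vc <- ValidationConfig()
  em <- EnergyModel()
  cat("FilterPolicy:\n")
  cat("  allowedElements:", paste(fp@allowedElements, collapse = " "), "\n")
  cat("  standardResidueIds:",
      paste(fp@standardResidueIds, collapse = " "), "\n")
  cat("  skipIds:", if (length(fp@skipIds))
    paste(fp@skipIds, collapse = " ") else "(none)", "\n")
  cat("EsdPolicy:\n")
  cat(sprintf("  esdMultiplier %g; floors bond %g A, angle %g deg\n",
              ep@esdMultiplier, ep@bondFloor, ep@angleFloor))
  cat(sprintf("  defaults: bond %g A, angle %g deg, plane %g A\n",
              ep@defaultBondEsd, ep@defaultAngleEsd, ep@defaultPlaneEsd))
  cat("  torsion esd by period:",
      paste(sprintf("%s=%g", names(ep@torsionEsdByPeriod),
                    ep@torsionEsdByPeriod), collapse = " "), "\n")
  cat("ValidationConfig:\n")
  cat(sprintf("  bands < %g / %g / %g; floors bond %g A, angle %g deg\n",
              vc@zAwesome, vc@zSuperior, vc@zSatisfactory, vc@bondFloor,
              vc@angleFloor))
  cat("  backbone atoms:",
      paste(vc@sideChainBackboneNames, collapse = " "), "\n")
  cat("EnergyModel:\n")
  cat("  weights:", paste(sprintf("%s=%g", names(em@weights), em@weights),
                          collapse = " "), "\n")
  cat(sprintf("  vdwScale %g, fallback cutoff %g A, strength %g\n",
              em@vdwScale, em@repulsionCutoff, em@repulsionStrength))
  invisible(list(filter = fp, esd = ep, validation = vc, energy = em))
}
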