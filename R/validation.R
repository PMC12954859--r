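# Geometry validation: type keys, Z-scores, s.d. floors, maximum-Z
# classification.

#' Canonical bond/angle type key
#'
#' A deterministic stand-in for CSD/Mogul fragment typing: each atom
#' becomes a token \code{element.hybridization} with suffix \code{.ar}
#' for aromatic atoms or \code{.ring} for non-aromatic ring atoms.  Bond
#' keys join the two end tokens with "-" in sorted order; angle keys
#' join end|center|end with "|", the ends sorted and the center fixed in
#' the middle, so the key is invariant under tuple reversal.
#'
#' @param atoms character vector of 2 (bond) or 3 (angle) atom names.
#' @param kind "bond" or "angle".
#' @param graph a \code{\linkS4class{MolecularGraph}} with hybridization
#'   assigned.
#' @return the key string.
#' @examples
#' cc <- makeComponent("alkane_chain", n = 2)
#' g <- assignHybridization(buildGraph(cc), cc)
#' typeKey(c("C1", "C2"), "bond", g)
#' @export
typeKey <- function(atoms, kind = c("bond", "angle"), graph) {
  kind <- match.arg(kind)
  ringAtoms <- unique(unlist(graph@rings))
  token <- function(a) {
    t <- paste0(graph@elements[[a]], ".", graph@hybridization[[a]])
    if (a %in% graph@aromaticAtoms) paste0(t, ".ar")
    else if (a %in% ringAtoms) paste0(t, ".ring")
    else t
  }
  if (kind == "bond") {
    if (length(atoms) != 2L) stop("bond key needs 2 atoms", call. = FALSE)
    paste(sort(c(token(atoms[1L]), token(atoms[2L]))), collapse = "-")
  } else {
    if (length(atoms) != 3L) stop("angle key needs 3 atoms", call. = FALSE)
    ends <- sort(c(token(atoms[1L]), token(atoms[3L])))
    paste(c(ends[1L], token(atoms[2L]), ends[2L]), collapse = "|")
  }
}

#' Z-score of an observed value
#'
#' How many standard deviations an observed bond length or angle
#' deviates from its ideal value: |observed - ideal| / sd.
#'
#' @param observed,ideal,sd numeric, same units; \code{sd} must be
#'   positive (apply \code{\link{applySdFloor}} first when a reference
#'   s.d. may be zero).
#' @return the dimensionless Z-score.
#' @examples
#' zscore(1.681, 1.623, 0.009)  # > 6: fails the maximum-Z scheme
#' @export
zscore <- function(observed, ideal, sd) {
  if (any(sd <= 0))
    stop("sd must be positive; floor deficient s.d. values first",
         call. = FALSE)
  abs(observed - ideal) / sd
}

#' Apply the ad hoc s.d. floor
#'
#' Reference s.d. values can be tiny or exactly zero when only a few (or
#' one) observations of a bond/angle type exist; such values would make
#' validation impossible.  This floors the s.d. at the configured
#' minimum (defaults 0.005 Angstrom for bonds, 0.75 degrees for angles).
#'
#' @param sd non-negative s.d. value(s).
#' @param kind "bond" or "angle".
#' @param config a \code{\linkS4class{ValidationConfig}}.
#' @return list with elements \code{sd} (floored values) and
#'   \code{floored} (logical, whether the floor was applied).
#' @export
applySdFloor <- function(sd, kind = c("bond", "angle"),
                         config = ValidationConfig()) {
  kind <- match.arg(kind)
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  fl <- if (kind == "bond") config@bondFloor else config@angleFloor
  list(sd = pmax(sd, fl), floored = sd < fl)
}

#' Classify a maximum |Z|
#'
#' The maximum-Z scheme: max |Z| strictly below 2, 4 or 6 gives
#' "awesome", "superior" or "satisfactory" respectively; otherwise
#' "fail".  A geometry that passes only with floored s.d. values is
#' downgraded to "satisfactory" with flag \code{reasonable_std} no
#' matter its Z-score; side-chain-scoped validations carry flag
#' \code{side_chain}.
#'
#' @param maxAbsZ maximum absolute Z-score (NA fails).
#' @param usedFloor whether any floored s.d. entered the deciding pass.
#' @param sideChain whether the validation scope was side-chain only.
#' @param config a \code{\linkS4class{ValidationConfig}}.
#' @return list(classification, flags).
#' @export
classifyMaxZ <- function(maxAbsZ, usedFloor = FALSE, sideChain = FALSE,
                         config = ValidationConfig()) {
  cls <- if (is.na(maxAbsZ)) "fail"
  else if (maxAbsZ < config@zAwesome) "awesome"
  else if (maxAbsZ < config@zSuperior) "superior"
  else if (maxAbsZ < config@zSatisfactory) "satisfactory"
  else "fail"
  flags <- character(0)
  if (usedFloor && cls != "fail") {
    cls <- "satisfactory"
    flags <- c(flags, "reasonable_std")
  }
  if (sideChain) flags <- c(flags, "side_chain")
  list(classification = cls, flags = flags)
}

scoreTerms <- function(measured, graph, table, config, sideChainOnly,
                       useFloor) {
  termFrame <- function(kind) {
    m <- if (kind == "bond") measured@bonds else measured@angles
    if (!nrow(m)) return(NULL)
    refs <- if (kind == "bond") table@bonds else table@angles
    keys <- vapply(seq_len(nrow(m)), function(i)
      typeKey(unlist(m[i, grep("^atom", names(m))]), kind, graph), "")
    atoms <- apply(m[, grep("^atom", names(m)), drop = FALSE], 1L,
                   paste, collapse = "-")
    hit <- match(keys, refs$type_key)
    ideal <- refs$ideal[hit]
    sd_raw <- refs$sd[hit]
    if (useFloor) {
      fl <- applySdFloor(ifelse(is.na(sd_raw), 0, sd_raw), kind, config)
      sd_used <- ifelse(is.na(sd_raw), NA, fl$sd)
      floored <- !is.na(sd_raw) & fl$floored
    } else {
      sd_used <- sd_raw
      floored <- rep(FALSE, length(sd_raw))
    }
    matched <- !is.na(hit) & !is.na(sd_used) & sd_used > 0
    z <- rep(NA_real_, nrow(m))
    z[matched] <- zscore(m$value[matched], ideal[matched],
                         sd_used[matched])
    data.frame(kind = kind, atoms = unname(atoms), type_key = keys,
               observed = m$value, ideal = ideal, sd_used = sd_used,
               floored = floored, z = z, matched = matched,
               stringsAsFactors = FALSE)
  }
  scores <- rbind(termFrame("bond"), termFrame("angle"))
  if (is.null(scores))
    scores <- data.frame(kind = character(0), atoms = character(0),
                         type_key = character(0), observed = numeric(0),
                         ideal = numeric(0), sd_used = numeric(0),
                         floored = logical(0), z = numeric(0),
                         matched = logical(0))
  if (sideChainOnly && nrow(scores)) {
    backbone <- vapply(strsplit(scores$atoms, "-", fixed = TRUE),
                       function(a)
                         all(a %in% config@sideChainBackboneNames),
                       logical(1))
    scores <- scores[!backbone, , drop = FALSE]
    rownames(scores) <- NULL
  }
  scores
}

#' Validate a measured geometry against a reference table
#'
#' Every bond and angle term is typed with \code{\link{typeKey}} and
#' looked up in the reference table; terms without a usable entry are
#' counted as unmatched and excluded from scoring.  Scoring is
#' two-pass: pass 1 uses the raw reference s.d. values (terms with zero
#' s.d. are unmatched); only when pass 1 fails or zero-s.d. terms were
#' present is pass 2 run with the ad hoc floors applied, and a pass-2
#' verdict that is not "fail" is designated "satisfactory
#' (reasonable std)".  With \code{sideChainOnly}, terms lying entirely
#' within the polymer backbone are excluded and the report flagged
#' \code{side_chain}.
#'
#' @param measured a \code{\linkS4class{MeasuredGeometry}}.
#' @param graph the matching \code{\linkS4class{MolecularGraph}} with
#'   hybridization assigned.
#' @param table a \code{\linkS4class{ReferenceTable}}.
#' @param config a \code{\linkS4class{ValidationConfig}}.
#' @param sideChainOnly restrict scoring to side-chain terms.
#' @param componentId,variantLabel labels recorded in the report.
#' @return a \code{\linkS4class{ZscoreReport}}.
#' @export
validateGeometry <- function(measured, graph, table,
                             config = ValidationConfig(),
                             sideChainOnly = FALSE,
                             componentId = graph@componentId,
                             variantLabel = "in_situ") {
  validObject(table)
  emptyTable <- !nrow(table@bonds) && !nrow(table@angles)
  if (emptyTable)
    message("validateGeometry: empty reference table; all terms unmatched")

  pass1 <- scoreTerms(measured, graph, table, config, sideChainOnly,
                      useFloor = FALSE)
  hadZeroSd <- any(!is.na(pass1$sd_used) & pass1$sd_used == 0) ||
    any(is.na(pass1$sd_used) & !is.na(pass1$ideal))
  verdict1 <- classifyMaxZ(
    if (any(pass1$matched)) max(abs(pass1$z[pass1$matched])) else NA,
    usedFloor = FALSE, sideChain = sideChainOnly, config = config)

  if (verdict1$classification == "fail" || hadZeroSd) {
    scores <- scoreTerms(measured, graph, table, config, sideChainOnly,
                         useFloor = TRUE)
    usedFloor <- any(scores$floored[scores$matched])
    verdict <- classifyMaxZ(
      if (any(scores$matched)) max(abs(scores$z[scores$matched])) else NA,
      usedFloor = usedFloor, sideChain = sideChainOnly, config = config)
  } else {
    scores <- pass1
    verdict <- verdict1
  }
  rmsz <- function(kind) {
    z <- scores$z[scores$matched & scores$kind == kind]
    if (!length(z)) 0 else sqrt(mean(z^2))
  }
  new("ZscoreReport", componentId = componentId,
      variantLabel = variantLabel, scores = scores,
      maxAbsZ = if (any(scores$matched))
        max(abs(scores$z[scores$matched])) else NA_real_,
      rmszBonds = rmsz("bond"), rmszAngles = rmsz("angle"),
      nUnmatched = sum(!scores$matched),
      classification = verdict$classification, flags = verdict$flags)
}

#' Human-readable validation summary
#'
#' Text listing of all terms with |Z| greater than the "awesome"
#' threshold (2 by default), echoing validation-report practice, plus
#' the headline classification.
#'
#' @param report a \code{\linkS4class{ZscoreReport}}.
#' @param config a \code{\linkS4class{ValidationConfig}} (threshold for
#'   the listing).
#' @return a character vector of lines, invisibly; also printed.
#' @export
reportText <- function(report, config = ValidationConfig()) {
  s <- report@scores
  flg <- if (length(report@flags))
    paste0(" (", paste(report@flags, collapse = ", "), ")") else ""
  out <- c(sprintf("Component %s [%s]: %s%s", report@componentId,
                   report@variantLabel, report@classification, flg),
           sprintf("max|Z| = %s; rmsZ bonds %.3f, angles %.3f; %d unmatched",
                   if (is.na(report@maxAbsZ)) "NA"
                   else sprintf("%.3f", report@maxAbsZ),
                   report@rmszBonds, report@rmszAngles, report@nUnmatched))
  big <- s[s$matched & abs(s$z) > config@zAwesome, , drop = FALSE]
  if (nrow(big)) {
    out <- c(out, sprintf("terms with |Z| > %g:", config@zAwesome),
             sprintf("  %-5s %-20s obs %9.4f ideal %9.4f sd %8.4f Z %6.2f%s",
                     big$kind, big$atoms, big$observed, big$ideal,
                     big$sd_used, big$z,
                     ifelse(big$floored, " (floored)", "")))
  }
  cat(out, sep = "\n")
  invisible(out)
}

#' Serialize a validation report as JSON
#'
#' @param report a \code{\linkS4class{ZscoreReport}}.
#' @param file optional output path.
#' @return the JSON string (invisibly when \code{file} is given).
#' @export
reportJSON <- function(report, file = NULL) {
  x <- list(component_id = report@componentId,
            variant_label = report@variantLabel,
            classification = report@classification,
            flags = report@flags,
            max_abs_z = report@maxAbsZ,
            rmsz_bonds = report@rmszBonds,
            rmsz_angles = report@rmszAngles,
            n_unmatched = report@nUnmatched,
            scores = report@scores)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(file)) { writeLines(js, file); return(invisible(js)) }
  js
}

#' Read a reference table
#'
#' Delimited text (TSV or CSV, autodetected from the header line) with
#' columns kind, type_key, ideal, sd, n_obs; \code{kind} is "bond" or
#' "angle".  Zero s.d. values are accepted (a real outcome when a type
#' has a single observation); negative s.d. values are a parse error.
#' Duplicate keys keep the last row with a warning.
#'
#' @param text character vector of lines, a single string, or a file
#'   path.
#' @return a \code{\linkS4class{ReferenceTable}}.
#' @export
readReferenceTable <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[nzchar(trimws(text))]
  if (!length(text))
    return(new("ReferenceTable", bonds = emptyRefFrame(),
               angles = emptyRefFrame()))
  sep <- if (grepl("\t", text[1L])) "\t" else ","
  df <- utils::read.table(text = text, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("kind", "type_key", "ideal", "sd", "n_obs")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reference table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$sd < 0)) stop("negative sd in reference table", call. = FALSE)
  pick <- function(kind) {
    d <- df[df$kind == kind, c("type_key", "ideal", "sd", "n_obs")]
    if (anyDuplicated(d$type_key)) {
      warning("duplicate ", kind, " type_key(s): ",
              paste(unique(d$type_key[duplicated(d$type_key)]),
                    collapse = ", "), "; last wins", call. = FALSE)
      d <- d[!duplicated(d$type_key, fromLast = TRUE), , drop = FALSE]
    }
    rownames(d) <- NULL
    d
  }
  new("ReferenceTable", bonds = pick("bond"), angles = pick("angle"))
}

emptyRefFrame <- function() {
  data.frame(type_key = character(0), ideal = numeric(0), sd = numeric(0),
             n_obs = integer(0), stringsAsFactors = FALSE)
}

#' Write a reference table
#'
#' @param table a \code{\linkS4class{ReferenceTable}}.
#' @param file optional output path.
#' @param sep field separator (default tab).
#' @return the lines, invisibly when \code{file} is given.
#' @export
writeReferenceTable <- function(table, file = NULL, sep = "\t") {
  df <- rbind(
    if (nrow(table@bonds)) cbind(kind = "bond", table@bonds) else NULL,
    if (nrow(table@angles)) cbind(kind = "angle", table@angles) else NULL)
  if (is.null(df))
    df <- data.frame(kind = character(0), type_key = character(0),
                     ideal = numeric(0), sd = numeric(0),
                     n_obs = integer(0))
  lines <- c(paste(names(df), collapse = sep),
             if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                            list(sep = sep))))
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}
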