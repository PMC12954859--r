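# Monomer-Library-style restraint CIF serialization.

RESTRAINT_CATEGORIES <- c("chem_comp", "chem_comp_bond", "chem_comp_angle",
                          "chem_comp_tor", "chem_comp_chir",
                          "chem_comp_plane_atom")

#' Write a restraint dictionary as CIF
#'
#' Emits a \code{data_comp_<ID>} block with Monomer-Library-style loops:
#' \code{chem_comp_bond} (value_dist, value_dist_esd),
#' \code{chem_comp_angle}, \code{chem_comp_tor} (with period;
#' discrete-ideal torsions are written as several rows sharing one
#' torsion id with period 0), \code{chem_comp_chir} (volume_sign) and
#' \code{chem_comp_plane_atom} (dist_esd).  Empty categories are
#' omitted.  \code{\link{readRestraintCIF}} inverts the output exactly.
#'
#' @param dictionary a valid \code{\linkS4class{RestraintDictionary}}.
#' @param file optional output path.
#' @return CIF text as a character vector of lines.
#' @export
writeRestraintCIF <- function(dictionary, file = NULL) {
  validObject(dictionary)
  id <- dictionary@componentId
  items <- c("chem_comp.id" = id,
             "chem_comp.variant" = dictionary@variantLabel,
             "chem_comp.provenance" =
               if (length(dictionary@provenance)) dictionary@provenance
               else "unknown")
  loops <- list()
  b <- dictionary@bonds
  if (nrow(b))
    loops$chem_comp_bond <- data.frame(
      comp_id = id, atom_id_1 = b$atom1, atom_id_2 = b$atom2,
      value_dist = cifNum(b$ideal), value_dist_esd = cifNum(b$esd),
      stringsAsFactors = FALSE)
  a <- dictionary@angles
  if (nrow(a))
    loops$chem_comp_angle <- data.frame(
      comp_id = id, atom_id_1 = a$atom1, atom_id_2 = a$atom2,
      atom_id_3 = a$atom3, value_angle = cifNum(a$ideal),
      value_angle_esd = cifNum(a$esd), stringsAsFactors = FALSE)
  tor <- dictionary@torsions
  if (nrow(tor)) {
    rows <- lapply(seq_len(nrow(tor)), function(i) {
      vals <- c(tor$ideal[i], tor$alt_ideals[[i]])
      data.frame(comp_id = id, id = tor$id[i], atom_id_1 = tor$atom1[i],
                 atom_id_2 = tor$atom2[i], atom_id_3 = tor$atom3[i],
                 atom_id_4 = tor$atom4[i], value_angle = cifNum(vals),
                 value_angle_esd = cifNum(tor$esd[i]),
                 period = as.character(tor$period[i]),
                 stringsAsFactors = FALSE)
    })
    loops$chem_comp_tor <- do.call(rbind, rows)
  }
  ch <- dictionary@chirality
  if (nrow(ch))
    loops$chem_comp_chir <- data.frame(
      comp_id = id, id = ch$id, atom_id_centre = ch$center,
      atom_id_1 = ch$n1, atom_id_2 = ch$n2, atom_id_3 = ch$n3,
      volume_sign = ch$sign, stringsAsFactors = FALSE)
  p <- dictionary@planes
  if (nrow(p))
    loops$chem_comp_plane_atom <- data.frame(
      comp_id = id, plane_id = p$plane_id, atom_id = p$atom_id,
      dist_esd = cifNum(p$esd), stringsAsFactors = FALSE)
  out <- cifWriteBlock(paste0("comp_", id), items, loops)
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

needCols <- function(df, cols, category) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("restraint CIF category ", category, " lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

#' Read a restraint dictionary CIF
#'
#' Full inverse of \code{\link{writeRestraintCIF}}; tolerant of column
#' reordering within loops.  Unknown categories produce a warning and
#' are skipped; missing mandatory columns are parse errors; e.s.d.
#' values that are not positive violate the dictionary invariants and
#' raise an error.
#'
#' @param text character vector of CIF lines, a single string, or a
#'   file path.
#' @return a \code{\linkS4class{RestraintDictionary}}.
#' @export
readRestraintCIF <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  blocks <- cifParse(text)
  if (!length(blocks)) stop("no data block found", call. = FALSE)
  block <- blocks[[1L]]
  unknown <- setdiff(names(block$loops), RESTRAINT_CATEGORIES)
  if (length(unknown))
    warning("skipping unknown categor", if (length(unknown) > 1) "ies: "
            else "y: ", paste(unknown, collapse = ", "), call. = FALSE)
  cc <- cifCategory(block, "chem_comp")
  id <- if (!is.null(cc) && "id" %in% names(cc)) cc$id[1L]
        else sub("^comp_", "", block$name)
  variant <- if (!is.null(cc) && "variant" %in% names(cc))
    cc$variant[1L] else "in_situ"
  provenance <- if (!is.null(cc) && "provenance" %in% names(cc))
    cc$provenance[1L] else "unknown"

  b <- block$loops[["chem_comp_bond"]]
  bonds <- if (is.null(b)) {
    data.frame(atom1 = character(0), atom2 = character(0),
               ideal = numeric(0), esd = numeric(0))
  } else {
    needCols(b, c("atom_id_1", "atom_id_2", "value_dist",
                  "value_dist_esd"), "chem_comp_bond")
    data.frame(atom1 = b$atom_id_1, atom2 = b$atom_id_2,
               ideal = as.numeric(b$value_dist),
               esd = as.numeric(b$value_dist_esd),
               stringsAsFactors = FALSE)
  }
  a <- block$loops[["chem_comp_angle"]]
  angles <- if (is.null(a)) {
    data.frame(atom1 = character(0), atom2 = character(0),
               atom3 = character(0), ideal = numeric(0), esd = numeric(0))
  } else {
    needCols(a, c("atom_id_1", "atom_id_2", "atom_id_3", "value_angle",
                  "value_angle_esd"), "chem_comp_angle")
    data.frame(atom1 = a$atom_id_1, atom2 = a$atom_id_2,
               atom3 = a$atom_id_3, ideal = as.numeric(a$value_angle),
               esd = as.numeric(a$value_angle_esd),
               stringsAsFactors = FALSE)
  }
  t <- block$loops[["chem_comp_tor"]]
  torsions <- if (is.null(t)) emptyTorsionFrame() else {
    needCols(t, c("id", "atom_id_1", "atom_id_2", "atom_id_3", "atom_id_4",
                  "value_angle", "value_angle_esd", "period"),
             "chem_comp_tor")
    ids <- unique(t$id)
    rows <- lapply(ids, function(tid) {
      sub <- t[t$id == tid, , drop = FALSE]
      vals <- as.numeric(sub$value_angle)
      data.frame(id = tid, atom1 = sub$atom_id_1[1L],
                 atom2 = sub$atom_id_2[1L], atom3 = sub$atom_id_3[1L],
                 atom4 = sub$atom_id_4[1L], ideal = vals[1L],
                 esd = as.numeric(sub$value_angle_esd[1L]),
                 period = as.integer(sub$period[1L]),
                 alt_ideals = I(list(vals[-1L])), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  ch <- block$loops[["chem_comp_chir"]]
  chirality <- if (is.null(ch)) {
    data.frame(id = character(0), center = character(0), n1 = character(0),
               n2 = character(0), n3 = character(0), sign = character(0))
  } else {
    needCols(ch, c("id", "atom_id_centre", "atom_id_1", "atom_id_2",
                   "atom_id_3", "volume_sign"), "chem_comp_chir")
    sgn <- c(positive = "positive", negative = "negative", both = "both",
             positiv = "positive", negativ = "negative")[
               tolower(ch$volume_sign)]
    data.frame(id = ch$id, center = ch$atom_id_centre, n1 = ch$atom_id_1,
               n2 = ch$atom_id_2, n3 = ch$atom_id_3, sign = unname(sgn),
               stringsAsFactors = FALSE)
  }
  p <- block$loops[["chem_comp_plane_atom"]]
  planes <- if (is.null(p)) {
    data.frame(plane_id = character(0), atom_id = character(0),
               esd = numeric(0))
  } else {
    needCols(p, c("plane_id", "atom_id", "dist_esd"),
             "chem_comp_plane_atom")
    data.frame(plane_id = p$plane_id, atom_id = p$atom_id,
               esd = as.numeric(p$dist_esd), stringsAsFactors = FALSE)
  }
  dict <- new("RestraintDictionary", componentId = id,
              variantLabel = variant, bonds = bonds, angles = angles,
              torsions = torsions, chirality = chirality, planes = planes,
              provenance = provenance)
  validObject(dict)
  dict
}
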