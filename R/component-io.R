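# Component CIF reading/writing and the admission filter.

newComponent <- function(id, name = id, atoms, bonds = emptyBonds(),
                         coords = NULL, smiles = character(0),
                         compClass = "non_polymer", obsolete = FALSE,
                         coordSource = NULL) {
  if (is.null(coords)) {
    coords <- matrix(numeric(0), 0L, 3L,
                     dimnames = list(NULL, c("x", "y", "z")))
    if (is.null(coordSource)) coordSource <- "none"
  } else {
    colnames(coords) <- c("x", "y", "z")
    coords <- coords[atoms$name, , drop = FALSE]
    if (is.null(coordSource)) coordSource <- "model"
  }
  new("Component", id = id, name = name, atoms = atoms, bonds = bonds,
      coords = coords, smiles = smiles, compClass = compClass,
      obsolete = obsolete, coordSource = coordSource)
}

emptyBonds <- function() {
  data.frame(atom1 = character(0), atom2 = character(0),
             order = character(0), stringsAsFactors = FALSE)
}

atomFrame <- function(name, element, charge = 0L,
                      legacy_name = NA_character_) {
  el <- normElement(element)
  data.frame(name = name, element = element,
             charge = as.integer(rep_len(charge, length(name))),
             is_hydrogen = el %in% c("H", "D"),
             legacy_name = rep_len(legacy_name, length(name)),
             stringsAsFactors = FALSE)
}

# CCD _chem_comp.type strings -> polymer class
compClassFromType <- function(type) {
  if (is.null(type) || is.na(type)) return("non_polymer")
  t <- tolower(type)
  if (grepl("peptide|amino", t)) return("amino_acid")
  if (grepl("rna|dna|nucle", t)) return("nucleic_acid")
  if (grepl("saccharide", t)) return("saccharide")
  if (grepl("non-polymer|non_polymer|nonpolymer", t)) return("non_polymer")
  if (grepl("linking|polymer", t)) return("other_polymer")
  "non_polymer"
}

compTypeFromClass <- function(cls) {
  switch(cls, amino_acid = "L-peptide linking",
         nucleic_acid = "RNA linking", saccharide = "saccharide",
         other_polymer = "other polymer", "non-polymer")
}

VALUE_ORDER_IN <- c(SING = "single", DOUB = "double", TRIP = "triple",
                    AROM = "aromatic", single = "single", double = "double",
                    triple = "triple", aromatic = "aromatic",
                    "1" = "single", "2" = "double", "3" = "triple")
VALUE_ORDER_OUT <- c(single = "SING", double = "DOUB", triple = "TRIP",
                     aromatic = "AROM")

#' Read a chemical-component CIF
#'
#' Parses a CCD-style chemical-component description: the
#' \code{chem_comp} metadata, the \code{chem_comp_atom} loop (names,
#' element symbols, formal charges, model and/or ideal Cartesian
#' coordinates) and the \code{chem_comp_bond} loop.  When both "ideal"
#' and "model" coordinate sets are present the ideal set is preferred and
#' the choice recorded in the component's \code{coordSource}.  A SMILES
#' string is taken from \code{_pdbx_chem_comp_descriptor} (preferring
#' \code{SMILES_CANONICAL}) when present.
#'
#' @param text a character vector of CIF lines, a single string, or the
#'   path of an existing file.
#' @return a \code{\linkS4class{Component}}.
#' @examples
#' cc <- makeComponent("acetic_acid")
#' txt <- writeComponentCIF(cc)
#' cc2 <- readComponentCIF(txt)
#' @export
readComponentCIF <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  blocks <- cifParse(text)
  if (!length(blocks)) stop("no data block found", call. = FALSE)
  block <- blocks[[1L]]
  cc <- cifCategory(block, "chem_comp")
  id <- if (!is.null(cc) && "id" %in% names(cc)) cc$id[1L] else block$name
  nm <- if (!is.null(cc) && "name" %in% names(cc) && !is.na(cc$name[1L]))
    cc$name[1L] else id
  cls <- compClassFromType(if (!is.null(cc)) cc$type[1L] else NA)
  obsolete <- FALSE
  if (!is.null(cc) && "pdbx_release_status" %in% names(cc))
    obsolete <- identical(toupper(cc$pdbx_release_status[1L]), "OBS")

  at <- cifCategory(block, "chem_comp_atom")
  if (is.null(at))
    stop("missing category chem_comp_atom", call. = FALSE)
  need <- c("atom_id", "type_symbol")
  if (!all(need %in% names(at)))
    stop("chem_comp_atom lacks mandatory column(s): ",
         paste(setdiff(need, names(at)), collapse = ", "), call. = FALSE)
  charge <- if ("charge" %in% names(at))
    suppressWarnings(as.integer(at$charge)) else 0L
  charge[is.na(charge)] <- 0L
  legacy <- if ("alt_atom_id" %in% names(at)) at$alt_atom_id
            else NA_character_
  legacy[!is.na(legacy) & legacy == at$atom_id] <- NA_character_
  atoms <- atomFrame(at$atom_id, at$type_symbol, charge, legacy)

  ideal_cols <- paste0("pdbx_model_Cartn_", c("x", "y", "z"), "_ideal")
  model_cols <- paste0("model_Cartn_", c("x", "y", "z"))
  coords <- NULL; coordSource <- "none"
  for (trial in list(list(ideal_cols, "ideal"), list(model_cols, "model"))) {
    if (all(trial[[1L]] %in% names(at))) {
      m <- suppressWarnings(
        matrix(as.numeric(unlist(at[trial[[1L]]])), ncol = 3L))
      if (!anyNA(m)) {
        coords <- m; rownames(coords) <- at$atom_id
        coordSource <- trial[[2L]]
        break
      }
    }
  }

  bd <- cifCategory(block, "chem_comp_bond")
  if (is.null(bd) || !nrow(bd)) {
    bonds <- emptyBonds()
  } else {
    need <- c("atom_id_1", "atom_id_2", "value_order")
    if (!all(need %in% names(bd)))
      stop("chem_comp_bond lacks mandatory column(s): ",
           paste(setdiff(need, names(bd)), collapse = ", "), call. = FALSE)
    ord <- unname(VALUE_ORDER_IN[bd$value_order])
    if (anyNA(ord))
      stop("unknown bond value_order: ",
           paste(unique(bd$value_order[is.na(ord)]), collapse = ", "),
           call. = FALSE)
    unknown <- setdiff(c(bd$atom_id_1, bd$atom_id_2), atoms$name)
    if (length(unknown))
      stop("bond references unknown atom name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bonds <- data.frame(atom1 = bd$atom_id_1, atom2 = bd$atom_id_2,
                        order = ord, stringsAsFactors = FALSE)
  }

  smiles <- character(0)
  de <- cifCategory(block, "pdbx_chem_comp_descriptor")
  if (!is.null(de) && all(c("type", "descriptor") %in% names(de))) {
    hit <- de$descriptor[toupper(de$type) == "SMILES_CANONICAL"]
    if (!length(hit)) hit <- de$descriptor[toupper(de$type) == "SMILES"]
    if (length(hit)) smiles <- hit[1L]
  }

  newComponent(id = id, name = nm, atoms = atoms, bonds = bonds,
               coords = coords, smiles = smiles, compClass = cls,
               obsolete = obsolete, coordSource = coordSource)
}

#' Write a chemical-component CIF
#'
#' Inverse of \code{\link{readComponentCIF}} on this package's dialect:
#' always writes loop_ form, with coordinates in the column family
#' matching the component's \code{coordSource} (ideal coordinates go to
#' the \code{pdbx_model_Cartn_*_ideal} columns).
#'
#' @param component a valid \code{\linkS4class{Component}}.
#' @param file optional path; when given the text is also written there.
#' @return the CIF text as a character vector of lines, invisibly when
#'   \code{file} is given.
#' @export
writeComponentCIF <- function(component, file = NULL) {
  validObject(component)
  a <- component@atoms
  items <- c("chem_comp.id" = component@id,
             "chem_comp.name" = component@name,
             "chem_comp.type" = compTypeFromClass(component@compClass),
             "chem_comp.pdbx_release_status" =
               if (component@obsolete) "OBS" else "REL",
             "chem_comp.pdbx_formal_charge" =
               as.character(netCharge(component)))
  atom_df <- data.frame(comp_id = component@id, atom_id = a$name,
                        alt_atom_id = ifelse(is.na(a$legacy_name), a$name,
                                             a$legacy_name),
                        type_symbol = a$element,
                        charge = as.character(a$charge),
                        stringsAsFactors = FALSE)
  if (hasCoords(component)) {
    xyz <- component@coords[a$name, , drop = FALSE]
    cols <- if (identical(component@coordSource, "ideal"))
      paste0("pdbx_model_Cartn_", c("x", "y", "z"), "_ideal")
    else paste0("model_Cartn_", c("x", "y", "z"))
    for (k in 1:3) atom_df[[cols[k]]] <- cifNum(xyz[, k])
  }
  loops <- list(chem_comp_atom = atom_df)
  b <- component@bonds
  loops$chem_comp_bond <- if (nrow(b))
    data.frame(comp_id = component@id, atom_id_1 = b$atom1,
               atom_id_2 = b$atom2,
               value_order = unname(VALUE_ORDER_OUT[b$order]),
               stringsAsFactors = FALSE) else NULL
  if (length(component@smiles))
    loops$pdbx_chem_comp_descriptor <-
      data.frame(comp_id = component@id, type = "SMILES_CANONICAL",
                 program = "LigandForge",
                 descriptor = component@smiles, stringsAsFactors = FALSE)
  out <- cifWriteBlock(component@id, items, loops)
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Decide whether a component enters the pipeline
#'
#' Applies the admission rules in a fixed precedence order and reports
#' the first matching exclusion: obsolete entries, single-atom entries
#' (mostly metal ions or inert gases), components containing elements
#' outside the allowed (non-metal) set, standard amino acids and nucleic
#' acids, and a manually curated skip list.  Components passing all
#' rules are kept.
#'
#' @param component a \code{\linkS4class{Component}}.
#' @param policy a \code{\linkS4class{FilterPolicy}}.
#' @return a \code{\linkS4class{FilterDecision}}.
#' @examples
#' filterComponent(makeComponent("benzene"))
#' @export
filterComponent <- function(component, policy = FilterPolicy()) {
  id <- toupper(component@id)
  reason <- if (component@obsolete) "obsolete"
  else if (nrow(component@atoms) == 1L) "single_atom"
  else if (!all(normElement(component@atoms$element) %in%
                policy@allowedElements)) "contains_metal"
  else if (id %in% policy@standardResidueIds) "standard_residue"
  else if (id %in% policy@skipIds) "manually_curated"
  else "kept"
  new("FilterDecision", componentId = component@id,
      kept = reason == "kept", reason = reason)
}
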