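# MDL SDF (V2000) reading via ChemmineR, with atom-name synthesis and
# M CHG formal-charge propagation.

#' Read an MDL molblock (SDF, V2000)
#'
#' Parses the first molecule of an SDF/molblock via
#' \code{ChemmineR::read.SDFset}.  SDF carries no atom names, so names
#' are synthesized as element symbol plus a 1-based per-element serial
#' (C1, C2, H1, ...); restraints are keyed by these names.  Formal
#' charges are taken from \code{M  CHG} property lines.
#'
#' @param text character vector of molblock lines, a single string with
#'   embedded newlines, or a file path.
#' @param id component identifier to assign (default "LIG").
#' @return a \code{\linkS4class{Component}} with coordinates from the
#'   molblock and \code{compClass} "non_polymer".
#' @export
readSDF <- function(text, id = "LIG") {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
             else text
  }
  if (length(lines) < 4L) stop("molblock too short", call. = FALSE)
  counts <- lines[4L]
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds))
    stop("malformed counts line: ", counts, call. = FALSE)
  if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  sdf <- sdfset[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  if (ncol(ab) < 3L && natoms >= 1L) {
    # ChemmineR rejects degenerate molblocks (e.g. a single atom);
    # parse the atom block lines directly
    if (length(lines) < 4L + natoms)
      stop("atom count mismatch: counts line says ", natoms,
           ", atom block has ", length(lines) - 4L, call. = FALSE)
    fields <- strsplit(trimws(lines[4L + seq_len(natoms)]), "[ \t]+")
    els <- vapply(fields, function(f)
      if (length(f) >= 4L) f[4L] else NA_character_, "")
    if (anyNA(els) || anyNA(normElement(els)))
      stop("atom count mismatch: counts line says ", natoms,
           " but the atom block is shorter", call. = FALSE)
    ab <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
    rownames(ab) <- paste0(els, "_", seq_len(natoms))
  }
  if (nrow(ab) != natoms)
    stop("atom count mismatch: counts line says ", natoms,
         ", atom block has ", nrow(ab), call. = FALSE)
  if (nbonds > 0L) {
    bb <- ChemmineR::bondblock(sdf)
    nb <- if (is.null(dim(bb))) as.integer(length(bb) > 0) else nrow(bb)
    if (nb != nbonds)
      stop("bond count mismatch: counts line says ", nbonds,
           ", bond block has ", nb, call. = FALSE)
  }

  element <- sub("_.*$", "", rownames(ab))
  if (anyNA(normElement(element)))
    stop("atom count mismatch: counts line says ", natoms,
         " but the atom block holds non-atom records", call. = FALSE)
  serial <- stats::ave(seq_along(element), element, FUN = seq_along)
  name <- paste0(element, serial)
  charge <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substring(ln, 7L)), "[ \t]+")[[1]])
    ncg <- f[1L]
    for (k in seq_len(ncg))
      charge[f[2L * k]] <- f[2L * k + 1L]
  }
  atoms <- atomFrame(name, element, charge)
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  rownames(coords) <- name
  bonds <- if (nbonds) {
    bbm <- if (is.null(dim(bb))) matrix(bb, nrow = 1L) else as.matrix(bb)
    ord <- c("single", "double", "triple", "aromatic")[
      pmin(as.integer(bbm[, 3L]), 4L)]
    data.frame(atom1 = name[as.integer(bbm[, 1L])],
               atom2 = name[as.integer(bbm[, 2L])],
               order = ord, stringsAsFactors = FALSE)
  } else emptyBonds()
  nm <- trimws(lines[1L])
  if (!nzchar(nm)) nm <- id
  newComponent(id = id, name = nm, atoms = atoms,
               bonds = bonds, coords = coords, coordSource = "sdf")
}
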