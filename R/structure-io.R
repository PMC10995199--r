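#' @include AllClasses.R constructors.R
NULL

#' Read an atomic model from PDB or mmCIF
#'
#' Thin wrapper over bio3d that fills a
#' \code{\linkS4class{StructureModel}}: elements are taken from the
#' element column (falling back to the first letter of the atom name),
#' subunits from the chain identifier. The helical unit index is left NA;
#' assign it with \code{\link{assignUnits}} before
#' \code{\link{recoverHelicalParams}}.
#'
#' @param path a .pdb or .cif file
#' @param chains optional chain subset
#' @return a \code{\linkS4class{StructureModel}}
#' @export
readStructure <- function(path, chains = NULL) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  atoms <- pdb$atom
  if (!is.null(chains)) atoms <- atoms[atoms$chain %in% chains, ]
  if (nrow(atoms) == 0) stop("no atoms read from ", path)
  elem <- atoms$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[0-9]", "", atoms$elety[bad]), 1, 1)
  structureModel(cbind(atoms$x, atoms$y, atoms$z), element = elem,
                 chain = atoms$chain, subunit = atoms$chain,
                 unit = NA_integer_)
}

#' Assign helical unit indices by chain/subunit grouping
#'
#' Maps each listed subunit group to a 0-based unit index, in the order
#' given. Use this to tell \code{\link{recoverHelicalParams}} which
#' chains form each repeating unit of a filament model.
#'
#' @param model a \code{\linkS4class{StructureModel}}
#' @param unitChains list of character vectors; element i holds the
#'   subunit names of unit i-1
#' @return the model with unit indices assigned
#' @export
assignUnits <- function(model, unitChains) {
  unit <- rep(NA_integer_, nrow(model@coords))
  for (i in seq_along(unitChains))
    unit[model@subunit %in% unitChains[[i]]] <- i - 1L
  initialize(model, unit = unit)
}

#' Write a structure model as PDB
#'
#' Filament subunits are mapped to successive single-letter chain
#' identifiers (the unit index is thereby recorded in the chain naming).
#'
#' @param model a \code{\linkS4class{StructureModel}}
#' @param path output .pdb path
#' @return invisibly, the chain mapping used
#' @export
writeStructurePDB <- function(model, path) {
  subs <- unique(model@subunit)
  ids <- c(LETTERS, letters, as.character(0:9))
  if (length(subs) > length(ids))
    stop("too many subunits for single-character PDB chain identifiers")
  map <- stats::setNames(ids[seq_along(subs)], subs)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(model@coords)),
                   chain = unname(map[model@subunit]),
                   elety = toupper(model@element),
                   resno = seq_len(nrow(model@coords)),
                   elesy = toupper(model@element))
  invisible(map)
}
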