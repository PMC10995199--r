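#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Standard slot accessors. Use these rather than \code{@} access.
#'
#' @param object an object of the documented class
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("twist", function(object) standardGeneric("twist"))
#' @rdname accessors
#' @export
setGeneric("rise", function(object) standardGeneric("rise"))
#' @rdname accessors
#' @export
setGeneric("pointGroup", function(object) standardGeneric("pointGroup"))
#' @rdname accessors
#' @export
setGeneric("atomCoords", function(object) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("nUnits", function(object) standardGeneric("nUnits"))
#' @rdname accessors
#' @export
setGeneric("nuclearChannel", function(object) standardGeneric("nuclearChannel"))
#' @rdname accessors
#' @export
setGeneric("reporterChannel", function(object) standardGeneric("reporterChannel"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("truthMask", function(object) standardGeneric("truthMask"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("nucleusLabels", function(object) standardGeneric("nucleusLabels"))
#' @rdname accessors
#' @export
setGeneric("cytoplasmLabels", function(object) standardGeneric("cytoplasmLabels"))
#' @rdname accessors
#' @export
setGeneric("injectionHeats", function(object) standardGeneric("injectionHeats"))

#' @rdname accessors
#' @export
setMethod("twist", "HelicalParams", function(object) object@twist)
#' @rdname accessors
#' @export
setMethod("rise", "HelicalParams", function(object) object@rise)
#' @rdname accessors
#' @export
setMethod("pointGroup", "HelicalParams", function(object) object@pointGroup)
#' @rdname accessors
#' @export
setMethod("atomCoords", "StructureModel", function(object) object@coords)
#' @rdname accessors
#' @export
setMethod("nUnits", "StructureModel", function(object) {
  u <- object@unit
  if (all(is.na(u))) 1L else length(unique(u[!is.na(u)]))
})
#' @rdname accessors
#' @export
setMethod("nuclearChannel", "CellImageSet", function(object) object@nuclear)
#' @rdname accessors
#' @export
setMethod("reporterChannel", "CellImageSet", function(object) object@reporter)
#' @rdname accessors
#' @export
setMethod("pixelSize", "CellImageSet", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("groundTruth", "CellImageSet", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("truthMask", "CellImageSet", function(object) object@truthMask)
#' @rdname accessors
#' @export
setMethod("nCells", "CellRegions", function(object) object@nCells)
#' @rdname accessors
#' @export
setMethod("nCells", "CellImageSet", function(object) nrow(object@labels))
#' @rdname accessors
#' @export
setMethod("nucleusLabels", "CellRegions", function(object) object@nucleusLabels)
#' @rdname accessors
#' @export
setMethod("cytoplasmLabels", "CellRegions", function(object) object@cytoplasmLabels)
#' @rdname accessors
#' @export
setMethod("injectionHeats", "ITCExperiment", function(object) object@heatsUcal)

setMethod("show", "HelicalParams", function(object) {
  cat(sprintf("HelicalParams: twist %.4g deg, rise %.4g A, point group %s\n",
              object@twist, object@rise, object@pointGroup))
  upt <- if (abs(object@twist) > 0) 360 / abs(object@twist) else NA_real_
  cat(sprintf("  units per turn: %.3f\n", upt))
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel: %d atoms, %d subunit(s), %d helical unit(s)\n",
              nrow(object@coords), length(unique(object@subunit)),
              nUnits(object)))
})

setMethod("show", "ScrewTransform", function(object) {
  cat(sprintf(
    "ScrewTransform: angle %.4g deg about (%.3f, %.3f, %.3f), translation %.4g A, RMSD %.3g A\n",
    object@angle, object@axis[1], object@axis[2], object@axis[3],
    object@translation, object@rmsd))
})

setMethod("show", "CellImageSet", function(object) {
  tab <- table(object@labels$true_class)
  cat(sprintf("CellImageSet: %d x %d px (%.3g um/px), %d cells (%s)\n",
              nrow(object@nuclear), ncol(object@nuclear), object@pixelSize,
              nrow(object@labels),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "CellRegions", function(object) {
  cat(sprintf("CellRegions: %d cells over %d x %d px\n", object@nCells,
              nrow(object@nucleusLabels), ncol(object@nucleusLabels)))
})

setMethod("show", "ITCExperiment", function(object) {
  cat(sprintf(
    "ITCExperiment: %g ul cell at %g uM, syringe %g uM, %d injections, %g C%s\n",
    object@cellVolumeUl, object@cellConcUm, object@syringeConcUm,
    length(object@injectionVolumesUl), object@temperatureC,
    if (is.null(object@heatsUcal)) " (no heats)" else ""))
})

setMethod("show", "ITCTwoSetsParams", function(object) {
  kd <- 1 / object@K
  cat("ITCTwoSetsParams (classes sorted by Kd):\n")
  for (i in 1:2)
    cat(sprintf("  site class %d: N = %.3g, Kd = %.4g M, dH = %.3g kcal/mol\n",
                i, object@N[i], kd[i], object@dH[i]))
})
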