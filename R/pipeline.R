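#' @include segmentation.R morphometry.R cohort.R simulate-images.R
NULL

#' Run the full classifier on one field of view
#'
#' Nucleus detection, cytoplasm expansion, reporter enhancement,
#' binarisation, per-cell object extraction, per-object morphometry and
#' cell-level classification, in one call.
#'
#' @param imageSet a \code{\linkS4class{CellImageSet}} (or any object
#'   with nuclear/reporter accessors)
#' @param segConfig a \code{\linkS4class{SegmentationConfig}}
#' @param morphConfig a \code{\linkS4class{MorphometryConfig}}; its
#'   pixel size is overridden by the image's
#' @return list with \code{cells} (per-cell classification data.frame),
#'   \code{objects} (per-object measurements), \code{regions}
#' @export
classifyImage <- function(imageSet, segConfig = segmentationConfig(),
                          morphConfig = morphometryConfig()) {
  px <- pixelSize(imageSet)
  morphConfig@pixelSize <- px
  nuc <- detectNuclei(nuclearChannel(imageSet), reporterChannel(imageSet),
                      segConfig)
  regions <- expandCytoplasm(nuc, segConfig, px)
  enhanced <- enhanceReporter(reporterChannel(imageSet), segConfig)
  mask <- binarizeObjects(enhanced, segConfig)
  objects <- extractObjects(mask, regions, segConfig)
  measured <- measureObjects(objects, morphConfig)
  cells <- classifyCells(measured, nCells(regions), morphConfig)
  list(cells = cells, objects = measured, regions = regions)
}

#' Simulate and classify a cohort of fields of view
#'
#' Generates \code{nImages} synthetic fields per condition (one derived
#' RNG stream per image) and runs \code{\link{classifyImage}} on each,
#' returning the combined per-cell table ready for
#' \code{\link{summarizeCondition}}.
#'
#' @param conditions named list: condition label ->
#'   \code{\linkS4class{ImageSimConfig}}
#' @param nImages fields of view per condition
#' @param segConfig,morphConfig pipeline configurations
#' @return data.frame with columns condition, image_id, cell_id,
#'   true_class, n_objects, d_class, perimeter_class
#' @export
simulateCohort <- function(conditions, nImages = 5,
                           segConfig = segmentationConfig(),
                           morphConfig = morphometryConfig()) {
  out <- list()
  img <- 0L
  for (cond in names(conditions)) {
    cfg <- conditions[[cond]]
    for (i in seq_len(nImages)) {
      img <- img + 1L
      im <- generateCellImage(cfg, index = i, condition = cond)
      res <- classifyImage(im, segConfig, morphConfig)
      truth <- groundTruth(im)
      cells <- res$cells
      # detected cell k is matched to the generated cell whose nucleus
      # centroid falls in k's nucleus mask (grid placement keeps this
      # unambiguous); unmatched detections keep NA truth
      cells$true_class <- NA_character_
      nucLab <- nucleusLabels(res$regions)
      if (nrow(truth) > 0 && nCells(res$regions) > 0) {
        rr <- pmin(pmax(round(truth$nucleus_row), 1), nrow(nucLab))
        cc <- pmin(pmax(round(truth$nucleus_col), 1), ncol(nucLab))
        lab <- nucLab[cbind(rr, cc)]
        ok <- lab > 0
        cells$true_class[lab[ok]] <- truth$true_class[ok]
      }
      cells$condition <- cond
      cells$image_id <- img
      out[[length(out) + 1]] <- cells
    }
  }
  do.call(rbind, out)
}
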