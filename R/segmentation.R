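#' @include AllClasses.R constructors.R utils.R
NULL

#' Detect nuclei from the nuclear and reporter channels
#'
#' Follows the high-content convention of combining the nuclear and
#' transfection (reporter) channels before segmentation: each channel is
#' percentile-rescaled, the two are combined with \code{channelWeights}
#' (nuclear-dominant by default, so bright cytoplasmic objects do not
#' masquerade as nuclei) and rescaled to [0, 1],
#' Gaussian-blurred with \code{blurSigma} (default 3 px), Otsu-thresholded,
#' and 8-connected components below \code{minNucleusArea} are removed.
#'
#' @param nuclear,reporter numeric matrices of identical shape
#' @param config a \code{\linkS4class{SegmentationConfig}}
#' @return integer label matrix, labels 1..K (0 = background); a blank or
#'   constant image yields zero labels, not an error
#' @export
detectNuclei <- function(nuclear, reporter, config = segmentationConfig()) {
  validObject(config)
  if (!all(dim(nuclear) == dim(reporter)))
    stop("nuclear and reporter images must have the same shape")
  w <- config@channelWeights
  combined <- w[1] * percentileRescale(nuclear, config@contrastPercentiles) +
    w[2] * percentileRescale(reporter, config@contrastPercentiles)
  if (diff(range(combined)) == 0)
    return(matrix(0L, nrow(nuclear), ncol(nuclear)))
  combined <- combined / max(combined)
  blurred <- as.matrix(EBImage::gblur(combined, sigma = config@blurSigma))
  if (diff(range(blurred)) == 0)
    return(matrix(0L, nrow(nuclear), ncol(nuclear)))
  th <- EBImage::otsu(EBImage::Image(blurred), range = range(blurred))
  mask <- blurred > th
  lab <- labelComponents(mask, connectivity = 8L)
  if (max(lab) == 0) return(lab)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(areas >= config@minNucleusArea)
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Expand cytoplasm territories around detected nuclei
#'
#' Nearest-seed growth: every pixel within \code{cytoplasmExpandRadius}
#' (um) of a nucleus is assigned to the nearest nucleus (contested pixels
#' go to the closer seed); nucleus pixels themselves are excluded from
#' the cytoplasm masks.
#'
#' @param nucleusLabels integer label matrix from
#'   \code{\link{detectNuclei}}
#' @param config a \code{\linkS4class{SegmentationConfig}}
#' @param pixelSize um per pixel, converting the expansion radius
#' @return a \code{\linkS4class{CellRegions}}
#' @export
expandCytoplasm <- function(nucleusLabels, config = segmentationConfig(),
                            pixelSize = 0.3) {
  validObject(config)
  k <- max(nucleusLabels)
  if (k == 0)
    return(new("CellRegions", nucleusLabels = nucleusLabels * 0L,
               cytoplasmLabels = nucleusLabels * 0L, nCells = 0L))
  radiusPx <- config@cytoplasmExpandRadius / pixelSize
  distToNucleus <- as.matrix(EBImage::distmap((nucleusLabels == 0) * 1))
  within <- distToNucleus <= radiusPx
  vor <- EBImage::propagate(EBImage::Image(matrix(0, nrow(nucleusLabels),
                                                  ncol(nucleusLabels))),
                            seeds = nucleusLabels, mask = within)
  vor <- matrix(as.integer(vor), nrow(nucleusLabels), ncol(nucleusLabels))
  cyto <- vor
  cyto[nucleusLabels > 0] <- 0L
  new("CellRegions", nucleusLabels = nucleusLabels,
      cytoplasmLabels = cyto, nCells = as.integer(k))
}

#' Enhance the reporter channel
#'
#' A consistent, image-derived contrast rule: percentile rescale to
#' [0, 1] (default 1st/99.5th percentiles) followed by CLAHE local
#' contrast enhancement. A constant image is returned as the all-zero
#' rescale (CLAHE is skipped since there is no contrast to equalise).
#'
#' @param reporter numeric matrix with finite values
#' @param config a \code{\linkS4class{SegmentationConfig}}
#' @return enhanced image in [0, 1]
#' @export
enhanceReporter <- function(reporter, config = segmentationConfig()) {
  validObject(config)
  if (!all(is.finite(reporter))) stop("reporter image must be finite")
  scaled <- percentileRescale(reporter, config@contrastPercentiles)
  if (diff(range(scaled)) == 0) return(scaled)
  nx <- max(2L, round(ncol(scaled) / config@claheKernel))
  ny <- max(2L, round(nrow(scaled) / config@claheKernel))
  out <- as.matrix(EBImage::clahe(EBImage::Image(scaled), nx = nx, ny = ny,
                                  limit = config@claheClip))
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Binarise the enhanced reporter image
#'
#' Global threshold (default Otsu) on a [0, 1] image. A degenerate
#' histogram (single value) yields an empty mask.
#'
#' @param enhanced numeric matrix in [0, 1]
#' @param config a \code{\linkS4class{SegmentationConfig}}
#' @return logical matrix
#' @export
binarizeObjects <- function(enhanced, config = segmentationConfig()) {
  validObject(config)
  if (min(enhanced) < -1e-9 || max(enhanced) > 1 + 1e-9)
    stop("enhanced image must lie in [0, 1]")
  if (diff(range(enhanced)) == 0)
    return(matrix(FALSE, nrow(enhanced), ncol(enhanced)))
  th <- EBImage::otsu(EBImage::Image(enhanced), range = c(0, 1))
  enhanced > th
}

#' Extract per-cell fluorescent objects
#'
#' Intersects the binary object mask with each cell's cytoplasm
#' territory and labels 4-connected components per cell; components
#' smaller than \code{minObjectArea} are dropped, and objects straddling
#' two cytoplasm territories are split at the territory boundary.
#'
#' @param mask logical matrix from \code{\link{binarizeObjects}}
#' @param regions a \code{\linkS4class{CellRegions}}
#' @param config a \code{\linkS4class{SegmentationConfig}}
#' @return a list with \code{table}, a data.frame (cell_id, object_id,
#'   area_px), and \code{pixels}, a list (parallel to the table rows) of
#'   matrices with columns row, col giving each object's pixels
#' @export
extractObjects <- function(mask, regions, config = segmentationConfig()) {
  validObject(config)
  if (!all(dim(mask) == dim(regions@cytoplasmLabels)))
    stop("mask and regions must share a shape")
  tab <- data.frame(cell_id = integer(0), object_id = integer(0),
                    area_px = integer(0))
  pixels <- list()
  oid <- 0L
  for (k in seq_len(regions@nCells)) {
    inCell <- mask & regions@cytoplasmLabels == k
    if (!any(inCell)) next
    lab <- labelComponents(inCell, connectivity = 4L)
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    for (j in which(areas >= config@minObjectArea)) {
      oid <- oid + 1L
      tab <- rbind(tab, data.frame(cell_id = k, object_id = oid,
                                   area_px = areas[j]))
      pixels[[oid]] <- which(lab == j, arr.ind = TRUE)
    }
  }
  rownames(tab) <- NULL
  list(table = tab, pixels = pixels)
}
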