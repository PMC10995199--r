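#' @include AllClasses.R constructors.R
NULL

#' Write / read a simulated field of view as per-channel TIFF + CSV
#'
#' The nuclear and reporter channels go to 32-bit float TIFFs
#' (\code{<prefix>_nuclear.tif}, \code{<prefix>_reporter.tif}), the
#' ground-truth labels to \code{<prefix>_labels.csv}.
#'
#' @param imageSet a \code{\linkS4class{CellImageSet}}
#' @param prefix output path prefix
#' @return invisibly, the files written
#' @export
writeCellImage <- function(imageSet, prefix) {
  fn <- paste0(prefix, c("_nuclear.tif", "_reporter.tif", "_labels.csv"))
  tiff::writeTIFF(pmin(pmax(nuclearChannel(imageSet), 0), 1), fn[1],
                  bits.per.sample = 32L)
  tiff::writeTIFF(pmin(pmax(reporterChannel(imageSet), 0), 1), fn[2],
                  bits.per.sample = 32L)
  utils::write.csv(groundTruth(imageSet), fn[3], row.names = FALSE)
  invisible(fn)
}

#' @rdname writeCellImage
#' @param pixelSize um per pixel to attach on read
#' @export
readCellImage <- function(prefix, pixelSize = 0.3) {
  fn <- paste0(prefix, c("_nuclear.tif", "_reporter.tif", "_labels.csv"))
  nuclear <- tiff::readTIFF(fn[1])
  reporter <- tiff::readTIFF(fn[2])
  labels <- if (file.exists(fn[3]))
    utils::read.csv(fn[3], stringsAsFactors = FALSE)
  else data.frame(cell_id = integer(0), true_class = character(0),
                  nucleus_row = numeric(0), nucleus_col = numeric(0),
                  object_count = integer(0))
  new("CellImageSet", nuclear = nuclear, reporter = reporter,
      pixelSize = pixelSize, labels = labels,
      truthMask = matrix(0L, nrow(nuclear), ncol(nuclear)),
      condition = NA_character_)
}
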