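#' @include AllClasses.R
NULL

#' Create an image simulation configuration
#'
#' Defaults emulate a 20x high-content field: 0.3 um/px sampling, nuclei
#' of 2.1-3.6 um radius, filaments drawn as curved 10-18 um strokes of
#' 0.6-0.9 um thickness, and puncta of 0.9-1.8 um diameter. Object size
#' ranges are free parameters of the generator (they are not calibrated
#' against any particular instrument); they are chosen so filament-like
#' objects carry long perimeters and high box-count dimension while
#' puncta are short and low, the contrast the downstream classifier keys
#' on.
#'
#' @param width,height image size in px
#' @param pixelSize um per px
#' @param nCells number of cells
#' @param fracFilamented fraction of cells drawn as filamented, in [0, 1]
#' @param filamentLength,filamentThickness,filamentCurvature,punctaDiameter,nucleusRadius
#'   two-element ranges (um except curvature, which is unitless in [0, 1])
#' @param punctaCount,filamentCount integer two-element ranges of objects
#'   per cell
#' @param backgroundLevel,signalLevel,noiseSd intensity model
#' @param seed integer seed
#' @return an \code{\linkS4class{ImageSimConfig}}
#' @export
imageSimConfig <- function(width = 512L, height = 512L, pixelSize = 0.3,
                           nCells = 25L, fracFilamented = 0.5,
                           filamentLength = c(10, 18),
                           filamentThickness = c(0.6, 0.9),
                           filamentCurvature = c(0.1, 0.6),
                           punctaDiameter = c(0.9, 1.8),
                           punctaCount = c(3L, 7L),
                           filamentCount = c(1L, 3L),
                           nucleusRadius = c(2.1, 3.6),
                           backgroundLevel = 0.05, signalLevel = 0.75,
                           noiseSd = 0.02, seed = 1L) {
  new("ImageSimConfig", width = as.integer(width), height = as.integer(height),
      pixelSize = pixelSize, nCells = as.integer(nCells),
      fracFilamented = fracFilamented, filamentLength = filamentLength,
      filamentThickness = filamentThickness,
      filamentCurvature = filamentCurvature, punctaDiameter = punctaDiameter,
      punctaCount = as.integer(punctaCount),
      filamentCount = as.integer(filamentCount),
      nucleusRadius = nucleusRadius, backgroundLevel = backgroundLevel,
      signalLevel = signalLevel, noiseSd = noiseSd, seed = as.integer(seed))
}

#' Create a segmentation configuration
#'
#' Defaults: blur sigma 3 px on the combined nuclear+reporter image,
#' 1st/99.5th percentile contrast rescale, CLAHE with a 127 px kernel and
#' clip limit 3, Otsu thresholding, and a 25 um nearest-seed cytoplasm
#' expansion.
#'
#' @param blurSigma px
#' @param channelWeights c(nuclear, reporter) weights for the combined
#'   nucleus-detection image
#' @param contrastPercentiles c(low, high) percentiles, 0-100
#' @param claheKernel px
#' @param claheClip unitless
#' @param thresholdMethod currently only \code{"otsu"}
#' @param minNucleusArea,minObjectArea px^2
#' @param cytoplasmExpandRadius um
#' @return a \code{\linkS4class{SegmentationConfig}}
#' @export
segmentationConfig <- function(blurSigma = 3, channelWeights = c(1, 0.3),
                               contrastPercentiles = c(1, 99.5),
                               claheKernel = 127L, claheClip = 3,
                               thresholdMethod = "otsu",
                               minNucleusArea = 40, minObjectArea = 4,
                               cytoplasmExpandRadius = 25) {
  thresholdMethod <- match.arg(thresholdMethod, "otsu")
  new("SegmentationConfig", blurSigma = blurSigma,
      channelWeights = channelWeights,
      contrastPercentiles = contrastPercentiles,
      claheKernel = as.integer(claheKernel), claheClip = claheClip,
      thresholdMethod = thresholdMethod, minNucleusArea = minNucleusArea,
      minObjectArea = minObjectArea,
      cytoplasmExpandRadius = cytoplasmExpandRadius)
}

#' Create a morphometry configuration
#'
#' Defaults: box sizes \{2, 3, 4, 6, 8, 12, 16, 32, 64\} px, D-threshold
#' 0.7, perimeter threshold 10 um, pixel size 0.3 um/px.
#'
#' @param boxSizes strictly increasing box edges (px)
#' @param dThreshold unitless
#' @param perimeterThreshold um
#' @param pixelSize um/px
#' @return a \code{\linkS4class{MorphometryConfig}}
#' @export
morphometryConfig <- function(boxSizes = c(2, 3, 4, 6, 8, 12, 16, 32, 64),
                              dThreshold = 0.7, perimeterThreshold = 10,
                              pixelSize = 0.3) {
  new("MorphometryConfig", boxSizes = boxSizes, dThreshold = dThreshold,
      perimeterThreshold = perimeterThreshold, pixelSize = pixelSize)
}

#' Create helical symmetry parameters
#'
#' @param twist signed degrees in (-180, 180]; negative = left-handed
#' @param rise Angstrom
#' @param pointGroup \code{"C1"} or \code{"D1"}
#' @return a \code{\linkS4class{HelicalParams}}
#' @examples
#' helicalParams(-108, 51, "D1")    # basal CBS filament architecture
#' helicalParams(-178.6, 46.7, "D1") # SAM-activated architecture
#' @export
helicalParams <- function(twist, rise, pointGroup = "C1") {
  new("HelicalParams", twist = twist, rise = rise, pointGroup = pointGroup)
}

#' Create a structure model
#'
#' @param coords n x 3 matrix (Angstrom)
#' @param element,chain,subunit per-atom character vectors (recycled)
#' @param unit per-atom helical unit index (0-based; NA when not a
#'   filament)
#' @return a \code{\linkS4class{StructureModel}}
#' @export
structureModel <- function(coords, element = "C", chain = "A",
                           subunit = chain, unit = NA_integer_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  new("StructureModel", coords = coords,
      element = rep_len(as.character(element), n),
      chain = rep_len(as.character(chain), n),
      subunit = rep_len(as.character(subunit), n),
      unit = rep_len(as.integer(unit), n))
}

#' Create an ITC experiment design
#'
#' Defaults follow common PEAQ-ITC practice for SAM into CBS: 200 ul
#' cell, one 0.4 ul pre-injection followed by 44 x 0.8 ul injections at
#' 25 C.
#'
#' @param cellVolumeUl ul
#' @param cellConcUm uM monomer in the cell
#' @param syringeConcUm uM ligand in the syringe
#' @param injectionVolumesUl ul per injection
#' @param temperatureC Celsius
#' @param heatsUcal observed heats (ucal), or NULL for a design-only
#'   object
#' @return an \code{\linkS4class{ITCExperiment}}
#' @export
itcExperiment <- function(cellVolumeUl = 200, cellConcUm = 30,
                          syringeConcUm = 500,
                          injectionVolumesUl = c(0.4, rep(0.8, 44)),
                          temperatureC = 25, heatsUcal = NULL) {
  new("ITCExperiment", cellVolumeUl = cellVolumeUl, cellConcUm = cellConcUm,
      syringeConcUm = syringeConcUm,
      injectionVolumesUl = injectionVolumesUl, temperatureC = temperatureC,
      heatsUcal = heatsUcal)
}

#' Create two-sets-of-sites binding parameters
#'
#' @param N sites per monomer, length 2
#' @param Kd dissociation constants in M, length 2 (stored as K = 1/Kd)
#' @param dH kcal/mol, length 2
#' @return an \code{\linkS4class{ITCTwoSetsParams}} with classes sorted by
#'   ascending Kd
#' @export
itcTwoSetsParams <- function(N, Kd, dH) {
  o <- order(Kd)
  new("ITCTwoSetsParams", N = N[o], K = 1 / Kd[o], dH = dH[o])
}

#' Create an assay simulation configuration
#'
#' @param model one of \code{"michaelis_menten"}, \code{"hill_activation"},
#'   \code{"thermal_sigmoid"}, \code{"itc_two_sets"}
#' @param trueParams named list of generating parameters (see
#'   \code{\link{generateAssayDataset}})
#' @param design numeric x-grid, or an \code{ITCExperiment} for the ITC
#'   model
#' @param noiseSd response-unit Gaussian noise sd
#' @param replicates replicate count
#' @param seed integer seed
#' @return an \code{\linkS4class{AssaySimConfig}}
#' @export
assaySimConfig <- function(model, trueParams, design, noiseSd = 0,
                           replicates = 1L, seed = 1L) {
  supported <- c("michaelis_menten", "hill_activation", "thermal_sigmoid",
                 "itc_two_sets")
  if (!model %in% supported)
    stop("unknown model '", model, "'; supported models: ",
         paste(supported, collapse = ", "))
  new("AssaySimConfig", model = model, trueParams = trueParams,
      design = design, noiseSd = noiseSd, replicates = as.integer(replicates),
      seed = as.integer(seed))
}

#' Calibrate a size-exclusion column from standards
#'
#' Fits log10(MW) against the partition coefficient
#' Kav = (Ve - V0) / (Vt - V0) by ordinary least squares.
#'
#' @param V0 void volume (ml)
#' @param Vt total column volume (ml)
#' @param standards data.frame with columns \code{mw_kda} and \code{ve_ml}
#' @return a \code{\linkS4class{SECCalibration}}
#' @export
secCalibration <- function(V0, Vt, standards) {
  stopifnot(is.data.frame(standards),
            all(c("mw_kda", "ve_ml") %in% names(standards)))
  if (nrow(standards) < 3)
    stop("at least 3 standards are required")
  kav <- (standards$ve_ml - V0) / (Vt - V0)
  fit <- lm(log10(standards$mw_kda) ~ kav)
  new("SECCalibration", V0 = V0, Vt = Vt, standards = standards,
      intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}
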