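#' @import methods
#' @importFrom stats lm coef rnorm runif sd pf ptukey qnorm median aov anova
#' @importFrom utils head tail
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' Configuration for the synthetic micrograph generator
#'
#' Describes one simulated high-content field of view: image geometry,
#' number of cells, the fraction of cells whose cytoplasmic reporter
#' objects are filament-like (the remainder carry small puncta), the
#' geometry ranges of the drawn objects, and the intensity model.
#'
#' All length units are micrometres; \code{pixelSize} converts to pixels.
#' The default 0.3 um/px corresponds to typical 20x high-content sampling,
#' so the 10 um perimeter threshold used downstream spans about 33 px.
#'
#' @slot width,height image size in pixels
#' @slot pixelSize um per pixel (> 0)
#' @slot nCells number of cells to place
#' @slot fracFilamented fraction of cells in [0, 1] drawn with filaments
#' @slot filamentLength,filamentThickness ranges (um) for filament geometry
#' @slot filamentCurvature range of curvature control (0 = straight, 1 =
#'   strongly bowed quadratic Bezier)
#' @slot punctaDiameter range (um) of punctum diameters
#' @slot punctaCount integer range of puncta per punctuated cell
#' @slot filamentCount integer range of filaments per filamented cell
#' @slot nucleusRadius range (um) of nucleus radii
#' @slot backgroundLevel,signalLevel,noiseSd intensity model (arbitrary
#'   units in [0, 1]); Gaussian read noise of sd \code{noiseSd} is added
#' @slot seed integer seed; identical configs give bit-identical output
#' @export
setClass("ImageSimConfig",
  representation(
    width = "integer", height = "integer", pixelSize = "numeric",
    nCells = "integer", fracFilamented = "numeric",
    filamentLength = "numeric", filamentThickness = "numeric",
    filamentCurvature = "numeric", punctaDiameter = "numeric",
    punctaCount = "integer", filamentCount = "integer",
    nucleusRadius = "numeric",
    backgroundLevel = "numeric", signalLevel = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("ImageSimConfig", function(object) {
  msg <- character()
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@fracFilamented < 0 || object@fracFilamented > 1)
    msg <- c(msg, "fracFilamented must lie in [0, 1]")
  if (object@nCells < 0) msg <- c(msg, "nCells must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  for (s in c("filamentLength", "filamentThickness", "filamentCurvature",
              "punctaDiameter", "nucleusRadius")) {
    v <- slot(object, s)
    if (length(v) != 2L || any(v < 0) || v[1] > v[2])
      msg <- c(msg, sprintf("%s must be an increasing non-negative range", s))
  }
  if (length(msg)) msg else TRUE
})

#' A simulated multi-channel field of view with ground truth
#'
#' Holds the nuclear and reporter channels of one synthetic micrograph
#' together with the generator's ground truth: per-cell labels
#' (\code{filamented}/\code{punctuated}), nucleus centroids, object counts,
#' and the exact raster of drawn reporter objects (for pixel-level
#' recovery tests).
#'
#' @slot nuclear,reporter numeric matrices (row, col), same shape
#' @slot pixelSize um per pixel
#' @slot labels data.frame with columns cell_id, true_class,
#'   nucleus_row, nucleus_col, object_count
#' @slot truthMask integer matrix; 0 = background, otherwise the cell_id
#'   whose object covers the pixel (noise-free raster of drawn objects)
#' @slot condition optional condition label carried into cohort summaries
#' @export
setClass("CellImageSet",
  representation(
    nuclear = "matrix", reporter = "matrix", pixelSize = "numeric",
    labels = "data.frame", truthMask = "matrix", condition = "character"
  )
)

setValidity("CellImageSet", function(object) {
  if (!all(dim(object@nuclear) == dim(object@reporter)))
    return("nuclear and reporter channels must have the same shape")
  if (nrow(object@labels) > 0 &&
      anyDuplicated(object@labels$cell_id))
    return("cell_id labels must be unique")
  TRUE
})

#' Segmentation configuration
#'
#' Parameters of the cell identification pipeline: Gaussian blur sigma
#' applied to the combined nuclear+reporter image (default 3 px),
#' percentile contrast rescaling, CLAHE local-contrast enhancement,
#' thresholding method, size filters and the cytoplasm expansion radius.
#'
#' @slot blurSigma Gaussian blur sigma in px (> 0; default 3)
#' @slot channelWeights weights of the rescaled nuclear and reporter
#'   channels in the combined image used for nucleus detection; the
#'   default 1:0.3 lets nuclear morphology dominate while the reporter
#'   channel rescues weakly stained nuclei
#' @slot contrastPercentiles low/high percentiles (0-100) for rescaling
#' @slot claheKernel CLAHE tile size in px
#' @slot claheClip CLAHE clip limit (unitless)
#' @slot thresholdMethod currently \code{"otsu"}
#' @slot minNucleusArea,minObjectArea size filters in px^2 (>= 1)
#' @slot cytoplasmExpandRadius um of nearest-seed expansion around nuclei
#' @export
setClass("SegmentationConfig",
  representation(
    blurSigma = "numeric", channelWeights = "numeric",
    contrastPercentiles = "numeric",
    claheKernel = "integer", claheClip = "numeric",
    thresholdMethod = "character",
    minNucleusArea = "numeric", minObjectArea = "numeric",
    cytoplasmExpandRadius = "numeric"
  )
)

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  if (object@blurSigma <= 0) msg <- c(msg, "blurSigma must be > 0")
  if (length(object@channelWeights) != 2L || any(object@channelWeights < 0) ||
      object@channelWeights[1] <= 0)
    msg <- c(msg, "channelWeights must be two non-negative weights (nuclear > 0)")
  p <- object@contrastPercentiles
  if (length(p) != 2L || p[1] < 0 || p[2] > 100 || p[1] >= p[2])
    msg <- c(msg, "contrastPercentiles must satisfy 0 <= low < high <= 100")
  if (object@minNucleusArea < 1 || object@minObjectArea < 1)
    msg <- c(msg, "minimum areas must be >= 1 px^2")
  if (object@cytoplasmExpandRadius <= 0)
    msg <- c(msg, "cytoplasmExpandRadius must be > 0")
  if (length(msg)) msg else TRUE
})

#' Segmented cell regions of one field of view
#'
#' Nucleus and cytoplasm territory of each detected cell, stored as two
#' label matrices (0 = unassigned, k = cell k). Cytoplasm labels exclude
#' nucleus pixels and are mutually disjoint by construction (nearest-seed
#' growth assigns contested pixels to the closer nucleus).
#'
#' @slot nucleusLabels,cytoplasmLabels integer label matrices, same shape
#' @slot nCells number of cells (labels run 1..nCells)
#' @export
setClass("CellRegions",
  representation(nucleusLabels = "matrix", cytoplasmLabels = "matrix",
                 nCells = "integer")
)

setValidity("CellRegions", function(object) {
  if (!all(dim(object@nucleusLabels) == dim(object@cytoplasmLabels)))
    return("label matrices must share a shape")
  ov <- object@nucleusLabels > 0 & object@cytoplasmLabels > 0
  if (any(ov)) return("nucleus and cytoplasm masks must be disjoint")
  TRUE
})

#' Morphometry configuration
#'
#' Box sizes for the box-counting fractal dimension, the cell-level
#' classification thresholds, and the pixel size. The default D-threshold
#' is 0.7 (objects meeting or exceeding it count as filament-like) and the
#' default perimeter threshold is 10 um.
#'
#' @slot boxSizes strictly increasing box edge lengths in px (>= 2, at
#'   least 3 sizes)
#' @slot dThreshold fractal-dimension threshold (default 0.7)
#' @slot perimeterThreshold um (default 10)
#' @slot pixelSize um per pixel
#' @export
setClass("MorphometryConfig",
  representation(boxSizes = "numeric", dThreshold = "numeric",
                 perimeterThreshold = "numeric", pixelSize = "numeric")
)

setValidity("MorphometryConfig", function(object) {
  msg <- character()
  b <- object@boxSizes
  if (length(b) < 3 || any(b < 2) || any(diff(b) <= 0))
    msg <- c(msg, "boxSizes must be >= 3 strictly increasing values >= 2")
  if (object@dThreshold <= 0) msg <- c(msg, "dThreshold must be > 0")
  if (object@perimeterThreshold <= 0)
    msg <- c(msg, "perimeterThreshold must be > 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Helical symmetry parameters
#'
#' Signed twist (degrees; negative = left-handed screw when the
#' translation is taken positive, matching the deposition convention),
#' rise along the helix axis (Angstrom), and the point group: \code{"C1"}
#' (asymmetric unit only) or \code{"D1"} (an additional two-fold axis
#' perpendicular to the helix axis).
#'
#' @slot twist degrees in (-180, 180]
#' @slot rise Angstrom (>= 0)
#' @slot pointGroup "C1" or "D1"
#' @export
setClass("HelicalParams",
  representation(twist = "numeric", rise = "numeric", pointGroup = "character")
)

setValidity("HelicalParams", function(object) {
  msg <- character()
  if (object@twist <= -180 || object@twist > 180)
    msg <- c(msg, "twist must lie in (-180, 180]")
  if (object@rise < 0) msg <- c(msg, "rise must be >= 0")
  if (!object@pointGroup %in% c("C1", "D1"))
    msg <- c(msg, "pointGroup must be 'C1' or 'D1'")
  if (length(msg)) msg else TRUE
})

#' Atomic (or pseudo-atomic) coordinate model
#'
#' A light container for coordinates grouped into subunits along a
#' filament: element (used to assign SASA radii), chain identifier,
#' subunit identifier and the helical unit index (0-based along the
#' filament, NA for non-filament models).
#'
#' @slot coords n x 3 numeric matrix, Angstrom
#' @slot element character vector length n
#' @slot chain character vector length n
#' @slot subunit character vector length n (partitions the atoms)
#' @slot unit integer vector length n (helical unit index, 0-based)
#' @export
setClass("StructureModel",
  representation(coords = "matrix", element = "character",
                 chain = "character", subunit = "character", unit = "integer")
)

setValidity("StructureModel", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3) return("coords must be n x 3")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  for (s in c("element", "chain", "subunit", "unit"))
    if (length(slot(object, s)) != n)
      return(sprintf("%s must have one entry per atom", s))
  TRUE
})

#' Screw-axis decomposition of a rigid transform
#'
#' The rigid transform superposing one helical unit onto the next,
#' decomposed into a rotation about the screw axis and a translation
#' along it. The axis is oriented so the translation is non-negative; the
#' rotation angle is signed by the right-hand rule about that axis.
#'
#' @slot angle degrees in (-180, 180]
#' @slot axis unit 3-vector
#' @slot point a point on the axis (Angstrom)
#' @slot translation Angstrom along the axis
#' @slot rmsd residual RMSD of the superposition (Angstrom)
#' @export
setClass("ScrewTransform",
  representation(angle = "numeric", axis = "numeric", point = "numeric",
                 translation = "numeric", rmsd = "numeric")
)

setValidity("ScrewTransform", function(object) {
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
    return("axis must be a unit vector")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  TRUE
})

#' An isothermal titration calorimetry experiment
#'
#' Cell and syringe concentrations, the injection schedule, temperature
#' and (optionally) the observed per-injection heats. The default
#' schedule, one 0.4 ul pre-injection followed by 44 x 0.8 ul, matches
#' standard PEAQ-ITC practice for SAM titrations into CBS.
#'
#' @slot cellVolumeUl active cell volume (ul)
#' @slot cellConcUm macromolecule (monomer) concentration in the cell (uM)
#' @slot syringeConcUm ligand concentration in the syringe (uM)
#' @slot injectionVolumesUl vector of injection volumes (ul)
#' @slot temperatureC experiment temperature (Celsius)
#' @slot heatsUcal observed heats per injection (ucal), or NULL
#' @export
setClass("ITCExperiment",
  representation(cellVolumeUl = "numeric", cellConcUm = "numeric",
                 syringeConcUm = "numeric", injectionVolumesUl = "numeric",
                 temperatureC = "numeric", heatsUcal = "numericOrNULL")
)

setValidity("ITCExperiment", function(object) {
  msg <- character()
  if (object@cellVolumeUl <= 0) msg <- c(msg, "cell volume must be > 0")
  if (any(object@injectionVolumesUl <= 0))
    msg <- c(msg, "injection volumes must be > 0")
  if (!is.null(object@heatsUcal) &&
      length(object@heatsUcal) != length(object@injectionVolumesUl))
    msg <- c(msg, "heats list length must equal the number of injections")
  if (length(msg)) msg else TRUE
})

#' Two-sets-of-sites binding parameters
#'
#' Two independent site classes per monomer, each with a stoichiometry
#' N_i (sites/monomer), association constant K_i (1/M; Kd_i = 1/K_i) and
#' enthalpy dH_i (kcal/mol). \code{\link{itcThermodynamics}} derives
#' dG_i = -RT ln K_i and -T dS_i = dG_i - dH_i at a given temperature.
#'
#' @slot N length-2 numeric, sites per monomer (>= 0)
#' @slot K length-2 numeric, association constants (1/M, > 0)
#' @slot dH length-2 numeric, kcal/mol
#' @export
setClass("ITCTwoSetsParams",
  representation(N = "numeric", K = "numeric", dH = "numeric")
)

setValidity("ITCTwoSetsParams", function(object) {
  if (length(object@N) != 2 || length(object@K) != 2 ||
      length(object@dH) != 2)
    return("N, K and dH must each have length 2 (one per site class)")
  if (any(object@N < 0)) return("N must be >= 0")
  if (any(object@K <= 0)) return("K must be > 0")
  TRUE
})

#' Size-exclusion chromatography calibration
#'
#' Column void volume V0, total volume Vt and a standards table
#' (MW in kDa, elution volume Ve in ml). The calibration line relates
#' log10(MW) linearly to the partition coefficient
#' Kav = (Ve - V0) / (Vt - V0).
#'
#' @slot V0,Vt ml, V0 < Vt
#' @slot standards data.frame with columns mw_kda and ve_ml
#' @slot intercept,slope fitted line log10(MW) = intercept + slope * Kav
#' @export
setClass("SECCalibration",
  representation(V0 = "numeric", Vt = "numeric", standards = "data.frame",
                 intercept = "numeric", slope = "numeric")
)

setValidity("SECCalibration", function(object) {
  if (object@V0 >= object@Vt) return("V0 must be < Vt")
  ve <- object@standards$ve_ml
  if (any(ve <= object@V0) || any(ve >= object@Vt))
    return("all standard elution volumes must satisfy V0 < Ve < Vt")
  TRUE
})

#' Configuration for synthetic assay datasets
#'
#' Ground-truth model, parameters, design and noise for one simulated
#' assay. Supported models: \code{"michaelis_menten"},
#' \code{"hill_activation"}, \code{"thermal_sigmoid"},
#' \code{"itc_two_sets"} (whose design is an \code{ITCExperiment}).
#'
#' @slot model model name
#' @slot trueParams named list of generating parameters
#' @slot design numeric x-grid (strictly increasing), or an
#'   \code{ITCExperiment} for \code{"itc_two_sets"}
#' @slot noiseSd Gaussian noise sd in response units (>= 0)
#' @slot replicates number of replicates
#' @slot seed integer seed
#' @export
setClass("AssaySimConfig",
  representation(model = "character", trueParams = "list", design = "ANY",
                 noiseSd = "numeric", replicates = "integer", seed = "integer")
)

setValidity("AssaySimConfig", function(object) {
  msg <- character()
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
  if (is.numeric(object@design) && length(object@design) > 1 &&
      any(diff(object@design) <= 0))
    msg <- c(msg, "x-grid must be strictly increasing")
  if (length(msg)) msg else TRUE
})
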