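#' @include AllClasses.R constructors.R models.R itc.R utils.R
NULL

#' Generate a noisy synthetic assay dataset
#'
#' Evaluates the configured forward model on the design grid and adds
#' i.i.d. Gaussian noise per replicate; with \code{noiseSd = 0} the
#' responses equal the forward model to machine precision.
#'
#' Expected \code{trueParams} entries by model:
#' \describe{
#'   \item{michaelis_menten}{\code{Vmax}, \code{Km}}
#'   \item{hill_activation}{\code{vBasal}, \code{vMax}, \code{Kact},
#'     \code{nHill}}
#'   \item{thermal_sigmoid}{\code{low}, \code{high}, \code{Tm},
#'     \code{slope}}
#'   \item{itc_two_sets}{\code{N}, \code{Kd} (M), \code{dH} (kcal/mol);
#'     the design must be an \code{\linkS4class{ITCExperiment}}}
#' }
#'
#' @param config an \code{\linkS4class{AssaySimConfig}}
#' @return for curve models, a data.frame \code{(x, replicate, response)};
#'   for \code{itc_two_sets}, a data.frame
#'   \code{(injection, replicate, heat_ucal)}
#' @export
generateAssayDataset <- function(config) {
  validObject(config)
  p <- config@trueParams
  set.seed(deriveSeed(config@seed, 0L))

  if (config@model == "itc_two_sets") {
    if (!is(config@design, "ITCExperiment"))
      stop("the itc_two_sets model requires an ITCExperiment design")
    pars <- itcTwoSetsParams(p$N, p$Kd, p$dH)
    clean <- itcModelHeats(pars, config@design)
    out <- do.call(rbind, lapply(seq_len(config@replicates), function(r) {
      data.frame(injection = seq_along(clean), replicate = r,
                 heat_ucal = clean +
                   rnorm(length(clean), 0, config@noiseSd))
    }))
    rownames(out) <- NULL
    return(out)
  }

  x <- config@design
  clean <- switch(config@model,
    michaelis_menten = michaelisMenten(x, p$Vmax, p$Km),
    hill_activation = hillActivation(x, p$vBasal, p$vMax, p$Kact, p$nHill),
    thermal_sigmoid = thermalSigmoid(x, p$low, p$high, p$Tm, p$slope),
    stop("unknown model '", config@model, "'; supported models: ",
         "michaelis_menten, hill_activation, thermal_sigmoid, itc_two_sets")
  )
  out <- do.call(rbind, lapply(seq_len(config@replicates), function(r) {
    data.frame(x = x, replicate = r,
               response = clean + rnorm(length(x), 0, config@noiseSd))
  }))
  rownames(out) <- NULL
  out
}
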