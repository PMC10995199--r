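#' @include AllClasses.R models.R
NULL

# Shared wrapper: Levenberg-Marquardt least squares with a fixed start
# grid; returns the best fit by residual sum of squares.
.lmFit <- function(resFun, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = resFun, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("nonlinear fit failed to converge from all starts")
  best
}

# Parameter standard errors from the Jacobian at the solution.
.lmSe <- function(fit) {
  np <- length(fit$par); nres <- length(fit$fvec)
  if (nres <= np) return(rep(NA_real_, np))
  s2 <- fit$deviance / (nres - np)
  h <- try(solve(fit$hessian), silent = TRUE)
  if (inherits(h, "try-error")) return(rep(NA_real_, np))
  sqrt(pmax(diag(h), 0) * s2)
}

#' Calibrate H2S production rates against a standard curve
#'
#' Ordinary least-squares line through (known H2S concentration, raw
#' fluorescence rate) standards; the returned object converts raw
#' fluorescence rates into uM H2S/min via the inverted line.
#'
#' @param concentration known H2S concentrations (uM)
#' @param rate raw fluorescence rates (instrument units/min)
#' @return list with \code{slope}, \code{intercept} (rate = intercept +
#'   slope * concentration) and \code{convert(rate)} giving uM H2S
#' @export
calibrateH2S <- function(concentration, rate) {
  if (length(concentration) < 3)
    stop("at least 3 standards are required")
  if (length(unique(concentration)) < 2)
    stop("standard concentrations are degenerate (singular design)")
  fit <- lm(rate ~ concentration)
  b <- unname(coef(fit))
  if (abs(b[2]) < .Machine$double.eps)
    stop("zero calibration slope: rates carry no concentration signal")
  list(intercept = b[1], slope = b[2],
       convert = function(r) (r - b[1]) / b[2])
}

#' Fit Michaelis-Menten kinetics
#'
#' Unweighted nonlinear least squares of v = Vmax S / (Km + S).
#'
#' @param S substrate concentrations
#' @param v rates
#' @return list with \code{Vmax}, \code{Km}, standard errors
#'   (\code{VmaxSe}, \code{KmSe}), \code{rss}, \code{fitted},
#'   \code{converged}
#' @export
fitMichaelisMenten <- function(S, v) {
  stopifnot(length(S) == length(v))
  if (length(unique(S)) < 4)
    stop("at least 4 distinct substrate levels are required")
  vScale <- max(v)
  kGuess <- stats::median(S[S > 0])
  resFun <- function(p) michaelisMenten(S, p[1], p[2]) - v
  starts <- list(c(vScale, kGuess), c(vScale, kGuess / 10),
                 c(vScale, kGuess * 10))
  fit <- .lmFit(resFun, starts, lower = c(1e-12, 1e-12),
                upper = c(Inf, Inf))
  se <- .lmSe(fit)
  list(Vmax = fit$par[1], Km = fit$par[2], VmaxSe = se[1], KmSe = se[2],
       rss = fit$deviance,
       fitted = michaelisMenten(S, fit$par[1], fit$par[2]),
       converged = fit$info %in% 1:4)
}

#' Fit the Hill activation model
#'
#' Unweighted nonlinear least squares of
#' v = v_basal + (v_max - v_basal) S^n / (K_act^n + S^n), with the Hill
#' coefficient bounded to (0.2, 10].
#'
#' @param S activator concentrations (must include 0 or near-0 for the
#'   basal plateau)
#' @param v rates
#' @return list with \code{vBasal}, \code{vMax}, \code{Kact},
#'   \code{nHill}, standard errors, \code{rss}, \code{fitted},
#'   \code{converged}, and \code{flag} (\code{"ok"} or
#'   \code{"Kact_outside_range"})
#' @export
fitHillActivation <- function(S, v) {
  stopifnot(length(S) == length(v))
  if (length(unique(S)) < 5)
    stop("at least 5 activator levels are required")
  v0 <- mean(v[S == min(S)]); v1 <- max(v)
  kGuess <- stats::median(S[S > 0])
  resFun <- function(p) hillActivation(S, p[1], p[2], p[3], p[4]) - v
  starts <- list(c(v0, v1, kGuess, 1), c(v0, v1, kGuess, 3),
                 c(v0, v1, kGuess / 5, 2), c(v0, v1, kGuess * 5, 2))
  fit <- .lmFit(resFun, starts,
                lower = c(-Inf, -Inf, 1e-12, 0.2 + 1e-9),
                upper = c(Inf, Inf, Inf, 10))
  se <- .lmSe(fit)
  p <- fit$par
  flag <- if (p[3] < min(S[S > 0]) || p[3] > max(S)) "Kact_outside_range"
          else "ok"
  list(vBasal = p[1], vMax = p[2], Kact = p[3], nHill = p[4],
       vBasalSe = se[1], vMaxSe = se[2], KactSe = se[3], nHillSe = se[4],
       rss = fit$deviance,
       fitted = hillActivation(S, p[1], p[2], p[3], p[4]),
       converged = fit$info %in% 1:4, flag = flag)
}

#' Fit the thermal-activation sigmoid
#'
#' Unweighted nonlinear least squares of a logistic between two plateaus;
#' Tm is the inflection temperature.
#'
#' @param T_ pre-incubation temperatures (Celsius)
#' @param v rates measured after treatment
#' @return list with \code{low}, \code{high}, \code{Tm}, \code{slope},
#'   standard errors, \code{rss}, \code{fitted}, \code{converged}
#' @export
fitThermalSigmoid <- function(T_, v) {
  stopifnot(length(T_) == length(v))
  if (length(unique(T_)) < 6)
    stop("at least 6 temperatures bracketing the transition are required")
  lo <- mean(v[T_ <= stats::quantile(T_, 0.2)])
  hi <- mean(v[T_ >= stats::quantile(T_, 0.8)])
  tmGuess <- stats::median(T_)
  resFun <- function(p) thermalSigmoid(T_, p[1], p[2], p[3], p[4]) - v
  starts <- list(c(lo, hi, tmGuess, 1), c(lo, hi, tmGuess, 3),
                 c(lo, hi, stats::quantile(T_, 0.35, names = FALSE), 2),
                 c(lo, hi, stats::quantile(T_, 0.65, names = FALSE), 2))
  fit <- .lmFit(resFun, starts,
                lower = c(-Inf, -Inf, min(T_), 1e-6),
                upper = c(Inf, Inf, max(T_), diff(range(T_))))
  p <- fit$par
  # data a straight line explains as well as the logistic carry no
  # usable inflection; refuse rather than report a fake midpoint
  rssLine <- sum(stats::lm(v ~ T_)$residuals^2)
  if (p[3] <= min(T_) + 1e-6 || p[3] >= max(T_) - 1e-6 ||
      rssLine <= fit$deviance * (1 + 1e-9) + 1e-12)
    stop("no inflection within the assayed temperature range")
  se <- .lmSe(fit)
  list(low = p[1], high = p[2], Tm = p[3], slope = p[4],
       lowSe = se[1], highSe = se[2], TmSe = se[3], slopeSe = se[4],
       rss = fit$deviance,
       fitted = thermalSigmoid(T_, p[1], p[2], p[3], p[4]),
       converged = fit$info %in% 1:4)
}

#' Estimate molecular weight from SEC elution volume
#'
#' Computes Kav = (Ve - V0)/(Vt - V0) and inverts the calibration line
#' log10(MW) ~ Kav.
#'
#' @param calibration a \code{\linkS4class{SECCalibration}}
#' @param VeSample elution volume of the sample (ml)
#' @return list with \code{kav}, \code{mw_kda} and \code{flag}
#'   (\code{"ok"}, \code{"extrapolated"} when Kav falls outside the
#'   standards, or \code{"void_volume"} with no estimate when the sample
#'   elutes at or before V0)
#' @export
secMwEstimate <- function(calibration, VeSample) {
  validObject(calibration)
  if (VeSample <= calibration@V0)
    return(list(kav = NA_real_, mw_kda = NA_real_, flag = "void_volume"))
  kav <- (VeSample - calibration@V0) / (calibration@Vt - calibration@V0)
  mw <- 10^(calibration@intercept + calibration@slope * kav)
  kavStd <- (calibration@standards$ve_ml - calibration@V0) /
    (calibration@Vt - calibration@V0)
  flag <- if (kav < min(kavStd) || kav > max(kavStd)) "extrapolated"
          else "ok"
  list(kav = kav, mw_kda = mw, flag = flag)
}
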