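#' @include AllClasses.R
NULL

#' Population-mean transcription kinetics after cold release
#'
#' Deterministic relative intensity of the nucleolar transcription signal at
#' time \code{t} after return to 37 degrees C:
#' \deqn{M(t) = \mathrm{ramp}(t)\,[1 + a(t)\cos(2\pi (t - t_{peak})/T)]}
#' where \code{ramp(t) = min(t / rampEnd, 1)} models the recovery of the
#' transcription machinery and the oscillation amplitude
#' \code{a(t)} equals \code{amplitude} up to the first peak and decays as
#' \code{amplitude * exp(-(t - firstPeak) / damping)} afterwards, expressing
#' the gradual loss of synchrony across the population. On the default
#' 15-150 min grid the maxima fall at 30, 90 and 150 min and the
#' 15 min to 30 min ratio is exactly 3.
#'
#' @param t numeric vector of times in minutes, all \code{>= 0}.
#' @param cfg a \linkS4class{KineticsConfig}.
#' @return numeric vector of non-negative relative intensities (1 =
#'   baseline).
#' @examples
#' meanKinetics(c(15, 30, 90))   # 0.5, 1.5, ~1.2247
#' @export
meanKinetics <- function(t, cfg = kineticsConfig()) {
  stopifnot(is(cfg, "KineticsConfig"))
  validObject(cfg)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0")
  ramp <- pmin(t / cfg@rampEnd, 1)
  a <- ifelse(t <= cfg@firstPeak, cfg@amplitude,
              cfg@amplitude * exp(-(t - cfg@firstPeak) / cfg@damping))
  ramp * (1 + a * cos(2 * pi * (t - cfg@firstPeak) / cfg@period))
}

#' Noiseless mean trace on the configured time grid
#'
#' Convenience wrapper evaluating \code{baseline * meanKinetics(t)} at the
#' configured fixation time points and returning it as a
#' \linkS4class{TimeCourse} (SEM 0), ready for
#' \code{\link{coefficientOfVariation}} and \code{\link{fourierPeriodogram}}.
#'
#' @param cfg a \linkS4class{KineticsConfig}.
#' @return A \linkS4class{TimeCourse}.
#' @export
noiselessTrace <- function(cfg = kineticsConfig()) {
  timeCourse(cfg@timepoints, cfg@baseline * meanKinetics(cfg@timepoints, cfg))
}
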