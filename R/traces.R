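#' @include AllClasses.R kinetics.R
NULL

## lognormal with mean 1 and the requested coefficient of variation
rlnormCV <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Simulate per-cell compartment intensities across the fixation design
#'
#' Emulates the fixed-cell experimental design: at every time point a fresh
#' set of cells (\code{experiments x cellsPerExperiment}) is "fixed" and
#' measured, so the table holds population samples, not single-cell
#' trajectories. The nucleolar intensity of cell i at time t is
#' \deqn{B\,m_i(t)\,b_i\,(1 + \epsilon_i)\,(1 + \beta_t)}
#' with \code{m_i(t) = M(t)} under synchronized phases (see
#' \code{\link{meanKinetics}}), per-cell lognormal brightness \code{b_i},
#' Gaussian measurement noise \code{\epsilon_i} and a per-time-point batch
#' factor \code{\beta_t} (one draw per fixation point, shared by all cells
#' and experiments stained and imaged together). Under
#' \code{phaseMode = "random"} each cell draws its own uniform cosine phase
#' and the recovery ramp is dropped, which leaves the population mean flat at
#' the baseline. The nucleoplasmic intensity couples to the same cell's
#' kinetic state with attenuation \code{coupling} plus a shared
#' per-time-point fluctuation (see \linkS4class{NucleoplasmConfig}).
#'
#' @param cfg a \linkS4class{KineticsConfig}.
#' @param npCfg a \linkS4class{NucleoplasmConfig}.
#' @param seed single integer; identical seeds give identical tables.
#' @return A measurement table: \code{data.frame} with columns
#'   \code{experiment}, \code{cell}, \code{timepoint_min},
#'   \code{compartment} (\code{"nucleolar"} or \code{"nucleoplasmic"}) and
#'   \code{intensity}.
#' @examples
#' tab <- simulateTraces(seed = 1)
#' head(tab)
#' @export
simulateTraces <- function(cfg = kineticsConfig(),
                           npCfg = nucleoplasmConfig(), seed) {
  stopifnot(is(cfg, "KineticsConfig"), is(npCfg, "NucleoplasmConfig"))
  validObject(cfg); validObject(npCfg)
  if (missing(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed != round(seed))
    stop("seed must be a single integer")
  set.seed(as.integer(seed))

  n <- cfg@cellsPerExperiment * cfg@experiments
  expid <- rep(seq_len(cfg@experiments), each = cfg@cellsPerExperiment)
  cellid <- rep(seq_len(cfg@cellsPerExperiment), cfg@experiments)
  out <- vector("list", length(cfg@timepoints))

  for (j in seq_along(cfg@timepoints)) {
    t <- cfg@timepoints[j]
    batch <- stats::rnorm(1, 0, cfg@batchSD)
    sharedNp <- stats::rnorm(1, 0, npCfg@sharedNoiseSD)
    bright <- rlnormCV(n, cfg@cellBrightnessCV)
    noiseNuc <- stats::rnorm(n, 0, cfg@cellNoiseCV)
    noiseNp <- stats::rnorm(n, 0, npCfg@cellNoiseCV)
    if (cfg@phaseMode == "synchronized") {
      m <- rep(meanKinetics(t, cfg), n)
    } else {
      a <- if (t <= cfg@firstPeak) cfg@amplitude else
        cfg@amplitude * exp(-(t - cfg@firstPeak) / cfg@damping)
      m <- 1 + a * cos(stats::runif(n, 0, 2 * pi))
    }
    nuc <- cfg@baseline * m * bright * (1 + noiseNuc) * (1 + batch)
    np <- cfg@baseline * (1 + npCfg@coupling * (m - 1)) *
      (1 + sharedNp) * (1 + noiseNp)
    out[[j]] <- data.frame(
      experiment = rep(expid, 2L), cell = rep(cellid, 2L),
      timepoint_min = t,
      compartment = rep(c("nucleolar", "nucleoplasmic"), each = n),
      intensity = c(nuc, np))
  }
  do.call(rbind, out)
}
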