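#' @import methods
NULL

## ---------------------------------------------------------------------------
## Configuration classes
## ---------------------------------------------------------------------------

#' Kinetics configuration for the synchronized transcription model
#'
#' Parameters of the population-level transcription kinetics after release
#' from a cold block: a linear recovery ramp multiplied by a damped cosine,
#' \deqn{M(t) = \mathrm{ramp}(t)\,[1 + a(t)\cos(2\pi (t - t_{peak})/T)]}
#' with \code{ramp(t) = min(t/rampEnd, 1)} and an oscillation amplitude that
#' stays at \code{amplitude} up to the first peak and then decays
#' exponentially with time constant \code{damping} (loss of population
#' synchrony).
#'
#' @slot timepoints numeric, fixation time points in minutes (default 15,
#'   30, ..., 150; fresh cells are fixed at every point).
#' @slot period numeric, undulation period T in minutes (default 60).
#' @slot firstPeak numeric, time of the first activity maximum in minutes
#'   (default 30).
#' @slot rampEnd numeric, end of the post-cold recovery ramp in minutes
#'   (default 30).
#' @slot amplitude numeric, initial relative oscillation amplitude a0
#'   (default 0.5; dimensionless, must lie in [0, 1)).
#' @slot damping numeric, exponential damping time constant in minutes
#'   (default 75 for the HeLa preset; 120 for the slower-damping LEC preset).
#' @slot baseline numeric, baseline intensity B in arbitrary units
#'   (default 100).
#' @slot phaseMode character, \code{"synchronized"} (all cells share the
#'   cosine phase) or \code{"random"} (each cell draws a uniform phase and
#'   the ramp is dropped; emulates untreated control populations).
#' @slot cellBrightnessCV numeric, CV of the per-cell multiplicative
#'   lognormal brightness factor (default 0.2).
#' @slot cellNoiseCV numeric, SD of per-cell additive measurement noise as a
#'   fraction of the signal (default 0.1).
#' @slot batchSD numeric, SD of the per-time-point staining/imaging batch
#'   factor (default 0.07); one draw per time point, shared by all cells
#'   measured at that point.
#' @slot cellsPerExperiment integer, cells measured per experiment and time
#'   point (default 50).
#' @slot experiments integer, number of experiment repeats (default 8).
#' @slot coldFactor numeric, relative polymerase-I signal level retained in
#'   the cold state (default 0.6).
#' @export
setClass("KineticsConfig",
  representation(
    timepoints = "numeric", period = "numeric", firstPeak = "numeric",
    rampEnd = "numeric", amplitude = "numeric", damping = "numeric",
    baseline = "numeric", phaseMode = "character",
    cellBrightnessCV = "numeric", cellNoiseCV = "numeric",
    batchSD = "numeric", cellsPerExperiment = "integer",
    experiments = "integer", coldFactor = "numeric"),
  prototype(
    timepoints = seq(15, 150, by = 15), period = 60, firstPeak = 30,
    rampEnd = 30, amplitude = 0.5, damping = 75, baseline = 100,
    phaseMode = "synchronized", cellBrightnessCV = 0.2, cellNoiseCV = 0.1,
    batchSD = 0.07, cellsPerExperiment = 50L, experiments = 8L,
    coldFactor = 0.6))

setValidity("KineticsConfig", function(object) {
  msg <- NULL
  if (object@period <= 0) msg <- c(msg, "period must be > 0")
  if (object@amplitude < 0 || object@amplitude >= 1)
    msg <- c(msg, "amplitude must lie in [0, 1)")
  if (object@damping <= 0) msg <- c(msg, "damping must be > 0")
  if (object@rampEnd <= 0) msg <- c(msg, "rampEnd must be > 0")
  if (length(object@timepoints) < 1 || any(diff(object@timepoints) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (any(object@timepoints < 0)) msg <- c(msg, "timepoints must be >= 0")
  if (object@cellsPerExperiment < 2L)
    msg <- c(msg, "cellsPerExperiment must be >= 2")
  if (object@experiments < 1L) msg <- c(msg, "experiments must be >= 1")
  if (!object@phaseMode %in% c("synchronized", "random"))
    msg <- c(msg, "phaseMode must be 'synchronized' or 'random'")
  if (object@baseline <= 0) msg <- c(msg, "baseline must be > 0")
  if (object@coldFactor < 0) msg <- c(msg, "coldFactor must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Create a kinetics configuration
#'
#' @param ... named values overriding the slot defaults documented in
#'   \linkS4class{KineticsConfig}.
#' @return A \linkS4class{KineticsConfig} object.
#' @examples
#' cfg <- kineticsConfig(damping = 120)
#' @export
kineticsConfig <- function(...) {
  args <- list(...)
  for (nm in c("cellsPerExperiment", "experiments"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("KineticsConfig"), args))
}

#' Preset kinetics configurations
#'
#' \code{"hela_sync"} is the synchronized HeLa default; \code{"lec_sync"}
#' uses the slower damping of limbal epithelial cells; \code{"control"} is
#' the unsynchronized (random-phase) population; \code{"cold"} keeps the
#' HeLa kinetics and is rendered at \code{coldFactor} times the normal
#' signal level by the image pipeline.
#'
#' @param preset one of \code{"hela_sync"}, \code{"lec_sync"},
#'   \code{"control"}, \code{"cold"}.
#' @return A \linkS4class{KineticsConfig}.
#' @export
kineticsPreset <- function(preset = c("hela_sync", "lec_sync", "control",
                                      "cold")) {
  preset <- match.arg(preset)
  switch(preset,
    hela_sync = kineticsConfig(),
    lec_sync  = kineticsConfig(damping = 120),
    control   = kineticsConfig(phaseMode = "random"),
    cold      = kineticsConfig())
}

#' Nucleoplasm coupling configuration
#'
#' The nucleoplasmic signal tracks the nucleolar kinetics with attenuated
#' amplitude plus an independent shared fluctuation. Defaults are calibrated
#' so that the expected nucleolus-nucleoplasm correlation is about 0.65 and
#' the nucleoplasmic CV about 0.17: with r the target correlation, CVnp the
#' target nucleoplasmic CV and CVnuc the noiseless nucleolar CV,
#' \code{coupling = r * CVnp / CVnuc} and
#' \code{sharedNoiseSD = CVnp * sqrt(1 - r^2)}.
#'
#' @slot coupling numeric in [0, 1], attenuation of the kinetic modulation
#'   (default 0.414).
#' @slot sharedNoiseSD numeric, SD of the per-time-point shared nucleoplasmic
#'   fluctuation (default 0.13).
#' @slot cellNoiseCV numeric, per-cell measurement noise SD as a fraction of
#'   the signal (default 0.2).
#' @export
setClass("NucleoplasmConfig",
  representation(coupling = "numeric", sharedNoiseSD = "numeric",
                 cellNoiseCV = "numeric"),
  prototype(coupling = 0.414, sharedNoiseSD = 0.13, cellNoiseCV = 0.2))

setValidity("NucleoplasmConfig", function(object) {
  msg <- NULL
  if (object@coupling < 0 || object@coupling > 1)
    msg <- c(msg, "coupling must lie in [0, 1]")
  if (object@sharedNoiseSD < 0) msg <- c(msg, "sharedNoiseSD must be >= 0")
  if (object@cellNoiseCV < 0) msg <- c(msg, "cellNoiseCV must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @rdname NucleoplasmConfig-class
#' @param ... named values overriding the slot defaults.
#' @return A \linkS4class{NucleoplasmConfig}.
#' @export
nucleoplasmConfig <- function(...) new("NucleoplasmConfig", ...)

#' Scene configuration for synthetic confocal stacks
#'
#' Geometry, brightness and noise of the rendered 3D scenes: one elliptical
#' nucleus with a dim uniform interior, one to a few disc-shaped nucleoli
#' carrying a diffuse signal plus bright diffraction-limited FC/DFC spots,
#' and many dim nucleoplasmic foci. Spots are anisotropic 3D Gaussians.
#'
#' @slot shape integer(3), stack size as (y, x, z) voxels
#'   (default 256 x 256 x 21).
#' @slot zAspect numeric, ratio of the z step to the xy pixel size
#'   (default 3).
#' @slot nucleoliPerCell integer (default 2).
#' @slot unitsPerCell integer, FC/DFC spots per cell (default 30).
#' @slot spotSigmaXY numeric, lateral Gaussian sigma in pixels (default 1.3).
#' @slot spotSigmaZ numeric, axial sigma in slices (default 0.8).
#' @slot unitBrightnessCV numeric, lognormal CV of spot amplitudes
#'   (default 0.3).
#' @slot nucleolarDiffuseFrac numeric, diffuse nucleolar intensity as a
#'   fraction of the mean spot amplitude (default 0.15).
#' @slot nucleoplasmicFoci integer, number of dim nucleoplasmic foci
#'   (default 100).
#' @slot fociAmplitudeFrac numeric, focus amplitude relative to the mean
#'   spot amplitude (default 0.1).
#' @slot nucleusBase numeric, uniform nuclear interior intensity
#'   (default 20).
#' @slot nucleolusRadius numeric, nucleolus disc radius in pixels
#'   (default 20).
#' @slot minUnitSeparation numeric, minimum xy distance between planted
#'   spot centres in pixels (default 6).
#' @slot poissonGain numeric, gain of the Poisson shot-noise model
#'   (default 1; 0 disables shot noise for noise-free renders).
#' @slot readNoiseSD numeric, Gaussian read-noise SD (default 2; 0 disables).
#' @export
setClass("SceneConfig",
  representation(
    shape = "integer", zAspect = "numeric", nucleoliPerCell = "integer",
    unitsPerCell = "integer", spotSigmaXY = "numeric", spotSigmaZ = "numeric",
    unitBrightnessCV = "numeric", nucleolarDiffuseFrac = "numeric",
    nucleoplasmicFoci = "integer", fociAmplitudeFrac = "numeric",
    nucleusBase = "numeric", nucleolusRadius = "numeric",
    minUnitSeparation = "numeric", poissonGain = "numeric",
    readNoiseSD = "numeric"),
  prototype(
    shape = c(256L, 256L, 21L), zAspect = 3, nucleoliPerCell = 2L,
    unitsPerCell = 30L, spotSigmaXY = 1.3, spotSigmaZ = 0.8,
    unitBrightnessCV = 0.3, nucleolarDiffuseFrac = 0.15,
    nucleoplasmicFoci = 100L, fociAmplitudeFrac = 0.1, nucleusBase = 20,
    nucleolusRadius = 20, minUnitSeparation = 6, poissonGain = 1,
    readNoiseSD = 2))

setValidity("SceneConfig", function(object) {
  msg <- NULL
  if (length(object@shape) != 3 || any(object@shape < 1))
    msg <- c(msg, "shape must be three positive integers (y, x, z)")
  if (object@spotSigmaXY <= 0 || object@spotSigmaZ <= 0)
    msg <- c(msg, "spot sigmas must be > 0")
  if (object@nucleolarDiffuseFrac < 0 || object@nucleolarDiffuseFrac > 1)
    msg <- c(msg, "nucleolarDiffuseFrac must lie in [0, 1]")
  if (object@fociAmplitudeFrac < 0 || object@fociAmplitudeFrac > 1)
    msg <- c(msg, "fociAmplitudeFrac must lie in [0, 1]")
  if (object@zAspect <= 0) msg <- c(msg, "zAspect must be > 0")
  if (object@poissonGain < 0 || object@readNoiseSD < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SceneConfig-class
#' @param ... named values overriding the slot defaults.
#' @return A \linkS4class{SceneConfig}.
#' @export
sceneConfig <- function(...) {
  args <- list(...)
  ints <- c("shape", "nucleoliPerCell", "unitsPerCell", "nucleoplasmicFoci")
  for (nm in ints) if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("SceneConfig"), args))
}

#' Detection parameters for FC/DFC unit quantification
#'
#' @slot blurSigma numeric, Gaussian sigma (pixels) used to blur the maximum
#'   intensity projection before Otsu masking (default 9; the working range
#'   is 8-10).
#' @slot minSeparation numeric, minimum distance (pixels) between accepted
#'   local maxima (default 3).
#' @slot radii numeric, ascending sphere radii (pixels) at which integral
#'   intensities are measured (default 1.0, 1.5, ..., 4.0).
#' @slot reportRadius numeric, radius used for reporting and ranking
#'   (default 1.5, the most noise-resistant choice).
#' @slot fitWindow integer, odd side length (pixels) of the square crop used
#'   for the Gaussian fit (default 7).
#' @slot annulusInner,annulusOuter numeric, inner/outer radii (pixels, z
#'   scaled by the stack anisotropy) of the local-background annulus
#'   (defaults 5 and 7).
#' @slot minIntensity numeric, minimum background-subtracted integral at the
#'   report radius for \code{\link{countUnits}} (default 0 = keep all).
#' @slot peakSNR numeric, candidate local maxima must exceed the nucleolar
#'   mask median by this many robust noise SDs (default 5).
#' @slot maskContrastSNR numeric, the within-nucleus Otsu split is accepted
#'   as nucleolar foreground only if its contrast exceeds this many robust
#'   SDs of the blurred image (default 5); otherwise no units are reported.
#' @export
setClass("DetectionParams",
  representation(
    blurSigma = "numeric", minSeparation = "numeric", radii = "numeric",
    reportRadius = "numeric", fitWindow = "integer", annulusInner = "numeric",
    annulusOuter = "numeric", minIntensity = "numeric", peakSNR = "numeric",
    maskContrastSNR = "numeric"),
  prototype(
    blurSigma = 9, minSeparation = 3, radii = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
    reportRadius = 1.5, fitWindow = 7L, annulusInner = 5, annulusOuter = 7,
    minIntensity = 0, peakSNR = 5, maskContrastSNR = 5))

setValidity("DetectionParams", function(object) {
  msg <- NULL
  if (any(object@radii <= 0) || any(diff(object@radii) <= 0))
    msg <- c(msg, "radii must be positive and strictly ascending")
  if (!any(abs(object@radii - object@reportRadius) < 1e-9))
    msg <- c(msg, "reportRadius must be one of radii")
  if (object@blurSigma <= 0) msg <- c(msg, "blurSigma must be > 0")
  if (object@fitWindow < 3L || object@fitWindow %% 2L == 0L)
    msg <- c(msg, "fitWindow must be an odd integer >= 3")
  if (object@annulusOuter <= object@annulusInner)
    msg <- c(msg, "annulusOuter must exceed annulusInner")
  if (object@minSeparation <= 0) msg <- c(msg, "minSeparation must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @rdname DetectionParams-class
#' @param ... named values overriding the slot defaults.
#' @return A \linkS4class{DetectionParams}.
#' @export
detectionParams <- function(...) {
  args <- list(...)
  if (!is.null(args$fitWindow)) args$fitWindow <- as.integer(args$fitWindow)
  do.call(new, c(list("DetectionParams"), args))
}

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' 3D image stack with voxel anisotropy
#'
#' Voxel intensities are stored as a numeric array indexed \code{[y, x, z]}
#' (a list of xy slices stacked along z, matching multi-page TIFF order).
#' All exported coordinate interfaces use 0-based \code{(x, y, z)}
#' coordinates, as written to the units and ground-truth CSV files.
#'
#' @slot voxels numeric array (y, x, z) of non-negative finite intensities.
#' @slot zAspect numeric, ratio of z spacing to xy pixel size.
#' @export
setClass("ImageStack",
  representation(voxels = "array", zAspect = "numeric"),
  prototype(voxels = array(0, c(1, 1, 1)), zAspect = 3))

setValidity("ImageStack", function(object) {
  msg <- NULL
  d <- dim(object@voxels)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "voxels must be a 3D array with at least one slice")
  if (!all(is.finite(object@voxels)))
    msg <- c(msg, "voxel values must be finite")
  if (length(object@zAspect) != 1L || object@zAspect <= 0)
    msg <- c(msg, "zAspect must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' @rdname ImageStack-class
#' @param voxels numeric 3D array (y, x, z).
#' @param zAspect ratio of z spacing to xy pixel size (default 3).
#' @return An \linkS4class{ImageStack}.
#' @examples
#' st <- imageStack(array(runif(4 * 4 * 3), c(4, 4, 3)))
#' dim(st)
#' @export
imageStack <- function(voxels, zAspect = 3) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  new("ImageStack", voxels = voxels, zAspect = zAspect)
}

#' Per-time-point population statistics of a measured compartment
#'
#' @slot timepoints numeric, fixation times in minutes, strictly increasing
#'   with constant spacing.
#' @slot mean numeric, per-time-point mean intensity.
#' @slot sem numeric, standard error of the mean.
#' @slot n integer, number of cells per time point.
#' @export
setClass("TimeCourse",
  representation(timepoints = "numeric", mean = "numeric", sem = "numeric",
                 n = "integer"))

setValidity("TimeCourse", function(object) {
  msg <- NULL
  k <- length(object@timepoints)
  if (k < 3L) msg <- c(msg, "at least 3 time points are required")
  if (length(object@mean) != k || length(object@sem) != k ||
      length(object@n) != k)
    msg <- c(msg, "timepoints, mean, sem, n must have equal length")
  if (any(diff(object@timepoints) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (k >= 3L) {
    dt <- diff(object@timepoints)
    if (max(dt) - min(dt) > 1e-8 * max(dt))
      msg <- c(msg, "timepoints must be equally spaced")
  }
  if (any(object@sem < 0)) msg <- c(msg, "sem must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' @rdname TimeCourse-class
#' @param timepoints,mean,sem,n slot values; \code{sem} defaults to zeros
#'   and \code{n} to 1 for deterministic traces.
#' @return A \linkS4class{TimeCourse}.
#' @export
timeCourse <- function(timepoints, mean, sem = rep(0, length(mean)),
                       n = rep(1L, length(mean))) {
  new("TimeCourse", timepoints = as.numeric(timepoints),
      mean = as.numeric(mean), sem = as.numeric(sem), n = as.integer(n))
}

#' Fourier-amplitude periodogram on a period grid
#'
#' @slot periods numeric, ascending candidate periods in minutes.
#' @slot amplitudes numeric, non-negative Fourier amplitudes.
#' @export
setClass("Periodogram",
  representation(periods = "numeric", amplitudes = "numeric"))

setValidity("Periodogram", function(object) {
  msg <- NULL
  if (length(object@periods) != length(object@amplitudes))
    msg <- c(msg, "periods and amplitudes must have equal length")
  if (any(diff(object@periods) <= 0))
    msg <- c(msg, "periods must be strictly ascending")
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Labelled 2D region mask
#'
#' Integer label image derived from the maximum intensity projection;
#' label 0 is background.
#'
#' @slot labels integer matrix of region labels.
#' @slot kind character, one of \code{"nucleus"}, \code{"nucleolus"},
#'   \code{"nucleoplasm"}.
#' @export
setClass("RegionMask",
  representation(labels = "matrix", kind = "character"))

setValidity("RegionMask", function(object) {
  msg <- NULL
  if (!object@kind %in% c("nucleus", "nucleolus", "nucleoplasm"))
    msg <- c(msg, "kind must be nucleus, nucleolus or nucleoplasm")
  if (any(object@labels < 0)) msg <- c(msg, "labels must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Pipeline configuration
#'
#' Bundles all module configurations with a preset name, a root seed and an
#' output directory; see \code{\link{runTraces}} and \code{\link{runImages}}.
#'
#' @slot preset character, one of \code{"hela_sync"}, \code{"lec_sync"},
#'   \code{"control"}, \code{"cold"}.
#' @slot seed integer root seed; all stage seeds are derived from it.
#' @slot outputDir character, directory for result files.
#' @slot kinetics a \linkS4class{KineticsConfig}.
#' @slot nucleoplasm a \linkS4class{NucleoplasmConfig}.
#' @slot scene a \linkS4class{SceneConfig}.
#' @slot detection a \linkS4class{DetectionParams}.
#' @slot stacksPerTimepoint integer, rendered cells per time point in the
#'   image-based pipeline (default 2).
#' @export
setClass("PipelineConfig",
  representation(
    preset = "character", seed = "integer", outputDir = "character",
    kinetics = "KineticsConfig", nucleoplasm = "NucleoplasmConfig",
    scene = "SceneConfig", detection = "DetectionParams",
    stacksPerTimepoint = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- NULL
  if (!object@preset %in% c("hela_sync", "lec_sync", "control", "cold"))
    msg <- c(msg, sprintf("unknown preset '%s'", object@preset))
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (object@stacksPerTimepoint < 2L)
    msg <- c(msg, "stacksPerTimepoint must be >= 2")
  if (is.null(msg)) TRUE else msg
})

#' @rdname PipelineConfig-class
#' @param preset preset name.
#' @param seed integer root seed.
#' @param outputDir output directory.
#' @param kinetics optional \linkS4class{KineticsConfig}; defaults to the
#'   preset's configuration.
#' @param nucleoplasm a \linkS4class{NucleoplasmConfig}.
#' @param scene a \linkS4class{SceneConfig}.
#' @param detection a \linkS4class{DetectionParams}.
#' @param stacksPerTimepoint rendered cells per time point (default 2).
#' @return A \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(preset = "hela_sync", seed = 1L,
                           outputDir = tempfile("nucleoPulse_"),
                           kinetics = NULL,
                           nucleoplasm = nucleoplasmConfig(),
                           scene = sceneConfig(),
                           detection = detectionParams(),
                           stacksPerTimepoint = 2L) {
  if (!is.character(preset) ||
      !preset %in% c("hela_sync", "lec_sync", "control", "cold"))
    stop("unknown preset '", paste(preset, collapse = ","), "'")
  if (is.null(kinetics)) kinetics <- kineticsPreset(preset)
  new("PipelineConfig", preset = preset, seed = as.integer(seed),
      outputDir = outputDir, kinetics = kinetics, nucleoplasm = nucleoplasm,
      scene = scene, detection = detection,
      stacksPerTimepoint = as.integer(stacksPerTimepoint))
}
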