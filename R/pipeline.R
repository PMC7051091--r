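#' @include AllClasses.R traces.R scene.R detection.R segmentation.R
#' @include timecourse.R io.R
NULL

summaryJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

runManifest <- function(config, files, outputDir) {
  cfgList <- list(
    preset = config@preset, seed = config@seed,
    kinetics = configAsList(config@kinetics),
    nucleoplasm = configAsList(config@nucleoplasm),
    scene = configAsList(config@scene),
    detection = configAsList(config@detection),
    stacksPerTimepoint = config@stacksPerTimepoint)
  list(config = cfgList,
       configHash = rlang::hash(cfgList),
       packageVersion = as.character(utils::packageVersion("nucleoPulse")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       files = files)
}

#' Run the trace-based analysis pipeline
#'
#' Simulates per-cell compartment intensities for the configured preset,
#' assembles nucleolar and nucleoplasmic time courses and computes the full
#' fluctuation analysis: coefficient of variation, Fourier-amplitude
#' periodogram, dominant period with its sampling-interval uncertainty,
#' nucleolus-nucleoplasm correlation and the 15-to-30 min fold change.
#' Writes \code{measurements.csv}, \code{timecourse_<compartment>.csv},
#' \code{periodogram.csv}, \code{summary.json} and \code{manifest.json}
#' into the output directory. Re-running with the same configuration and
#' seed reproduces \code{summary.json} byte for byte.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return the summary list, invisibly.
#' @export
runTraces <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config@outputDir))
    stop("cannot create output directory ", config@outputDir)

  kin <- config@kinetics
  if (config@preset == "cold")
    kin <- kineticsConfig(baseline = kin@baseline * kin@coldFactor,
                          damping = kin@damping, phaseMode = kin@phaseMode)
  tab <- simulateTraces(kin, config@nucleoplasm, seed = config@seed)
  tcNuc <- assembleTimecourse(tab, "nucleolar")
  tcNp <- assembleTimecourse(tab, "nucleoplasmic")
  pg <- fourierPeriodogram(tcNuc)
  dom <- dominantPeriod(pg)
  dt <- diff(timePoints(tcNuc))[1]
  iv <- periodInterval(dom, dt)
  summary <- list(
    preset = config@preset, seed = config@seed,
    cv_nucleolar = coefficientOfVariation(tcNuc),
    cv_nucleoplasmic = coefficientOfVariation(tcNp),
    dominant_period_min = dom,
    period_interval_min = iv,
    correlation_nucleolus_nucleoplasm = compartmentCorrelation(tcNuc, tcNp),
    fold_change_15_30 = if (all(c(15, 30) %in% timePoints(tcNuc)))
      foldChange(tcNuc, 15, 30) else NA_real_)

  od <- config@outputDir
  writeMeasurementTable(tab, file.path(od, "measurements.csv"))
  for (cm in c("nucleolar", "nucleoplasmic")) {
    tc <- if (cm == "nucleolar") tcNuc else tcNp
    utils::write.csv(
      data.frame(timepoint_min = timePoints(tc), mean = tcMean(tc),
                 sem = tcSEM(tc), n = tcN(tc)),
      file.path(od, sprintf("timecourse_%s.csv", cm)), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(period_min = periods(pg), amplitude = amplitudes(pg)),
    file.path(od, "periodogram.csv"), row.names = FALSE)
  summaryJSON(summary, file.path(od, "summary.json"))
  files <- c("measurements.csv", "timecourse_nucleolar.csv",
             "timecourse_nucleoplasmic.csv", "periodogram.csv",
             "summary.json")
  summaryJSON(runManifest(config, files, od),
              file.path(od, "manifest.json"))
  invisible(summary)
}

#' Run the image-based analysis pipeline
#'
#' Renders stacks for every fixation time point at signal levels following
#' the preset kinetics (the \code{"cold"} preset scales all levels by the
#' cold factor), detects and quantifies FC/DFC units, segments nuclei /
#' nucleoli / nucleoplasm, and assembles per-cell compartment intensities
#' into the same fluctuation statistics as \code{\link{runTraces}}, plus
#' unit counts per time point and the 15-to-30 min unit-intensity fold
#' change. Writes \code{units.csv}, \code{regions.csv},
#' \code{measurements.csv}, \code{summary.json} and \code{manifest.json}.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return the summary list, invisibly.
#' @export
runImages <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config@outputDir))
    stop("cannot create output directory ", config@outputDir)

  kin <- config@kinetics
  stacks <- simulateTimecourseStacks(
    kin, config@scene, seed = config@seed,
    stacksPerTimepoint = config@stacksPerTimepoint,
    cold = config@preset == "cold")

  unitRows <- list(); regionRows <- list(); measRows <- list()
  repCol <- reportColumn(config@detection)
  for (ent in stacks) {
    units <- detectUnits(ent$stack, config@detection)
    if (nrow(units) > 0) {
      unitRows[[length(unitRows) + 1L]] <-
        cbind(data.frame(timepoint_min = ent$timepoint_min,
                         cell_id = ent$cell), units)
      measRows[[length(measRows) + 1L]] <- data.frame(
        experiment = 1L, cell = ent$cell, timepoint_min = ent$timepoint_min,
        compartment = "unit", intensity = mean(units[[repCol]]))
    }
    nucleus <- segmentNucleus(ent$stack,
                              blurSigma = config@detection@blurSigma)
    if (any(regionLabels(nucleus) > 0L)) {
      nucleoli <- segmentNucleoli(ent$stack, nucleus)
      nplasm <- nucleoplasmMask(nucleus, nucleoli)
      for (msk in list(nucleus, nucleoli, nplasm)) {
        m <- measureRegions(ent$stack, msk)
        if (nrow(m) > 0)
          regionRows[[length(regionRows) + 1L]] <-
            cbind(data.frame(timepoint_min = ent$timepoint_min,
                             cell_id = ent$cell), m)
      }
      for (kind in c("nucleolus", "nucleoplasm")) {
        msk <- if (kind == "nucleolus") nucleoli else nplasm
        m <- measureRegions(ent$stack, msk)
        if (nrow(m) > 0)
          measRows[[length(measRows) + 1L]] <- data.frame(
            experiment = 1L, cell = ent$cell,
            timepoint_min = ent$timepoint_min,
            compartment = if (kind == "nucleolus") "nucleolar"
                          else "nucleoplasmic",
            intensity = sum(m$integral))
      }
    }
  }
  if (length(unitRows) == 0)
    stop("detection returned zero units at every time point")
  unitTab <- do.call(rbind, unitRows)
  measTab <- do.call(rbind, measRows)

  tcUnit <- assembleTimecourse(measTab, "unit")
  tcNuc <- assembleTimecourse(measTab, "nucleolar")
  tcNp <- assembleTimecourse(measTab, "nucleoplasmic")
  pg <- fourierPeriodogram(tcNuc)
  dom <- dominantPeriod(pg)
  dt <- diff(timePoints(tcNuc))[1]
  counts <- vapply(split(unitTab, unitTab$timepoint_min), nrow,
                   integer(1)) / config@stacksPerTimepoint
  tt <- if (all(c(15, 30) %in% unitTab$timepoint_min))
    studentTTest(unitTab[[repCol]][unitTab$timepoint_min == 15],
                 unitTab[[repCol]][unitTab$timepoint_min == 30])
  else list(statistic = NA_real_, p.value = NA_real_)

  summary <- list(
    preset = config@preset, seed = config@seed,
    cv_nucleolar = coefficientOfVariation(tcNuc),
    cv_unit = coefficientOfVariation(tcUnit),
    dominant_period_min = dom,
    period_interval_min = periodInterval(dom, dt),
    correlation_nucleolus_nucleoplasm = compartmentCorrelation(tcNuc, tcNp),
    unit_fold_change_15_30 = if (all(c(15, 30) %in% timePoints(tcUnit)))
      foldChange(tcUnit, 15, 30) else NA_real_,
    unit_counts_per_cell = as.list(counts),
    t_test_15_vs_30 = tt)

  od <- config@outputDir
  writeUnits(unitTab, file.path(od, "units.csv"))
  utils::write.csv(do.call(rbind, regionRows),
                   file.path(od, "regions.csv"), row.names = FALSE)
  writeMeasurementTable(measTab, file.path(od, "measurements.csv"))
  summaryJSON(summary, file.path(od, "summary.json"))
  files <- c("units.csv", "regions.csv", "measurements.csv", "summary.json")
  summaryJSON(runManifest(config, files, od),
              file.path(od, "manifest.json"))
  invisible(summary)
}
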