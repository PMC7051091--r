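#' @include AllClasses.R
NULL

#' Read a multi-page TIFF as an ImageStack
#'
#' Slices are read in file order (z ascending). Integer TIFFs are returned
#' on their native integer scale.
#'
#' @param path TIFF file path.
#' @param zAspect ratio of z spacing to xy pixel size (default 3).
#' @return An \linkS4class{ImageStack}.
#' @export
readStack <- function(path, zAspect = 3) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  v <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) v[, , i] <- pages[[i]]
  imageStack(v, zAspect = zAspect)
}

#' Write an ImageStack as a multi-page 16-bit TIFF
#'
#' Voxel values are rounded and clamped to the unsigned 16-bit range, the
#' standard container for microscopy intensities; continuous simulated
#' values are therefore quantized to integers on disk.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  v <- voxels(stack)
  v <- pmin(pmax(round(v), 0), 65535)
  pages <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Write / read a measurement table as CSV
#'
#' Columns: \code{experiment}, \code{cell}, \code{timepoint_min},
#' \code{compartment}, \code{intensity}.
#'
#' @param table measurement \code{data.frame}.
#' @param path CSV file path.
#' @return \code{path} invisibly (write); the \code{data.frame} (read).
#' @export
writeMeasurementTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMeasurementTable
#' @export
readMeasurementTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a unit table as CSV
#'
#' One row per detected unit: 0-based \code{x}, \code{y}, \code{z},
#' \code{fwhm}, \code{chi2}, \code{background} and the integral-intensity
#' columns \code{I_1.0} ... \code{I_4.0}.
#'
#' @param units unit table from \code{\link{detectUnits}}, optionally with
#'   id columns prepended.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
writeUnits <- function(units, path) {
  utils::write.csv(units, path, row.names = FALSE)
  invisible(path)
}

## S4 config -> plain named list (for YAML round trips)
configAsList <- function(cfg) {
  nm <- slotNames(class(cfg))
  out <- lapply(nm, function(s) slot(cfg, s))
  names(out) <- nm
  out
}

#' Save or load module configurations as YAML
#'
#' @param cfg a \linkS4class{KineticsConfig}, \linkS4class{NucleoplasmConfig},
#'   \linkS4class{SceneConfig} or \linkS4class{DetectionParams}.
#' @param path YAML file path.
#' @param class name of the configuration class to reconstruct.
#' @return \code{path} invisibly (write); the config object (read).
#' @export
writeConfigYAML <- function(cfg, path) {
  yaml::write_yaml(c(list(class = class(cfg)[1]), configAsList(cfg)), path)
  invisible(path)
}

#' @rdname writeConfigYAML
#' @export
readConfigYAML <- function(path, class = NULL) {
  lst <- yaml::read_yaml(path)
  cls <- if (!is.null(class)) class else lst$class
  if (is.null(cls)) stop("YAML does not name a configuration class")
  lst$class <- NULL
  ctor <- switch(cls,
    KineticsConfig = kineticsConfig,
    NucleoplasmConfig = nucleoplasmConfig,
    SceneConfig = sceneConfig,
    DetectionParams = detectionParams,
    stop(sprintf("unknown configuration class '%s'", cls)))
  do.call(ctor, lst)
}
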