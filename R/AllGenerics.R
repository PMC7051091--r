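#' @include AllClasses.R
NULL

#' Extract voxel data from an ImageStack
#' @param x an \linkS4class{ImageStack}.
#' @return numeric array (y, x, z).
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname voxels
#' @export
setMethod("voxels", "ImageStack", function(x) x@voxels)

#' Ratio of z spacing to xy pixel size
#' @param x an \linkS4class{ImageStack}.
#' @return numeric scalar.
#' @export
setGeneric("zAspect", function(x) standardGeneric("zAspect"))

#' @rdname zAspect
#' @export
setMethod("zAspect", "ImageStack", function(x) x@zAspect)

#' @describeIn ImageStack-class stack dimensions (y, x, z).
#' @param x an \linkS4class{ImageStack}.
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@voxels))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d pixels, %d slices (z aspect %.2f)\n",
              d[1], d[2], d[3], object@zAspect))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(object@voxels), max(object@voxels)))
})

#' Time points of a TimeCourse or Periodogram grid
#' @param x a \linkS4class{TimeCourse}.
#' @return numeric vector of minutes.
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname timePoints
#' @export
setMethod("timePoints", "TimeCourse", function(x) x@timepoints)

#' Per-time-point means of a TimeCourse
#' @param x a \linkS4class{TimeCourse}.
#' @return numeric vector.
#' @export
setGeneric("tcMean", function(x) standardGeneric("tcMean"))

#' @rdname tcMean
#' @export
setMethod("tcMean", "TimeCourse", function(x) x@mean)

#' Per-time-point standard errors of a TimeCourse
#' @param x a \linkS4class{TimeCourse}.
#' @return numeric vector.
#' @export
setGeneric("tcSEM", function(x) standardGeneric("tcSEM"))

#' @rdname tcSEM
#' @export
setMethod("tcSEM", "TimeCourse", function(x) x@sem)

#' Cells per time point of a TimeCourse
#' @param x a \linkS4class{TimeCourse}.
#' @return integer vector.
#' @export
setGeneric("tcN", function(x) standardGeneric("tcN"))

#' @rdname tcN
#' @export
setMethod("tcN", "TimeCourse", function(x) x@n)

setMethod("show", "TimeCourse", function(object) {
  cat(sprintf("TimeCourse: %d points, %g-%g min (step %g)\n",
              length(object@timepoints), min(object@timepoints),
              max(object@timepoints), diff(object@timepoints)[1]))
  print(data.frame(timepoint_min = object@timepoints, mean = object@mean,
                   sem = object@sem, n = object@n), row.names = FALSE)
})

#' Period grid of a Periodogram
#' @param x a \linkS4class{Periodogram}.
#' @return numeric vector of minutes.
#' @export
setGeneric("periods", function(x) standardGeneric("periods"))

#' @rdname periods
#' @export
setMethod("periods", "Periodogram", function(x) x@periods)

#' Fourier amplitudes of a Periodogram
#' @param x a \linkS4class{Periodogram}.
#' @return numeric vector.
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname amplitudes
#' @export
setMethod("amplitudes", "Periodogram", function(x) x@amplitudes)

setMethod("show", "Periodogram", function(object) {
  imax <- which.max(object@amplitudes)
  cat(sprintf("Periodogram: %d periods, %g-%g min; peak %.3g at %g min\n",
              length(object@periods), min(object@periods),
              max(object@periods), object@amplitudes[imax],
              object@periods[imax]))
})

#' Label matrix of a RegionMask
#' @param x a \linkS4class{RegionMask}.
#' @return integer matrix; 0 is background.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname regionLabels
#' @export
setMethod("regionLabels", "RegionMask", function(x) x@labels)

#' Region kind of a RegionMask
#' @param x a \linkS4class{RegionMask}.
#' @return character scalar.
#' @export
setGeneric("regionKind", function(x) standardGeneric("regionKind"))

#' @rdname regionKind
#' @export
setMethod("regionKind", "RegionMask", function(x) x@kind)

setMethod("show", "RegionMask", function(object) {
  labs <- setdiff(unique(as.vector(object@labels)), 0L)
  cat(sprintf("RegionMask (%s): %d region(s), %d foreground pixels\n",
              object@kind, length(labs), sum(object@labels > 0)))
})

setMethod("show", "KineticsConfig", function(object) {
  cat(sprintf(paste0("KineticsConfig: T=%g min, first peak %g min, a0=%g, ",
                     "tau=%g min, B=%g, %s phases\n"),
              object@period, object@firstPeak, object@amplitude,
              object@damping, object@baseline, object@phaseMode))
  cat(sprintf("  %d experiments x %d cells at %d time points (%g-%g min)\n",
              object@experiments, object@cellsPerExperiment,
              length(object@timepoints), min(object@timepoints),
              max(object@timepoints)))
})
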