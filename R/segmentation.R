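#' @include AllClasses.R otsu.R
NULL

#' Segment cell nuclei on the maximum intensity projection
#'
#' Blurs the projection with a wide Gaussian, applies the Otsu threshold,
#' fills holes and labels connected components, discarding components
#' smaller than \code{minArea} pixels (debris). An image without any
#' surviving component yields an empty mask, not an error.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param blurSigma Gaussian sigma in pixels (default 9).
#' @param minArea minimum component area in pixels (default 500).
#' @return A \linkS4class{RegionMask} of kind \code{"nucleus"}.
#' @export
segmentNucleus <- function(stack, blurSigma = 9, minArea = 500) {
  stopifnot(is(stack, "ImageStack"))
  mip <- maxIntensityProjection(stack)
  empty <- function() new("RegionMask",
                          labels = matrix(0L, nrow(mip), ncol(mip)),
                          kind = "nucleus")
  if (diff(range(mip)) == 0) return(empty())
  bl <- EBImage::gblur(mip, sigma = blurSigma)
  thr <- otsuThreshold(bl)
  fg <- EBImage::fillHull(bl > thr)
  lab <- EBImage::bwlabel(fg)
  if (max(lab) == 0) return(empty())
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= minArea)
  if (length(keep) == 0) return(empty())
  relab <- integer(max(lab) + 1L)
  relab[keep + 1L] <- seq_along(keep)
  out <- matrix(relab[as.integer(lab) + 1L], nrow(mip), ncol(mip))
  new("RegionMask", labels = out, kind = "nucleus")
}

#' Segment nucleoli within a nucleus mask
#'
#' Second-stage Otsu restricted to the nucleus: the threshold is estimated
#' from the blurred projection inside an eroded core of the nucleus mask
#' (excluding the blurred boundary ramp, which would otherwise distort the
#' histogram) and applied to all nucleus pixels. A split whose contrast is
#' below \code{contrastSNR} robust SDs of the within-core intensities is
#' rejected as noise, yielding an empty mask - as does a constant intensity
#' inside the nucleus.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param nucleusMask a \linkS4class{RegionMask} of kind \code{"nucleus"};
#'   must be non-empty.
#' @param blurSigma Gaussian sigma in pixels for the projection blur
#'   (default 4).
#' @param contrastSNR minimum Otsu-split contrast in robust SDs (default 5).
#' @return A \linkS4class{RegionMask} of kind \code{"nucleolus"}, labels
#'   contained in the nucleus foreground.
#' @export
segmentNucleoli <- function(stack, nucleusMask, blurSigma = 4,
                            contrastSNR = 5) {
  stopifnot(is(stack, "ImageStack"), is(nucleusMask, "RegionMask"))
  nuc <- regionLabels(nucleusMask) > 0L
  if (!any(nuc)) stop("nucleus mask is empty")
  mip <- maxIntensityProjection(stack)
  empty <- function() new("RegionMask",
                          labels = matrix(0L, nrow(mip), ncol(mip)),
                          kind = "nucleolus")
  if (diff(range(mip[nuc])) == 0) return(empty())
  bl <- EBImage::gblur(mip, sigma = blurSigma)
  erodeR <- max(3L, ceiling(2 * blurSigma))
  core <- EBImage::erode(nuc, EBImage::makeBrush(2L * erodeR + 1L, "disc"))
  core <- core > 0
  if (!any(core)) core <- nuc
  vals <- bl[core]
  if (diff(range(vals)) == 0) return(empty())
  thr <- otsuThreshold(vals)
  bright <- nuc & bl > thr
  if (!any(bright)) return(empty())
  ## accept the split only if its contrast clearly exceeds the residual
  ## noise of the blurred image; smoothing white noise of SD s with a
  ## Gaussian of width sigma leaves SD s / (2 sqrt(pi) sigma). A MAD of the
  ## core values would not do here: both the nucleolar class and its blurred
  ## edge ramp can occupy a large share of the core and inflate it.
  noiseSD <- highPassNoiseSD(mip, nuc)
  spread <- noiseSD / (2 * sqrt(pi) * blurSigma)
  contrast <- stats::median(bl[bright]) - stats::median(vals[vals <= thr])
  if (spread > 0 && contrast < contrastSNR * spread) return(empty())
  ## the bright class must also be brighter in the unblurred projection;
  ## a blur-induced edge ramp alone (e.g. a uniform nucleus) is not one
  if (stats::median(mip[bright]) <= stats::median(mip[nuc & !bright]))
    return(empty())
  lab <- EBImage::bwlabel(EBImage::fillHull(bright))
  new("RegionMask", labels = matrix(as.integer(lab), nrow(mip), ncol(mip)),
      kind = "nucleolus")
}

#' Nucleoplasm mask as nucleus minus nucleoli
#'
#' @param nucleusMask a \linkS4class{RegionMask} of kind \code{"nucleus"}.
#' @param nucleoliMask a \linkS4class{RegionMask} of kind
#'   \code{"nucleolus"}.
#' @return A \linkS4class{RegionMask} of kind \code{"nucleoplasm"} keeping
#'   the nucleus labels outside all nucleoli.
#' @export
nucleoplasmMask <- function(nucleusMask, nucleoliMask) {
  stopifnot(is(nucleusMask, "RegionMask"), is(nucleoliMask, "RegionMask"))
  lab <- regionLabels(nucleusMask)
  lab[regionLabels(nucleoliMask) > 0L] <- 0L
  new("RegionMask", labels = lab, kind = "nucleoplasm")
}

#' Measure area and intensities of one labelled region
#'
#' Measurements are taken on the maximum intensity projection: the area in
#' pixels, the integral intensity (sum over the region) and the average
#' intensity (integral / area, exact by construction).
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param mask a \linkS4class{RegionMask}.
#' @param label region label to measure (must exist in the mask).
#' @return \code{data.frame} with columns \code{label}, \code{kind},
#'   \code{area_px}, \code{integral}, \code{average}.
#' @export
measureRegion <- function(stack, mask, label) {
  stopifnot(is(stack, "ImageStack"), is(mask, "RegionMask"))
  sel <- regionLabels(mask) == label
  if (label <= 0 || !any(sel))
    stop(sprintf("label %s not present in mask", label))
  mip <- maxIntensityProjection(stack)
  area <- sum(sel)
  integral <- sum(mip[sel])
  data.frame(label = as.integer(label), kind = regionKind(mask),
             area_px = area, integral = integral, average = integral / area)
}

#' Measure all regions of a mask
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param mask a \linkS4class{RegionMask}.
#' @return \code{data.frame} with one row per label (zero rows for an empty
#'   mask); columns as in \code{\link{measureRegion}}.
#' @export
measureRegions <- function(stack, mask) {
  labs <- sort(setdiff(unique(as.vector(regionLabels(mask))), 0L))
  if (length(labs) == 0)
    return(data.frame(label = integer(0), kind = character(0),
                      area_px = integer(0), integral = numeric(0),
                      average = numeric(0)))
  do.call(rbind, lapply(labs, function(l) measureRegion(stack, mask, l)))
}
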