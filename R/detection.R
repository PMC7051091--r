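#' @include AllClasses.R otsu.R segmentation.R
NULL

#' Maximum intensity projection
#'
#' Projects a 3D stack onto 2D by taking, for every (y, x) position, the
#' maximum intensity across all optical sections.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @return numeric matrix (y, x).
#' @export
maxIntensityProjection <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  v <- voxels(stack)
  d <- dim(v)
  if (d[3] == 1L) return(v[, , 1])
  apply(v, c(1, 2), max)
}

## robust pixel-noise SD of a 2D image from horizontal first differences,
## restricted to a mask; immune to smooth structure and sparse spots
highPassNoiseSD <- function(im, mask) {
  nx <- ncol(im)
  d <- im[, -1] - im[, -nx]
  m <- mask[, -1] & mask[, -nx]
  dv <- d[m]
  if (length(dv) < 10) dv <- as.vector(d)
  stats::mad(dv) / sqrt(2)
}

## integrals at several radii around one centre; background = median of the
## scaled annulus; per-voxel clamp at 0 keeps integrals monotone in radius
sphereIntegrals <- function(v, za, y0, x0, z0, radii, annIn, annOut) {
  d <- dim(v)
  rmax <- max(max(radii), annOut)
  ys <- max(1, floor(y0 - rmax)):min(d[1], ceiling(y0 + rmax))
  xs <- max(1, floor(x0 - rmax)):min(d[2], ceiling(x0 + rmax))
  zs <- max(1, floor(z0 - rmax / za)):min(d[3], ceiling(z0 + rmax / za))
  if (y0 < 1 - rmax || y0 > d[1] + rmax || x0 < 1 - rmax ||
      x0 > d[2] + rmax || z0 < 1 - rmax / za || z0 > d[3] + rmax / za)
    stop("integration sphere lies entirely outside the stack")
  g <- expand.grid(y = ys, x = xs, z = zs)
  dist <- sqrt((g$y - y0)^2 + (g$x - x0)^2 + (za * (g$z - z0))^2)
  vals <- v[cbind(g$y, g$x, g$z)]
  ann <- vals[dist > annIn & dist <= annOut]
  bg <- if (length(ann)) stats::median(ann) else 0
  ints <- vapply(radii, function(r) {
    sel <- dist <= r
    if (!any(sel)) return(NA_real_)
    sum(pmax(vals[sel] - bg, 0))
  }, numeric(1))
  list(integrals = ints, annulusBackground = bg)
}

#' Background-subtracted integral intensity in a sphere
#'
#' Sums \code{max(voxel - background, 0)} over all voxels whose scaled
#' distance \eqn{\sqrt{\Delta x^2 + \Delta y^2 + (z_{aspect}\Delta z)^2}}
#' from the centre is at most \code{radius}; the local background is the
#' median of the annulus between \code{annulusInner} and
#' \code{annulusOuter}. The per-voxel clamp makes the integral
#' non-decreasing in the radius.
#'
#' The sphere is centred laterally on the sub-voxel (x, y) position but
#' axially on the unit's optical section (z rounded to the nearest slice):
#' with anisotropic voxels a small sphere centred between two sections
#' would otherwise contain no voxel at all.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param center numeric (x, y, z), 0-based sub-voxel coordinates.
#' @param radius sphere radius in pixels (> 0).
#' @param params a \linkS4class{DetectionParams} (annulus radii).
#' @return numeric intensity.
#' @export
integralIntensity <- function(stack, center, radius,
                              params = detectionParams()) {
  stopifnot(is(stack, "ImageStack"), length(center) == 3)
  if (radius <= 0) stop("radius must be > 0")
  res <- sphereIntegrals(voxels(stack), zAspect(stack),
                         center[2] + 1, center[1] + 1,
                         round(center[3]) + 1,
                         radius, params@annulusInner, params@annulusOuter)
  if (is.na(res$integrals[1]))
    stop("integration sphere lies entirely outside the stack")
  res$integrals[1]
}

#' Sub-voxel Gaussian fit of one unit
#'
#' Fits an isotropic 2D Gaussian plus constant offset,
#' \eqn{A \exp(-((x-x_0)^2 + (y-y_0)^2) / 2\sigma^2) + c}, to the
#' \code{fitWindow} crop of the optical section on which the unit is
#' brightest (Levenberg-Marquardt). The size is reported as
#' \code{fwhm = 2 sqrt(2 ln 2) sigma} and the goodness of fit as the
#' scale-invariant \eqn{\chi^2 = \sum r^2 / \sum (model - c)^2}. The axial
#' sub-voxel position is refined by parabolic interpolation of the intensity
#' profile through the brightest section. If the fit fails or wanders out of
#' the crop the unit is kept with its integer seed position and flagged
#' (\code{converged = FALSE}).
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param seedPoint numeric (x, y, z), 0-based voxel coordinates of the
#'   candidate; z must be the brightest section (as found by
#'   \code{\link{detectUnits}}), or any section to fit on.
#' @param params a \linkS4class{DetectionParams}.
#' @return list with \code{center} (0-based x, y, z), \code{fwhm},
#'   \code{chi2}, \code{background} (fitted offset) and \code{converged}.
#' @export
fitUnit <- function(stack, seedPoint, params = detectionParams()) {
  stopifnot(is(stack, "ImageStack"), length(seedPoint) == 3)
  seedPoint <- unname(as.numeric(seedPoint))
  v <- voxels(stack)
  d <- dim(v)
  x <- round(seedPoint[1]) + 1L; y <- round(seedPoint[2]) + 1L
  z <- round(seedPoint[3]) + 1L
  if (x < 1 || x > d[2] || y < 1 || y > d[1] || z < 1 || z > d[3])
    stop("seedPoint outside stack bounds")
  h <- (params@fitWindow - 1L) %/% 2L
  ys <- max(1, y - h):min(d[1], y + h)
  xs <- max(1, x - h):min(d[2], x + h)
  crop <- v[ys, xs, z]
  df <- data.frame(val = as.vector(crop),
                   Y = rep(ys, length(xs)), X = rep(xs, each = length(ys)))
  bg0 <- stats::median(crop)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      val ~ A * exp(-((Y - y0)^2 + (X - x0)^2) / (2 * s^2)) + c0,
      data = df,
      start = list(A = max(crop) - bg0, y0 = y, x0 = x,
                   s = 1.3, c0 = bg0),
      control = minpack.lm::nls.lm.control(maxiter = 60)),
    error = function(e) NULL, warning = function(w) NULL)
  converged <- FALSE
  y0 <- y; x0 <- x; sig <- NA_real_; c0 <- bg0; chi2 <- NA_real_
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    if (all(is.finite(p)) && abs(p["y0"] - y) <= h + 1 &&
        abs(p["x0"] - x) <= h + 1 && abs(p["s"]) > 1e-3) {
      y0 <- unname(p["y0"]); x0 <- unname(p["x0"])
      sig <- abs(unname(p["s"])); c0 <- unname(p["c0"])
      pred <- stats::predict(fit)
      denom <- sum((pred - c0)^2)
      chi2 <- if (denom > 0) sum((df$val - pred)^2) / denom else Inf
      converged <- TRUE
    }
  }
  ## sub-voxel z: parabola through the axial profile at the seed pixel
  z0 <- z
  if (z > 1 && z < d[3]) {
    zp <- v[y, x, (z - 1):(z + 1)]
    den <- zp[1] - 2 * zp[2] + zp[3]
    if (is.finite(den) && den < 0) {
      dz <- 0.5 * (zp[1] - zp[3]) / den
      if (abs(dz) <= 1) z0 <- z + dz
    }
  }
  list(center = c(x0 - 1, y0 - 1, z0 - 1),
       fwhm = 2 * sqrt(2 * log(2)) * sig,
       chi2 = chi2, background = c0, converged = converged)
}

#' Detect and quantify FC/DFC units in a 3D stack
#'
#' Detection pipeline: (1) maximum intensity projection; (2) Gaussian blur
#' with \code{blurSigma}; (3) Otsu threshold of the blurred projection for
#' the coarse foreground, refined by a second within-foreground Otsu to the
#' nucleolar mask (see \code{\link{segmentNucleoli}}); (4) local maxima of
#' the \emph{unblurred} projection inside the mask, at least
#' \code{minSeparation} px apart (brighter maxima win; ties resolved toward
#' the smaller coordinates) and above the mask median by
#' \code{peakSNR} robust noise SDs; (5) for each candidate the brightest
#' optical section is located, the sub-voxel centre, FWHM and chi-square are
#' fitted (\code{\link{fitUnit}}), and background-subtracted integral
#' intensities are measured in spheres at all configured radii.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param params a \linkS4class{DetectionParams}.
#' @return \code{data.frame} with one row per unit, sorted by decreasing
#'   integral at \code{reportRadius}: 0-based \code{x}, \code{y}, \code{z},
#'   \code{fwhm}, \code{chi2}, \code{background}, \code{converged} and one
#'   column \code{I_<radius>} per configured radius. Zero rows when no
#'   foreground survives thresholding.
#' @examples
#' sc <- renderScene(sceneConfig(shape = c(128, 128, 9), unitsPerCell = 8,
#'                               nucleoliPerCell = 1, nucleoplasmicFoci = 20),
#'                   level = 100, seed = 1)
#' units <- detectUnits(sc$stack)
#' nrow(units)
#' @export
detectUnits <- function(stack, params = detectionParams()) {
  stopifnot(is(stack, "ImageStack"), is(params, "DetectionParams"))
  validObject(params)
  emptyRecords <- function() {
    cols <- c("x", "y", "z", "fwhm", "chi2", "background", "converged",
              intensityColumns(params))
    df <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(df) <- cols
    df
  }
  mip <- maxIntensityProjection(stack)
  if (diff(range(mip)) == 0) return(emptyRecords())
  nucleus <- segmentNucleus(stack, blurSigma = params@blurSigma,
                            minArea = 0)
  if (all(regionLabels(nucleus) == 0L)) return(emptyRecords())
  nucleoli <- segmentNucleoli(stack, nucleus, blurSigma = params@blurSigma,
                              contrastSNR = params@maskContrastSNR)
  mask <- regionLabels(nucleoli) > 0L
  if (!any(mask)) return(emptyRecords())

  noiseSD <- highPassNoiseSD(mip, regionLabels(nucleus) > 0L)
  floorVal <- stats::median(mip[mask]) + params@peakSNR * noiseSD

  ## non-maximum suppression on the raw projection
  brush <- EBImage::makeBrush(2 * ceiling(params@minSeparation) + 1, "disc")
  dil <- EBImage::dilate(mip, brush)
  cand <- which(mask & mip >= dil & mip > floorVal, arr.ind = TRUE)
  if (nrow(cand) == 0) return(emptyRecords())
  vv <- mip[cand]
  o <- order(-vv, cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i] || i == nrow(cand)) next
    j <- (i + 1):nrow(cand)
    close <- (cand[j, 1] - cand[i, 1])^2 + (cand[j, 2] - cand[i, 2])^2 <=
      params@minSeparation^2
    keep[j][close] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]

  v <- voxels(stack)
  za <- zAspect(stack)
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    yi <- cand[i, 1]; xi <- cand[i, 2]
    zi <- which.max(v[yi, xi, ])
    fit <- fitUnit(stack, c(xi - 1, yi - 1, zi - 1), params)
    ctr <- fit$center
    ints <- sphereIntegrals(v, za, ctr[2] + 1, ctr[1] + 1, zi,
                            params@radii, params@annulusInner,
                            params@annulusOuter)
    row <- data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
                      fwhm = fit$fwhm, chi2 = fit$chi2,
                      background = fit$background,
                      converged = fit$converged)
    ival <- as.list(ints$integrals)
    names(ival) <- intensityColumns(params)
    rows[[i]] <- cbind(row, as.data.frame(ival, check.names = FALSE))
  }
  rec <- do.call(rbind, rows)
  repCol <- reportColumn(params)
  rec[order(-rec[[repCol]]), , drop = FALSE]
}

## column names for the per-radius integrals, e.g. I_1.0 ... I_4.0
intensityColumns <- function(params) sprintf("I_%.1f", params@radii)
reportColumn <- function(params) sprintf("I_%.1f", params@reportRadius)

#' Count units above an intensity cutoff
#'
#' Number of detected units whose background-subtracted integral at the
#' report radius exceeds \code{minIntensity}.
#'
#' @param records unit table from \code{\link{detectUnits}}.
#' @param minIntensity intensity cutoff (default taken from \code{params}).
#' @param params a \linkS4class{DetectionParams} naming the report radius.
#' @return integer count.
#' @export
countUnits <- function(records, minIntensity = params@minIntensity,
                       params = detectionParams()) {
  if (is.null(records) || nrow(records) == 0) return(0L)
  sum(records[[reportColumn(params)]] > minIntensity)
}
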