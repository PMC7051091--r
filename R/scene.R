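#' @include AllClasses.R traces.R
NULL

## add a truncated 3D Gaussian spot (1-based continuous centre, y/x/z order)
addSpot <- function(img, y0, x0, z0, A, sxy, sz) {
  if (A == 0) return(img)
  d <- dim(img)
  ys <- max(1, floor(y0 - 5 * sxy)):min(d[1], ceiling(y0 + 5 * sxy))
  xs <- max(1, floor(x0 - 5 * sxy)):min(d[2], ceiling(x0 + 5 * sxy))
  zs <- max(1, floor(z0 - 4 * sz)):min(d[3], ceiling(z0 + 4 * sz))
  gy <- exp(-(ys - y0)^2 / (2 * sxy^2))
  gx <- exp(-(xs - x0)^2 / (2 * sxy^2))
  gz <- exp(-(zs - z0)^2 / (2 * sz^2))
  img[ys, xs, zs] <- img[ys, xs, zs] + A * outer(outer(gy, gx), gz)
  img
}

## scene geometry shared by rendering and tests
sceneGeometry <- function(scene) {
  ny <- scene@shape[1]; nx <- scene@shape[2]; nz <- scene@shape[3]
  rN <- scene@nucleolusRadius
  ay <- 0.36 * ny; ax <- 0.42 * nx
  if (min(ay, ax) < rN + 6 || nz < 5)
    stop("scene shape too small to contain a nucleus with its nucleoli")
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  zlo <- max(2L, ceiling(0.15 * nz)); zhi <- min(nz - 1L, floor(0.85 * nz))
  zc <- round((zlo + zhi) / 2)
  ## nucleoli spread along x, at least 2*rN + 8 apart
  k <- scene@nucleoliPerCell
  offs <- if (k == 1) 0 else seq(-0.45, 0.45, length.out = k) * ax
  if (k > 1 && min(diff(offs)) < 2 * rN + 8)
    stop("scene shape too small: nucleoli would touch")
  list(ny = ny, nx = nx, nz = nz, cy = cy, cx = cx, ay = ay, ax = ax,
       zlo = zlo, zhi = zhi, zc = zc, rN = rN,
       nucleoliCenters = lapply(offs, function(o) c(cy, cx + o)))
}

#' Render one synthetic confocal stack with ground truth
#'
#' Builds a 3D scene with one elliptical nucleus of uniform dim interior,
#' \code{nucleoliPerCell} disc-shaped nucleoli carrying a diffuse signal of
#' \code{nucleolarDiffuseFrac * level}, \code{unitsPerCell} bright 3D
#' Gaussian FC/DFC spots planted inside the nucleoli (mean amplitude
#' \code{level}, lognormal spread \code{unitBrightnessCV}, centres at least
#' \code{minUnitSeparation} px apart), and \code{nucleoplasmicFoci} dim foci
#' outside the nucleoli; then applies Poisson shot noise
#' (\code{poissonGain}; 0 disables) and Gaussian read noise
#' (\code{readNoiseSD}). Spot amplitudes are exactly proportional to
#' \code{level}, so paired renders at two levels have a true-amplitude
#' ratio equal to the level ratio.
#'
#' @param scene a \linkS4class{SceneConfig}.
#' @param level mean spot amplitude in intensity units (\code{>= 0});
#'   typically \code{baseline * meanKinetics(t)}.
#' @param seed single integer; renders are voxel-identical under the same
#'   seed.
#' @return A list with elements \code{stack} (an \linkS4class{ImageStack})
#'   and \code{truth}, a ground-truth \code{data.frame} with 0-based
#'   sub-voxel columns \code{x}, \code{y}, \code{z} plus \code{amplitude},
#'   \code{cell} and \code{timepoint_min} (\code{NA} for single scenes).
#' @examples
#' sc <- renderScene(sceneConfig(shape = c(128, 128, 9)), level = 100,
#'                   seed = 1)
#' sc$stack
#' nrow(sc$truth)
#' @export
renderScene <- function(scene = sceneConfig(), level, seed) {
  stopifnot(is(scene, "SceneConfig"))
  validObject(scene)
  if (length(level) != 1 || !is.finite(level) || level < 0)
    stop("level must be a single number >= 0")
  if (missing(seed) || length(seed) != 1 || seed != round(seed))
    stop("seed must be a single integer")
  set.seed(as.integer(seed))
  g <- sceneGeometry(scene)

  yy <- matrix(seq_len(g$ny), g$ny, g$nx)
  xx <- matrix(seq_len(g$nx), g$ny, g$nx, byrow = TRUE)
  nuc2d <- ((yy - g$cy) / g$ay)^2 + ((xx - g$cx) / g$ax)^2 <= 1
  img <- array(0, c(g$ny, g$nx, g$nz))
  for (z in g$zlo:g$zhi)
    img[, , z] <- scene@nucleusBase * nuc2d

  no2d <- matrix(FALSE, g$ny, g$nx)
  for (cc in g$nucleoliCenters)
    no2d <- no2d | ((yy - cc[1])^2 + (xx - cc[2])^2 <= g$rN^2)
  znlo <- max(g$zlo, g$zc - 3L); znhi <- min(g$zhi, g$zc + 3L)
  diffuse <- scene@nucleolarDiffuseFrac * level
  for (z in znlo:znhi)
    img[, , z] <- img[, , z] + diffuse * no2d

  ## plant unit positions inside the nucleoli with minimum separation
  k <- scene@nucleoliPerCell
  per <- rep(scene@unitsPerCell %/% k, k)
  per[seq_len(scene@unitsPerCell %% k)] <- per[seq_len(scene@unitsPerCell %% k)] + 1L
  pos <- matrix(numeric(0), 0, 3)
  for (i in seq_len(k)) {
    cc <- g$nucleoliCenters[[i]]
    got <- 0L; tries <- 0L
    while (got < per[i]) {
      tries <- tries + 1L
      if (tries > 20000L)
        stop("could not place units: too many per nucleolar area")
      th <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1)) * (g$rN - 4)
      p <- c(cc[1] + rr * sin(th), cc[2] + rr * cos(th),
             g$zc + stats::runif(1, -1.5, 1.5))
      if (nrow(pos) == 0 ||
          min(sqrt((pos[, 1] - p[1])^2 + (pos[, 2] - p[2])^2)) >=
            scene@minUnitSeparation) {
        pos <- rbind(pos, p); got <- got + 1L
      }
    }
  }
  amp <- level * rlnormCV(nrow(pos), scene@unitBrightnessCV)
  for (i in seq_len(nrow(pos)))
    img <- addSpot(img, pos[i, 1], pos[i, 2], pos[i, 3], amp[i],
                   scene@spotSigmaXY, scene@spotSigmaZ)

  ## dim nucleoplasmic foci
  npPix <- which(nuc2d & !no2d, arr.ind = TRUE)
  nf <- min(scene@nucleoplasmicFoci, nrow(npPix))
  if (nf > 0) {
    fi <- npPix[sample.int(nrow(npPix), nf), , drop = FALSE]
    fa <- scene@fociAmplitudeFrac * level * rlnormCV(nf, scene@unitBrightnessCV)
    fz <- g$zc + stats::runif(nf, -2, 2)
    for (i in seq_len(nf))
      img <- addSpot(img, fi[i, 1], fi[i, 2], fz[i], fa[i],
                     scene@spotSigmaXY, scene@spotSigmaZ)
  }

  if (scene@poissonGain > 0)
    img <- array(stats::rpois(length(img), img / scene@poissonGain) *
                   scene@poissonGain, dim(img))
  if (scene@readNoiseSD > 0)
    img <- img + array(stats::rnorm(length(img), 0, scene@readNoiseSD),
                       dim(img))
  img[img < 0] <- 0

  truth <- data.frame(cell = 1L, timepoint_min = NA_real_,
                      x = pos[, 2] - 1, y = pos[, 1] - 1, z = pos[, 3] - 1,
                      amplitude = amp)
  list(stack = imageStack(img, zAspect = scene@zAspect), truth = truth)
}

#' Render image stacks for every fixation time point
#'
#' End-to-end fixture for the image pipeline: for each configured time
#' point, renders \code{stacksPerTimepoint} independent cells whose mean
#' spot amplitude follows \code{baseline * meanKinetics(t)} (multiplied by
#' \code{coldFactor} when \code{cold = TRUE}).
#'
#' @param cfg a \linkS4class{KineticsConfig} supplying the time grid,
#'   baseline and kinetics.
#' @param scene a \linkS4class{SceneConfig}.
#' @param seed single integer root seed; per-stack seeds are derived from it.
#' @param stacksPerTimepoint number of cells rendered per time point.
#' @param cold logical; multiply all levels by \code{cfg@coldFactor}.
#' @return A list with one element per (time point, cell): each a list with
#'   \code{timepoint_min}, \code{cell}, \code{level}, \code{stack} and
#'   \code{truth} (ground truth with \code{timepoint_min} filled in).
#' @export
simulateTimecourseStacks <- function(cfg = kineticsConfig(),
                                     scene = sceneConfig(), seed,
                                     stacksPerTimepoint = 1L,
                                     cold = FALSE) {
  stopifnot(is(cfg, "KineticsConfig"), is(scene, "SceneConfig"))
  validObject(cfg)
  if (length(cfg@timepoints) == 0) stop("timepoints must be non-empty")
  if (missing(seed) || length(seed) != 1 || seed != round(seed))
    stop("seed must be a single integer")
  fac <- if (cold) cfg@coldFactor else 1
  out <- list()
  idx <- 0L
  for (j in seq_along(cfg@timepoints)) {
    t <- cfg@timepoints[j]
    lev <- fac * cfg@baseline * meanKinetics(t, cfg)
    for (cell in seq_len(stacksPerTimepoint)) {
      idx <- idx + 1L
      sc <- renderScene(scene, lev, subSeed(seed, 1000L * j + cell))
      sc$truth$cell <- cell
      sc$truth$timepoint_min <- t
      out[[idx]] <- list(timepoint_min = t, cell = cell, level = lev,
                         stack = sc$stack, truth = sc$truth)
    }
  }
  out
}

## deterministic sub-seed derivation (kept below 2^31)
subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %%
               2147483647)
}
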