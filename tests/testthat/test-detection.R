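test_that("maximum intensity projection picks the per-pixel maximum", {
  v <- array(0, c(4, 5, 3))
  v[2, 3, 2] <- 100
  st <- imageStack(v)
  mip <- maxIntensityProjection(st)
  expect_equal(dim(mip), c(4, 5))
  expect_equal(sum(mip > 0), 1)
  expect_equal(mip[2, 3], 100)
  expect_equal(max(mip), max(v))

  one <- imageStack(matrix(runif(16), 4, 4))
  expect_equal(maxIntensityProjection(one), voxels(one)[, , 1])
})

test_that("noise-free scenes are detected exactly with sub-pixel accuracy", {
  scn <- noiseFreeScene()
  sc <- renderScene(scn, level = 100, seed = 21)
  units <- detectUnits(sc$stack)
  expect_equal(nrow(units), scn@unitsPerCell)
  m <- matchUnits(units, sc$truth, radius = 1)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_true(all(m$dist <= 1))
})

test_that("fitted FWHM recovers an isolated spot width within 2 percent", {
  # isolated noise-free spot at sub-pixel offsets: closed-form FWHM
  expected <- 2 * sqrt(2 * log(2)) * 1.3
  for (off in list(c(0, 0), c(0.3, -0.4), c(-0.5, 0.2))) {
    v <- array(12, c(31, 31, 5))
    for (dy in -7:7) for (dx in -7:7)
      v[16 + dy, 16 + dx, 3] <- 12 +
        80 * exp(-((dy - off[1])^2 + (dx - off[2])^2) / (2 * 1.3^2))
    f <- fitUnit(imageStack(v), c(15, 15, 2))
    expect_true(f$converged)
    expect_lt(abs(f$fwhm - expected) / expected, 0.02)
    expect_equal(f$center[1:2], c(15 + off[2], 15 + off[1]),
                 tolerance = 1e-3)
    expect_lt(f$chi2, 1e-10)
  }
})

test_that("fitted widths on a rendered noise-free scene stay accurate", {
  # dim nucleoplasmic foci can graze a fit window, so the bound is looser
  # than for isolated spots
  scn <- noiseFreeScene()
  sc <- renderScene(scn, level = 100, seed = 22)
  units <- detectUnits(sc$stack)
  expected <- 2 * sqrt(2 * log(2)) * scn@spotSigmaXY
  expect_true(all(abs(units$fwhm - expected) / expected < 0.05))
  expect_true(all(units$chi2 < 0.05))
  expect_true(all(units$converged))
})

test_that("doubling the amplitude leaves centre and width unchanged", {
  v <- array(10, c(41, 41, 7))
  g <- function(A) {
    w <- v
    for (dy in -6:6) for (dx in -6:6)
      w[21 + dy, 21 + dx, 4] <- 10 + A * exp(-(dx^2 + dy^2) / (2 * 1.3^2))
    imageStack(w)
  }
  f1 <- fitUnit(g(100), c(20, 20, 3))
  f2 <- fitUnit(g(200), c(20, 20, 3))
  expect_equal(f1$center[1:2], f2$center[1:2], tolerance = 1e-6)
  expect_equal(f1$fwhm, f2$fwhm, tolerance = 1e-6)
  expect_equal(f1$background, 10, tolerance = 1e-6)
  expect_lt(f1$chi2, 1e-10)
})

test_that("integral intensities are monotone in the radius", {
  sc <- renderScene(smallScene(), level = 120, seed = 23)
  units <- detectUnits(sc$stack)
  expect_gt(nrow(units), 0)
  cols <- sprintf("I_%.1f", c(1, 1.5, 2, 2.5, 3, 3.5, 4))
  im <- as.matrix(units[, cols])
  expect_true(all(diff(t(im)) >= -1e-9))
})

test_that("a single bright voxel integrates to its own value", {
  v <- array(0, c(15, 15, 7))
  v[8, 8, 4] <- 250
  st <- imageStack(v, zAspect = 3)
  # radius 1.5 with z aspect 3: only the central slice contributes
  expect_equal(integralIntensity(st, c(7, 7, 3), 1.5), 250)
  expect_error(integralIntensity(st, c(7, 7, 3), -1), "radius")
  expect_error(integralIntensity(st, c(500, 500, 3), 1.5), "outside")
})

test_that("noise-free integrals match the analytic per-slice Gaussian mass", {
  # oracle: analytic 2D Gaussian mass within the sphere's xy radius on each
  # optical section, evaluated at the slice positions the instrument samples
  scn <- noiseFreeScene(nucleolarDiffuseFrac = 0, nucleoplasmicFoci = 0,
                        unitsPerCell = 4)
  sc <- renderScene(scn, level = 200, seed = 24)
  units <- detectUnits(sc$stack)
  expect_equal(nrow(units), 4)
  m <- matchUnits(units, sc$truth, radius = 1)
  expect_equal(m$recall, 1)
  r <- 4; za <- scn@zAspect
  sxy <- scn@spotSigmaXY; sz <- scn@spotSigmaZ
  for (i in seq_len(nrow(units))) {
    j <- which.min((sc$truth$x - units$x[i])^2 + (sc$truth$y - units$y[i])^2)
    A <- sc$truth$amplitude[j]
    # the sphere is centred on the unit's optical section; slice weights
    # follow the true axial Gaussian of the planted spot
    zc <- round(units$z[i])
    mass <- 0
    for (z in (zc - floor(r / za)):(zc + floor(r / za))) {
      rxy2 <- r^2 - (za * (z - zc))^2
      if (rxy2 > 0)
        mass <- mass + A * exp(-(z - sc$truth$z[j])^2 / (2 * sz^2)) *
          2 * pi * sxy^2 * (1 - exp(-rxy2 / (2 * sxy^2)))
    }
    expect_equal(units$I_4.0[i], mass, tolerance = 0.05)
  }
})

test_that("detection is equivariant under whole-voxel translations", {
  scn <- noiseFreeScene(unitsPerCell = 6)
  sc <- renderScene(scn, level = 150, seed = 25)
  v <- voxels(sc$stack)
  shifted <- array(0, dim(v))
  shifted[4:128, 7:128, ] <- v[1:125, 1:122, ]
  u0 <- detectUnits(sc$stack)
  u1 <- detectUnits(imageStack(shifted, zAspect = zAspect(sc$stack)))
  expect_equal(nrow(u1), nrow(u0))
  o0 <- order(u0$x, u0$y); o1 <- order(u1$x, u1$y)
  expect_equal(u1$x[o1] - u0$x[o0], rep(6, nrow(u0)), tolerance = 1e-3)
  expect_equal(u1$y[o1] - u0$y[o0], rep(3, nrow(u0)), tolerance = 1e-3)
})

test_that("blank stacks yield at most a couple of spurious units", {
  sc <- renderScene(smallScene(), level = 0, seed = 26)
  expect_lte(nrow(detectUnits(sc$stack)), 2)
  # fully empty stack: no foreground at all
  expect_equal(nrow(detectUnits(imageStack(array(0, c(64, 64, 5))))), 0)
})

test_that("unit counting respects the intensity cutoff", {
  expect_equal(countUnits(NULL), 0L)
  sc <- renderScene(smallScene(), level = 100, seed = 27)
  units <- detectUnits(sc$stack)
  expect_equal(countUnits(units, minIntensity = 0), nrow(units))
  expect_equal(countUnits(units, minIntensity = Inf), 0L)
})

test_that("records come sorted by decreasing report-radius integral", {
  sc <- renderScene(smallScene(), level = 100, seed = 28)
  units <- detectUnits(sc$stack)
  expect_true(all(diff(units$I_1.5) <= 1e-9))
})
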