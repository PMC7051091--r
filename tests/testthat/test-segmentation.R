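test_that("nucleus segmentation recovers the planted ellipse area", {
  # default-size noise-free scene: the sigma = 9 blur erodes a convex
  # contour by roughly sigma^2 x curvature, small relative to this nucleus
  scn <- sceneConfig(poissonGain = 0, readNoiseSD = 0)
  sc <- renderScene(scn, level = 100, seed = 31)
  mask <- segmentNucleus(sc$stack)
  expect_s4_class(mask, "RegionMask")
  expect_equal(regionKind(mask), "nucleus")
  labs <- setdiff(unique(as.vector(regionLabels(mask))), 0L)
  expect_length(labs, 1)
  planted <- pi * (0.36 * 256) * (0.42 * 256)
  expect_equal(sum(regionLabels(mask) > 0), planted, tolerance = 0.1)
})

test_that("blank images give an empty nucleus mask, not an error", {
  st <- imageStack(array(0, c(64, 64, 3)))
  mask <- segmentNucleus(st)
  expect_true(all(regionLabels(mask) == 0L))
})

test_that("two disjoint nuclei receive two labels", {
  im <- matrix(0, 200, 200)
  yy <- row(im); xx <- col(im)
  im[(yy - 50)^2 + (xx - 50)^2 <= 30^2] <- 100
  im[(yy - 150)^2 + (xx - 150)^2 <= 30^2] <- 100
  im <- im + matrix(rnorm(length(im), 0, 2), 200, 200)
  mask <- segmentNucleus(imageStack(im), minArea = 500)
  labs <- setdiff(unique(as.vector(regionLabels(mask))), 0L)
  expect_length(labs, 2)
})

test_that("nucleoli are segmented inside the nucleus with good overlap", {
  scn <- sceneConfig(shape = c(160, 160, 11), nucleoliPerCell = 2,
                     unitsPerCell = 12, nucleoplasmicFoci = 30)
  sc <- renderScene(scn, level = 100, seed = 32)
  nucleus <- segmentNucleus(sc$stack)
  nucleoli <- segmentNucleoli(sc$stack, nucleus)
  labs <- setdiff(unique(as.vector(regionLabels(nucleoli))), 0L)
  expect_length(labs, 2)
  # containment in the nucleus
  expect_true(all(regionLabels(nucleus)[regionLabels(nucleoli) > 0] > 0))
  # IoU of each nucleolar label against the nearest planted disc >= 0.5
  g <- matrix(0L, 160, 160)
  yy <- row(g); xx <- col(g)
  cy <- (160 + 1) / 2; cx <- (160 + 1) / 2
  offs <- c(-0.45, 0.45) * 0.42 * 160
  for (k in 1:2)
    g[(yy - cy)^2 + (xx - (cx + offs[k]))^2 <= scn@nucleolusRadius^2] <- k
  for (l in labs) {
    seg <- regionLabels(nucleoli) == l
    ious <- vapply(1:2, function(k) {
      truth <- g == k
      sum(seg & truth) / sum(seg | truth)
    }, numeric(1))
    expect_gte(max(ious), 0.5)
  }
})

test_that("segmenting nucleoli demands a non-empty nucleus mask", {
  st <- imageStack(array(runif(64 * 64 * 3), c(64, 64, 3)))
  empty <- new("RegionMask", labels = matrix(0L, 64, 64), kind = "nucleus")
  expect_error(segmentNucleoli(st, empty), "empty")
})

test_that("constant intensity inside the nucleus yields no nucleoli", {
  v <- array(0, c(80, 80, 3))
  yy <- row(v[, , 1]); xx <- col(v[, , 1])
  inside <- (yy - 40)^2 + (xx - 40)^2 <= 30^2
  for (z in 1:3) v[, , z][inside] <- 50
  st <- imageStack(v)
  nucleus <- segmentNucleus(st)
  nucleoli <- segmentNucleoli(st, nucleus)
  expect_true(all(regionLabels(nucleoli) == 0L))
})

test_that("region measurements are exact on uniform regions and additive", {
  im <- matrix(5, 60, 60)
  im[10:29, 10:29] <- 20   # 400-px square region
  st <- imageStack(im)
  lab <- matrix(0L, 60, 60)
  lab[10:29, 10:29] <- 1L
  mask <- new("RegionMask", labels = lab, kind = "nucleolus")
  m <- measureRegion(st, mask, 1)
  expect_equal(m$area_px, 400)
  expect_equal(m$integral, 20 * 400)
  expect_equal(m$average, 20)
  expect_error(measureRegion(st, mask, 99), "not present")

  # splitting a region preserves the total integral
  lab2 <- lab
  lab2[10:29, 20:29] <- 2L
  mask2 <- new("RegionMask", labels = lab2, kind = "nucleolus")
  m2 <- measureRegions(st, mask2)
  expect_equal(sum(m2$integral), m$integral)
})

test_that("nucleus integral equals nucleoli plus nucleoplasm", {
  sc <- renderScene(smallScene(), level = 100, seed = 33)
  nucleus <- segmentNucleus(sc$stack)
  nucleoli <- segmentNucleoli(sc$stack, nucleus)
  nplasm <- nucleoplasmMask(nucleus, nucleoli)
  iN <- sum(measureRegions(sc$stack, nucleus)$integral)
  iNo <- sum(measureRegions(sc$stack, nucleoli)$integral)
  iNp <- sum(measureRegions(sc$stack, nplasm)$integral)
  expect_equal(iN, iNo + iNp, tolerance = 1e-12)
  # masks are disjoint
  expect_equal(sum(regionLabels(nucleoli) > 0 & regionLabels(nplasm) > 0), 0)
  # average = integral / area exactly, and nucleoli brighter on average
  mAll <- rbind(measureRegions(sc$stack, nucleus),
                measureRegions(sc$stack, nucleoli),
                measureRegions(sc$stack, nplasm))
  expect_equal(mAll$average, mAll$integral / mAll$area_px)
  avgNo <- iNo / sum(regionLabels(nucleoli) > 0)
  avgNp <- iNp / sum(regionLabels(nplasm) > 0)
  expect_gt(avgNo, avgNp)
})

test_that("intensity rescaling scales integrals but not areas", {
  sc <- renderScene(smallScene(), level = 100, seed = 34)
  st2 <- imageStack(voxels(sc$stack) * 3, zAspect = zAspect(sc$stack))
  nucleus <- segmentNucleus(sc$stack)
  m1 <- measureRegions(sc$stack, nucleus)
  m2 <- measureRegions(st2, nucleus)
  expect_equal(m2$area_px, m1$area_px)
  expect_equal(m2$integral, 3 * m1$integral)
  expect_equal(m2$average, 3 * m1$average)
})
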