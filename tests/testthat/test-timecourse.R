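makeTable <- function(values, timepoints = seq(15, 150, 15)) {
  do.call(rbind, lapply(seq_along(timepoints), function(j) {
    data.frame(experiment = 1L, cell = seq_along(values[[j]]),
               timepoint_min = timepoints[j], compartment = "nucleolar",
               intensity = values[[j]])
  }))
}

test_that("time-course assembly computes mean, SEM and n per point", {
  tab <- makeTable(rep(list(c(1, 3)), 10))
  tc <- assembleTimecourse(tab, "nucleolar")
  expect_equal(tcMean(tc), rep(2, 10))
  expect_equal(tcSEM(tc), rep(1, 10))   # sd = sqrt(2), n = 2
  expect_equal(tcN(tc), rep(2L, 10))

  const <- makeTable(rep(list(rep(7, 5)), 10))
  tcC <- assembleTimecourse(const, "nucleolar")
  expect_equal(tcMean(tcC), rep(7, 10))
  expect_equal(tcSEM(tcC), rep(0, 10))

  bad <- makeTable(c(rep(list(c(1, 2)), 9), list(5)))
  expect_error(assembleTimecourse(bad, "nucleolar"), "at least 2 cells")
  expect_error(assembleTimecourse(tab, "nucleoplasmic"), "no rows")
})

test_that("assembled means agree with the generator expectation", {
  tab <- simulateTraces(seed = 2)
  tc <- assembleTimecourse(tab, "nucleolar")
  expected <- 100 * meanKinetics(timePoints(tc))
  tol <- 3 * sqrt(tcSEM(tc)^2 + (0.07 * expected)^2)
  expect_true(all(abs(tcMean(tc) - expected) <= tol))
})

test_that("CV is zero for constant traces and scale invariant", {
  const <- timeCourse(seq(15, 150, 15), rep(5, 10))
  expect_equal(coefficientOfVariation(const), 0)
  tc <- noiselessTrace()
  expect_equal(coefficientOfVariation(tc),
               coefficientOfVariation(tcMean(tc) * 17))
  expect_error(coefficientOfVariation(rep(0, 5)), "positive")
})

test_that("the noiseless default trace has CV ~ 0.267", {
  # closed-form oracle evaluated independently of the package kinetics
  tt <- seq(15, 150, 15)
  a <- ifelse(tt <= 30, 0.5, 0.5 * exp(-(tt - 30) / 75))
  m <- pmin(tt / 30, 1) * (1 + a * cos(2 * pi * (tt - 30) / 60))
  oracle <- sqrt(mean((m - mean(m))^2)) / mean(m)
  expect_equal(oracle, 0.2675549, tolerance = 1e-6)
  expect_equal(coefficientOfVariation(noiselessTrace()), oracle,
               tolerance = 1e-12)
})

test_that("the periodogram localizes pure cosines on the period grid", {
  tt <- seq(15, 150, 15)
  for (P in c(50, 60, 75)) {
    tc <- timeCourse(tt, 100 + 20 * cos(2 * pi * tt / P))
    pg <- fourierPeriodogram(tc)
    expect_lte(abs(dominantPeriod(pg) - P), 1)
  }
})

test_that("periodograms are mean-subtracted and shift invariant", {
  tt <- seq(15, 150, 15)
  const <- timeCourse(tt, rep(4, 10))
  pg <- fourierPeriodogram(const)
  expect_true(all(amplitudes(pg) < 1e-10))
  expect_error(dominantPeriod(pg), "zero")

  x <- 100 * meanKinetics(tt)
  a1 <- amplitudes(fourierPeriodogram(timeCourse(tt, x)))
  a2 <- amplitudes(fourierPeriodogram(timeCourse(tt, x + 123.4)))
  expect_equal(a1, a2, tolerance = 1e-9)
  expect_error(fourierPeriodogram(timeCourse(tt, x), periods = c(-5, 10)),
               "> 0")
})

test_that("the noiseless default trace peaks near one hour", {
  pg <- fourierPeriodogram(noiselessTrace())
  dom <- dominantPeriod(pg)
  expect_lte(abs(dom - 60), 5)
  # the one-hour amplitude dwarfs the long-period competitors
  amp <- amplitudes(pg)[match(c(60, 75, 150), periods(pg))] / 100
  expect_equal(amp[1], 1.41, tolerance = 0.01)
  expect_true(all(amp[2:3] <= 0.58))
})

test_that("period uncertainty spans one sampling interval each way", {
  expect_equal(periodInterval(60, 15), c(45, 75))
  expect_equal(periodInterval(100, 15), c(85, 115))
  expect_equal(periodInterval(60, 1e-9), c(60, 60), tolerance = 1e-6)
  expect_error(periodInterval(10, 15), "exceed")
  expect_error(periodInterval(60, 0), "dt")
})

test_that("compartment correlation behaves like Pearson r", {
  tc <- noiselessTrace()
  expect_equal(compartmentCorrelation(tc, tc), 1)
  reflected <- timeCourse(timePoints(tc), 2 * mean(tcMean(tc)) - tcMean(tc))
  expect_equal(compartmentCorrelation(tc, reflected), -1)
  # invariance under positive affine maps
  affine <- timeCourse(timePoints(tc), 3 * tcMean(tc) + 7)
  expect_equal(compartmentCorrelation(tc, affine), 1)
  const <- timeCourse(timePoints(tc), rep(1, 10))
  expect_error(compartmentCorrelation(tc, const), "variance")
  other <- timeCourse(seq(10, 145, 15), tcMean(tc))
  expect_error(compartmentCorrelation(tc, other), "identical")
})

test_that("fold changes come from the population means", {
  tc <- noiselessTrace()
  expect_equal(foldChange(tc, 15, 30), 3.0)
  expect_equal(foldChange(tc, 45, 45), 1.0)
  scaled <- timeCourse(timePoints(tc), tcMean(tc) * 9)
  expect_equal(foldChange(scaled, 15, 30), 3.0)
  expect_error(foldChange(tc, 15, 37), "present")
})

test_that("the pooled t-test handles identical and degenerate groups", {
  r <- studentTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  expect_equal(studentTTest(rep(2, 4), rep(2, 5)),
               list(statistic = 0, p.value = 1))
  expect_error(studentTTest(rep(1, 3), rep(2, 3)), "zero pooled variance")
  expect_error(studentTTest(1, c(1, 2)), "at least 2")
  # agreement with the classical pooled-variance formula
  set.seed(9)
  a <- rnorm(20, 10, 2); b <- rnorm(25, 12, 2)
  r2 <- studentTTest(a, b)
  sp <- sqrt(((19 * var(a) + 24 * var(b)) / 43))
  tman <- (mean(a) - mean(b)) / (sp * sqrt(1 / 20 + 1 / 25))
  expect_equal(r2$statistic, tman, tolerance = 1e-12)
  expect_equal(r2$p.value, 2 * pt(-abs(tman), 43), tolerance = 1e-12)
})
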