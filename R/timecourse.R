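#' @include AllClasses.R
NULL

#' Assemble per-time-point population statistics
#'
#' Pools all cells of all experiments measured at each fixation time point
#' and computes the mean, the standard error of the mean (SD/sqrt(n)) and
#' the cell count.
#'
#' @param table measurement table as returned by
#'   \code{\link{simulateTraces}} (columns \code{experiment}, \code{cell},
#'   \code{timepoint_min}, \code{compartment}, \code{intensity}).
#' @param compartment which compartment to assemble
#'   (\code{"nucleolar"}, \code{"nucleoplasmic"} or any value present in
#'   the table, e.g. \code{"unit"}).
#' @return A \linkS4class{TimeCourse}.
#' @export
assembleTimecourse <- function(table, compartment = c("nucleolar",
                                                      "nucleoplasmic")) {
  compartment <- compartment[1]
  need <- c("timepoint_min", "compartment", "intensity")
  if (!all(need %in% names(table)))
    stop("table must have columns timepoint_min, compartment, intensity")
  sub <- table[table$compartment == compartment, , drop = FALSE]
  if (nrow(sub) == 0)
    stop(sprintf("no rows for compartment '%s'", compartment))
  tps <- sort(unique(sub$timepoint_min))
  ns <- tapply(sub$intensity, sub$timepoint_min, length)[as.character(tps)]
  if (any(ns < 2))
    stop("every time point needs at least 2 cells")
  mns <- tapply(sub$intensity, sub$timepoint_min, mean)[as.character(tps)]
  sds <- tapply(sub$intensity, sub$timepoint_min, stats::sd)[as.character(tps)]
  timeCourse(tps, as.numeric(mns), as.numeric(sds / sqrt(ns)),
             as.integer(ns))
}

#' Coefficient of variation of a mean trace
#'
#' The population SD (divisor N) of the per-time-point means divided by
#' their grand mean - the fluctuation-strength statistic of the time
#' course. Scale-invariant: multiplying all intensities by a positive
#' constant leaves it unchanged.
#'
#' @param tc a \linkS4class{TimeCourse} or a numeric vector of means.
#' @return dimensionless CV.
#' @export
coefficientOfVariation <- function(tc) {
  x <- if (is(tc, "TimeCourse")) tcMean(tc) else as.numeric(tc)
  m <- mean(x)
  if (!is.finite(m) || m <= 0)
    stop("grand mean must be positive")
  sqrt(mean((x - m)^2)) / m
}

#' Fourier-amplitude periodogram on a period grid
#'
#' Direct complex sum evaluated per candidate period T:
#' \deqn{A(T) = \left| \sum_j (x_j - \bar x)\, e^{-2\pi i\, t_j / T} \right|}
#' with mandatory mean subtraction (so constant traces give identically
#' zero amplitudes and additive offsets do not change the result). The
#' period grid is dense rather than tied to the DFT frequencies of the
#' short series, because the sampling (10 points, 15 min apart) makes the
#' canonical DFT grid far too coarse to localize a period near one hour.
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @param periods candidate periods in minutes; default
#'   \code{seq(2 * dt, max(timepoints), by = 1)} from twice the sampling
#'   interval (Nyquist) up to the span end.
#' @return A \linkS4class{Periodogram}.
#' @export
fourierPeriodogram <- function(tc, periods = NULL) {
  stopifnot(is(tc, "TimeCourse"))
  t <- timePoints(tc)
  x <- tcMean(tc)
  if (length(t) < 3) stop("need at least 3 time points")
  if (is.null(periods)) {
    dt <- diff(t)[1]
    periods <- seq(2 * dt, max(t), by = 1)
  }
  if (any(periods <= 0)) stop("periods must be > 0")
  xc <- x - mean(x)
  amps <- vapply(periods,
                 function(P) Mod(sum(xc * exp(-2i * pi * t / P))),
                 numeric(1))
  new("Periodogram", periods = as.numeric(periods), amplitudes = amps)
}

#' Dominant period of a periodogram
#'
#' Period of maximal Fourier amplitude; ties are broken toward the smaller
#' period. All-zero amplitudes (a constant trace) have no peak and raise an
#' error.
#'
#' @param pg a \linkS4class{Periodogram}.
#' @return dominant period in minutes.
#' @export
dominantPeriod <- function(pg) {
  stopifnot(is(pg, "Periodogram"))
  a <- amplitudes(pg)
  if (length(a) == 0) stop("empty periodogram")
  if (max(a) <= .Machine$double.eps * length(a))
    stop("all amplitudes are zero: no dominant peak")
  periods(pg)[which.max(a)]
}

#' Sampling-interval uncertainty of a recovered period
#'
#' With measurements \code{dt} minutes apart, a recovered period P is only
#' localized to within one sampling interval on either side; the interval
#' is \code{(P - dt, P + dt)}.
#'
#' @param P dominant period in minutes (must exceed \code{dt}).
#' @param dt sampling interval in minutes (> 0).
#' @return numeric length-2 vector (low, high).
#' @examples
#' periodInterval(60, 15)   # 45 75
#' @export
periodInterval <- function(P, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (P <= dt) stop("P must exceed the sampling interval")
  c(P - dt, P + dt)
}

#' Pearson correlation between two compartment traces
#'
#' @param tc1,tc2 \linkS4class{TimeCourse} objects on identical time points.
#' @return Pearson r of the two mean vectors.
#' @export
compartmentCorrelation <- function(tc1, tc2) {
  stopifnot(is(tc1, "TimeCourse"), is(tc2, "TimeCourse"))
  if (!isTRUE(all.equal(timePoints(tc1), timePoints(tc2))))
    stop("time points must be identical")
  x <- tcMean(tc1); y <- tcMean(tc2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y)
}

#' Fold change between two time points
#'
#' Ratio \code{mean(tB) / mean(tA)} of the population means, e.g. the
#' increase of the transcription signal from the 15 min trough to the
#' 30 min peak.
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @param tA,tB time points in minutes, both present in \code{tc}.
#' @return dimensionless fold change.
#' @export
foldChange <- function(tc, tA, tB) {
  stopifnot(is(tc, "TimeCourse"))
  t <- timePoints(tc)
  iA <- which(abs(t - tA) < 1e-9)
  iB <- which(abs(t - tB) < 1e-9)
  if (length(iA) != 1 || length(iB) != 1)
    stop("both time points must be present in the time course")
  mA <- tcMean(tc)[iA]
  if (mA <= 0) stop("mean at tA must be positive")
  tcMean(tc)[iB] / mA
}

#' Two-sample Student's t-test with pooled variance
#'
#' Classical equal-variance two-sample t statistic with a two-sided p-value.
#' Degenerate groups with zero pooled variance return \code{t = 0, p = 1}
#' when the means are equal and raise an error otherwise.
#'
#' @param groupA,groupB numeric vectors, each with at least 2 values.
#' @return list with \code{statistic} (t) and \code{p.value}.
#' @export
studentTTest <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(statistic = 0, p.value = 1))
    stop("zero pooled variance with unequal means: t undefined")
  }
  ht <- stats::t.test(groupA, groupB, var.equal = TRUE,
                      alternative = "two.sided")
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
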