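#' @include AllClasses.R
NULL

#' Otsu threshold over a 256-bin histogram
#'
#' Automatic threshold selection maximizing the inter-class variance
#' \eqn{w_1 w_2 (\mu_1 - \mu_2)^2} over a 256-bin histogram spanning the
#' image range. The returned threshold is the upper edge of the last bin of
#' the lower class, so \code{image > threshold} is the foreground. Because
#' the histogram is built on the data range, adding a constant to the image
#' shifts the threshold by exactly that constant.
#'
#' @param image numeric matrix or vector with at least two distinct values.
#' @param levels number of histogram bins (default 256).
#' @return numeric threshold.
#' @examples
#' otsuThreshold(c(rep(0, 50), rep(10, 50)))   # strictly between 0 and 10
#' @export
otsuThreshold <- function(image, levels = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) < 2) stop("image must contain at least two finite values")
  r <- range(v)
  if (r[1] == r[2])
    stop("constant image: no threshold exists")
  edges <- seq(r[1], r[2], length.out = levels + 1L)
  ## right-closed bins; clamp the minimum into bin 1
  bin <- pmin(pmax(ceiling((v - r[1]) / (r[2] - r[1]) * levels), 1L), levels)
  h <- tabulate(bin, nbins = levels)
  p <- h / sum(h)
  ## bin values are the means of the data falling in each bin (not the
  ## geometric midpoints), so class means - and hence the maximization -
  ## are exact whenever distinct values occupy distinct bins
  agg <- rowsum(v, bin)
  sums <- numeric(levels)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  mids <- ifelse(h > 0, sums / pmax(h, 1L), 0)
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  muT <- mu1[levels]
  ## inter-class variance for a cut after each bin k (k = 1..levels-1)
  k <- seq_len(levels - 1L)
  valid <- w1[k] > 0 & w1[k] < 1
  sigma2 <- rep(-Inf, levels - 1L)
  sigma2[valid] <- (muT * w1[k][valid] - mu1[k][valid])^2 /
    (w1[k][valid] * (1 - w1[k][valid]))
  kbest <- which.max(sigma2)          # ties: smallest threshold
  edges[kbest + 1L]
}
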