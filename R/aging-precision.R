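## Reader-agreement statistics for repeated otolith age reads.
##
## Input convention: `reads` is a matrix or data.frame with one row per
## fish and one column per reader (R >= 2). Fish with a missing read from
## any reader are excluded from all statistics, matching the usual practice
## of comparing only the subsample read by every reader.

as_read_matrix <- function(reads, min_readers = 2L) {
  m <- as.matrix(reads)
  storage.mode(m) <- "double"
  if (ncol(m) < min_readers)
    stop_domain("need at least ", min_readers, " readers")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 1) stop_domain("need at least one fish with complete reads")
  if (any(m < 1)) stop_domain("all reads must be >= 1")
  m
}

#' Beamish-Fournier average percent error (APE)
#'
#' For fish j with reads x_ij from R readers and mean age x-bar_j,
#' APE_j = (100/R) * sum_i |x_ij - x-bar_j| / x-bar_j; the statistic is the
#' mean of APE_j over fish.
#'
#' @param reads Matrix/data.frame of integer ages, fish x readers.
#' @return APE in percent (>= 0).
#' @export
#' @examples
#' average_percent_error(cbind(c(10, 5), c(12, 5)))  # 4.5455
average_percent_error <- function(reads) {
  m <- as_read_matrix(reads)
  xbar <- rowMeans(m)
  if (any(xbar <= 0)) stop_domain("fish with mean age 0 are not allowed")
  mean(100 / ncol(m) * rowSums(abs(m - xbar)) / xbar)
}

#' Chang's mean coefficient of variation between readers
#'
#' CV_j = 100 * s_j / x-bar_j with s_j the sample (n-1) standard deviation
#' of fish j's reads; returns the mean over fish. For two readers
#' CV = sqrt(2) * APE for every fish.
#'
#' @inheritParams average_percent_error
#' @return Mean CV in percent.
#' @export
mean_cv <- function(reads) {
  m <- as_read_matrix(reads)
  xbar <- rowMeans(m)
  if (any(xbar <= 0)) stop_domain("fish with mean age 0 are not allowed")
  s <- apply(m, 1, sd)
  mean(100 * s / xbar)
}

#' Percent reader agreement within a tolerance
#'
#' Share of fish whose two reads differ by at most `tolerance` years.
#' Only defined for exactly two readers.
#'
#' @inheritParams average_percent_error
#' @param tolerance Non-negative integer tolerance in years (0 = exact
#'   agreement).
#' @return Agreement in percent.
#' @export
percent_agreement <- function(reads, tolerance = 0) {
  m <- as_read_matrix(reads)
  if (ncol(m) != 2)
    stop_domain("percent agreement is only supported for exactly 2 readers")
  if (tolerance < 0) stop_domain("tolerance must be >= 0")
  100 * mean(abs(m[, 1] - m[, 2]) <= tolerance)
}

#' One-row summary of ageing precision
#'
#' @inheritParams average_percent_error
#' @return A one-row `data.frame` with `ape_pct`, `cv_pct`, `agree0_pct`,
#'   `agree1_pct`, `agree2_pct`, and `n` (fish with complete reads).
#' @export
precision_summary <- function(reads) {
  m <- as_read_matrix(reads)
  data.frame(ape_pct = average_percent_error(m),
             cv_pct = mean_cv(m),
             agree0_pct = percent_agreement(m, 0),
             agree1_pct = percent_agreement(m, 1),
             agree2_pct = percent_agreement(m, 2),
             n = nrow(m))
}
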