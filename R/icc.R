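#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from
#' the standard variance-component ANOVA decomposition of an
#' `n subjects x 2 raters` table:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with
#' `k = 2`. When the between-subject variance vanishes (degenerate
#' denominator) the ICC is defined as 0 with a warning.
#'
#' @param x,y equal-length numeric subject vectors (two ratings of the
#'   same subjects), `n >= 3`.
#' @return The ICC, a scalar in `[-1, 1]`.
#' @export
compute_icc <- function(x, y) {
  if (length(x) != length(y)) stop("ratings must have equal length")
  n <- length(x)
  if (n < 3) stop("ICC requires at least 3 subjects")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("ratings must be finite")
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (!is.finite(den) || den <= 0) {
    warning("zero between-subject variance: ICC defined as 0")
    return(0)
  }
  max(min((msr - mse) / den, 1), -1)
}

#' Landis-Koch interpretation band for an agreement coefficient
#'
#' `(0.80, 1.00]` is "excellent", `(0.60, 0.80]` "substantial", and
#' anything at or below 0.60 "poor/moderate" (the exclusion zone of the
#' reliability filter).
#'
#' @param icc a finite agreement value.
#' @return Character band label.
#' @export
landis_koch_band <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc > 0.80) "excellent"
  else if (icc > 0.60) "substantial"
  else "poor/moderate"
}

#' Reliability filter on repeated-reading feature tables
#'
#' Computes, per feature, the inter-reader ICC (reader 1 read 1 vs
#' reader 2) and intra-reader ICC (reader 1 read 1 vs reader 1 read 2)
#' and drops a feature when either is at or below the threshold: a
#' feature must be adequately reproducible both across and within
#' readers to survive.
#'
#' @param r1r1,r1r2,r2r1 numeric matrices `subjects x features` with
#'   identical column names: reader 1 read 1, reader 1 read 2 (repeat
#'   segmentation), reader 2 read 1.
#' @param threshold exclusion threshold; `ICC <= threshold` drops the
#'   feature (default 0.6).
#' @return A `reliability_report` data frame: `feature`, `icc_inter`,
#'   `icc_intra`, `band` (of the smaller ICC), `verdict` (`keep` /
#'   `drop_icc`), `partner` (filled by [redundancy_prune()]).
#' @export
reliability_filter <- function(r1r1, r1r2, r2r1, threshold = 0.6) {
  stopifnot(identical(colnames(r1r1), colnames(r1r2)),
            identical(colnames(r1r1), colnames(r2r1)),
            nrow(r1r1) == nrow(r1r2), nrow(r1r1) == nrow(r2r1))
  feats <- colnames(r1r1)
  icc_inter <- icc_intra <- numeric(length(feats))
  for (i in seq_along(feats)) {
    icc_inter[i] <- suppressWarnings(compute_icc(r1r1[, i], r2r1[, i]))
    icc_intra[i] <- suppressWarnings(compute_icc(r1r1[, i], r1r2[, i]))
  }
  worst <- pmin(icc_inter, icc_intra)
  rep <- data.frame(
    feature = feats,
    icc_inter = icc_inter,
    icc_intra = icc_intra,
    band = vapply(worst, landis_koch_band, character(1)),
    verdict = ifelse(worst <= threshold, "drop_icc", "keep"),
    partner = NA_character_,
    stringsAsFactors = FALSE)
  class(rep) <- c("reliability_report", class(rep))
  rep
}
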