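#' Histogram features of the in-mask intensities
#'
#' Mean, variance, skewness and excess kurtosis of the raw in-mask
#' intensity values. Zero variance yields skewness = kurtosis = 0.
#'
#' @param img a [gray_image()].
#' @param mask logical matrix congruent with `img`.
#' @return Named numeric vector `Mean`, `Variance`, `Skewness`,
#'   `Kurtosis`.
#' @export
histogram_features <- function(img, mask) {
  v <- img$pixels[mask]
  if (!length(v)) stop("empty mask")
  s <- moment_stats(v)
  c(Mean = unname(s["mean"]), Variance = unname(s["variance"]),
    Skewness = unname(s["skewness"]), Kurtosis = unname(s["kurtosis"]))
}

#' Absolute-gradient features on the 4-bit quantized image
#'
#' The absolute gradient at a pixel is the Euclidean norm of the central
#' differences of the 4-bit level image. Only in-mask pixels whose four
#' axial neighbours are all in-mask contribute; mask-edge and image-edge
#' pixels are excluded. Features: gradient mean, variance, skewness,
#' excess kurtosis, and the fraction of contributing pixels with a
#' non-zero gradient.
#'
#' @param q4 a `quantized_image` from 4-bit quantization.
#' @return Named numeric vector `GrMean`, `GrVariance`, `GrSkewness`,
#'   `GrKurtosis`, `GrNonZeros`.
#' @export
gradient_features <- function(q4) {
  stopifnot(inherits(q4, "quantized_image"))
  if (q4$bits != 4) stop("gradient family requires the 4-bit image")
  lev <- q4$levels
  nr <- nrow(lev); nc <- ncol(lev)
  inner_r <- 2:(nr - 1); inner_c <- 2:(nc - 1)
  ctr <- lev[inner_r, inner_c]
  up <- lev[inner_r - 1, inner_c]; dn <- lev[inner_r + 1, inner_c]
  lf <- lev[inner_r, inner_c - 1]; rt <- lev[inner_r, inner_c + 1]
  ok <- !is.na(ctr) & !is.na(up) & !is.na(dn) & !is.na(lf) & !is.na(rt)
  if (!any(ok)) stop("no pixel with a full 4-neighbourhood in mask")
  gx <- (rt[ok] - lf[ok]) / 2
  gy <- (dn[ok] - up[ok]) / 2
  g <- sqrt(gx^2 + gy^2)
  s <- moment_stats(g)
  c(GrMean = unname(s["mean"]), GrVariance = unname(s["variance"]),
    GrSkewness = unname(s["skewness"]), GrKurtosis = unname(s["kurtosis"]),
    GrNonZeros = mean(g > 0))
}
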