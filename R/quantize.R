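#' Normalization window by the +/- 3 sigma rule
#'
#' Grey-level normalization window derived from the in-ROI intensity
#' distribution: `[mu - 3 sigma, mu + 3 sigma]`. Windowing to this range
#' before quantization corrects for small technical intensity variations
#' between acquisitions and makes the quantized image invariant to affine
#' intensity maps `v -> k v + c` (k > 0).
#'
#' @param img a [gray_image()].
#' @param mask logical matrix congruent with `img`.
#' @return List with `mu`, `sigma`, `lo`, `hi`.
#' @export
normalization_window <- function(img, mask) {
  stopifnot(inherits(img, "gray_image"), all(dim(mask) == dim(img$pixels)))
  v <- img$pixels[mask]
  if (!length(v)) stop("empty mask")
  mu <- mean(v)
  sigma <- stats::sd(v)
  if (!is.finite(sigma)) sigma <- 0
  list(mu = mu, sigma = sigma, lo = mu - 3 * sigma, hi = mu + 3 * sigma)
}

#' Window and quantize a masked image to Ng = 2^bits grey levels
#'
#' In-mask intensities are windowed to `[mu - 3 sigma, mu + 3 sigma]`
#' (statistics over in-mask pixels only) and mapped to integer levels
#' `1..Ng` by `clamp(1 + floor((v - lo) / (hi - lo) * Ng), 1, Ng)`;
#' values at or below `lo` map to 1 and at or above `hi` to `Ng`.
#' Out-of-mask pixels are flagged `NA`. Co-occurrence and run-length
#' families use 6 bits (Ng = 64), the gradient family 4 bits (Ng = 16).
#'
#' @param img a [gray_image()].
#' @param mask logical matrix congruent with `img`.
#' @param bits 4 or 6 bits per pixel.
#' @return An object of class `quantized_image`: integer matrix `levels`
#'   with `NA` outside the mask, plus `ng`, `bits` and the window.
#' @export
normalize_and_quantize <- function(img, mask, bits = 6) {
  if (!bits %in% c(4, 6)) stop("bits must be 4 or 6")
  w <- normalization_window(img, mask)
  ng <- as.integer(2^bits)
  lev <- matrix(NA_integer_, nrow(img$pixels), ncol(img$pixels))
  v <- img$pixels[mask]
  if (w$sigma <= 0) {
    warning("degenerate +/-3 sigma window (sigma = 0): all levels set to 1")
    lev[mask] <- 1L
  } else {
    q <- 1L + as.integer(floor((v - w$lo) / (w$hi - w$lo) * ng))
    lev[mask] <- pmin(pmax(q, 1L), ng)
  }
  structure(list(levels = lev, ng = ng, bits = as.integer(bits), window = w),
            class = "quantized_image")
}

#' @export
print.quantized_image <- function(x, ...) {
  cat(sprintf("<quantized_image> %d x %d, Ng = %d (%d bits), %d in-mask\n",
              nrow(x$levels), ncol(x$levels), x$ng, x$bits,
              sum(!is.na(x$levels))))
  invisible(x)
}
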