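#' Haar wavelet sub-band energies
#'
#' The analysis window is the largest dyadic (power-of-two) square that
#' fits inside the bounding box of the mask, centered in the box; raw
#' image intensities are analyzed (the window may include pixels just
#' outside the mask, as is usual for windowed wavelet texture measures).
#' An orthonormal 2D Haar transform is applied recursively to the
#' low-pass band; at each scale `s` the energy of a sub-band (LL, LH =
#' horizontal detail, HL = vertical detail, HH = diagonal detail) is the
#' mean of its squared coefficients. Scales beyond the window size
#' return `NA`.
#'
#' @param img a [gray_image()].
#' @param mask logical matrix congruent with `img`.
#' @param scales integer vector of scales, consecutive from 1 (up to 7).
#' @return Named numeric vector `WavEnLL.s<k>`, `WavEnLH.s<k>`,
#'   `WavEnHL.s<k>`, `WavEnHH.s<k>` for each requested scale `k`,
#'   `NA` where the sub-band is unrealizable.
#' @export
wavelet_features <- function(img, mask, scales = 1:7) {
  stopifnot(inherits(img, "gray_image"), all(dim(mask) == dim(img$pixels)))
  if (!length(scales) || scales[1] != 1 || any(diff(scales) != 1)) {
    stop("scales must be consecutive from 1")
  }
  out <- rep(NA_real_, 4 * length(scales))
  names(out) <- as.vector(vapply(
    scales, function(s) paste0("WavEn", c("LL", "LH", "HL", "HH"), ".s", s),
    character(4)))
  win <- dyadic_window(mask)
  if (is.null(win)) return(out)  # window < 2x2: all MISSING
  block <- img$pixels[win$rows, win$cols]
  side <- nrow(block)
  max_scale <- min(max(scales), as.integer(log2(side)))
  ll <- block
  for (s in seq_len(max_scale)) {
    tr <- haar_step(ll)
    out[paste0("WavEnLL.s", s)] <- mean(tr$LL^2)
    out[paste0("WavEnLH.s", s)] <- mean(tr$LH^2)
    out[paste0("WavEnHL.s", s)] <- mean(tr$HL^2)
    out[paste0("WavEnHH.s", s)] <- mean(tr$HH^2)
    ll <- tr$LL
  }
  out
}

# Largest dyadic square inside the mask bounding box, centered; NULL if
# smaller than 2x2.
dyadic_window <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (!nrow(w)) return(NULL)
  r0 <- min(w[, 1]); r1 <- max(w[, 1])
  c0 <- min(w[, 2]); c1 <- max(w[, 2])
  side <- 2^floor(log2(min(r1 - r0 + 1, c1 - c0 + 1)))
  if (side < 2) return(NULL)
  ro <- r0 + floor((r1 - r0 + 1 - side) / 2)
  co <- c0 + floor((c1 - c0 + 1 - side) / 2)
  list(rows = ro:(ro + side - 1), cols = co:(co + side - 1), side = side)
}

# One orthonormal 2D Haar analysis step on an even-sided square block.
# Row pairs are combined with (a+b)/sqrt(2), (a-b)/sqrt(2) along both
# axes; LH carries horizontal detail (differences along columns), HL
# vertical detail.
haar_step <- function(x) {
  n <- nrow(x)
  o <- seq(1, n - 1, by = 2); e <- seq(2, n, by = 2)
  # columns (horizontal direction)
  lo_c <- (x[, o, drop = FALSE] + x[, e, drop = FALSE]) / sqrt(2)
  hi_c <- (x[, o, drop = FALSE] - x[, e, drop = FALSE]) / sqrt(2)
  # rows (vertical direction)
  comb <- function(m) list(lo = (m[o, , drop = FALSE] + m[e, , drop = FALSE]) / sqrt(2),
                           hi = (m[o, , drop = FALSE] - m[e, , drop = FALSE]) / sqrt(2))
  a <- comb(lo_c); b <- comb(hi_c)
  list(LL = a$lo, LH = b$lo, HL = a$hi, HH = b$hi)
}
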