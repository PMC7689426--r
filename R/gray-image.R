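#' Grayscale image with physical pixel spacing
#'
#' A `gray_image` is a 2D real-valued intensity grid together with the
#' physical in-plane pixel spacing in millimetres. The grid is stored
#' row-major conceptually: `pixels[r, c]` is row `r`, column `c`.
#' Continuous coordinates are 0-based with pixel centers at integers:
#' `x` is the column index, `y` the row index.
#'
#' @param pixels numeric matrix of intensities (at least 2 x 2, all finite).
#' @param spacing_row,spacing_col mm per pixel along rows / columns (> 0).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, spacing_row, spacing_col = spacing_row) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels))) {
    stop("image intensities must be finite numerics")
  }
  if (nrow(pixels) < 2 || ncol(pixels) < 2) {
    stop("image must be at least 2 x 2 pixels")
  }
  if (!is.numeric(spacing_row) || !is.numeric(spacing_col) ||
      spacing_row <= 0 || spacing_col <= 0) {
    stop("pixel spacing must be > 0")
  }
  structure(list(pixels = pixels,
                 spacing_row = as.numeric(spacing_row),
                 spacing_col = as.numeric(spacing_col)),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d pixels, spacing %.6g x %.6g mm\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_row, x$spacing_col))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Read an image file into a `gray_image`
#'
#' Supported format: 16-bit (or 8-bit) PGM rasters, plain (`P2`) or binary
#' (`P5`), with the pixel spacing supplied by a plain-text sidecar file
#' `<path>.spacing` containing one or two numbers (mm per pixel; row
#' then column), or passed directly via `spacing`. Pixel spacing is
#' mandatory: without it the image cannot be resampled to a physical grid.
#'
#' @param path path to a PGM file.
#' @param spacing optional numeric of length 1 or 2 overriding the sidecar.
#' @return A [gray_image()].
#' @export
read_image <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  px <- read_pgm(path)
  if (is.null(spacing)) {
    sidecar <- paste0(path, ".spacing")
    if (!file.exists(sidecar)) {
      stop("spacing unavailable: no sidecar ", sidecar,
           " and no `spacing` argument")
    }
    spacing <- scan(sidecar, what = numeric(), quiet = TRUE)
  }
  if (length(spacing) == 1) spacing <- c(spacing, spacing)
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing unavailable: sidecar must hold 1 or 2 positive numbers")
  }
  gray_image(px, spacing_row = spacing[1], spacing_col = spacing[2])
}

# Minimal PGM reader (P2 plain / P5 binary, maxval <= 65535, big-endian
# 16-bit per the netpbm convention). Returns a numeric matrix.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header: magic, width, height, maxval -- comments (#...) skipped
  buf <- character(0)
  while (length(tokens) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0 || nchar(ch) == 0) stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  n <- w * h
  if (magic == "P2") {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else if (magic == "P5") {
    if (maxval > 255) {
      raw2 <- readBin(con, "raw", n = 2L * n)
      vals <- as.numeric(readBin(raw2, "integer", n = n, size = 2,
                                 signed = FALSE, endian = "big"))
    } else {
      vals <- as.numeric(readBin(con, "integer", n = n, size = 1,
                                 signed = FALSE))
    }
  } else {
    stop("unsupported raster format (expected PGM P2/P5): ", magic)
  }
  if (length(vals) != n) stop("truncated PGM pixel data")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a `gray_image` (or integer matrix) as a plain PGM with sidecar
#'
#' Intensities are rounded and clamped to `[0, maxval]`. When `img` is a
#' `gray_image` a `<path>.spacing` sidecar is written alongside.
#'
#' @param img a [gray_image()] or numeric matrix.
#' @param path output path.
#' @param maxval maximum grey value recorded in the header.
#' @export
write_pgm <- function(img, path, maxval = 65535) {
  px <- if (inherits(img, "gray_image")) img$pixels else as.matrix(img)
  v <- pmin(pmax(round(px), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), as.character(maxval)), con)
  write(t(v), file = con, ncolumns = min(ncol(v), 16))
  if (inherits(img, "gray_image")) {
    writeLines(format(c(img$spacing_row, img$spacing_col), digits = 12),
               paste0(path, ".spacing"))
  }
  invisible(path)
}

#' Resample an image to a uniform target pixel spacing
#'
#' Bilinear interpolation on pixel centers; the physical extent of the
#' image is preserved to within one output pixel. Pixel center `i'`
#' (0-based) of the output lies at physical position `(i' + 1/2) * target`,
#' so an image already at the target spacing is returned pixel-identical.
#' The study default target is 0.390625 mm (200 mm field of view over a
#' 512 matrix).
#'
#' @param img a [gray_image()].
#' @param target mm per pixel of the output grid (> 0).
#' @return A resampled [gray_image()] with `spacing_row = spacing_col =
#'   target`.
#' @export
resample_to_spacing <- function(img, target = 0.390625) {
  stopifnot(inherits(img, "gray_image"))
  if (!is.numeric(target) || target <= 0) stop("target spacing must be > 0")
  nr <- nrow(img$pixels); nc <- ncol(img$pixels)
  out_nr <- round(nr * img$spacing_row / target)
  out_nc <- round(nc * img$spacing_col / target)
  if (out_nr < 2 || out_nc < 2) stop("resampled grid smaller than 2 x 2")
  if (out_nr == nr && out_nc == nc &&
      img$spacing_row == target && img$spacing_col == target) {
    return(img)  # exact identity, no interpolation round-off
  }
  # output center i' maps to input continuous coordinate (0-based)
  ry <- (seq_len(out_nr) - 0.5) * target / img$spacing_row - 0.5
  rx <- (seq_len(out_nc) - 0.5) * target / img$spacing_col - 0.5
  gray_image(bilinear_sample(img$pixels, ry, rx),
             spacing_row = target, spacing_col = target)
}

# Bilinear sampling of matrix `px` at the coordinate grid ry (rows) x
# rx (cols), 0-based continuous coordinates, edge-clamped.
bilinear_sample <- function(px, ry, rx) {
  nr <- nrow(px); nc <- ncol(px)
  y0 <- pmin(pmax(floor(ry), 0), nr - 1)
  x0 <- pmin(pmax(floor(rx), 0), nc - 1)
  y1 <- pmin(y0 + 1, nr - 1)
  x1 <- pmin(x0 + 1, nc - 1)
  wy <- pmin(pmax(ry - y0, 0), 1)
  wx <- pmin(pmax(rx - x0, 0), 1)
  # outer products assemble the four corner contributions
  p00 <- px[cbind(rep(y0 + 1, length(x0)), rep(x0 + 1, each = length(y0)))]
  p01 <- px[cbind(rep(y0 + 1, length(x1)), rep(x1 + 1, each = length(y0)))]
  p10 <- px[cbind(rep(y1 + 1, length(x0)), rep(x0 + 1, each = length(y1)))]
  p11 <- px[cbind(rep(y1 + 1, length(x1)), rep(x1 + 1, each = length(y1)))]
  dim(p00) <- dim(p01) <- dim(p10) <- dim(p11) <- c(length(ry), length(rx))
  wy <- matrix(wy, length(ry), length(rx))
  wx <- matrix(wx, length(ry), length(rx), byrow = TRUE)
  (1 - wy) * ((1 - wx) * p00 + wx * p01) + wy * ((1 - wx) * p10 + wx * p11)
}
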