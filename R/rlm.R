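#' Run-length table of a masked quantized image
#'
#' Maximal runs of equal grey level along the scan lines of one angle
#' (0, 45, 90 or 135 degrees), truncated at mask boundaries: an
#' out-of-mask pixel ends the current run and in-mask segments of one
#' scan line are processed independently.
#'
#' @param q a `quantized_image` (6-bit for the run-length family).
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @return Object of class `run_length_table`: `runs`, an Ng x Lmax
#'   integer matrix of run counts by grey level and run length, plus
#'   `angle` and `n_pixels` (in-mask pixels of the image).
#' @export
build_run_table <- function(q, angle) {
  stopifnot(inherits(q, "quantized_image"))
  angle <- as.character(angle)
  if (!angle %in% c("0", "45", "90", "135")) {
    stop("angle must be one of 0, 45, 90, 135")
  }
  lev <- q$levels
  n_pixels <- sum(!is.na(lev))
  if (n_pixels == 0) stop("empty mask")
  sl <- scan_line_index(dim(lev), angle)
  # all scan lines concatenated with a break sentinel between lines, so
  # one rle pass finds every run without crossing line boundaries
  vals <- rep(-1L, sl$total)
  vals[sl$fill] <- lev[sl$idx]
  vals[is.na(vals)] <- -1L
  r <- rle(vals)
  keep <- r$values != -1L
  gl <- r$values[keep]
  ln <- r$lengths[keep]
  lmax <- max(ln)
  runs <- matrix(tabulate((ln - 1L) * q$ng + gl, nbins = q$ng * lmax),
                 q$ng, lmax)
  structure(list(runs = runs, angle = as.numeric(angle),
                 n_pixels = n_pixels, ng = q$ng),
            class = "run_length_table")
}

# Cached concatenated scan-line indices for a grid shape and angle:
# `idx` walks every pixel line by line along the angle's unit offset,
# `fill` are the slots of the padded vector (one sentinel slot between
# lines), `total` its length. Every pixel lies on exactly one line.
.scan_cache <- new.env(parent = emptyenv())

scan_line_index <- function(shape, angle) {
  key <- paste(shape[1], shape[2], angle, sep = "x")
  hit <- .scan_cache[[key]]
  if (!is.null(hit)) return(hit)
  nr <- shape[1]; nc <- shape[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  if (angle == "0") {                    # horizontal, left to right
    key_m <- row; ord <- order(key_m, col)
  } else if (angle == "90") {            # vertical, top to bottom
    key_m <- col; ord <- order(key_m, row)
  } else if (angle == "45") {            # up-right, row+col constant
    key_m <- row + col; ord <- order(key_m, -row)
  } else {                               # 135: up-left, col-row constant
    key_m <- col - row; ord <- order(key_m, -row)
  }
  idx <- seq_len(nr * nc)[ord]
  line_id <- as.integer(factor(as.vector(key_m)[ord]))
  # slot for element j within the padded vector: its position plus one
  # sentinel per preceding line break
  fill <- seq_along(idx) + (line_id - 1L)
  out <- list(idx = idx, fill = fill,
              total = length(idx) + max(line_id) - 1L)
  .scan_cache[[key]] <- out
  out
}

#' Run-length features (Galloway)
#'
#' Short-run emphasis, long-run emphasis, grey-level non-uniformity,
#' run-length non-uniformity, and fraction of image in runs (run count
#' divided by the number of in-mask pixels), computed from the run table
#' of one angle.
#'
#' @param rt a `run_length_table` from [build_run_table()].
#' @return Named numeric vector of the 5 features.
#' @export
rlm_features <- function(rt) {
  runs <- rt$runs
  lmax <- ncol(runs)
  nruns <- sum(runs)
  l <- seq_len(lmax)
  by_len <- colSums(runs)
  by_gl <- rowSums(runs)
  c(ShrtREmp = sum(by_len / l^2) / nruns,
    LngREmph = sum(by_len * l^2) / nruns,
    GLevNonU = sum(by_gl^2) / nruns,
    RLNonUni = sum(by_len^2) / nruns,
    Fraction = nruns / rt$n_pixels)
}
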