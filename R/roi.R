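#' Polygonal region of interest
#'
#' An ordered list of continuous `(x, y)` vertices (0-based, `x` = column,
#' `y` = row, pixel centers at integers), implicitly closed. Polygons must
#' be simple (non-self-intersecting) with at least 3 vertices.
#'
#' @param vertices two-column numeric matrix (or coercible) of `(x, y)`
#'   coordinates.
#' @param reader,read optional reader / read tags (1 or 2), carried as
#'   attributes.
#' @return An object of class `roi_polygon`.
#' @export
roi_polygon <- function(vertices, reader = NA_integer_, read = NA_integer_) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2) stop("vertices must be an n x 2 matrix of (x, y)")
  if (nrow(v) < 3) stop("polygon needs at least 3 vertices")
  if (any(!is.finite(v))) stop("polygon vertices must be finite")
  if (!polygon_is_simple(v)) stop("polygon is self-intersecting")
  colnames(v) <- c("x", "y")
  structure(list(vertices = v, reader = as.integer(reader),
                 read = as.integer(read)),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> %d vertices (reader %s, read %s)\n",
              nrow(x$vertices), x$reader, x$read))
  invisible(x)
}

# Simple-polygon test: no two non-adjacent edges intersect (properly or
# by touching) and adjacent edges only share their common endpoint.
# Fully vectorized over the O(V^2) edge pairs.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  adj <- (pr[, 2] == pr[, 1] + 1) | (pr[, 1] == 1 & pr[, 2] == n)
  pr <- pr[!adj, , drop = FALSE]
  if (!nrow(pr)) return(TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  p1x <- v[i, 1]; p1y <- v[i, 2]; p2x <- v[nxt[i], 1]; p2y <- v[nxt[i], 2]
  p3x <- v[j, 1]; p3y <- v[j, 2]; p4x <- v[nxt[j], 1]; p4y <- v[nxt[j], 2]
  crs <- function(px, py, qx, qy, rx, ry) {
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  }
  d1 <- crs(p3x, p3y, p4x, p4y, p1x, p1y)
  d2 <- crs(p3x, p3y, p4x, p4y, p2x, p2y)
  d3 <- crs(p1x, p1y, p2x, p2y, p3x, p3y)
  d4 <- crs(p1x, p1y, p2x, p2y, p4x, p4y)
  proper <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  if (any(proper)) return(FALSE)
  on_seg <- function(px, py, qx, qy, rx, ry, d) {
    d == 0 & pmin(px, qx) <= rx & rx <= pmax(px, qx) &
      pmin(py, qy) <= ry & ry <= pmax(py, qy)
  }
  touch <- on_seg(p3x, p3y, p4x, p4y, p1x, p1y, d1) |
    on_seg(p3x, p3y, p4x, p4y, p2x, p2y, d2) |
    on_seg(p1x, p1y, p2x, p2y, p3x, p3y, d3) |
    on_seg(p1x, p1y, p2x, p2y, p4x, p4y, d4)
  !any(touch)
}

#' Read a ROI polygon from its JSON file
#'
#' Expected layout: `{"vertices": [[x, y], ...], "reader": 1, "read": 1}`.
#'
#' @param path path to the JSON file.
#' @return A [roi_polygon()].
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  roi_polygon(obj$vertices,
              reader = obj$reader %||% NA_integer_,
              read = obj$read %||% NA_integer_)
}

#' Write a ROI polygon to JSON
#' @param poly a [roi_polygon()].
#' @param path output path.
#' @export
write_roi_json <- function(poly, path) {
  jsonlite::write_json(
    list(vertices = unname(poly$vertices),
         reader = poly$reader, read = poly$read),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Map polygon coordinates from a grid with spacing (sr, sc) to the grid
# produced by resample_to_spacing(target): polygons are re-rasterized on
# the new grid, never interpolated as masks.
rescale_polygon <- function(poly, spacing_row, spacing_col, target) {
  v <- poly$vertices
  v[, "x"] <- (v[, "x"] + 0.5) * spacing_col / target - 0.5
  v[, "y"] <- (v[, "y"] + 0.5) * spacing_row / target - 0.5
  roi_polygon(v, reader = poly$reader, read = poly$read)
}

#' Rasterize a polygon to a boolean mask
#'
#' A pixel belongs to the mask iff its center lies inside the polygon
#' under the even-odd rule. Scanline implementation: for each pixel row
#' the crossings of polygon edges with the horizontal line through the
#' pixel centers are collected and sorted; pixels between odd and even
#' crossings are inside. Half-open edge convention (`min(y) <= yc <
#' max(y)`) makes vertices count once.
#'
#' @param poly a [roi_polygon()].
#' @param shape integer vector `c(nrow, ncol)` of the target grid.
#' @param min_pixels smallest admissible mask; texture statistics are
#'   meaningless below roughly this size.
#' @return Logical matrix of dimension `shape` (class `roi_mask`).
#' @export
rasterize_roi <- function(poly, shape, min_pixels = 16) {
  stopifnot(inherits(poly, "roi_polygon"), length(shape) == 2)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  v <- poly$vertices
  n <- nrow(v)
  x1 <- v[, "x"]; y1 <- v[, "y"]
  x2 <- v[c(2:n, 1), "x"]; y2 <- v[c(2:n, 1), "y"]
  mask <- matrix(FALSE, nr, nc)
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  xc <- 0:(nc - 1)
  for (r in seq_len(nr)) {
    yc <- r - 1  # pixel-center y, 0-based
    hit <- which(ylo <= yc & yc < yhi)
    if (!length(hit)) next
    xs <- x1[hit] + (yc - y1[hit]) * (x2[hit] - x1[hit]) / (y2[hit] - y1[hit])
    # even-odd rule with a +x ray: inside iff an odd number of edge
    # crossings lies strictly to the right of the pixel center
    n_right <- length(xs) - findInterval(xc, sort(xs))
    mask[r, ] <- (n_right %% 2) == 1
  }
  if (sum(mask) < min_pixels) {
    stop("ROI too small: ", sum(mask), " pixels (minimum ", min_pixels, ")")
  }
  class(mask) <- c("roi_mask", class(mask))
  mask
}

#' Dice overlap between two masks
#' @param a,b logical matrices of equal dimension.
#' @return Dice coefficient in `[0, 1]`.
#' @export
mask_dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
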