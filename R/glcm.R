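#' Grey-level co-occurrence matrix over a masked quantized image
#'
#' Counts ordered pixel pairs `(p, p + d * direction)` with both pixels
#' inside the mask and accumulates them symmetrically: each pair
#' increments both `(i, j)` and `(j, i)`, so the matrix is symmetric and
#' every direction also covers its opposite. Probabilities are the counts
#' jointly normalized to sum 1. The panel default uses the four
#' directions 0, 45, 90 and 135 degrees at inter-pixel distances 1..5.
#'
#' @param q a `quantized_image` (6-bit for the co-occurrence family).
#' @param distance inter-pixel distance `a >= 1`.
#' @param direction length-2 integer offset `c(drow, dcol)` for a unit
#'   step; the pair offset is `distance * direction`. The canonical four:
#'   `c(0, 1)` 0 deg, `c(-1, 1)` 45 deg, `c(-1, 0)` 90 deg, `c(-1, -1)`
#'   135 deg (rows grow downwards).
#' @return Object of class `cooccurrence_matrix` with integer `counts`
#'   (Ng x Ng), `probabilities`, `distance`, `direction`.
#' @export
build_cooccurrence <- function(q, distance, direction) {
  stopifnot(inherits(q, "quantized_image"))
  if (distance < 1) stop("distance must be >= 1")
  dr <- as.integer(distance * direction[1])
  dc <- as.integer(distance * direction[2])
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  rs <- r0[r0 + dr >= 1 & r0 + dr <= nr]
  cs <- c0[c0 + dc >= 1 & c0 + dc <= nc]
  if (!length(rs) || !length(cs)) stop("empty co-occurrence: offset exceeds image")
  a <- lev[rs, cs, drop = FALSE]
  b <- lev[rs + dr, cs + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("empty co-occurrence: no valid pixel pair in mask")
  idx <- (b[ok] - 1L) * q$ng + a[ok]
  counts <- matrix(tabulate(idx, nbins = q$ng * q$ng), q$ng, q$ng)
  counts <- counts + t(counts)  # symmetric accumulation
  structure(list(counts = counts,
                 probabilities = counts / sum(counts),
                 distance = as.integer(distance),
                 direction = c(dr = dr, dc = dc),
                 ng = q$ng),
            class = "cooccurrence_matrix")
}

#' Haralick features of a co-occurrence matrix
#'
#' The eleven classical texture statistics computed from the normalized
#' symmetric co-occurrence probabilities: angular second moment,
#' contrast, correlation, sum of squares (variance), inverse difference
#' moment, sum average, sum variance, sum entropy, entropy, difference
#' variance, difference entropy. Entropies use the natural logarithm with
#' the convention `0 log 0 = 0`; sum variance is taken about the sum
#' average. A single-level (zero-variance) matrix has correlation
#' defined as 0.
#'
#' @param m a `cooccurrence_matrix`.
#' @return Named numeric vector of the 11 features.
#' @export
glcm_features <- function(m) {
  p <- m$probabilities
  ng <- nrow(p)
  gi <- glcm_index(ng)
  i <- gi$i; j <- gi$j
  px <- rowSums(p)                       # symmetric: px == py
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  # diagonal-band marginals p_{x+y}(k), k = 2..2Ng and p_{|x-y|}(n), n = 0..Ng-1
  psum <- as.vector(rowsum(as.vector(p), gi$gsum))
  pdif <- as.vector(rowsum(as.vector(p), gi$gdif))
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  asm <- sum(p^2)
  contrast <- sum((0:(ng - 1))^2 * pdif)
  correlation <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0
  sosq <- sum((i - mu)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_avg <- sum((2:(2 * ng)) * psum)
  sum_var <- sum(((2:(2 * ng)) - sum_avg)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(p))
  dif_avg <- sum((0:(ng - 1)) * pdif)
  dif_var <- sum(((0:(ng - 1)) - dif_avg)^2 * pdif)
  dif_entropy <- -sum(xlogx(pdif))
  c(AngScMom = asm, Contrast = contrast, Correlat = correlation,
    SumOfSqs = sosq, InvDfMom = idm, SumAverg = sum_avg,
    SumVarnc = sum_var, SumEntrp = sum_entropy, Entropy = entropy,
    DifVarnc = dif_var, DifEntrp = dif_entropy)
}

# Cached index matrices and diagonal-band groupings for an Ng x Ng
# co-occurrence matrix.
.glcm_cache <- new.env(parent = emptyenv())

glcm_index <- function(ng) {
  key <- as.character(ng)
  hit <- .glcm_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  out <- list(i = i, j = j,
              gsum = as.vector(i + j),        # levels 2..2Ng
              gdif = as.vector(abs(i - j)))   # levels 0..Ng-1
  .glcm_cache[[key]] <- out
  out
}

# Canonical unit offsets for the four co-occurrence / run-length angles.
# Angles are measured in image convention (x right, y down is +row);
# 45 deg runs up-right.
angle_offsets <- function() {
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}
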