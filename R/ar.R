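#' Causal autoregressive model features
#'
#' Fits the causal four-neighbour autoregressive model
#' `v(p) = theta1 v(W) + theta2 v(NW) + theta3 v(N) + theta4 v(NE) + e`
#' over all in-mask pixels whose four causal neighbours (west,
#' north-west, north, north-east) are also in-mask, on mean-centered
#' levels, by least squares. Rank-deficient systems are resolved by the
#' minimum-norm (pseudoinverse) solution; a fully degenerate system
#' (constant image) returns `theta = 0, sigma = 0` with a warning.
#' `Sigma` is the root-mean-square residual.
#'
#' @param q a `quantized_image`.
#' @param min_pixels smallest number of eligible pixels for a fit.
#' @return Named numeric vector `Teta1..Teta4`, `Sigma`.
#' @export
ar_features <- function(q, min_pixels = 20) {
  stopifnot(inherits(q, "quantized_image"))
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  rr <- 2:nr; cc <- 2:(nc - 1)
  ctr <- lev[rr, cc]
  w  <- lev[rr, cc - 1]
  nw <- lev[rr - 1, cc - 1]
  n  <- lev[rr - 1, cc]
  ne <- lev[rr - 1, cc + 1]
  ok <- !is.na(ctr) & !is.na(w) & !is.na(nw) & !is.na(n) & !is.na(ne)
  if (sum(ok) < min_pixels) {
    stop("too few pixels with a causal neighbourhood for the AR fit (",
         sum(ok), " < ", min_pixels, ")")
  }
  mu <- mean(lev, na.rm = TRUE)
  y <- ctr[ok] - mu
  X <- cbind(w[ok], nw[ok], n[ok], ne[ok]) - mu
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) {
    warning("degenerate autoregressive system (constant image)")
    return(c(Teta1 = 0, Teta2 = 0, Teta3 = 0, Teta4 = 0, Sigma = 0))
  }
  theta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  res <- y - X %*% theta
  out <- c(theta, sqrt(mean(res^2)))
  names(out) <- c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma")
  out
}
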