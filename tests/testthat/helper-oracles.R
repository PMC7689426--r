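# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles by direct enumeration, sharing no code
# path with the package implementation.

# Wrap an integer level matrix (NA = out of mask) as a quantized image.
make_q <- function(lev, bits = 6) {
  lev <- as.matrix(lev)
  structure(list(levels = lev, ng = as.integer(2^bits),
                 bits = as.integer(bits),
                 window = list(mu = NA, sigma = NA, lo = NA, hi = NA)),
            class = "quantized_image")
}

# Exhaustive double-loop co-occurrence counts with symmetric accumulation.
brute_glcm_counts <- function(lev, ng, distance, direction) {
  dr <- distance * direction[1]; dc <- distance * direction[2]
  counts <- matrix(0L, ng, ng)
  for (r in seq_len(nrow(lev))) {
    for (c in seq_len(ncol(lev))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
      a <- lev[r, c]; b <- lev[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1L
      counts[b, a] <- counts[b, a] + 1L
    }
  }
  counts
}

# Straight-from-the-formula Haralick features, explicit loops only.
haralick_direct <- function(p) {
  ng <- nrow(p)
  xlogx <- function(v) if (v > 0) v * log(v) else 0
  asm <- contrast <- idm <- ent <- cross <- sosq <- 0
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      v <- p[i, j]
      asm <- asm + v^2
      contrast <- contrast + (i - j)^2 * v
      idm <- idm + v / (1 + (i - j)^2)
      ent <- ent - xlogx(v)
      cross <- cross + i * j * v
      sosq <- sosq + (i - mux)^2 * v
    }
  }
  corr <- if (sx > 0 && sy > 0) (cross - mux * muy) / (sx * sy) else 0
  psum <- numeric(2 * ng)
  pdif <- numeric(ng)
  for (i in seq_len(ng)) {
    for (j in seq_len(ng)) {
      psum[i + j] <- psum[i + j] + p[i, j]
      pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
    }
  }
  savg <- sum(seq_len(2 * ng) * psum)
  svar <- sum((seq_len(2 * ng) - savg)^2 * psum)
  sent <- -sum(vapply(psum, xlogx, numeric(1)))
  davg <- sum((0:(ng - 1)) * pdif)
  dvar <- sum(((0:(ng - 1)) - davg)^2 * pdif)
  dent <- -sum(vapply(pdif, xlogx, numeric(1)))
  c(AngScMom = asm, Contrast = contrast, Correlat = corr, SumOfSqs = sosq,
    InvDfMom = idm, SumAverg = savg, SumVarnc = svar, SumEntrp = sent,
    Entropy = ent, DifVarnc = dvar, DifEntrp = dent)
}

# Exhaustive run finder: walk every scan line pixel by pixel.
brute_run_table <- function(lev, ng, angle) {
  off <- switch(as.character(angle),
                "0" = c(0L, 1L), "45" = c(-1L, 1L),
                "90" = c(-1L, 0L), "135" = c(-1L, -1L))
  nr <- nrow(lev); nc <- ncol(lev)
  inb <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc
  runs <- list()
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      # start of a line: predecessor out of bounds
      if (inb(r0 - off[1], c0 - off[2])) next
      vals <- c()
      r <- r0; c <- c0
      while (inb(r, c)) {
        vals <- c(vals, lev[r, c])
        r <- r + off[1]; c <- c + off[2]
      }
      cur <- NA; len <- 0
      for (v in c(vals, NA)) {
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1
        } else {
          if (!is.na(cur)) runs[[length(runs) + 1]] <- c(cur, len)
          cur <- v; len <- 1
        }
      }
    }
  }
  lmax <- max(vapply(runs, `[`, numeric(1), 2))
  out <- matrix(0L, ng, lmax)
  for (rn in runs) out[rn[1], rn[2]] <- out[rn[1], rn[2]] + 1L
  out
}

# Galloway run-length features by explicit summation over the run table.
rlm_oracle <- function(runs, n_pixels) {
  sre <- lre <- gln <- rln <- 0
  nruns <- sum(runs)
  for (g in seq_len(nrow(runs))) {
    for (l in seq_len(ncol(runs))) {
      sre <- sre + runs[g, l] / l^2
      lre <- lre + runs[g, l] * l^2
    }
    gln <- gln + sum(runs[g, ])^2
  }
  for (l in seq_len(ncol(runs))) rln <- rln + sum(runs[, l])^2
  c(ShrtREmp = sre / nruns, LngREmph = lre / nruns, GLevNonU = gln / nruns,
    RLNonUni = rln / nruns, Fraction = nruns / n_pixels)
}

# Per-point even-odd crossing test (ray towards +x).
pip_point <- function(v, x, y) {
  n <- nrow(v)
  crossings <- 0
  for (k in seq_len(n)) {
    p1 <- v[k, ]; p2 <- v[if (k == n) 1 else k + 1, ]
    y1 <- p1[2]; y2 <- p2[2]
    if ((y1 <= y && y < y2) || (y2 <= y && y < y1)) {
      xc <- p1[1] + (y - y1) * (p2[1] - p1[1]) / (y2 - y1)
      if (xc > x) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

# Direct bilinear interpolation of one point (0-based coords, clamped).
bilinear_point <- function(px, yy, xx) {
  nr <- nrow(px); nc <- ncol(px)
  y0 <- min(max(floor(yy), 0), nr - 1); x0 <- min(max(floor(xx), 0), nc - 1)
  y1 <- min(y0 + 1, nr - 1); x1 <- min(x0 + 1, nc - 1)
  wy <- min(max(yy - y0, 0), 1); wx <- min(max(xx - x0, 0), 1)
  (1 - wy) * ((1 - wx) * px[y0 + 1, x0 + 1] + wx * px[y0 + 1, x1 + 1]) +
    wy * ((1 - wx) * px[y1 + 1, x0 + 1] + wx * px[y1 + 1, x1 + 1])
}

# ICC(2,1) via anova() mean squares (two-way model, subjects + raters).
icc_via_aov <- function(x, y) {
  n <- length(x)
  d <- data.frame(v = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- anova(stats::lm(v ~ subj + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# Small random integer level image with an irregular mask.
rand_lev <- function(nr, nc, ng, na_frac = 0.2) {
  lev <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  lev[sample.int(nr * nc, round(na_frac * nr * nc))] <- NA
  lev
}
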