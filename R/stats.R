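#' Mann-Whitney U test
#'
#' `U` is computed from rank sums with midrank ties. For small samples
#' (`n1 + n2 <= 12`) the two-tailed p-value is exact by enumeration of
#' all group labelings of the observed pooled values (a permutation
#' null, so ties are handled exactly); otherwise a normal approximation
#' with tie correction and continuity correction is used. The p-value is
#' two-tailed on the distance of `U` from its null mean `n1 n2 / 2`.
#'
#' @param a,b numeric value vectors for the two groups.
#' @return List with `U` (for group `a`), `p`, and `method`.
#' @export
mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    warning("all values identical across both groups")
    return(list(U = n1 * n2 / 2, p = 1, method = "degenerate"))
  }
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  u <- u_stat(seq_len(n1))
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 12) {
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, u_stat)
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
    method <- "normal"
  }
  list(U = u, p = min(p, 1), method = method)
}

#' ROC area under the curve by the rank method
#'
#' Trapezoidal / midrank AUC: equals `U / (n1 n2)` where `U` is the
#' Mann-Whitney statistic of the positive-class scores, so tied scores
#' contribute 1/2.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary labels (1 = positive).
#' @return AUC in `[0, 1]`; 0.5 when either class is absent is an error
#'   instead.
#' @export
roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("both classes required for AUC")
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Area under the precision-recall curve
#'
#' Scores are swept from high to low (ties grouped); the area is the
#' trapezoid of precision over recall between successive attained
#' thresholds, starting from recall 0 at the precision of the first
#' threshold group.
#'
#' @inheritParams roc_auc
#' @return PRC area in `[0, 1]`.
#' @export
prc_auc <- function(scores, labels) {
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("both classes required for PRC area")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  rec <- prec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    sel <- scores >= thr[k]
    tp <- sum(labels[sel] == 1)
    rec[k] <- tp / npos
    prec[k] <- tp / sum(sel)
  }
  rec <- c(0, rec); prec <- c(prec[1], prec)
  sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' Hanley-McNeil comparison of two AUCs
#'
#' Standard error of an AUC by the 1982 closed form
#' `SE^2 = [A(1-A) + (n_pos - 1)(Q1 - A^2) + (n_neg - 1)(Q2 - A^2)] /
#' (n_pos n_neg)` with `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`,
#' and the z test `z = (A1 - A2) / sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2)`
#' for two AUCs measured on the same subjects with correlation term `r`
#' (0 for independent samples).
#'
#' @param a1,a2 the two AUCs in `[0, 1]`.
#' @param n_pos,n_neg class sizes (shared by both curves).
#' @param r_hm correlation term between the two AUC estimates, in
#'   `[-1, 1]`.
#' @return List with `a1`, `a2`, `se1`, `se2`, `z`, `p` (two-tailed
#'   normal).
#' @export
hanley_mcneil <- function(a1, n_pos, n_neg, a2, r_hm = 0) {
  stopifnot(a1 >= 0, a1 <= 1, a2 >= 0, a2 <= 1,
            n_pos >= 1, n_neg >= 1, r_hm >= -1, r_hm <= 1)
  se <- function(a) {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    sqrt((a * (1 - a) + (n_pos - 1) * (q1 - a^2) +
            (n_neg - 1) * (q2 - a^2)) / (n_pos * n_neg))
  }
  se1 <- se(a1); se2 <- se(a2)
  den2 <- se1^2 + se2^2 - 2 * r_hm * se1 * se2
  if (a1 == a2) {
    # equal AUCs compare as z = 0 even when the SE denominator vanishes
    return(list(a1 = a1, a2 = a2, se1 = se1, se2 = se2, z = 0, p = 1))
  }
  if (den2 <= 0) stop("comparison undefined: zero standard-error denominator")
  z <- (a1 - a2) / sqrt(den2)
  list(a1 = a1, a2 = a2, se1 = se1, se2 = se2, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Estimate the Hanley-McNeil correlation term from paired scores
#'
#' The intermediate correlation is taken as the average of the Pearson
#' correlations between the two classifiers' scores within the positive
#' and within the negative class, the usual plug-in for the tabled
#' `r` of the 1983 correlated-AUC method.
#'
#' @param s1,s2 score vectors of the two classifiers on the same
#'   subjects.
#' @param labels binary labels.
#' @return Estimated correlation term in `[-1, 1]`.
#' @export
estimate_r_hm <- function(s1, s2, labels) {
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  (safe_cor(s1[labels == 1], s2[labels == 1]) +
     safe_cor(s1[labels == 0], s2[labels == 0])) / 2
}
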