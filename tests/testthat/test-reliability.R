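test_that("perfect agreement gives ICC 1 and independence gives ICC near 0", {
  set.seed(17)
  x <- rnorm(20, 50, 10)
  expect_equal(compute_icc(x, x), 1)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(compute_icc(a, b)), 0.03)
})

test_that("ICC(2,1) matches the ANOVA mean-square oracle on small tables", {
  set.seed(18)
  for (case in 1:6) {
    x <- rnorm(6, 10, 3)
    y <- x + rnorm(6, 0.5, 1.2)
    expect_equal(compute_icc(x, y), icc_via_aov(x, y), tolerance = 1e-10)
  }
})

test_that("ICC is symmetric and invariant to a common affine transform", {
  set.seed(19)
  x <- rnorm(15, 100, 20); y <- x + rnorm(15, 0, 8)
  expect_equal(compute_icc(x, y), compute_icc(y, x))
  expect_equal(compute_icc(2.5 * x + 7, 2.5 * y + 7), compute_icc(x, y),
               tolerance = 1e-12)
})

test_that("zero between-subject variance yields ICC 0 with a warning", {
  expect_warning(v <- compute_icc(rep(5, 6), rep(5, 6)), "between-subject")
  expect_equal(v, 0)
})

test_that("Landis-Koch bands follow the stated cut points", {
  expect_equal(landis_koch_band(0.75), "substantial")
  expect_equal(landis_koch_band(0.90), "excellent")
  expect_equal(landis_koch_band(0.80), "substantial")  # upper bound inclusive
  expect_equal(landis_koch_band(0.61), "substantial")
  expect_equal(landis_koch_band(0.60), "poor/moderate")
  expect_equal(landis_koch_band(-0.2), "poor/moderate")
})

test_that("the reliability filter drops at ICC <= threshold and keeps above", {
  set.seed(20)
  n <- 30
  x <- rnorm(n, 0, 2)
  r1r1 <- cbind(f = x)
  r1r2 <- cbind(f = x + rnorm(n, 0, 1))
  r2r1 <- cbind(f = x + rnorm(n, 0, 1))
  inter <- compute_icc(r1r1[, 1], r2r1[, 1])
  intra <- compute_icc(r1r1[, 1], r1r2[, 1])
  worst <- min(inter, intra)
  # threshold exactly at the computed ICC: <= means drop
  rep_at <- reliability_filter(r1r1, r1r2, r2r1, threshold = worst)
  expect_equal(rep_at$verdict, "drop_icc")
  # threshold just below: keep
  rep_below <- reliability_filter(r1r1, r1r2, r2r1,
                                  threshold = worst - 1e-9)
  expect_equal(rep_below$verdict, "keep")
  expect_equal(rep_at$icc_inter, inter)
  expect_equal(rep_at$icc_intra, intra)
})

test_that("a feature with injected true ICC 0.3 is nearly always dropped", {
  # variance components: subject sd 1, reader noise sd sqrt(7/3) gives
  # ICC = 1 / (1 + 7/3) = 0.3
  set.seed(23)
  dropped <- replicate(200, {
    subj <- rnorm(58)
    noise_sd <- sqrt(7 / 3)
    r1r1 <- cbind(f = subj + rnorm(58, 0, noise_sd))
    r1r2 <- cbind(f = subj + rnorm(58, 0, noise_sd))
    r2r1 <- cbind(f = subj + rnorm(58, 0, noise_sd))
    reliability_filter(r1r1, r1r2, r2r1)$verdict == "drop_icc"
  })
  expect_gte(mean(dropped), 0.95)
})

test_that("the ICC filter separates stable from unstable feature groups", {
  # stable features: true ICC 0.9; unstable: true ICC 0.3; the filter
  # should drop the unstable (sensitivity) and keep the stable
  # (specificity), each at least 90% of the time over 200 cohorts
  set.seed(22)
  icc_to_sd <- function(icc) sqrt((1 - icc) / icc)
  res <- replicate(200, {
    subj <- rnorm(58)
    mk <- function() cbind(stable = subj + rnorm(58, 0, icc_to_sd(0.9)),
                           unstable = subj + rnorm(58, 0, icc_to_sd(0.3)))
    r1r1 <- mk(); r1r2 <- mk(); r2r1 <- mk()
    v <- reliability_filter(r1r1, r1r2, r2r1)$verdict
    c(dropped_unstable = v[2] == "drop_icc", kept_stable = v[1] == "keep")
  })
  expect_gte(mean(res["dropped_unstable", ]), 0.9)
  expect_gte(mean(res["kept_stable", ]), 0.9)
})

test_that("redundancy pruning keeps the higher-ICC member of a duplicate pair", {
  set.seed(24)
  x <- rnorm(20)
  tab <- cbind(A = x, B = x, C = rnorm(20))
  report <- data.frame(feature = c("A", "B", "C"),
                       icc_inter = c(0.9, 0.8, 0.7),
                       icc_intra = c(0.9, 0.8, 0.7),
                       band = "excellent", verdict = "keep",
                       partner = NA_character_, stringsAsFactors = FALSE)
  out <- redundancy_prune(tab, report)
  expect_equal(kept_features(out), c("A", "C"))
  expect_equal(out$verdict[out$feature == "B"], "drop_redundant")
  expect_equal(out$partner[out$feature == "B"], "A")
})

test_that("a pair exactly at the correlation threshold is kept whole", {
  set.seed(25)
  x <- rnorm(24)
  y <- 0.6 * scale(x)[, 1] + 0.8 * scale(resid(lm(rnorm(24) ~ x)))[, 1]
  r <- abs(cor(x, y))
  tab <- cbind(A = x, B = y)
  report <- data.frame(feature = c("A", "B"), icc_inter = c(0.9, 0.8),
                       icc_intra = c(0.9, 0.8), band = "excellent",
                       verdict = "keep", partner = NA_character_,
                       stringsAsFactors = FALSE)
  # threshold equal to the observed |r|: strict > means both kept
  out_at <- redundancy_prune(tab, report, r_threshold = r)
  expect_equal(kept_features(out_at), c("A", "B"))
  out_below <- redundancy_prune(tab, report, r_threshold = r - 1e-9)
  expect_equal(kept_features(out_below), "A")
})

test_that("the greedy sweep resolves correlation chains by reliability order", {
  # A-B and B-C redundant (r > 0.8), A-C not; ICC order A > B > C.
  # Hand trace of the greedy sweep: keep A; drop B against A; keep C.
  set.seed(26)
  n <- 5000
  target <- matrix(c(1, 0.85, 0.45, 0.85, 1, 0.85, 0.45, 0.85, 1), 3, 3)
  z <- matrix(rnorm(n * 3), n, 3) %*% chol(target)
  tab <- cbind(A = z[, 1], B = z[, 2], C = z[, 3])
  expect_gt(abs(cor(tab[, "A"], tab[, "B"])), 0.8)
  expect_gt(abs(cor(tab[, "B"], tab[, "C"])), 0.8)
  expect_lt(abs(cor(tab[, "A"], tab[, "C"])), 0.8)
  report <- data.frame(feature = c("A", "B", "C"),
                       icc_inter = c(0.95, 0.85, 0.75),
                       icc_intra = c(0.95, 0.85, 0.75),
                       band = "excellent", verdict = "keep",
                       partner = NA_character_, stringsAsFactors = FALSE)
  out <- redundancy_prune(tab, report, r_threshold = 0.8)
  expect_equal(kept_features(out), c("A", "C"))
  expect_equal(out$partner[out$feature == "B"], "A")
})

test_that("zero-variance features are dropped as degenerate with a warning", {
  tab <- cbind(A = rnorm(10), B = rep(3, 10))
  report <- data.frame(feature = c("A", "B"), icc_inter = c(0.9, 0.95),
                       icc_intra = c(0.9, 0.95), band = "excellent",
                       verdict = "keep", partner = NA_character_,
                       stringsAsFactors = FALSE)
  expect_warning(out <- redundancy_prune(tab, report), "zero-variance")
  expect_equal(kept_features(out), "A")
  expect_equal(out$verdict[out$feature == "B"], "drop_degenerate")
})

test_that("pruning on random tables always leaves a pairwise |r| <= 0.8 set", {
  set.seed(27)
  for (case in 1:5) {
    n <- 25; p <- 12
    base <- matrix(rnorm(n * 3), n, 3)
    tab <- base[, sample(3, p, replace = TRUE)] +
      matrix(rnorm(n * p, 0, 0.6), n, p)
    colnames(tab) <- paste0("F", seq_len(p))
    report <- data.frame(feature = colnames(tab),
                         icc_inter = runif(p, 0.6, 1),
                         icc_intra = runif(p, 0.6, 1),
                         band = "excellent", verdict = "keep",
                         partner = NA_character_, stringsAsFactors = FALSE)
    out <- redundancy_prune(tab, report)
    kept <- kept_features(out)
    expect_gt(length(kept), 0)
    cm <- abs(cor(tab[, kept, drop = FALSE]))
    expect_true(all(cm[upper.tri(cm)] <= 0.8))
    # rerun: identical kept set (determinism)
    expect_identical(kept_features(redundancy_prune(tab, report)), kept)
  }
})
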