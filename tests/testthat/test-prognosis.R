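make_cohort_xy <- function(n = 58, n_pos = 6, p = 4, sep = 0, seed = 1) {
  set.seed(seed)
  y <- integer(n); y[sample.int(n, n_pos)] <- 1L
  x <- matrix(rnorm(n * p), n, p)
  x[y == 1, ] <- x[y == 1, ] + sep
  colnames(x) <- paste0("F", seq_len(p))
  list(x = x, y = y)
}

test_that("stratified folds partition the cohort for every seed", {
  d <- make_cohort_xy()
  for (seed in 1:10) {
    fold <- stratified_folds(d$y, 10, seed)
    expect_equal(sort(unique(fold)), 1:10)
    expect_equal(length(fold), 58)
    # every fold has 5 or 6 non-events and at most 1 event
    expect_true(all(table(fold[d$y == 1]) <= 1))
    expect_true(all(table(fold) %in% 5:7))
  }
})

test_that("a perfectly separable feature yields pooled AUC 1 for every classifier", {
  d <- make_cohort_xy(sep = 50, seed = 2)
  for (cl in c("NaiveBayes", "J48", "RandomForest", "SMO", "ANN-MLP")) {
    cv <- run_crossval(d$x, d$y, classifier_spec(cl), k = 10, seed = 3)
    m <- pooled_metrics(cv)
    expect_equal(unname(m["auc"]), 1, tolerance = 1e-12)
  }
})

test_that("cross-validation is bit-reproducible given spec and seed", {
  d <- make_cohort_xy(sep = 1, seed = 4)
  for (cl in c("NaiveBayes", "RandomForest", "ANN-MLP")) {
    a <- run_crossval(d$x, d$y, classifier_spec(cl), seed = 7)
    b <- run_crossval(d$x, d$y, classifier_spec(cl), seed = 7)
    expect_identical(a$scores, b$scores)
    expect_identical(a$fold, b$fold)
  }
})

test_that("permuted labels give null-centred NaiveBayes AUC across seeds", {
  d <- make_cohort_xy(p = 3, sep = 0, seed = 5)
  aucs <- vapply(1:20, function(s) {
    set.seed(s + 100)
    yp <- sample(d$y)
    unname(pooled_metrics(run_crossval(d$x, yp, classifier_spec("NaiveBayes"),
                                       seed = s))["auc"])
  }, numeric(1))
  expect_gte(mean(aucs), 0.40)
  expect_lte(mean(aucs), 0.60)
})

test_that("held-out naive Bayes posteriors equal the closed-form values", {
  # 8 subjects, 1 feature, k = 2: each training split has 2 per class
  x <- matrix(c(0, 1.5, 2, 0.5, 8, 10.5, 9, 11), 8, 1,
              dimnames = list(NULL, "F"))
  y <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  fold <- stratified_folds(y, 2, seed = 1)
  for (f in 1:2) {
    te <- fold == f
    m <- nb_fit(x[!te, , drop = FALSE], y[!te])
    got <- nb_predict(m, x[te, , drop = FALSE])
    mu0 <- mean(x[!te & y == 0, ]); mu1 <- mean(x[!te & y == 1, ])
    sd0 <- sd(x[!te & y == 0, ]); sd1 <- sd(x[!te & y == 1, ])
    want <- vapply(x[te, ], function(v) {
      l1 <- dnorm(v, mu1, sd1) * 0.5
      l0 <- dnorm(v, mu0, sd0) * 0.5
      l1 / (l1 + l0)
    }, numeric(1))
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("our Gaussian naive Bayes matches e1071 posteriors", {
  skip_if_not_installed("e1071")
  d <- make_cohort_xy(n = 40, n_pos = 15, p = 3, sep = 0.8, seed = 6)
  m <- nb_fit(d$x, d$y)
  ref <- e1071::naiveBayes(d$x, factor(d$y, levels = c(0, 1)))
  got <- nb_predict(m, d$x)
  want <- predict(ref, d$x, type = "raw")[, "1"]
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
})

test_that("confusion metrics follow their definitions", {
  # pooled confusion TP 5, FN 1, TN 40, FP 12 via a crafted cv_result
  labels <- c(rep(1L, 6), rep(0L, 52))
  classes <- c(rep(1L, 5), 0L, rep(0L, 40), rep(1L, 12))
  scores <- classes + seq_along(classes) * 1e-4
  cv <- structure(list(scores = scores, classes = classes, labels = labels,
                       fold = rep(1:10, length.out = 58),
                       spec = classifier_spec("NaiveBayes"), seed = 1),
                  class = "cv_result")
  m <- pooled_metrics(cv)
  expect_equal(unname(m["TP"]), 5)
  expect_equal(unname(m["sensitivity"]), 5 / 6)
  expect_equal(unname(m["specificity"]), 40 / 52)
  expect_equal(unname(m["precision"]), 5 / 17)
  expect_equal(unname(m["recall"]), unname(m["sensitivity"]))
  f <- 2 * (5 / 17) * (5 / 6) / (5 / 17 + 5 / 6)
  expect_equal(unname(m["f_measure"]), f)
})

test_that("metric orientations exchange sensitivity and specificity", {
  d <- make_cohort_xy(sep = 1.5, seed = 8)
  cv <- run_crossval(d$x, d$y, classifier_spec("NaiveBayes"), seed = 9)
  m1 <- pooled_metrics(cv, positive_class = 1)
  m0 <- pooled_metrics(cv, positive_class = 0)
  expect_equal(unname(m1["sensitivity"]), unname(m0["specificity"]))
  expect_equal(unname(m1["specificity"]), unname(m0["sensitivity"]))
  # discrimination is orientation-symmetric: complementing both labels
  # and scores leaves the AUC unchanged
  expect_equal(unname(m1["auc"]), unname(m0["auc"]), tolerance = 1e-12)
})

test_that("ROC AUC equals the Mann-Whitney statistic scaled by n1 n2", {
  set.seed(10)
  scores <- c(rnorm(6, 1), rnorm(52))
  labels <- c(rep(1, 6), rep(0, 52))
  auc <- roc_auc(scores, labels)
  u <- mann_whitney(scores[labels == 1], scores[labels == 0])$U
  expect_equal(auc, u / (6 * 52), tolerance = 1e-12)
  expect_equal(roc_auc(rep(1, 58), labels), 0.5)  # all-tied convention
})

test_that("replicated cross-validation reports both orientations with intervals", {
  d <- make_cohort_xy(sep = 2, seed = 11)
  out <- cv_replicates(d$x, d$y, classifier_spec("NaiveBayes"), seed = 1,
                       seeds = 101:105)
  expect_setequal(unique(out$positive_class), c(0, 1))
  expect_true(all(out$lo <= out$mean & out$mean <= out$hi))
  auc1 <- out$mean[out$metric == "auc" & out$positive_class == 1]
  expect_gt(auc1, 0.8)
})
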