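#' Classifier specification
#'
#' The five classifiers of the evaluation suite, with the fixed
#' hyperparameter conventions:
#' \describe{
#'   \item{ANN-MLP}{single-hidden-layer perceptron with
#'     `floor((p + c) / 2)` hidden units for `p` features and `c = 2`
#'     classes ([nnet::nnet()]).}
#'   \item{J48}{pruned C4.5-style decision tree (CART via
#'     [rpart::rpart()], cost-complexity pruned).}
#'   \item{NaiveBayes}{Gaussian naive Bayes with per-feature
#'     class-conditional normals (implemented in this package, see
#'     [nb_fit()]).}
#'   \item{RandomForest}{bagged trees with feature subsampling
#'     ([randomForest::randomForest()]).}
#'   \item{SMO}{linear-kernel support-vector classifier
#'     ([e1071::svm()]).}
#' }
#'
#' @param name one of `"ANN-MLP"`, `"J48"`, `"NaiveBayes"`,
#'   `"RandomForest"`, `"SMO"`.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(name = c("NaiveBayes", "ANN-MLP", "J48",
                                     "RandomForest", "SMO")) {
  name <- match.arg(name)
  structure(list(name = name), class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec>", x$name, "\n")
  invisible(x)
}

# Fit `spec` on x (matrix) / y (0/1 integer) under `seed`; returns an
# object that score_classifier() can turn into positive-class scores.
fit_classifier <- function(spec, x, y, seed) {
  x <- as.matrix(x)
  yf <- factor(y, levels = c(0, 1))
  with_seed(seed, switch(
    spec$name,
    "NaiveBayes" = nb_fit(x, y),
    "ANN-MLP" = {
      size <- max(1, floor((ncol(x) + 2) / 2))
      nnet::nnet(x, class.ind(yf), size = size, softmax = TRUE,
                 maxit = 200, trace = FALSE,
                 MaxNWts = (ncol(x) + 1) * size + (size + 1) * 2 + 10)
    },
    "J48" = {
      df <- data.frame(x, .y = yf)
      # C4.5-like leaf sizes: rare-event cohorts need small buckets
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 4, minbucket = 2, xval = 10))
      cp <- fit$cptable
      best <- cp[which.min(cp[, "xerror"]), "CP"]
      rpart::prune(fit, cp = best)
    },
    "RandomForest" = randomForest::randomForest(x, yf, ntree = 500),
    "SMO" = e1071::svm(x, yf, kernel = "linear", scale = apply(x, 2, stats::sd) > 0)
  ))
}

class.ind <- function(f) {
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

# Positive-class score and hard class prediction on new data.
score_classifier <- function(spec, model, x) {
  x <- as.matrix(x)
  switch(
    spec$name,
    "NaiveBayes" = {
      s <- nb_predict(model, x)
      list(score = s, class = as.integer(s >= 0.5))
    },
    "ANN-MLP" = {
      p <- stats::predict(model, x)
      list(score = p[, "1"], class = as.integer(p[, "1"] >= 0.5))
    },
    "J48" = {
      p <- stats::predict(model, data.frame(x), type = "prob")
      list(score = p[, "1"], class = as.integer(p[, "1"] >= 0.5))
    },
    "RandomForest" = {
      p <- stats::predict(model, x, type = "prob")
      list(score = p[, "1"], class = as.integer(p[, "1"] >= 0.5))
    },
    "SMO" = {
      pr <- stats::predict(model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      s <- dv[, 1]
      # decision values point towards the first level of the pair name
      if (startsWith(colnames(dv)[1], "0")) s <- -s
      list(score = s, class = as.integer(as.character(pr)))
    })
}

#' Gaussian naive Bayes (reference implementation)
#'
#' Per-feature Gaussian class-conditionals with class priors from the
#' training frequencies; class-conditional standard deviations are
#' floored at a small fraction of the pooled standard deviation so
#' constant-in-class features stay usable.
#'
#' @param x numeric feature matrix.
#' @param y binary 0/1 labels.
#' @return A model for [nb_predict()].
#' @export
nb_fit <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(all(y %in% c(0, 1)), length(y) == nrow(x))
  stats_for <- function(cls) {
    xs <- x[y == cls, , drop = FALSE]
    list(mu = colMeans(xs),
         sd = apply(xs, 2, stats::sd))
  }
  pooled_sd <- apply(x, 2, stats::sd)
  floor_sd <- pmax(pooled_sd, 1e-9) * 1e-3
  s0 <- stats_for(0); s1 <- stats_for(1)
  s0$sd <- pmax(s0$sd, floor_sd, na.rm = TRUE)
  s1$sd <- pmax(s1$sd, floor_sd, na.rm = TRUE)
  list(prior1 = mean(y == 1), s0 = s0, s1 = s1)
}

#' @rdname nb_fit
#' @param model a fitted naive Bayes model.
#' @param newx numeric matrix of new observations.
#' @return Posterior probability of class 1 for each row of `newx`.
#' @export
nb_predict <- function(model, newx) {
  newx <- as.matrix(newx)
  loglik <- function(s) {
    ll <- vapply(seq_len(ncol(newx)), function(j) {
      stats::dnorm(newx[, j], s$mu[j], s$sd[j], log = TRUE)
    }, numeric(nrow(newx)))
    rowSums(matrix(ll, nrow = nrow(newx)))
  }
  l1 <- loglik(model$s1) + log(model$prior1)
  l0 <- loglik(model$s0) + log(1 - model$prior1)
  1 / (1 + exp(l0 - l1))
}
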