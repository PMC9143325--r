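# Classifier fit/score adapter. The pipeline's substance is the harness,
# metrics, applicability domain and alert mining; the learners themselves are
# consumed through this uniform contract: fit_classifier() returns an object
# whose score_classifier() yields P(toxicant) in [0, 1].

ALGORITHMS <- c("svm_rbf", "knn", "random_forest", "naive_bayes", "ann",
                "adaboost", "xgboost")

#' Classifier specification
#'
#' @param algorithm one of `"svm_rbf"`, `"knn"`, `"random_forest"`,
#'   `"naive_bayes"`, `"ann"`, `"adaboost"`, `"xgboost"`.
#' @param params named list of hyperparameters (one setting, not a grid):
#'   `svm_rbf`: `C`; `knn`: `k`; `random_forest`: `ntree`, `max_features`
#'   (`"sqrt"`/`"log2"`), depth capped at 4; `ann`: `size` (hidden units);
#'   `adaboost`: `n_estimators`; `xgboost`: `max_depth`,
#'   `min_child_weight`, optional `nrounds` (default 50); `naive_bayes`:
#'   none (provider defaults).
#' @param seed integer seed for stochastic learners.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm, params = list(), seed = 1) {
  if (!algorithm %in% ALGORITHMS)
    stopf("unknown algorithm '%s' (available: %s)", algorithm,
          paste(ALGORITHMS, collapse = ", "))
  structure(list(algorithm = algorithm, params = params, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  ps <- if (length(x$params))
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ") else "defaults"
  cat(sprintf("<classifier_spec> %s (%s)\n", x$algorithm, ps))
  invisible(x)
}

# Fit one classifier; X numeric matrix, y binary 0/1.
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("non-finite features reached the learner")
  if (length(unique(y)) < 2) stopf("training fold lost a class")
  p <- spec$params
  yf <- factor(y, levels = c(0, 1))
  fit <- with_seed(spec$seed, switch(spec$algorithm,
    svm_rbf = e1071::svm(x = X, y = yf, kernel = "radial",
                         cost = p$C %||% 1, probability = TRUE, scale = FALSE),
    knn = list(X = X, y = y, k = p$k %||% 5),
    random_forest = {
      mtry_fun <- switch(p$max_features %||% "sqrt",
                         sqrt = function(d) max(1, floor(sqrt(d))),
                         log2 = function(d) max(1, floor(log2(d))))
      randomForest::randomForest(x = X, y = yf, ntree = p$ntree %||% 100,
                                 mtry = mtry_fun(ncol(X)),
                                 maxnodes = 2^(p$max_depth %||% 4))
    },
    naive_bayes = e1071::naiveBayes(x = X, y = yf),
    ann = nnet::nnet(x = X, y = as.numeric(y), size = p$size %||% 50,
                     decay = p$decay %||% 1e-4, maxit = p$maxit %||% 150,
                     MaxNWts = 1e6, trace = FALSE),
    adaboost = fit_adaboost(X, y, n_estimators = p$n_estimators %||% 100),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = p$max_depth %||% 4,
                    min_child_weight = p$min_child_weight %||% 1,
                    eta = p$eta %||% 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
      nrounds = p$nrounds %||% 50, verbose = 0)
  ))
  structure(list(algorithm = spec$algorithm, fit = fit, seed = spec$seed,
                 features = colnames(X)),
            class = "fitted_classifier")
}

# Score P(positive class) on new rows.
score_classifier <- function(object, X) {
  stopifnot(inherits(object, "fitted_classifier"))
  X <- as.matrix(X)
  s <- with_seed(object$seed, switch(object$algorithm,
    svm_rbf = {
      pr <- attr(stats::predict(object$fit, X, probability = TRUE), "probabilities")
      pr[, "1"]
    },
    knn = {
      pred <- class::knn(object$fit$X, X, factor(object$fit$y, levels = c(0, 1)),
                         k = min(object$fit$k, nrow(object$fit$X)), prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    random_forest = stats::predict(object$fit, X, type = "prob")[, "1"],
    naive_bayes = stats::predict(object$fit, X, type = "raw")[, "1"],
    ann = as.numeric(stats::predict(object$fit, X)),
    adaboost = predict_adaboost(object$fit, X),
    xgboost = stats::predict(object$fit, xgboost::xgb.DMatrix(X, nthread = 1))
  ))
  pmin(1, pmax(0, as.numeric(s)))
}

# --- AdaBoost.M1 (discrete, SAMME with 2 classes) on rpart stumps.
# No installed package provides AdaBoost, so the boosting loop is authored
# here; the weak learner is an rpart depth-1 tree fitted with case weights.
fit_adaboost <- function(X, y, n_estimators = 100) {
  n <- nrow(X)
  ys <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  df <- data.frame(X, check.names = FALSE)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0, maxsurrogate = 0,
                               usesurrogate = 0)
  for (m in seq_len(n_estimators)) {
    df$.y <- factor(ys, levels = c(-1, 1))
    stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = ctrl)
    pred <- ifelse(stats::predict(stump, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != ys])
    if (err >= 0.5) break                      # weak learner no better than chance
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ys * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break                    # perfect stump: margin saturated
  }
  if (!length(stumps)) {                       # fall back to the class prior
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y))
}

predict_adaboost <- function(model, X) {
  if (!length(model$stumps)) return(rep(model$prior, nrow(X)))
  df <- data.frame(X, check.names = FALSE)
  margin <- rep(0, nrow(X))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(stats::predict(model$stumps[[m]], df, type = "class") == "1", 1, -1)
    margin <- margin + model$alphas[m] * pred
  }
  1 / (1 + exp(-2 * margin))                   # logistic link on the boosted margin
}
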