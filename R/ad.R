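# Euclidean-distance applicability domain. Reliability of a QSAR prediction
# is tied to how close a query sits to the training data in the (normalized)
# feature space of the selected model.

#' Fit a Euclidean-distance applicability domain
#'
#' For every training row the leave-one-out nearest-neighbor Euclidean
#' distance is computed; the AD threshold is the `percentile` quantile of
#' these distances (default 0.95). A query is inside the domain when its
#' distance to the nearest training row (self-matches allowed, so training
#' rows are always inside) does not exceed the threshold. A centroid-distance
#' variant is available via `method = "centroid"`: distances to the training
#' centroid, thresholded at the same percentile.
#'
#' @param train_features numeric matrix of training features (>= 3 rows,
#'   finite), normally the min-max normalized block of the selected model.
#' @param percentile quantile of the reference distances (default 0.95).
#' @param method `"nn"` (leave-one-out nearest neighbor, default) or
#'   `"centroid"`.
#' @return object of class `ad_model`: `reference`, `threshold`,
#'   `percentile`, `method`.
#' @export
fit_ad <- function(train_features, percentile = 0.95, method = c("nn", "centroid")) {
  method <- match.arg(method)
  X <- as.matrix(train_features)
  if (nrow(X) < 3) stopf("applicability domain needs >= 3 training rows")
  if (!all(is.finite(X))) stopf("features must be finite")
  if (!(percentile > 0 && percentile <= 1)) stopf("percentile must be in (0, 1]")
  if (method == "nn") {
    d <- as.matrix(stats::dist(X))
    diag(d) <- Inf
    ref_dist <- apply(d, 1, min)
  } else {
    ctr <- colMeans(X)
    ref_dist <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  }
  threshold <- unname(stats::quantile(ref_dist, percentile, type = 7))
  structure(list(reference = X, threshold = threshold, percentile = percentile,
                 method = method, reference_distances = unname(ref_dist)),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("<ad_model> %s, %d reference rows, %d features, threshold %.4g (percentile %.2f)\n",
              x$method, nrow(x$reference), ncol(x$reference), x$threshold, x$percentile))
  invisible(x)
}

#' Assess compounds against an applicability domain
#'
#' @param object a fitted `ad_model`.
#' @param newdata numeric matrix (or single vector) with the reference
#'   dimensionality.
#' @param ... unused.
#' @return data.frame with columns `distance` and `inside` (distance <=
#'   threshold; boundary counts as inside).
#' @export
predict.ad_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != ncol(object$reference))
    stopf("dimension mismatch: %d features vs %d in the reference", ncol(X),
          ncol(object$reference))
  if (object$method == "nn") {
    # per-query difference form: exact zeros for self-matches (the expanded
    # quadratic form leaves ~1e-8 residues on identical rows)
    tref <- t(object$reference)
    dist <- apply(X, 1, function(x) sqrt(min(colSums((tref - x)^2))))
  } else {
    ctr <- colMeans(object$reference)
    dist <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  }
  data.frame(distance = as.numeric(dist),
             inside = as.numeric(dist) <= object$threshold,
             row.names = rownames(X))
}

#' Applicability-domain coverage report
#'
#' @param object a fitted `ad_model`.
#' @param X feature matrix to assess.
#' @param labels optional binary labels for per-class inside/outside counts.
#' @return `list(n, n_inside, n_outside, coverage_pct, per_class)`;
#'   `coverage_pct` is `100 * n_inside / n` rounded to 1 decimal place.
#' @examples
#' ad <- fit_ad(matrix(seq(0, 9), ncol = 1))
#' ad_coverage(ad, matrix(c(1, 2, 100), ncol = 1))$coverage_pct
#' @export
ad_coverage <- function(object, X, labels = NULL) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (nrow(X) == 0) stopf("empty assessment set")
  res <- predict(object, X)
  per_class <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(X))
    per_class <- data.frame(
      class = c("P", "N"),
      inside = c(sum(res$inside & labels == 1), sum(res$inside & labels == 0)),
      outside = c(sum(!res$inside & labels == 1), sum(!res$inside & labels == 0)))
  }
  list(n = nrow(X), n_inside = sum(res$inside), n_outside = sum(!res$inside),
       coverage_pct = round_half_up(100 * mean(res$inside), 1),
       per_class = per_class)
}
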