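#' SMOTE: synthetic minority oversampling
#'
#' Balances a binary training set by synthesizing minority-class points on
#' the segments joining each minority point to one of its `k` nearest
#' minority neighbors (Euclidean): \eqn{x_{new} = x + u (x_{nn} - x)} with
#' \eqn{u \sim U(0, 1)}. Original rows are preserved, ordered first;
#' synthetic rows are appended until the minority/majority ratio reaches
#' `target_ratio`. Majority rows are never altered or duplicated.
#'
#' @param X numeric feature matrix (finite values).
#' @param y binary labels in `{0, 1}`, length `nrow(X)`.
#' @param k_neighbors neighbors considered per minority point (default 5);
#'   reduced with a warning when the minority class is smaller than `k + 1`.
#' @param target_ratio minority/majority ratio to reach (default 1, full
#'   balance); must lie in (0, 1].
#' @param seed integer seed; fixed seed gives identical output.
#' @return `list(X, y, n_synthetic)`; rows `1:nrow(X_input)` of the output
#'   equal the input.
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(10, 3), 5))
#' res <- smote_oversample(X, rep(c(0, 1), c(20, 5)), seed = 1)
#' table(res$y)
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, target_ratio = 1, seed = 1) {
  X <- as.matrix(X)
  if (!all(y %in% c(0, 1))) stopf("labels must be binary 0/1")
  if (length(y) != nrow(X)) stopf("X and y sizes differ")
  if (!all(is.finite(X))) stopf("features must be finite for SMOTE")
  if (!(target_ratio > 0 && target_ratio <= 1)) stopf("target_ratio must be in (0, 1]")
  if (k_neighbors < 1) stopf("k_neighbors must be >= 1")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  minority <- if (n1 <= n0) 1 else 0
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  n_target <- floor(target_ratio * n_maj)
  n_new <- n_target - n_min
  if (n_new <= 0) return(list(X = X, y = y, n_synthetic = 0L))
  if (n_min < 2) stopf("minority class needs >= 2 members to interpolate")
  if (k_neighbors >= n_min) {
    warnf("k_neighbors reduced from %d to %d (minority size %d)",
          k_neighbors, n_min - 1, n_min)
    k_neighbors <- n_min - 1
  }
  Xm <- X[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn_idx <- do.call(rbind, lapply(seq_len(n_min), function(i)
    order(d[i, ])[seq_len(k_neighbors)]))
  synth <- with_seed(seed, {
    base <- sample(rep_len(seq_len(n_min), n_new))
    nn_pick <- nn_idx[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    Xm[base, , drop = FALSE] + u * (Xm[nn_pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  })
  rownames(synth) <- if (!is.null(rownames(X)))
    sprintf("synthetic%d", seq_len(n_new)) else NULL
  list(X = rbind(X, synth),
       y = c(y, rep(minority, n_new)),
       n_synthetic = as.integer(n_new))
}
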