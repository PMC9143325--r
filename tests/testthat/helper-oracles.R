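# Independent brute-force oracles and tiny fixture builders used across the
# suite. Each oracle is written from first principles and never calls the
# package code path it is checking.

# Entropy-based information gain from an explicit 2x2 contingency table.
brute_ig <- function(frag, y) {
  h <- function(cnt) {
    n <- sum(cnt)
    if (n == 0) return(0)
    p <- cnt[cnt > 0] / n
    -sum(p * log2(p))
  }
  n <- length(y)
  tot <- h(c(sum(y == 0), sum(y == 1)))
  cond <- 0
  for (v in c(0, 1)) {
    sel <- frag == v
    cond <- cond + sum(sel) / n * h(c(sum(y[sel] == 0), sum(y[sel] == 1)))
  }
  tot - cond
}

# AUC by explicit enumeration of all (positive, negative) pairs.
brute_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Metrics recomputed directly from prediction vectors.
brute_metrics <- function(y, yhat) {
  tp <- sum(y == 1 & yhat == 1); tn <- sum(y == 0 & yhat == 0)
  fp <- sum(y == 0 & yhat == 1); fn <- sum(y == 1 & yhat == 0)
  den <- sqrt(fp + tn) * sqrt(fp + tp) * sqrt(fn + tn) * sqrt(fn + tp)
  list(ACC = (tp + tn) / length(y),
       SE = if (tp + fn > 0) tp / (tp + fn) else NA,
       SP = if (tn + fp > 0) tn / (tn + fp) else NA,
       MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# TRUE when point s lies on the segment between some pair of rows of pts
# (triangle degeneracy: d(a,s) + d(s,b) == d(a,b)).
on_some_segment <- function(s, pts, tol = 1e-9) {
  d_to <- sqrt(colSums((t(pts) - s)^2))
  for (a in seq_len(nrow(pts) - 1)) {
    for (b in (a + 1):nrow(pts)) {
      dab <- sqrt(sum((pts[a, ] - pts[b, ])^2))
      if (abs(d_to[a] + d_to[b] - dab) < tol) return(TRUE)
    }
  }
  FALSE
}

# Minimum Euclidean distance from each row of X to any row of ref.
brute_min_dist <- function(X, ref) {
  apply(X, 1, function(x) min(sqrt(colSums((t(ref) - x)^2))))
}

toy_block <- function(mat, kind = "continuous", name = "toy") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("m%d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("f%d", seq_len(ncol(mat)))
  feature_block(name, kind, mat)
}

toy_dataset <- function(n = 10, labels = rep(c(1, 0), length.out = n)) {
  ditp_dataset(sprintf("m%d", seq_len(n)), rep(NA_character_, n), labels,
               validate_smiles = FALSE)
}

write_temp_csv <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
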