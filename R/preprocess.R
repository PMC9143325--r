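# Descriptor streamlining and min-max normalization, fit on training rows
# only. Binary fingerprint columns pass through untouched by default; the
# filters and the (x - min) / (max - min) rescaling apply to continuous
# columns.

#' Fit the feature preprocessor on training data
#'
#' Removal order on continuous columns: (1) columns containing non-finite
#' values or magnitudes above `extreme_limit`; (2) zero-variance columns;
#' (3) for each pair with |Pearson r| > `corr_threshold`, the later column in
#' block order (greedy scan in column order). Per-survivor training min/max
#' are then recorded for min-max normalization. Binary columns are kept as-is
#' unless `drop_constant_bits = TRUE`, which removes zero-variance bits.
#'
#' @param block a [feature_block()] of training molecules only.
#' @param corr_threshold absolute Pearson correlation above which the later
#'   column of a pair is dropped (default 0.95).
#' @param extreme_limit magnitude above which a value counts as extreme
#'   (default `1e8`).
#' @param drop_constant_bits also drop zero-variance binary columns.
#' @return object of class `preprocessor` with elements `kept` (ordered
#'   column names), `min`/`max` per continuous survivor, `dropped` (named by
#'   reason), `source_block`.
#' @export
fit_preprocessor <- function(block, corr_threshold = 0.95, extreme_limit = 1e8,
                             drop_constant_bits = FALSE) {
  stopifnot(inherits(block, "feature_block"))
  m <- block$matrix
  kinds <- block$kinds
  cont <- which(kinds == "continuous")
  bin <- which(kinds == "binary")
  dropped <- list(extreme = character(0), constant = character(0),
                  correlated = character(0))

  keep_cont <- cont
  if (length(cont)) {
    bad <- cont[vapply(cont, function(j) {
      x <- m[, j]
      any(!is.finite(x)) || any(abs(x) > extreme_limit)
    }, TRUE)]
    dropped$extreme <- colnames(m)[bad]
    keep_cont <- setdiff(keep_cont, bad)
    const <- keep_cont[vapply(keep_cont, function(j) stats::var(m[, j]) == 0, TRUE)]
    dropped$constant <- colnames(m)[const]
    keep_cont <- setdiff(keep_cont, const)
    if (length(keep_cont) > 1) {
      cm <- abs(suppressWarnings(stats::cor(m[, keep_cont, drop = FALSE])))
      drop_flag <- rep(FALSE, length(keep_cont))
      for (a in seq_along(keep_cont)) {
        if (drop_flag[a]) next
        for (b in seq_along(keep_cont)) {
          if (b <= a || drop_flag[b]) next
          if (isTRUE(cm[a, b] > corr_threshold)) drop_flag[b] <- TRUE
        }
      }
      dropped$correlated <- colnames(m)[keep_cont[drop_flag]]
      keep_cont <- keep_cont[!drop_flag]
    }
  }
  keep_bin <- bin
  if (drop_constant_bits && length(bin)) {
    const_bits <- bin[vapply(bin, function(j) stats::var(m[, j]) == 0, TRUE)]
    dropped$constant <- c(dropped$constant, colnames(m)[const_bits])
    keep_bin <- setdiff(bin, const_bits)
  }
  keep <- sort(c(keep_cont, keep_bin))
  if (!length(keep)) stopf("preprocessing removed every feature")
  mins <- maxs <- stats::setNames(rep(NA_real_, length(keep)), colnames(m)[keep])
  for (j in seq_along(keep)) {
    if (kinds[keep[j]] == "continuous") {
      mins[j] <- min(m[, keep[j]]); maxs[j] <- max(m[, keep[j]])
    }
  }
  structure(list(kept = colnames(m)[keep], kinds = kinds[keep],
                 min = mins, max = maxs, dropped = dropped,
                 corr_threshold = corr_threshold, extreme_limit = extreme_limit,
                 source_block = block$name),
            class = "preprocessor")
}

#' @export
print.preprocessor <- function(x, ...) {
  cat(sprintf("<preprocessor> '%s': %d features kept (dropped: %d extreme, %d constant, %d correlated)\n",
              x$source_block, length(x$kept), length(x$dropped$extreme),
              length(x$dropped$constant), length(x$dropped$correlated)))
  invisible(x)
}

#' Apply a fitted preprocessor
#'
#' Continuous survivors are rescaled by `(x - min) / (max - min)` with the
#' *training* extremes; values outside the training range (external data)
#' are clipped to `[0, 1]` and counted. Binary survivors pass through.
#'
#' @param object a fitted `preprocessor`.
#' @param newdata a [feature_block()] containing all kept features.
#' @param ... unused.
#' @return a [feature_block()] restricted to kept features, with attribute
#'   `"clipped"` = number of clipped values.
#' @export
predict.preprocessor <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "feature_block"))
  missing <- setdiff(object$kept, colnames(newdata$matrix))
  if (length(missing))
    stopf("block '%s' is missing kept feature(s): %s", newdata$name,
          paste(utils::head(missing, 5), collapse = ", "))
  m <- newdata$matrix[, object$kept, drop = FALSE]
  clipped <- 0L
  for (j in seq_along(object$kept)) {
    if (object$kinds[j] != "continuous") next
    lo <- object$min[j]; hi <- object$max[j]
    x <- (m[, j] - lo) / (hi - lo)
    clipped <- clipped + sum(x < 0 | x > 1)
    m[, j] <- pmin(1, pmax(0, x))
  }
  out <- feature_block(newdata$name, newdata$kind, m, kinds = object$kinds)
  attr(out, "clipped") <- clipped
  out
}

#' Serialize / restore a preprocessor
#'
#' @param object a `preprocessor`.
#' @param path JSON file path.
#' @return `write_preprocessor` returns `path` invisibly;
#'   `read_preprocessor` returns the restored `preprocessor`.
#' @export
write_preprocessor <- function(object, path) {
  stopifnot(inherits(object, "preprocessor"))
  jsonlite::write_json(unclass(object), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_preprocessor
#' @export
read_preprocessor <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$min <- stats::setNames(as.numeric(x$min), x$kept)
  x$max <- stats::setNames(as.numeric(x$max), x$kept)
  structure(x, class = "preprocessor")
}
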