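# Structural-alert mining: rank substructure fragments by the information
# gain their presence/absence yields about the toxicity label, and keep those
# enriched in toxicants by the class-frequency ratio.

#' Information gain of a fragment for the class variable
#'
#' \deqn{IG = Ent(D) - \sum_{V \in \{0,1\}} \frac{|D^V|}{|D|} Ent(D^V)}
#' with base-2 entropies \eqn{Ent(D) = -\sum_k P_k \log_2 P_k} over the class
#' prior, and \eqn{D^V} the subset of compounds with fragment value `V`. An
#' empty partition contributes 0; \eqn{0 \log 0 = 0}.
#'
#' @param fragment_column binary presence vector.
#' @param labels binary class vector (both classes present).
#' @return information gain in bits, in `[0, Ent(D)]`.
#' @examples
#' information_gain(c(1, 1, 0, 0), c(1, 1, 0, 0))  # perfect split: Ent(D) = 1
#' @export
information_gain <- function(fragment_column, labels) {
  if (length(fragment_column) != length(labels)) stopf("length mismatch")
  if (!all(fragment_column %in% c(0, 1)) || !all(labels %in% c(0, 1)))
    stopf("fragment values and labels must be binary 0/1")
  ent <- function(y) {
    if (!length(y)) return(0)
    p <- tabulate(y + 1L, 2L) / length(y)
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
  n <- length(labels)
  cond <- sum(vapply(c(0, 1), function(v) {
    sel <- fragment_column == v
    sum(sel) / n * ent(labels[sel])
  }, 1))
  ig <- ent(labels) - cond
  max(ig, 0)  # clip the occasional -1e-16 from floating-point cancellation
}

#' Class-enrichment frequency of a fragment
#'
#' \deqn{freq_P = \frac{N_{fragment\_P} \cdot N_{total}}{N_{fragment\_total} \cdot N_P}}
#' the ratio of the fragment's prevalence among toxicants to its overall
#' prevalence; 1 means no enrichment, > 1 enrichment in toxicants. The
#' non-toxicant frequency is the same expression with non-toxicant counts.
#'
#' @param n_fragment_P compounds containing the fragment within the positive
#'   class.
#' @param n_total dataset size.
#' @param n_fragment_total compounds containing the fragment (> 0).
#' @param n_P positive-class size (> 0).
#' @return the enrichment frequency (non-negative).
#' @export
fragment_frequency <- function(n_fragment_P, n_total, n_fragment_total, n_P) {
  if (n_fragment_total <= 0 || n_P <= 0) stopf("zero denominator in fragment frequency")
  (n_fragment_P * n_total) / (n_fragment_total * n_P)
}

#' Mine structural alerts from a binary fragment block
#'
#' Computes per-fragment occurrence counts, information gain and class
#' frequencies, keeps fragments occurring more than `min_occurrences - 1`
#' times (default: strictly more than 6) whose toxicant frequency exceeds the
#' non-toxicant frequency, and ranks by information gain (ties: `freq_P`
#' descending, then fragment id).
#'
#' @param fragments binary [feature_block()] (e.g. an imported Klekota-Roth
#'   table or a [smarts_block()]).
#' @param labels binary class vector aligned with the block rows.
#' @param min_occurrences minimum dataset-wide occurrence count (default 7,
#'   i.e. "more than six times").
#' @param top_n optional cap on the number of reported alerts.
#' @param smarts optional named vector mapping fragment ids to SMARTS labels.
#' @return object of class `alert_report`: a data.frame with columns
#'   `fragment_id`, `smarts`, `n_fragment_total`, `n_fragment_P`, `ig`,
#'   `freq_P`, `freq_N`, ranked; attribute `"settings"` records the filters.
#'   No fragment passing the filters yields an empty report (not an error).
#' @export
mine_alerts <- function(fragments, labels, min_occurrences = 7, top_n = NULL,
                        smarts = NULL) {
  stopifnot(inherits(fragments, "feature_block"))
  m <- fragments$matrix
  if (!is_binary01(m)) stopf("alert mining requires a binary block")
  if (length(labels) != nrow(m)) stopf("labels must align with block rows")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stopf("labels must be binary with both classes present")
  n_total <- nrow(m); n_P <- sum(labels == 1); n_N <- n_total - n_P
  occ <- colSums(m)
  occ_P <- colSums(m[labels == 1, , drop = FALSE])
  keep <- which(occ >= min_occurrences)
  stats_df <- data.frame(
    fragment_id = colnames(m)[keep],
    n_fragment_total = as.integer(occ[keep]),
    n_fragment_P = as.integer(occ_P[keep]),
    stringsAsFactors = FALSE)
  stats_df$ig <- vapply(keep, function(j) information_gain(m[, j], labels), 1)
  stats_df$freq_P <- vapply(keep, function(j)
    fragment_frequency(occ_P[j], n_total, occ[j], n_P), 1)
  stats_df$freq_N <- vapply(keep, function(j)
    fragment_frequency(occ[j] - occ_P[j], n_total, occ[j], n_N), 1)
  stats_df <- stats_df[stats_df$freq_P > stats_df$freq_N, , drop = FALSE]
  ord <- order(-stats_df$ig, -stats_df$freq_P, stats_df$fragment_id)
  stats_df <- stats_df[ord, , drop = FALSE]
  if (!is.null(top_n)) stats_df <- utils::head(stats_df, top_n)
  stats_df$smarts <- if (is.null(smarts)) rep(NA_character_, nrow(stats_df))
                     else as.character(smarts[stats_df$fragment_id])
  rownames(stats_df) <- NULL
  stats_df <- stats_df[, c("fragment_id", "smarts", "n_fragment_total",
                           "n_fragment_P", "ig", "freq_P", "freq_N")]
  structure(stats_df,
            class = c("alert_report", "data.frame"),
            settings = list(min_occurrences = min_occurrences, top_n = top_n,
                            n_total = n_total, n_P = n_P))
}

#' @export
print.alert_report <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf("<alert_report> %d alert(s) (occurrence >= %d, freq_P > freq_N; n = %d, %d toxicants)\n",
              nrow(x), s$min_occurrences, s$n_total, s$n_P))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  invisible(x)
}
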