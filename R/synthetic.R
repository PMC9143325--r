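# Seeded synthetic datasets with the statistical structure the analysis
# assumes: binary fragment matrices with planted toxicant-enriched "alert"
# bits, a continuous descriptor block with class mean-shifts, configurable
# imbalance and label noise. Ground truth travels with the data so
# parameter-recovery tests are one-liners.

#' Synthetic dataset specification
#'
#' Defaults mirror the study conditions: 225 molecules at positive fraction
#' 0.41 (93/225 toxicants), a fragment block with a few strongly enriched
#' alert bits over sparse background bits, and a small descriptor block.
#'
#' @param n_molecules dataset size (>= 10).
#' @param positive_fraction toxicant fraction (default 0.41).
#' @param n_fragment_bits fragment-block width (default 200).
#' @param planted_alerts data.frame/list with `bit`, `p_pos`, `p_neg`: bit
#'   index (1-based, distinct, <= width), Bernoulli presence probability in
#'   each class. Default: 3 alerts at 0.8/0.1.
#' @param background_bit_probability presence probability of non-alert bits
#'   in both classes (default 0.1).
#' @param n_descriptors descriptor-block width (default 10).
#' @param descriptor_effect_sizes per-descriptor class mean-shift in sd
#'   units (recycled; default 1.5).
#' @param label_noise label flip probability (default 0).
#' @param seed integer seed.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 225, positive_fraction = 0.41,
                           n_fragment_bits = 200,
                           planted_alerts = data.frame(bit = 1:3, p_pos = 0.8,
                                                       p_neg = 0.1),
                           background_bit_probability = 0.1,
                           n_descriptors = 10,
                           descriptor_effect_sizes = 1.5,
                           label_noise = 0, seed = 1) {
  planted_alerts <- as.data.frame(planted_alerts)
  stopifnot(n_molecules >= 10,
            positive_fraction > 0, positive_fraction < 1,
            all(c("bit", "p_pos", "p_neg") %in% names(planted_alerts)) ||
              nrow(planted_alerts) == 0,
            background_bit_probability >= 0, background_bit_probability <= 1,
            label_noise >= 0, label_noise <= 1)
  if (nrow(planted_alerts)) {
    stopifnot(!anyDuplicated(planted_alerts$bit),
              all(planted_alerts$bit >= 1 & planted_alerts$bit <= n_fragment_bits),
              all(planted_alerts$p_pos >= 0 & planted_alerts$p_pos <= 1),
              all(planted_alerts$p_neg >= 0 & planted_alerts$p_neg <= 1))
  }
  structure(list(n_molecules = n_molecules, positive_fraction = positive_fraction,
                 n_fragment_bits = n_fragment_bits, planted_alerts = planted_alerts,
                 background_bit_probability = background_bit_probability,
                 n_descriptors = n_descriptors,
                 descriptor_effect_sizes = rep_len(descriptor_effect_sizes,
                                                   n_descriptors),
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labeled feature dataset
#'
#' Labels are Bernoulli(`positive_fraction`) (resampled, bounded, if a class
#' comes out empty); planted bits are Bernoulli at class-specific
#' probabilities, background bits at the background probability in both
#' classes; descriptors are unit-variance Gaussians whose positive-class
#' means are shifted by the effect sizes; label noise flips labels after
#' feature generation, so at noise > 0 the features carry information about
#' the *pre-flip* labels only.
#'
#' @param spec a [synthetic_spec()].
#' @return `list(dataset, fragments, descriptors, ground_truth)`: a
#'   [ditp_dataset()] stub (ids + labels, no SMILES), a binary and a
#'   continuous [feature_block()], and the ground-truth record (planted bits,
#'   theoretical enrichment `freq_P` from expected counts, effect sizes,
#'   pre-noise labels).
#' @examples
#' d <- generate_feature_dataset(synthetic_spec(n_molecules = 50, seed = 7))
#' table(d$dataset$label)
#' @export
generate_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_molecules
    y <- NULL
    for (i in 1:100) {
      y <- stats::rbinom(n, 1, spec$positive_fraction)
      if (length(unique(y)) == 2) break
    }
    if (length(unique(y)) < 2) stopf("could not draw both classes in 100 tries")
    ids <- sprintf("syn%04d", seq_len(n))
    p_bit <- matrix(spec$background_bit_probability, n, spec$n_fragment_bits)
    if (nrow(spec$planted_alerts)) {
      for (j in seq_len(nrow(spec$planted_alerts))) {
        a <- spec$planted_alerts[j, ]
        p_bit[, a$bit] <- ifelse(y == 1, a$p_pos, a$p_neg)
      }
    }
    frag <- matrix(stats::rbinom(n * spec$n_fragment_bits, 1, as.vector(p_bit)),
                   n, spec$n_fragment_bits,
                   dimnames = list(ids, sprintf("frag%03d", seq_len(spec$n_fragment_bits))))
    shift <- spec$descriptor_effect_sizes
    desc <- matrix(stats::rnorm(n * spec$n_descriptors), n, spec$n_descriptors,
                   dimnames = list(ids, sprintf("desc%02d", seq_len(spec$n_descriptors))))
    desc <- desc + outer(y, shift)
    y_true <- y
    if (spec$label_noise > 0) {
      flip <- stats::rbinom(n, 1, spec$label_noise) == 1
      y[flip] <- 1L - y[flip]
      if (length(unique(y)) < 2) stopf("label noise erased a class; lower label_noise")
    }
    # theoretical enrichment of each planted bit under expected counts (the
    # fragment-frequency formula evaluated at population quantities)
    pf <- spec$positive_fraction
    gt_freq <- if (nrow(spec$planted_alerts))
      with(spec$planted_alerts,
           (p_pos * pf) / (p_pos * pf + p_neg * (1 - pf))) / pf
      else numeric(0)
    list(
      dataset = ditp_dataset(ids, rep(NA_character_, n), y, validate_smiles = FALSE),
      fragments = feature_block("synthetic_fragments", "binary", frag),
      descriptors = feature_block("synthetic_descriptors", "continuous", desc),
      ground_truth = list(
        planted_bits = if (nrow(spec$planted_alerts))
          sprintf("frag%03d", spec$planted_alerts$bit) else character(0),
        theoretical_freq_P = gt_freq,
        descriptor_effect_sizes = spec$descriptor_effect_sizes,
        labels_pre_noise = y_true))
  })
}

#' Hand-validated SMILES fixture
#'
#' A fixed list of 24 simple, hand-checked molecules (alkanes, alcohols,
#' aromatics, amides, a beta-lactam-like ring, ...) with fixed labels, for
#' featurizer smoke tests. Repeated calls return the identical fixture.
#'
#' @param n number of molecules, 4..24 (default 24).
#' @return a [ditp_dataset()].
#' @export
generate_smiles_fixture <- function(n = 24) {
  fixture <- data.frame(
    id = c("methane", "ethylamine", "ethane", "acetamide", "propane",
           "phenol", "butane", "aniline", "isobutane", "ethanol",
           "aceticacid", "acetone", "dimethylether", "benzene", "toluene",
           "pyridine", "furan", "thiophene", "acetanilide", "benzamide",
           "betalactam", "nitrobenzene", "cyclohexane", "piperidine"),
    smiles = c("C", "CCN", "CC", "CC(N)=O", "CCC",
               "Oc1ccccc1", "CCCC", "Nc1ccccc1", "CC(C)C", "CCO",
               "CC(=O)O", "CC(C)=O", "COC", "c1ccccc1", "Cc1ccccc1",
               "c1ccncc1", "c1ccoc1", "c1ccsc1",
               "CC(=O)Nc1ccccc1", "NC(=O)c1ccccc1", "O=C1CCN1",
               "O=[N+]([O-])c1ccccc1", "C1CCCCC1", "C1CCNCC1"),
    label = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
              0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 1L),
    stringsAsFactors = FALSE)
  if (n < 4 || n > nrow(fixture))
    stopf("fixture size must be between 4 and %d", nrow(fixture))
  out <- fixture[seq_len(n), ]
  ditp_dataset(out$id, out$smiles, out$label, validate_smiles = FALSE)
}

#' Write a synthetic dataset in the CSV schema read_dataset() reads
#'
#' Allows synthetic runs to exercise the real I/O path; SMILES are filled
#' with a placeholder valid molecule when the dataset is a feature stub.
#'
#' @param ds a [ditp_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "ditp_dataset"))
  out <- data.frame(id = ds$id,
                    smiles = ifelse(is.na(ds$smiles), "C", ds$smiles),
                    label = ds$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
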