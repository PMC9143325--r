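# 881-bit substructure-key fingerprint in the public PubChem/CACTVS
# sectioning:
#   bits   1-115  element-count thresholds            (computed from formula)
#   bits 116-263  ring-count/type keys                (SSSR ring statistics)
#   bits 264-327  bonded element pairs                (bond table + H counts)
#   bits 328-881  substructure patterns               (bundled SMARTS catalog)
# Sections 1-3 are computed structurally. The pattern sections are driven by
# the catalog shipped in inst/extdata/pubchem_patterns.tsv, which covers the
# commonly-hit organic keys; bits without a catalog entry are always 0, and a
# full official catalog can be supplied via the same file format. Ring keys
# use SSSR ring perception (the original toolkit uses the extended ESSSR set).

# Element-count section: (element, threshold) in layout order.
PUBCHEM_ELEMENT_COUNTS <- local({
  counted <- list(
    H = c(4, 8, 16, 32), Li = c(1, 2), B = c(1, 2, 4), C = c(2, 4, 8, 16, 32),
    N = c(1, 2, 4, 8), O = c(1, 2, 4, 8, 16), F = c(1, 2, 4), Na = c(1, 2),
    Si = c(1, 2), P = c(1, 2, 4), S = c(1, 2, 4, 8), Cl = c(1, 2, 4, 8),
    K = c(1, 2), Br = c(1, 2, 4), I = c(1, 2, 4))
  singles <- c("Be", "Mg", "Al", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
               "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Kr", "Rb",
               "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag",
               "Cd", "In", "Sn", "Sb", "Te", "Xe", "Cs", "Ba", "La", "Ce",
               "Pr", "Nd", "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er",
               "Tm", "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt",
               "Au", "Hg", "Tl", "Pb", "Bi", "U")
  el <- c(rep(names(counted), lengths(counted)), singles)
  th <- c(unlist(counted, use.names = FALSE), rep(1, length(singles)))
  data.frame(element = el, threshold = th, stringsAsFactors = FALSE)
})
stopifnot(nrow(PUBCHEM_ELEMENT_COUNTS) == 115)

# Ring section: for each (size, count) unit, 7 type keys; then 8 aromatic keys.
PUBCHEM_RING_UNITS <- data.frame(
  size  = rep(c(3, 4, 5, 6, 7, 8, 9, 10), c(2, 2, 5, 5, 2, 2, 1, 1)),
  count = c(1:2, 1:2, 1:5, 1:5, 1:2, 1:2, 1, 1))
RING_TYPES <- c("any", "sat_carbon", "sat_nitrogen", "sat_hetero",
                "unsat_carbon", "unsat_nitrogen", "unsat_hetero")
stopifnot(nrow(PUBCHEM_RING_UNITS) * 7 + 8 == 148)

# Bonded element pairs (64 keys).
PUBCHEM_PAIRS <- matrix(c(
  "Li","H","Li","Li","B","H","B","B","B","C","B","N","B","O","B","F",
  "B","Si","B","P","B","S","B","Cl","B","Br","C","H","C","C","C","N",
  "C","O","C","F","C","Na","C","Mg","C","Al","C","Si","C","P","C","S",
  "C","Cl","C","As","C","Se","C","Br","C","I","N","H","N","N","N","O",
  "N","F","N","Si","N","P","N","S","N","Cl","N","Br","O","H","O","O",
  "O","Mg","O","Na","O","Al","O","Si","O","P","O","K","F","P","F","S",
  "Mg","H","Mg","Mg","Si","H","Si","Si","Si","Cl","P","H","P","P","As","H",
  "As","As","As","P","As","Se","Se","H","Se","Se","Br","H","I","H","S","H"),
  ncol = 2, byrow = TRUE)
stopifnot(nrow(PUBCHEM_PAIRS) == 64)

pubchem_pattern_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "pubchem_patterns.tsv", package = "ditpqsar")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]   # '#' is a bond symbol in SMARTS
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  stopifnot(all(c("bit", "smarts") %in% names(tab)))
  if (any(tab$bit < 328 | tab$bit > 881)) stopf("pattern bits must lie in 328..881")
  if (anyDuplicated(tab$bit)) stopf("duplicate bit assignments in pattern catalog")
  tab
}

#' Public-layout 881-bit substructure-key fingerprint
#'
#' Computes the 881-bit fingerprint in the public PubChem/CACTVS sectioning:
#' element counts, ring counts and types, bonded element pairs, and
#' substructure patterns from a bundled (replaceable) SMARTS catalog. The
#' width is constant (881) for every molecule. Pattern-section bits without a
#' catalog entry are deterministically 0; supply `catalog_path` pointing to a
#' bit-indexed SMARTS table to widen coverage.
#'
#' @param ds a [ditp_dataset()].
#' @param parsed optional pre-parsed molecule set (internal).
#' @param catalog_path optional path to a TSV with columns `bit` (328..881)
#'   and `smarts`, replacing the bundled pattern catalog.
#' @return binary [feature_block()] named `"PubChem"` with 881 columns.
#' @export
pubchem_fingerprint <- function(ds, parsed = NULL, catalog_path = NULL) {
  stopifnot(inherits(ds, "ditp_dataset"))
  if (is.null(parsed)) {
    parsed <- parse_molecules(ds$smiles, ds$id)
    if (any(!parsed$ok))
      stopf("unparseable SMILES for id(s): %s", paste(ds$id[!parsed$ok], collapse = ", "))
  }
  n <- nrow(ds)
  mat <- matrix(0L, n, 881, dimnames = list(ds$id, sprintf("PubChemFP%d", 0:880)))
  pr <- ob_scalar_props(ds$smiles, ds$id)
  counts <- lapply(pr$formula, parse_formula)

  # --- section 1: element counts (bits 1..115)
  for (j in seq_len(nrow(PUBCHEM_ELEMENT_COUNTS))) {
    e <- PUBCHEM_ELEMENT_COUNTS$element[j]; th <- PUBCHEM_ELEMENT_COUNTS$threshold[j]
    mat[, j] <- as.integer(vapply(counts, function(ct) (ct[e] %||% 0) >= th, TRUE))
  }

  # --- section 2: ring counts/types (bits 116..263)
  for (i in seq_len(n)) {
    cid <- ds$id[i]
    if (!cid %in% parsed$sdf_ids) next
    rs <- ring_stats(parsed$sdf[[cid]])
    if (nrow(rs) == 0) next
    for (u in seq_len(nrow(PUBCHEM_RING_UNITS))) {
      sz <- PUBCHEM_RING_UNITS$size[u]; k <- PUBCHEM_RING_UNITS$count[u]
      of_size <- rs[rs$size == sz, , drop = FALSE]
      base <- 115 + (u - 1) * 7
      sat_arom <- of_size$saturated | of_size$aromatic
      unsat <- !of_size$saturated & !of_size$aromatic
      flags <- c(nrow(of_size) >= k,
                 sum(sat_arom & of_size$carbon_only) >= k,
                 sum(sat_arom & of_size$has_n) >= k,
                 sum(sat_arom & of_size$has_het) >= k,
                 sum(unsat & of_size$carbon_only) >= k,
                 sum(unsat & of_size$has_n) >= k,
                 sum(unsat & of_size$has_het) >= k)
      mat[i, base + 1:7] <- as.integer(flags)
    }
    n_arom <- sum(rs$aromatic)
    n_het_arom <- sum(rs$aromatic & rs$has_het)
    base <- 115 + nrow(PUBCHEM_RING_UNITS) * 7
    mat[i, base + 1:4] <- as.integer(n_arom >= 1:4)
    mat[i, base + 5:8] <- as.integer(n_het_arom >= 1:4)
  }

  # --- section 3: bonded element pairs (bits 264..327)
  h_partner <- unique(PUBCHEM_PAIRS[PUBCHEM_PAIRS[, 2] == "H", 1])
  has_h <- sapply(h_partner, function(e)
    smarts_counts(parsed$sdf, parsed$sdf_ids, ds$id,
                  sprintf("[%s!H0]", e)) > 0, simplify = FALSE)
  for (i in seq_len(n)) {
    cid <- ds$id[i]
    pairs_present <- character(0)
    if (cid %in% parsed$sdf_ids) {
      mol <- parsed$sdf[[cid]]
      sym <- atom_symbols(mol); bonds <- bond_table(mol)
      if (nrow(bonds))
        pairs_present <- unique(paste(pmin(sym[bonds$a1], sym[bonds$a2]),
                                      pmax(sym[bonds$a1], sym[bonds$a2])))
    }
    for (j in seq_len(nrow(PUBCHEM_PAIRS))) {
      e1 <- PUBCHEM_PAIRS[j, 1]; e2 <- PUBCHEM_PAIRS[j, 2]
      hit <- if (e2 == "H") isTRUE(has_h[[e1]][[cid]])
             else paste(min(e1, e2), max(e1, e2)) %in% pairs_present
      if (hit) mat[i, 263 + j] <- 1L
    }
  }

  # --- sections 4-7: SMARTS pattern keys (bits 328..881)
  cat <- pubchem_pattern_catalog(catalog_path)
  for (j in seq_len(nrow(cat))) {
    hits <- smarts_counts(parsed$sdf, parsed$sdf_ids, ds$id, cat$smarts[j])
    mat[, cat$bit[j]] <- as.integer(hits > 0)
  }
  blk <- feature_block("PubChem", "binary", mat)
  blk$pattern_coverage <- nrow(cat) / 554
  blk
}
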