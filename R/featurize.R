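# Feature blocks: named n x d matrices of binary fingerprint bits or
# continuous descriptors, aligned to a ditp_dataset by row ids.

#' Construct a feature block
#'
#' @param name block identifier (e.g. `"MACCS"`, `"PubChem"`, `"extended"`).
#' @param kind `"binary"` or `"continuous"`; for mixed (combined) blocks a
#'   per-column `kinds` vector may be given instead.
#' @param matrix numeric matrix, one row per molecule; rownames are molecule
#'   ids, colnames are feature names.
#' @param kinds optional per-column kind vector (defaults to `kind` recycled).
#' @return object of class `feature_block`.
#' @export
feature_block <- function(name, kind = c("binary", "continuous"), matrix,
                          kinds = NULL) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix))) stopf("feature matrix must have molecule-id rownames")
  if (is.null(colnames(matrix))) colnames(matrix) <- paste0(name, seq_len(ncol(matrix)))
  if (anyDuplicated(colnames(matrix)))
    stopf("duplicate feature names in block '%s'", name)
  if (is.null(kinds)) kinds <- rep(kind, ncol(matrix))
  if (length(kinds) != ncol(matrix)) stopf("kinds length must equal column count")
  if (kind == "binary" && !is_binary01(matrix[is.finite(matrix)]))
    stopf("binary block '%s' contains values outside {0, 1}", name)
  structure(list(name = name, kind = kind, matrix = matrix, kinds = kinds),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> '%s' (%s): %d molecules x %d features\n",
              x$name, x$kind, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$matrix)

block_ids <- function(block) rownames(block$matrix)

#' Basic physicochemical properties
#'
#' MW (Da), AlogP (atom-contribution octanol/water logP from the open
#' provider), nHBA, nHBD, nRot (non-terminal non-ring single bonds not
#' adjacent to a triple bond), nRing (smallest set of smallest rings).
#'
#' @param ds a [ditp_dataset()] with parseable SMILES.
#' @return data.frame with one row per molecule (columns `id`, `MW`, `AlogP`,
#'   `nHBA`, `nHBD`, `nRot`, `nRing`).
#' @export
basic_properties <- function(ds) {
  stopifnot(inherits(ds, "ditp_dataset"))
  parsed <- parse_molecules(ds$smiles, ds$id)
  if (any(!parsed$ok))
    stopf("unparseable SMILES for id(s): %s", paste(ds$id[!parsed$ok], collapse = ", "))
  pr <- ob_scalar_props(ds$smiles, ds$id)
  nrot <- smarts_counts(parsed$sdf, parsed$sdf_ids, ds$id, ROTATABLE_SMARTS)
  nring <- stats::setNames(rep(0L, nrow(ds)), ds$id)
  for (cid in parsed$sdf_ids)
    nring[cid] <- sssr_count(parsed$sdf[[cid]])
  data.frame(id = ds$id, MW = pr$MW, AlogP = pr$logP,
             nHBA = as.integer(pr$HBA2), nHBD = as.integer(pr$HBD),
             nRot = as.integer(nrot), nRing = as.integer(nring),
             stringsAsFactors = FALSE)
}

#' Compute a molecular fingerprint block
#'
#' Families: `"maccs"` (166 MDL MACCS keys), `"pubchem"` (881-bit
#' substructure-key fingerprint in the public PubChem/CACTVS layout, see
#' [pubchem_fingerprint()]), `"hashed"` (linear-path hashed fingerprint,
#' default width 1024, standing in for CDK-style hashed fingerprints).
#'
#' @param ds a [ditp_dataset()] with parseable SMILES.
#' @param family `"maccs"`, `"pubchem"` or `"hashed"` (case-insensitive).
#' @param nbits width for `family = "hashed"`; must be a power of two
#'   dividing 1024.
#' @return binary [feature_block()] with constant width per family
#'   (MACCS 166, PubChem 881).
#' @export
compute_fingerprint <- function(ds, family = c("maccs", "pubchem", "hashed"),
                                nbits = 1024) {
  stopifnot(inherits(ds, "ditp_dataset"))
  family <- match.arg(tolower(family[1]), c("maccs", "pubchem", "hashed"))
  parsed <- parse_molecules(ds$smiles, ds$id)
  if (any(!parsed$ok))
    stopf("unparseable SMILES for id(s): %s", paste(ds$id[!parsed$ok], collapse = ", "))
  if (family == "pubchem")
    return(pubchem_fingerprint(ds, parsed))
  if (family == "maccs") {
    mat <- matrix(0L, nrow(ds), 166, dimnames = list(ds$id, sprintf("MACCS%d", 1:166)))
    if (!is.null(parsed$sdf)) {
      fp <- methods::slot(ChemmineR::fingerprintOB(parsed$sdf, "MACCS"), "fpma")
      mat[parsed$sdf_ids, ] <- fp[, 1:166]   # OpenBabel pads MACCS to 256 bits
    }
    return(feature_block("MACCS", "binary", mat))
  }
  if (!(nbits >= 8 && nbits <= 1024 && 1024 %% nbits == 0))
    stopf("hashed width must be a power of two dividing 1024")
  mat <- matrix(0L, nrow(ds), nbits, dimnames = list(ds$id, sprintf("FP%d", seq_len(nbits))))
  if (!is.null(parsed$sdf)) {
    fp <- methods::slot(ChemmineR::fingerprintOB(parsed$sdf, "FP2"), "fpma")
    # fold 1024 -> nbits by OR over congruent positions
    fold <- fp
    while (ncol(fold) > nbits) {
      half <- ncol(fold) / 2
      fold <- (fold[, 1:half, drop = FALSE] | fold[, half + 1:half, drop = FALSE]) * 1L
    }
    mat[parsed$sdf_ids, ] <- fold
  }
  feature_block("hashed", "binary", mat)
}

#' Compute a molecular descriptor block
#'
#' Two sets are built in:
#' \describe{
#' \item{`"md13"`}{the 13 classic descriptors: solubility (Delaney ESOL
#'   estimate, logS), MW, AlogP, logD7.4 (open-provider substitute: AlogP),
#'   nHBD, N+O count, nHBA, nRot, nRing, nAromRing, molecular surface area
#'   (vdW-sphere estimate), TPSA, fractional polar surface area.}
#' \item{`"extended"`}{the open descriptor provider's full continuous list:
#'   OpenBabel scalar properties plus structural counts (atoms, bonds,
#'   rings, element counts, ...); the column count is recorded, not forced.}
#' }
#' Aliases `"13MD"` and `"RDMD"` (the names used with the original
#' proprietary/legacy providers) are accepted for the two sets.
#'
#' @param ds a [ditp_dataset()] with parseable SMILES.
#' @param set `"md13"` or `"extended"` (aliases `"13MD"`, `"RDMD"`).
#' @param drop_estimated drop the proprietary-tool substitutes (solubility,
#'   logD7.4, surface areas) from `md13` instead of estimating them.
#' @return continuous [feature_block()].
#' @export
compute_descriptors <- function(ds, set = c("md13", "extended"),
                                drop_estimated = FALSE) {
  stopifnot(inherits(ds, "ditp_dataset"))
  set <- c(`13md` = "md13", rdmd = "extended", md13 = "md13",
           extended = "extended")[[tolower(set[1])]]
  if (is.null(set)) stopf("unknown descriptor set")
  parsed <- parse_molecules(ds$smiles, ds$id)
  if (any(!parsed$ok))
    stopf("unparseable SMILES for id(s): %s", paste(ds$id[!parsed$ok], collapse = ", "))
  pr <- ob_scalar_props(ds$smiles, ds$id)
  counts <- lapply(pr$formula, parse_formula)
  elem <- function(e) vapply(counts, function(ct) as.numeric(ct[e] %||% 0), 1)
  nrot <- as.numeric(smarts_counts(parsed$sdf, parsed$sdf_ids, ds$id, ROTATABLE_SMARTS))
  nring <- narom <- stats::setNames(rep(0, nrow(ds)), ds$id)
  msa <- stats::setNames(rep(0, nrow(ds)), ds$id)
  for (cid in ds$id) {
    if (cid %in% parsed$sdf_ids) {
      mol <- parsed$sdf[[cid]]
      nring[cid] <- sssr_count(mol)
      rs <- ring_stats(mol)
      narom[cid] <- sum(rs$aromatic)
      msa[cid] <- vdw_surface_area(mol, counts[[match(cid, ds$id)]])
    } else {
      msa[cid] <- vdw_surface_area(NULL, counts[[match(cid, ds$id)]])
    }
  }
  n_no <- elem("N") + elem("O")
  arom_atoms <- smarts_counts(parsed$sdf, parsed$sdf_ids, ds$id, "[a]")
  heavy <- vapply(counts, function(ct) sum(ct[setdiff(names(ct), "H")]), 1)
  # Delaney ESOL: logS = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP
  ap <- ifelse(heavy > 0, as.numeric(arom_atoms) / heavy, 0)
  esol <- 0.16 - 0.63 * pr$logP - 0.0062 * pr$MW + 0.066 * nrot - 0.74 * ap
  fpsa <- ifelse(msa > 0, pr$TPSA / msa, 0)
  if (set == "md13") {
    mat <- cbind(Solubility_logS = esol, MW = pr$MW, AlogP = pr$logP,
                 logD74 = pr$logP, nHBD = pr$HBD, N_plus_O = n_no,
                 nHBA = pr$HBA2, nRot = nrot, nRing = as.numeric(nring),
                 nAromRing = as.numeric(narom), MolSurfArea = as.numeric(msa),
                 TPSA = pr$TPSA, FPSA = fpsa)
    if (drop_estimated)
      mat <- mat[, setdiff(colnames(mat),
                           c("Solubility_logS", "logD74", "MolSurfArea", "FPSA")),
                 drop = FALSE]
    rownames(mat) <- ds$id
    return(feature_block("md13", "continuous", mat))
  }
  # extended set: provider scalars + structural counts
  extra_smarts <- c(
    nAmide = "[CX3](=O)[NX3]", nCarboxyl = "[CX3](=O)[OX2H1]",
    nEster = "[CX3](=O)[OX2][#6]", nNitro = "[N+](=O)[O-]",
    nSulfonyl = "[#16](=O)(=O)", nPhenol = "[OX2H][c]",
    nEther = "[OX2]([#6])[#6]", nAmine = "[NX3;!$(N=O);!$(NC=O)]",
    nHalogenC = "[#6][F,Cl,Br,I]", nBasicN = "[NX3;H2,H1;!$(NC=O)]",
    nNitrile = "[CX2]#[NX1]", nKetone = "[#6][CX3](=O)[#6]",
    nAromN = "[nX2,nX3]", nAromO = "[o]", nAromS = "[s]",
    nDoubleBond = "[!a]=[!a]", nTripleBond = "*#*")
  sm <- vapply(extra_smarts,
               function(s) as.numeric(smarts_counts(parsed$sdf, parsed$sdf_ids, ds$id, s)),
               numeric(nrow(ds)))
  if (nrow(ds) == 1) sm <- matrix(sm, 1, dimnames = list(NULL, names(extra_smarts)))
  mat <- cbind(MW = pr$MW, AlogP = pr$logP, MR = pr$MR, TPSA = pr$TPSA,
               FPSA = fpsa, Solubility_logS = esol, MolSurfArea = as.numeric(msa),
               nHBA1 = pr$HBA1, nHBA = pr$HBA2, nHBD = pr$HBD,
               nF = pr$nF, nRot = nrot,
               nRing = as.numeric(nring), nAromRing = as.numeric(narom),
               nAtoms = vapply(counts, sum, 1), nHeavyAtoms = heavy,
               nC = elem("C"), nN = elem("N"), nO = elem("O"), nS = elem("S"),
               nP = elem("P"), nCl = elem("Cl"), nBr = elem("Br"), nI = elem("I"),
               nH = elem("H"), N_plus_O = n_no,
               nHalogen = elem("F") + elem("Cl") + elem("Br") + elem("I"),
               nAromAtoms = as.numeric(arom_atoms),
               AromProportion = ap, HeavyMW = pr$MW - elem("H") * 1.008,
               sm)
  rownames(mat) <- ds$id
  feature_block("extended", "continuous", mat)
}

`%||%` <- function(a, b)
  if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

# van der Waals molecular surface estimate: sum of atomic sphere areas
# (implicit H included via the formula) minus spherical caps cut off by each
# bond at the sum of covalent radii. A coarse open-provider stand-in for the
# proprietary 3D surface-area descriptor; deterministic and monotone in size.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Cl = 1.75,
               Br = 1.85, I = 1.98, S = 1.80, P = 1.80, Si = 2.10, B = 1.92,
               Se = 1.90, As = 1.85, Na = 2.27, K = 2.75, Li = 1.82,
               Mg = 1.73, Ca = 2.31, Zn = 1.39, Fe = 2.05, Cu = 1.40)
COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Cl = 1.02,
               Br = 1.20, I = 1.39, S = 1.05, P = 1.07, Si = 1.11, B = 0.84,
               Se = 1.20, As = 1.19, Na = 1.66, K = 2.03, Li = 1.28,
               Mg = 1.41, Ca = 1.76, Zn = 1.22, Fe = 1.32, Cu = 1.32)

cap_area <- function(r1, r2, d) {
  # area of the cap removed from sphere r1 by intersecting sphere r2 at distance d
  if (d >= r1 + r2) return(0)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  max(0, 2 * pi * r1 * min(h, r1))
}

vdw_surface_area <- function(sdf_mol, formula_counts) {
  rad <- function(e) VDW_RADII[e] %||% 1.8
  crad <- function(e) COV_RADII[e] %||% 1.2
  total <- sum(vapply(names(formula_counts), function(e)
    formula_counts[[e]] * 4 * pi * rad(e)^2, 1))
  if (!is.null(sdf_mol)) {
    sym <- atom_symbols(sdf_mol)
    bonds <- bond_table(sdf_mol)
    for (k in seq_len(nrow(bonds))) {
      e1 <- sym[bonds$a1[k]]; e2 <- sym[bonds$a2[k]]
      d <- crad(e1) + crad(e2)
      total <- total - cap_area(rad(e1), rad(e2), d) - cap_area(rad(e2), rad(e1), d)
    }
    # caps for implicit hydrogens: H count minus explicit H atoms
    n_h <- formula_counts["H"] %||% 0
    n_h_expl <- sum(sym == "H")
    heavy_with_h <- sum(pmin(1, n_h - n_h_expl))  # coarse: one correction per H
    if (n_h > n_h_expl) {
      e_med <- "C"
      d <- crad(e_med) + crad("H")
      total <- total - (n_h - n_h_expl) *
        (cap_area(rad("H"), rad(e_med), d) + cap_area(rad(e_med), rad("H"), d))
    }
  }
  max(total, 0)
}

#' Import an externally computed feature table
#'
#' Loads a CSV of externally computed features (e.g. Klekota-Roth, CDK or
#' atom-pair fingerprints from PaDEL, or bioactivity-signature descriptors),
#' reorders rows to dataset order and validates binary blocks.
#'
#' @param path CSV path; first column (or `id_column`) holds molecule ids.
#' @param kind `"binary"` or `"continuous"`.
#' @param name block name.
#' @param ids dataset molecule ids the table must cover (order target).
#' @param id_column id column name (default: first column).
#' @param sep delimiter.
#' @return a [feature_block()] with rows in `ids` order.
#' @export
load_feature_table <- function(path, kind = c("binary", "continuous"), name,
                               ids, id_column = NULL, sep = ",") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (is.null(id_column)) id_column <- names(tab)[1]
  if (!id_column %in% names(tab)) stopf("id column '%s' missing", id_column)
  tab_ids <- as.character(tab[[id_column]])
  missing <- setdiff(ids, tab_ids)
  if (length(missing))
    stopf("feature table %s is missing dataset id(s): %s", path,
          paste(missing, collapse = ", "))
  mat <- as.matrix(tab[match(ids, tab_ids), setdiff(names(tab), id_column), drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric feature values in %s", path)
  rownames(mat) <- ids
  if (kind == "binary" && !is_binary01(mat))
    stopf("binary feature table %s contains values outside {0, 1}", path)
  feature_block(name, kind, mat)
}

#' Match a SMARTS catalog against a dataset (fingerprint plugin)
#'
#' Builds a binary block from any user-supplied SMARTS list: bit j is 1 when
#' pattern j matches the molecule. This is the route for externally defined
#' substructure-key sets (e.g. a Klekota-Roth catalog).
#'
#' @param ds a [ditp_dataset()].
#' @param smarts named character vector of SMARTS patterns.
#' @param name block name (default `"smarts"`).
#' @return binary [feature_block()] with `length(smarts)` columns.
#' @export
smarts_block <- function(ds, smarts, name = "smarts") {
  stopifnot(inherits(ds, "ditp_dataset"), length(smarts) > 0)
  if (is.null(names(smarts))) names(smarts) <- paste0(name, seq_along(smarts))
  parsed <- parse_molecules(ds$smiles, ds$id)
  if (any(!parsed$ok))
    stopf("unparseable SMILES for id(s): %s", paste(ds$id[!parsed$ok], collapse = ", "))
  mat <- vapply(smarts, function(s)
    as.numeric(smarts_counts(parsed$sdf, parsed$sdf_ids, ds$id, s) > 0),
    numeric(nrow(ds)))
  if (nrow(ds) == 1) mat <- matrix(mat, 1, dimnames = list(NULL, names(smarts)))
  rownames(mat) <- ds$id
  feature_block(name, "binary", mat)
}

#' Concatenate feature blocks column-wise
#'
#' Rows are aligned by molecule id (not position); feature names are prefixed
#' `"blockname:"`; the per-column kind is preserved so downstream
#' preprocessing can treat descriptor and fingerprint columns differently.
#'
#' @param blocks list of [feature_block()]s covering identical molecule ids.
#' @param name combined block name (default: names joined by `"+"`).
#' @return a [feature_block()] with `sum(d_i)` columns.
#' @export
combine_blocks <- function(blocks, name = NULL) {
  stopifnot(length(blocks) >= 1)
  if (length(blocks) == 1) return(blocks[[1]])
  nms <- vapply(blocks, function(b) b$name, "")
  if (anyDuplicated(nms)) stopf("duplicate block names: %s",
                                paste(nms[duplicated(nms)], collapse = ", "))
  ids <- block_ids(blocks[[1]])
  for (b in blocks[-1]) {
    if (!setequal(block_ids(b), ids))
      stopf("blocks '%s' and '%s' cover different molecules", blocks[[1]]$name, b$name)
  }
  mats <- lapply(blocks, function(b) {
    m <- b$matrix[ids, , drop = FALSE]
    colnames(m) <- paste0(b$name, ":", colnames(b$matrix))
    m
  })
  kinds <- unlist(lapply(blocks, function(b) b$kinds))
  mixed <- length(unique(kinds)) > 1
  feature_block(name %||% paste(nms, collapse = "+"),
                if (mixed) "continuous" else unique(kinds),
                do.call(cbind, mats), kinds = kinds)
}

#' Pairwise Tanimoto similarity of a binary block
#'
#' \eqn{S_{ij} = |a \wedge b| / |a \vee b|} over set bits. A pair of all-zero
#' rows is defined as similarity 1 (maximally similar under absence of
#' features); this convention is recorded in the result.
#'
#' @param fp binary [feature_block()].
#' @return `list(matrix, mean_offdiagonal)`; the matrix is symmetric with
#'   unit diagonal for non-empty rows.
#' @export
tanimoto_matrix <- function(fp) {
  stopifnot(inherits(fp, "feature_block"))
  if (!is_binary01(fp$matrix)) stopf("tanimoto_matrix requires a binary block")
  m <- fp$matrix
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  s <- ifelse(uni > 0, inter / uni, 1)  # both-empty pair: similarity 1
  dimnames(s) <- list(rownames(m), rownames(m))
  n <- nrow(s)
  mean_off <- if (n > 1) mean(s[upper.tri(s)]) else NA_real_
  list(matrix = s, mean_offdiagonal = mean_off)
}
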