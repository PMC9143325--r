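# Chemistry provider layer: all contact with OpenBabel/ChemmineR lives here.
# Molecules are carried as SMILES; parsed SDF containers are built on demand.
# Single-heavy-atom species (water, bare ions) are legal inputs but break
# ChemmineR's SDFset accessors, so they are tracked separately and served by
# formula arithmetic and the obabel CLI instead.

# Parse a SMILES vector. Returns list(ok, degenerate, errors, sdf, sdf_ids):
#  ok         logical, SMILES accepted by OpenBabel
#  degenerate logical, parseable but < 2 atoms (no SDF representation kept)
#  errors     character, parse message for rejected rows ("" when ok)
#  sdf        SDFset of the non-degenerate molecules, cid = ids[ok & !degenerate]
parse_molecules <- function(smiles, ids = as.character(seq_along(smiles))) {
  stopifnot(length(smiles) == length(ids))
  n <- length(smiles)
  ok <- logical(n); degen <- logical(n); errors <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(c(x = smiles[[i]]))),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[i] <- conditionMessage(res)
    } else {
      ok[i] <- TRUE
      degen[i] <- !isTRUE(suppressWarnings(ChemmineR::validSDF(res))[1])
    }
  }
  keep <- which(ok & !degen)
  sdf <- NULL
  if (length(keep)) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[keep], ids[keep])))
    ChemmineR::cid(sdf) <- ids[keep]
  }
  list(ok = ok, degenerate = degen, errors = errors, sdf = sdf, sdf_ids = ids[keep])
}

# Scalar molecular properties through one batched obabel call (handles
# degenerate molecules that SDFset cannot). Returns a data.frame keyed by id
# with MW, HBA1, HBA2, HBD, logP, TPSA, MR, formula.
OB_PROPS <- c("MW", "HBA1", "HBA2", "HBD", "logP", "TPSA", "MR", "formula")

ob_scalar_props <- function(smiles, ids = as.character(seq_along(smiles))) {
  stopifnot(length(smiles) == length(ids))
  tmp_in <- tempfile(fileext = ".smi")
  on.exit(unlink(tmp_in), add = TRUE)
  tag <- sprintf("m%06d", seq_along(smiles))
  writeLines(paste(smiles, tag), tmp_in)
  out <- suppressWarnings(system2("obabel",
    c(tmp_in, "-otxt", "--append", shQuote(paste(OB_PROPS, collapse = " "))),
    stdout = TRUE, stderr = TRUE))
  lines <- grep("^m[0-9]{6}[ \t]", out, value = TRUE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  fields <- fields[vapply(fields, length, 1L) == length(OB_PROPS) + 1L]
  got <- vapply(fields, `[[`, "", 1L)
  res <- data.frame(id = ids, MW = NA_real_, HBA1 = NA_real_, HBA2 = NA_real_,
                    HBD = NA_real_, logP = NA_real_, TPSA = NA_real_, MR = NA_real_,
                    formula = NA_character_, stringsAsFactors = FALSE)
  m <- match(tag, got)
  for (j in seq_along(OB_PROPS)) {
    vals <- vapply(fields, `[[`, "", j + 1L)[m]
    if (OB_PROPS[j] == "formula") res$formula <- vals
    else res[[OB_PROPS[j]]] <- suppressWarnings(as.numeric(vals))
  }
  if (anyNA(res$MW))
    stopf("obabel failed to compute properties for molecule(s): %s",
          paste(ids[is.na(res$MW)], collapse = ", "))
  res
}

# "C9H8O4", "Na+", "C2H6O2-" -> named integer vector of element counts
# (trailing charge tokens stripped).
parse_formula <- function(f) {
  f <- sub("[0-9]*[+-]+$", "", f)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  tapply(ct, el, sum)
}

atom_symbols <- function(sdf_mol) {
  ab <- ChemmineR::atomblock(sdf_mol)
  gsub("_.*$", "", rownames(ab))
}

# Bond table of one molecule: data.frame(a1, a2, order) with atom indices.
bond_table <- function(sdf_mol) {
  bb <- ChemmineR::bondblock(sdf_mol)
  if (is.null(bb) || nrow(bb) == 0)
    return(data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)))
  data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
             order = as.integer(bb[, 3]))
}

# Number of connected components of the molecular graph.
n_components <- function(n_atoms, bonds) {
  parent <- seq_len(n_atoms)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(bonds))) {
    ra <- find(bonds$a1[k]); rb <- find(bonds$a2[k])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n_atoms), find, 1L)))
}

# SSSR ring count (cyclomatic number) of one molecule.
sssr_count <- function(sdf_mol) {
  bonds <- bond_table(sdf_mol)
  n_atoms <- nrow(ChemmineR::atomblock(sdf_mol))
  nrow(bonds) - n_atoms + n_components(n_atoms, bonds)
}

# Per-ring statistics of one molecule: data.frame(size, aromatic, saturated,
# carbon_only, has_n, has_het) using ChemmineR ring perception.
ring_stats <- function(sdf_mol) {
  empty <- data.frame(size = integer(0), aromatic = logical(0),
                      saturated = logical(0), carbon_only = logical(0),
                      has_n = logical(0), has_het = logical(0))
  rl <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf_mol, upper = 12, type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (is.null(rl) || length(rl$RINGS) == 0) return(empty)
  bonds <- bond_table(sdf_mol)
  key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  order_of <- stats::setNames(bonds$order, key)
  do.call(rbind, lapply(seq_along(rl$RINGS), function(i) {
    atoms <- rl$RINGS[[i]]
    idx <- as.integer(gsub("^.*_", "", atoms))
    el <- gsub("_.*$", "", atoms)
    sz <- length(idx)
    ring_orders <- vapply(seq_len(sz), function(j) {
      a <- idx[j]; b <- idx[if (j == sz) 1L else j + 1L]
      o <- order_of[paste(min(a, b), max(a, b))]
      if (is.na(o)) 1L else as.integer(o)
    }, 1L)
    arom <- isTRUE(rl$AROMATIC[[i]])
    data.frame(size = sz, aromatic = arom,
               saturated = !arom && all(ring_orders == 1L),
               carbon_only = all(el == "C"),
               has_n = any(el == "N"),
               has_het = any(!el %in% c("C", "H")))
  }))
}

# Count molecules matching each SMARTS pattern; returns match counts
# (0 for molecules absent from the SDFset, e.g. degenerate ones).
smarts_counts <- function(sdf, sdf_ids, all_ids, smarts) {
  out <- stats::setNames(rep(0, length(all_ids)), all_ids)
  if (!is.null(sdf) && length(sdf_ids)) {
    hits <- tryCatch(
      suppressWarnings(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = TRUE)),
      error = function(e) stopf("SMARTS pattern failed: %s (%s)", smarts, conditionMessage(e)))
    out[sdf_ids] <- as.numeric(hits)
  }
  out
}

ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"
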