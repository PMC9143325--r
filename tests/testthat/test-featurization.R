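# Chemistry-backed featurization. The hand-validated SMILES fixture keeps
# these tests self-contained; block widths and structure-forced property
# values are the oracles.

fixture <- generate_smiles_fixture(24)

test_that("the SMILES fixture is stable, parseable and two-class", {
  expect_equal(nrow(fixture), 24)
  expect_setequal(unique(fixture$label), c(0, 1))
  expect_identical(fixture, generate_smiles_fixture(24))
  small <- generate_smiles_fixture(4)
  expect_equal(nrow(small), 4)
  expect_setequal(unique(small$label), c(0, 1))
  expect_error(generate_smiles_fixture(40), "between")
  # every SMILES parses under full validation
  ds <- ditp_dataset(fixture$id, fixture$smiles, fixture$label,
                     validate_smiles = TRUE)
  expect_equal(nrow(ds), 24)
})

test_that("fingerprint widths are constant regardless of the molecule", {
  fp <- compute_fingerprint(fixture, "maccs")
  expect_equal(ncol(fp$matrix), 166)
  expect_equal(fp$kind, "binary")
  expect_true(all(fp$matrix %in% c(0, 1)))
  hb <- compute_fingerprint(fixture, "hashed", nbits = 1024)
  expect_equal(ncol(hb$matrix), 1024)
  hb256 <- compute_fingerprint(fixture, "hashed", nbits = 256)
  expect_equal(ncol(hb256$matrix), 256)
  expect_error(compute_fingerprint(fixture, "hashed", nbits = 100), "power of two")
  expect_error(compute_fingerprint(fixture, "daylight"), "arg")
})

test_that("featurization is deterministic: the same molecule gives identical rows", {
  twice <- ditp_dataset(c("x1", "x2", "y1"), c("CCO", "CCO", "c1ccccc1"),
                        c(1, 0, 1), validate_smiles = FALSE)
  fp <- compute_fingerprint(twice, "maccs")
  expect_identical(fp$matrix["x1", ], fp$matrix["x2", ])
  expect_false(identical(fp$matrix["x1", ], fp$matrix["y1", ]))
  d <- compute_descriptors(twice, "md13")
  expect_identical(d$matrix["x1", ], d$matrix["x2", ])
})

test_that("structure-forced descriptor values are exact", {
  ds <- ditp_dataset(c("benzene", "ethane", "ethanol", "butane", "water"),
                     c("c1ccccc1", "CC", "CCO", "CCCC", "O"),
                     c(0, 1, 0, 1, 0), validate_smiles = FALSE)
  d <- compute_descriptors(ds, "13MD")
  expect_equal(ncol(d$matrix), 13)
  m <- d$matrix
  expect_equal(unname(m["benzene", c("nRing", "nHBD", "nHBA")]), c(1, 0, 0))
  expect_equal(unname(m["ethane", "nRot"]), 0)
  expect_equal(unname(m["butane", "nRot"]), 1)
  expect_equal(unname(m["ethanol", "MW"]), 46.07, tolerance = 1e-3)
  expect_equal(unname(m["water", "MW"]), 18.02, tolerance = 1e-3)
  expect_equal(unname(m["water", c("nRing", "nRot", "nAromRing")]), c(0, 0, 0))
})

test_that("the extended descriptor set is continuous, finite and names its columns", {
  d <- compute_descriptors(fixture, "RDMD")
  expect_gt(ncol(d$matrix), 30)
  expect_true(all(is.finite(d$matrix)))
  expect_false(anyDuplicated(colnames(d$matrix)) > 0)
  expect_equal(d$kind, "continuous")
  expect_equal(unname(d$matrix["benzene", "nAromRing"]), 1)
  expect_equal(unname(d$matrix["pyridine", "nN"]), 1)
  expect_equal(unname(d$matrix["nitrobenzene", "nO"]), 2)
})

test_that("basic properties match structural counts", {
  bp <- basic_properties(fixture)
  rownames(bp) <- bp$id
  expect_equal(bp["benzene", "nRing"], 1L)
  expect_equal(bp["butane", "nRot"], 1L)
  expect_equal(bp["cyclohexane", "nRing"], 1L)
  expect_equal(bp["acetamide", "nHBD"], 1L)
  expect_true(all(bp$MW > 0))
  expect_true(all(bp[, c("nHBA", "nHBD", "nRot", "nRing")] >= 0))
})

test_that("feature tables round-trip through CSV import with id alignment", {
  m <- matrix(rbinom(12, 1, 0.5), 4, 3,
              dimnames = list(NULL, c("b1", "b2", "b3")))
  tab <- data.frame(molecule = c("m2", "m1", "m4", "m3"), m)
  path <- write_temp_csv(tab)
  blk <- load_feature_table(path, "binary", "imported", c("m1", "m2", "m3", "m4"))
  expect_equal(ncol(blk$matrix), 3)
  expect_equal(blk$matrix["m1", ],
               stats::setNames(as.numeric(m[2, ]), c("b1", "b2", "b3")))
  expect_error(load_feature_table(path, "binary", "x", c("m1", "m9")), "m9")
  tab2 <- tab; tab2$b1[1] <- 2
  expect_error(load_feature_table(write_temp_csv(tab2), "binary", "x",
                                  c("m1", "m2", "m3", "m4")), "outside")
})

test_that("blocks combine by id with prefixed names and summed widths", {
  a <- toy_block(matrix(1:6, 3, 2), name = "A")
  b_mat <- matrix(c(1, 0, 1), 3, 1,
                  dimnames = list(c("m3", "m1", "m2"), "bit"))
  b <- feature_block("B", "binary", b_mat)
  cb <- combine_blocks(list(a, b))
  expect_equal(ncol(cb$matrix), 3)
  expect_equal(colnames(cb$matrix), c("A:f1", "A:f2", "B:bit"))
  expect_equal(cb$matrix["m1", "B:bit"], 0)       # aligned by id, not position
  expect_equal(cb$kinds, c("continuous", "continuous", "binary"))
  expect_identical(combine_blocks(list(a)), a)
  expect_error(combine_blocks(list(a, a)), "duplicate")
  c_other <- toy_block(matrix(1:4, 2, 2), name = "C")
  expect_error(combine_blocks(list(a, c_other)), "different molecules")
})

test_that("Tanimoto similarity follows the set-overlap definition", {
  m <- rbind(m1 = c(1, 1, 0, 1), m2 = c(1, 0, 1, 1), m3 = c(1, 1, 0, 1),
             m4 = c(0, 0, 1, 1), m5 = c(1, 1, 0, 0), m6 = c(0, 0, 0, 0))
  colnames(m) <- paste0("b", 1:4)
  tm <- tanimoto_matrix(feature_block("fp", "binary", m))
  s <- tm$matrix
  expect_equal(s["m1", "m3"], 1)                  # identical non-zero rows
  expect_equal(s["m4", "m5"], 0)                  # disjoint
  expect_equal(s["m1", "m2"], 0.5)                # 1101 vs 1011: 2/4
  expect_equal(s["m6", "m6"], 1)                  # both-empty convention
  expect_true(isSymmetric(s))
  expect_true(all(diag(s) == 1))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(tanimoto_matrix(toy_block(matrix(rnorm(4), 2))), "binary")
})

test_that("SMARTS catalogs produce binary blocks that hit the right molecules", {
  blk <- smarts_block(fixture, c(aromatic = "c1ccccc1", carbonyl = "C=O",
                                 lactam = "O=C1CCN1"))
  expect_equal(ncol(blk$matrix), 3)
  expect_equal(unname(blk$matrix["benzene", "aromatic"]), 1)
  expect_equal(unname(blk$matrix["butane", "aromatic"]), 0)
  expect_equal(unname(blk$matrix["betalactam", "lactam"]), 1)
  expect_equal(sum(blk$matrix[, "lactam"]), 1)
})
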