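test_that("robust_z matches hand-computed median/MAD within batches", {
  raw <- screen_matrix(matrix(c(1, 2, 3, 4, 100), 5, 1,
                              dimnames = list(paste0("g", 1:5), "L1")),
                       flavor = "raw", batch = rep("b1", 5))
  z <- robust_z(raw)
  # median 3, MAD = median(|x - 3|) = 1
  expect_equal(as.vector(z$values), c(-2, -1, 0, 1, 97))
  expect_identical(z$flavor, "z")

  # symmetric batch [-a, 0, a] -> [-1, 0, 1] for any a > 0
  for (a in c(0.5, 2, 1e3)) {
    raw2 <- screen_matrix(matrix(c(-a, 0, a), 3, 1,
                                 dimnames = list(paste0("g", 1:3), "L1")),
                          flavor = "raw", batch = rep("b", 3))
    expect_equal(as.vector(robust_z(raw2)$values), c(-1, 0, 1))
  }
})

test_that("robust_z is computed per batch and rejects degenerate batches", {
  vals <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2,
                 dimnames = list(paste0("g", 1:4), c("L1", "L2")))
  raw <- screen_matrix(vals, flavor = "raw")
  # per-entry batches: column 1 is batch A, column 2 batch B
  bm <- matrix(rep(c("A", "B"), each = 4), 4, 2)
  z <- robust_z(raw, batch = bm)
  expect_equal(z$values[, 1], (vals[, 1] - 2.5) / 1, ignore_attr = TRUE)
  expect_equal(z$values[, 2], (vals[, 2] - 25) / 10, ignore_attr = TRUE)

  flat <- screen_matrix(matrix(5, 4, 1, dimnames = list(paste0("g", 1:4), "L1")),
                        flavor = "raw", batch = rep("b9", 4))
  expect_error(robust_z(flat), "b9")
  tiny <- screen_matrix(matrix(1:2, 2, 1, dimnames = list(c("g1", "g2"), "L1")),
                        flavor = "raw", batch = c("bX", "bX"))
  expect_error(robust_z(tiny), "fewer than 3")
})

test_that("hit calls are invariant to per-batch constant shifts", {
  gen <- tiny_screen()
  vals <- matrix(rnorm(60, mean = 5), 20, 3,
                 dimnames = list(paste0("g", 1:20), paste0("L", 1:3)))
  batch <- rep(c("p1", "p2"), each = 10)
  raw <- screen_matrix(vals, flavor = "raw", batch = batch)
  shifted <- vals
  shifted[batch == "p1", ] <- shifted[batch == "p1", ] + 7
  shifted[batch == "p2", ] <- shifted[batch == "p2", ] - 3
  raw2 <- screen_matrix(shifted, flavor = "raw", batch = batch)
  expect_equal(binarize(robust_z(raw))$values, binarize(robust_z(raw2))$values)
})

test_that("combine_min keeps the more lethal score and the gene union", {
  za <- screen_matrix(matrix(c(-3.5, 0, 2, -1), 2, 2,
                             dimnames = list(c("A", "B"), c("L1", "L2"))),
                      flavor = "z")
  zb <- screen_matrix(matrix(c(-1.0, -4, 1, 1), 2, 2,
                             dimnames = list(c("A", "C"), c("L1", "L2"))),
                      flavor = "z")
  cm <- combine_min(za, zb)
  expect_equal(cm$values["A", "L1"], -3.5)   # hit in either library is kept
  expect_equal(sort(cm$gene_ids), c("A", "B", "C"))
  expect_equal(cm$values["B", "L1"], 0)      # single-library gene retained
  expect_equal(cm$values["C", "L1"], -4)

  # commutativity and idempotence
  cm2 <- combine_min(zb, za)
  expect_equal(cm$values[sort(cm$gene_ids), ], cm2$values[sort(cm2$gene_ids), ])
  expect_equal(combine_min(za, za)$values, za$values)
  # never increases any entry
  expect_true(all(cm$values["A", ] <= za$values["A", ]))
  expect_true(all(cm$values["A", ] <= zb$values["A", ]))

  zc <- screen_matrix(matrix(0, 1, 1, dimnames = list("A", "LX")), flavor = "z")
  expect_error(combine_min(za, zc), "shared")
})

test_that("binarize uses a strict threshold and is monotone in it", {
  z <- screen_matrix(matrix(c(-4, -2.9, -3.0001, -3.0, 0, -3.5), 6, 1,
                            dimnames = list(paste0("g", 1:6), "L1")),
                     flavor = "z")
  b <- binarize(z)
  expect_equal(as.vector(b$values), c(1, 0, 1, 0, 0, 1))
  expect_true(all(b$values %in% c(0, 1)))
  # lowering the threshold never adds hits
  b_low <- binarize(z, threshold = -3.6)
  expect_true(all(b_low$values <= b$values))
  zero <- screen_matrix(matrix(0, 3, 2, dimnames = list(paste0("g", 1:3),
                                                        c("L1", "L2"))),
                        flavor = "z")
  expect_true(all(binarize(zero)$values == 0))
})

test_that("impute_row_median fills gaps from the row and flags all-NA rows", {
  vals <- matrix(c(1, NA, 3, 5, NA, NA), 2, 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), paste0("L", 1:3)))
  x <- screen_matrix(vals, flavor = "continuous")
  imp <- impute_row_median(x)
  expect_equal(as.vector(imp$values["gA", ]), c(1, 2, 3))
  expect_equal(as.vector(imp$values["gB", ]), c(5, 5, 5))

  clean <- screen_matrix(matrix(rnorm(6), 2, 3,
                                dimnames = list(c("gA", "gB"), paste0("L", 1:3))),
                         flavor = "continuous")
  expect_identical(impute_row_median(clean)$values, clean$values)

  allna <- screen_matrix(matrix(c(NA_real_, NA_real_, 1, 2), 2, 2, byrow = TRUE,
                                dimnames = list(c("gBAD", "gOK"), c("L1", "L2"))),
                         flavor = "continuous")
  expect_error(impute_row_median(allna), "gBAD")
})

test_that("GMT parsing, duplicate names and round trips behave", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("LSm\tx\tA\tB\tC", "eIF3\tdesc\tD\tE"), path)
  gsc <- read_gmt(path)
  expect_equal(gsc$sets$LSm, c("A", "B", "C"))
  expect_equal(length(gsc), 2L)

  writeLines(c("S1\tx\tA", "S1\tx\tB"), path)
  expect_error(read_gmt(path), "duplicate set name")

  gsc2 <- gene_set_collection(list(a = c("G1", "G2", "G2"), b = "G9"))
  expect_equal(gsc2$sets$a, c("G1", "G2"))        # dedup within set
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gsc2, out)
  back <- read_gmt(out)
  expect_identical(back$sets, gsc2$sets)
})

test_that("matrix TSV round trip is bit exact and ragged rows are caught", {
  gen <- tiny_screen()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(gen$matrix, path)
  back <- read_matrix_tsv(path, flavor = "binary")
  expect_identical(back$values, gen$matrix$values)
  expect_identical(back$line_ids, gen$matrix$line_ids)

  cont <- screen_matrix(matrix(c(pi, -1 / 3, NA, 1e-12), 2, 2,
                               dimnames = list(c("g1", "g2"), c("L1", "L2"))),
                        flavor = "continuous")
  write_matrix_tsv(cont, path)
  back2 <- read_matrix_tsv(path, flavor = "continuous")
  expect_identical(back2$values, cont$values)

  writeLines(c("gene\tL1\tL2", "g1\t0\t1", "g2\t0"), path)
  expect_error(read_matrix_tsv(path), "line 3")
})

test_that("duplicated gene symbols are retained with disambiguated keys", {
  vals <- matrix(rnorm(6), 3, 2,
                 dimnames = list(c("TP53", "TP53", "KRAS"), c("L1", "L2")))
  x <- screen_matrix(vals, flavor = "continuous")
  expect_equal(x$gene_ids, c("TP53", "TP53", "KRAS"))
  expect_false(anyDuplicated(x$gene_keys) > 0)
  # both rows participate in profile extraction by symbol
  ex <- extract_profile(x, c("TP53", "KRAS"), min_mapped = 2L)
  expect_equal(ex$r, 3L)
})

test_that("extract_profile maps, deduplicates and skips small sets", {
  gen <- tiny_screen()
  M <- gen$matrix
  set <- M$gene_ids[c(1, 2, 2, 5)]            # duplicate symbol listed twice
  ex <- extract_profile(M, set, min_mapped = 3L)
  expect_equal(ex$r, 3L)
  expect_identical(colnames(ex$profile), M$line_ids)
  expect_false(ex$skipped)

  ex2 <- extract_profile(M, c(M$gene_ids[1], "NOT_A_GENE"), min_mapped = 3L)
  expect_true(ex2$skipped)
  expect_equal(ex2$unmapped, "NOT_A_GENE")
  expect_null(ex2$profile)
})

test_that("normalize_medians subtracts row then column medians once", {
  vals <- matrix(c(7, 6, 4, 2, 2, 9, 2, 5, 2), 3, 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), paste0("L", 1:3)))
  raw <- screen_matrix(vals, flavor = "raw")
  nm <- normalize_medians(raw)
  step1 <- sweep(vals, 1, apply(vals, 1, median))
  expected <- sweep(step1, 2, apply(step1, 2, median))
  expect_equal(unname(nm$values), unname(expected))
  # the two passes are applied row-first: reversing the order differs here
  alt1 <- sweep(vals, 2, apply(vals, 2, median))
  alt <- sweep(alt1, 1, apply(alt1, 1, median))
  expect_false(isTRUE(all.equal(unname(nm$values), unname(alt))))
})
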