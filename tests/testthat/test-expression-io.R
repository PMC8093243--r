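# Count-matrix I/O, CPM normalization, QC filtering, replicate averaging,
# z-scoring, and GMT parsing.

test_that("count matrix round-trips through TSV and validates its contract", {
  counts <- matrix(c(5, 0, 3, 2, 7, 1), nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  m <- count_matrix(counts, dup_pct = c(gA = 1, gB = 30, gC = 5))
  expect_equal(dim(m), c(3L, 2L))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  m2 <- suppressMessages(read_count_matrix(path))
  expect_equal(unclass(m2)[, ], unclass(m)[, ])
  expect_equal(attr(m2, "dup_pct"), attr(m, "dup_pct"))

  # duplicate gene ID named in the error
  bad <- counts; rownames(bad) <- c("MYC", "MYC", "gC")
  expect_error(count_matrix(bad), "duplicate gene ID: MYC")

  # negative entry located by (gene, sample)
  neg <- counts; neg["gB", "s2"] <- -1
  expect_error(count_matrix(neg), "gene 'gB', sample 's2'")
  frac <- counts; frac["gA", "s1"] <- 1.5
  expect_error(count_matrix(frac), "invalid count")
})

test_that("CPM normalization scales columns to one million and is idempotent", {
  counts <- matrix(c(25, 75, 0, 1, 0, 3), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("a", "b")))
  m <- count_matrix(counts)
  cpm <- cpm_normalize(m)
  expect_equal(expr_unit(cpm), "CPM")
  expect_equal(unname(unclass(cpm)[, "a"]), c(250000, 750000, 0))
  expect_equal(unname(unclass(cpm)[, "b"]), c(250000, 0, 750000))
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))

  # equal counts -> 1e6 / n each
  eq <- count_matrix(matrix(7, 4, 1, dimnames = list(paste0("g", 1:4), "s")))
  expect_equal(unname(unclass(cpm_normalize(eq))[, 1]), rep(2.5e5, 4))

  # idempotent up to scaling: re-normalizing a CPM matrix is the identity
  expect_equal(unclass(cpm_normalize(cpm))[, ], unclass(cpm)[, ])

  # zero-total sample named
  z <- counts; z[, "b"] <- 0
  expect_error(cpm_normalize(count_matrix(z)), "zero-total sample: b")
})

test_that("CPM agrees with edgeR's on a random count matrix", {
  skip_if_not_installed("edgeR")
  set.seed(5)
  counts <- matrix(rpois(60, 50), 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  mine <- unclass(cpm_normalize(count_matrix(counts)))[, ]
  ref <- edgeR::cpm(counts)
  expect_equal(mine, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("QC filter removes mean CPM < 5 and dup% > 20, strictly, idempotently", {
  # 10 genes: 3 fail the CPM rule, 3 fail the dup rule, disjointly -> 4 left
  means <- c(4, 4.9, 0, 10, 20, 30, 40, 6, 7, 8)
  dup <- c(0, 0, 0, 25, 21, 100, 5, 10, 20, 15)  # genes 4,5,6 fail dup
  m <- make_cpm(matrix(rep(means, 2), ncol = 2))
  f <- filter_genes_qc(m, dup_pct = dup)
  expect_equal(rownames(f), c("g7", "g8", "g9", "g10"))

  # boundary: dup_pct exactly 20 retained (g9), mean CPM exactly 5 retained
  b <- make_cpm(matrix(c(5, 4.999), ncol = 1))
  expect_equal(rownames(filter_genes_qc(b, dup_pct = c(20, 0))), "g1")

  # idempotence
  f2 <- filter_genes_qc(f, dup_pct = dup[7:10])
  expect_equal(unclass(f2)[, ], unclass(f)[, ])

  # missing dup_pct: criterion skipped with a warning
  expect_warning(fw <- filter_genes_qc(m), "dup_pct unavailable")
  expect_equal(nrow(fw), 7)

  expect_error(filter_genes_qc(make_cpm(matrix(c(1, 2), ncol = 1)),
                               dup_pct = c(0, 0)),
               "empty matrix after QC")
})

test_that("low-expression filter uses a strict mean-CPM cutoff", {
  m <- make_cpm(matrix(c(0.5, 1.0, 2.0), ncol = 1))
  expect_equal(rownames(filter_low_expression(m)), c("g2", "g3"))
  # cpm_min = 0 is the identity; single sample mean is the sample itself
  expect_equal(nrow(filter_low_expression(m, cpm_min = 0)), 3)
})

test_that("replicate averaging collapses annotated groups by the mean", {
  vals <- matrix(c(2, 10, 4, 20, 6, 30, 1, 1, 5, 5, 9, 9), nrow = 2,
                 dimnames = list(c("gA", "gB"), paste0("s", 1:6)))
  m <- expr_matrix(vals, unit = "CPM")
  ann <- data.frame(sample_id = paste0("s", 1:6),
                    group = "x",
                    replicate_of = c("r1", "r2", "r2", "r3", "r3", "r3"))
  av <- average_replicates(m, ann)
  expect_equal(colnames(av), c("r1", "r2", "r3"))
  expect_equal(unname(unclass(av)["gA", ]), c(2, mean(c(4, 6)), mean(c(1, 5, 9))))
  # singleton group is the identity column
  expect_equal(unclass(av)[, "r1"], vals[, "s1"])
  expect_error(average_replicates(m, ann[-1, ]), "without annotation: s1")
})

test_that("z-scoring satisfies its mean/variance invariants on random matrices", {
  v <- matrix(c(1, 2, 3), 1, dimnames = list("g", paste0("s", 1:3)))
  z <- zscore_matrix(expr_matrix(v, unit = "counts"), log2_transform = FALSE)
  expect_equal(unname(unclass(z)[1, ]), c(-1, 0, 1))

  # constant gene dropped with warning
  v2 <- rbind(v, gc = c(5, 5, 5))
  expect_warning(z2 <- zscore_matrix(expr_matrix(v2, unit = "counts"),
                                     log2_transform = FALSE),
                 "zero-variance")
  expect_equal(rownames(z2), "g")

  set.seed(17)
  for (i in 1:100) {
    m <- matrix(rnorm(6 * 4, sd = runif(1, 0.5, 5)), 6,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
    zg <- zscore_matrix(expr_matrix(m, unit = "counts"),
                        axis = "per_gene_across_samples",
                        log2_transform = FALSE)
    expect_true(all(abs(rowMeans(zg)) < 1e-12))
    expect_true(all(abs(apply(zg, 1, sd) - 1) < 1e-9))
    zs <- zscore_matrix(expr_matrix(m, unit = "counts"),
                        axis = "per_sample_across_genes",
                        log2_transform = FALSE)
    expect_true(all(abs(colMeans(zs)) < 1e-12))
    expect_true(all(abs(apply(zs, 2, sd) - 1) < 1e-9))
  }
})

test_that("GMT files parse, de-duplicate members, and reject malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tg1\tg2", "S2\tother\tg3\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("S1", "S2"))
  expect_equal(length(sets$S1), 2)
  expect_equal(attr(sets$S2, "description"), "other")

  writeLines("S1\tdesc\tg1\tg1", path)
  expect_warning(s <- read_gmt(path), "duplicate members")
  expect_equal(length(s$S1), 1)

  writeLines(c("S1\tdesc\tg1", "S1\tdesc\tg2"), path)
  expect_error(read_gmt(path), "duplicate set name: S1")

  writeLines("S1\tdesc", path)
  expect_error(read_gmt(path), "line 1 has fewer than 3 fields")

  # round-trip
  out <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(A = c("g1", "g2"), B = c("g9"))
  attr(sets$A, "description") <- "first"
  write_gmt(sets, out)
  back <- read_gmt(out)
  expect_equal(unname(unlist(back)), c("g1", "g2", "g9"))
})
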