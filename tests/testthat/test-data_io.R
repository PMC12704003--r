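test_that("Matrix-Market triplet semantics and round trips hold", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "2 2 3"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  counts <- read_counts(dir, "mtx")
  expect_identical(unname(counts),
                   matrix(c(5L, 0L, 0L, 0L, 3L, 0L), 3, 2))
  expect_identical(rownames(counts), c("gA", "gB", "gC"))

  set.seed(1)
  orig <- tiny_counts(matrix(rpois(24, 2), 4, 6))
  for (fmt in c("mtx", "tsv")) {
    path <- if (fmt == "mtx") file.path(dir, "rt")
            else file.path(dir, "rt.tsv")
    write_counts(orig, path, fmt)
    back <- read_counts(path, fmt)
    expect_identical(back, orig)
  }
})

test_that("malformed Matrix-Market inputs are rejected with diagnostics", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 5", "1 1 2"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  expect_error(read_counts(dir, "mtx"), "duplicate triplet.*gene 1, cell 1")

  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 1 2.5"), file.path(dir, "matrix.mtx"))
  expect_error(read_counts(dir, "mtx"), "non-integer")

  writeLines("not a header", file.path(dir, "matrix.mtx"))
  expect_error(read_counts(dir, "mtx"))
})

test_that("log_normalize matches its formula and contracts", {
  counts <- tiny_counts(matrix(c(1L, 3L, 0L, 2L), 2, 2))
  expr <- log_normalize(counts, scale_factor = 4)
  expect_equal(expr[, 1], c(g01 = log(2), g02 = log(4)))
  # entry zero iff count zero
  expect_identical(unname(expr == 0), unname(counts == 0))
  # per-cell identity: sum(exp(entry) - 1) = scale_factor
  set.seed(2)
  big <- tiny_counts(matrix(rpois(200, 3) + 1, 10, 20))
  e <- log_normalize(big, 1e4)
  expect_equal(unname(colSums(exp(e) - 1)), rep(1e4, 20))
  # strictly monotone within a cell
  ord <- order(big[, 5])
  expect_true(all(diff(e[ord, 5]) >= 0))
  # all-zero gene stays zero
  z <- tiny_counts(rbind(c(0L, 0L), c(2L, 1L)))
  expect_equal(unname(log_normalize(z)[1, ]), c(0, 0))
  # zero-total cell rejected by ID
  bad <- tiny_counts(matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_error(log_normalize(bad), "c02")
})

test_that("analysis gene selection applies band, HVG and detection rules", {
  set.seed(3)
  n <- 200
  mk <- function(frac, hi = FALSE) {
    x <- integer(n)
    on <- sample(n, round(frac * n))
    x[on] <- if (hi) rpois(length(on), 8) + 1L else rep(1L, length(on))
    x
  }
  counts1 <- tiny_counts(rbind(
    housekeeping = rep(1L, n),
    everywhere = mk(0.6), both_ok = mk(0.10, hi = TRUE),
    only2_detected = integer(n), low = mk(0.10),
    filler1 = mk(0.2), filler2 = mk(0.3)), cells = sprintf("a%03d", 1:n))
  counts2 <- tiny_counts(rbind(
    housekeeping = rep(1L, n),
    everywhere = mk(0.6), both_ok = mk(0.10, hi = TRUE),
    only2_detected = mk(0.1), low = mk(0.10),
    filler1 = mk(0.2), filler2 = mk(0.3)), cells = sprintf("b%03d", 1:n))
  e1 <- log_normalize(counts1); e2 <- log_normalize(counts2)
  gs <- select_analysis_genes(e1, e2, n_hvg = 10)
  # 60% expression frequency: outside the 0.5-50% band
  expect_false("everywhere" %in% gs$gene_ids)
  # zero detected cells in condition 1: excluded no matter what
  expect_false("only2_detected" %in% gs$gene_ids)
  expect_true("both_ok" %in% gs$gene_ids)
  # symmetric up to provenance
  gs_sw <- select_analysis_genes(e2, e1, n_hvg = 10)
  expect_identical(gs$gene_ids, gs_sw$gene_ids)

  # union rule: HVG in one condition only is enough (among detected genes)
  gs2 <- select_analysis_genes(e1, e2, n_hvg = 2)
  pr <- gs2$provenance
  expected <- pr$gene_id[(pr$passed1 | pr$passed2) &
                           pr$detected1 & pr$detected2]
  expect_identical(sort(gs2$gene_ids), sort(expected))
})
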