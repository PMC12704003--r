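test_that("two clean blocks yield exactly two full modules", {
  D <- block_dist(c(10, 10))
  ms <- assemble_modules(rownames(D), D)
  expect_length(ms$modules, 2L)
  got <- lapply(ms$modules, `[[`, "gene_ids")
  # oracle: the 2-partition minimizing average intra-distance is the blocks
  expect_setequal(got[[1]], rownames(D)[1:10])
  expect_setequal(got[[2]], rownames(D)[11:20])
  # invariant to the input order of significant genes
  ms2 <- assemble_modules(rev(rownames(D)), D)
  expect_identical(lapply(ms$modules, `[[`, "gene_ids"),
                   lapply(ms2$modules, `[[`, "gene_ids"))
})

test_that("undersized clusters are dropped and outliers filtered once", {
  D <- block_dist(c(10, 4))
  ms <- assemble_modules(rownames(D), D)
  expect_length(ms$modules, 1L)
  expect_setequal(ms$modules[[1]]$gene_ids, rownames(D)[1:10])

  # hand-checkable outlier: one gene clearly off its 5 module mates (mean
  # intra-distance 4 vs ~0.1, far beyond median + 3 x MAD) yet close
  # enough to be cut into the same cluster
  D2 <- block_dist(c(6, 10))
  far <- rownames(D2)[1]
  D2[far, 2:6] <- D2[2:6, far] <- 4
  ms2 <- assemble_modules(rownames(D2), D2)
  expect_true(far %in% ms2$outlier_genes)
  expect_false(far %in% unlist(lapply(ms2$modules, `[[`, "gene_ids")))
  # idempotent: re-running the filter on retained genes removes nothing
  for (m in ms2$modules) {
    sub <- D2[m$gene_ids, m$gene_ids]
    mean_d <- rowSums(sub) / (length(m$gene_ids) - 1)
    expect_true(all(mean_d <= median(mean_d) + 3 * mad(mean_d)))
  }
  expect_warning(assemble_modules(rownames(D)[1:3], D[1:3, 1:3]),
                 "min_size")
})

test_that("module importance weights eigenvector fractions by eigenvalue", {
  D <- block_dist(c(10, 10))
  ms <- assemble_modules(rownames(D), D)
  spec <- structure(list(values = c(3, 2, rep(0.5, 18)),
                         vectors = matrix(0, 20, 20),
                         n_sig = 2L, gene_ids = rownames(D)),
                    class = "spectral_result")
  # genes of module 1 -> eigenvector 1; module 2 split 50/50
  sig <- data.frame(gene_id = rownames(D),
                    significant = TRUE,
                    assigned_eigenvector = c(rep(1L, 10),
                                             rep(c(1L, 2L), 5)))
  ms <- module_importance(ms, spec, sig)
  w <- setNames(vapply(ms$modules, `[[`, 0, "importance"),
                vapply(ms$modules, function(m)
                  as.character(length(m$gene_ids)), ""))
  lam_hat <- c(3, 2) / 5
  expect_equal(sort(unname(w), decreasing = TRUE),
               sort(c(lam_hat[1], 0.5 * lam_hat[1] + 0.5 * lam_hat[2]),
                    decreasing = TRUE))
  # modules come back sorted by importance
  expect_true(!is.unsorted(rev(vapply(ms$modules, `[[`, 0, "importance"))))
  # a module gene without a contributing eigenvector is a pipeline bug
  sig_bad <- sig; sig_bad$assigned_eigenvector[1] <- NA
  expect_error(module_importance(ms, spec, sig_bad), "contributing")
})

test_that("module activity is scaled to [0,1] and tracks the signal", {
  set.seed(21)
  counts <- tiny_counts(matrix(rpois(30 * 50, 2), 30, 50))
  expr <- log_normalize(counts)
  act <- module_activity(expr, rownames(expr)[1:5], seed = 3)
  expect_equal(min(act), 0)
  expect_equal(max(act), 1)
  # deterministic given the seed
  expect_identical(act, module_activity(expr, rownames(expr)[1:5],
                                        seed = 3))
  # constant expression: all-zero scores
  flat <- tiny_counts(matrix(2L, 10, 8))
  expect_equal(unname(module_activity(log_normalize(flat),
                                      rownames(flat)[1:3],
                                      method = "mean")),
               rep(0, 8))
  expect_error(module_activity(expr, character()), "empty")
})

test_that("injected-module activity is elevated inside its neighborhood", {
  cfg <- simulation_config(n_genes = 120L, n_cells = 300L, seed = 5L)
  ds <- simulate_benchmark(cfg, preset = "signal", inject_into = 2L)
  expr <- log_normalize(ds$counts2)
  act <- module_activity(expr, ds$truth, seed = 1)
  inside <- ds$neighborhoods[[1]]$cell_ids
  inside <- intersect(inside, names(act))
  expect_gt(median(act[inside]),
            median(act[setdiff(names(act), inside)]))
})
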