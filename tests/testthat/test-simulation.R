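test_that("background generation is reproducible and over-dispersed", {
  cfg <- simulation_config(seed = 7L)
  a <- generate_background(200L, 150L, 42L, cfg)
  b <- generate_background(200L, 150L, 42L, cfg)
  expect_identical(a, b)
  expect_identical(dim(a), c(200L, 150L))
  expect_true(all(a >= 0))
  # NB moment identity var = mu + mu^2/theta: across genes the variance
  # exceeds the mean on average at finite dispersion
  mu <- rowMeans(a)
  v <- apply(a, 1, var)
  expect_gt(mean(v - mu), 0)
  d <- generate_background(200L, 150L, 43L, cfg)
  expect_false(identical(a, d))
})

test_that("neighborhoods are core-anchored nearest-cell sets", {
  cfg <- simulation_config(seed = 8L)
  counts <- generate_background(150L, 200L, 99L, cfg)
  nb <- pick_neighborhood(counts, 0.1, seed = 3L)
  expect_identical(length(nb$members), 20L)
  expect_true(nb$core %in% nb$members)
  # every member is at least as close to the core as every non-member
  expr <- log_normalize(counts)
  pc <- colodiff:::.pca_coords(expr, 10L, 150L)
  d <- sqrt(colSums((t(pc) - pc[nb$core, ])^2))
  expect_lte(max(d[nb$members]), min(d[-nb$members]) + 1e-12)
  expect_error(pick_neighborhood(counts, 0.001, 1L), "fewer than 2")
})

test_that("candidate genes obey the band, detection and dispersion rules", {
  n <- 200
  base <- matrix(0L, 4, n)
  base[1, 1:120] <- 1L                                   # 60% frequency
  base[2, 1:20] <- c(9L, rep(1L, 19))                    # var > mean
  base[3, 1:20] <- 1L                                    # var < mean
  base[4, 1:20] <- c(9L, rep(1L, 19))                    # absent elsewhere
  counts_test <- tiny_counts(base, genes = c("toowide", "good", "flat",
                                             "undetected"))
  other <- tiny_counts(rbind(toowide = rep(1L, n), good = rep(1L, n),
                             flat = rep(1L, n),
                             undetected = rep(0L, n)),
                       cells = sprintf("o%03d", 1:n))
  cand <- candidate_genes(counts_test, other)
  expect_identical(cand, "good")
})

test_that("signal injection follows the within/outside models", {
  cfg <- simulation_config(n_genes = 100L, n_cells = 240L,
                           p_dropout = 0.4, seed = 9L)
  counts <- generate_background(100L, 240L, 77L, cfg)
  nb <- pick_neighborhood(counts, 0.1, seed = 2L)
  genes <- candidate_genes(counts, counts)[1:5]
  # p_outside min rule, forced: |nb| = 100, outside = 1000, baseline 0.3
  expect_equal(min(0.3, 100 / 1000), 0.1)
  inj <- inject_signal(counts, nb, genes, cfg, seed = 4L)
  # only the selected genes change; the rest of the matrix is untouched
  expect_identical(inj[setdiff(rownames(counts), genes), ],
                   counts[setdiff(rownames(counts), genes), ])
  # full dropout zeroes every injected entry
  cfg_drop <- simulation_config(n_genes = 100L, n_cells = 240L,
                                p_dropout = 1, seed = 9L)
  inj0 <- inject_signal(counts, nb, genes, cfg_drop, seed = 4L)
  expect_true(all(inj0[genes, ] == 0L))
  # expressing cells outside never exceed inside in expectation
  ins <- out <- 0
  for (s in 1:8) {
    rep_inj <- inject_signal(counts, nb, genes, cfg, seed = 100L + s)
    ins <- ins + sum(rep_inj[genes, nb$members] > 0)
    out <- out + sum(rep_inj[genes, -nb$members] > 0)
  }
  expect_lte(out, ins)
  # injected genes stay within the analysis expression band on average
  frac <- rowMeans(inj[genes, ] > 0)
  expect_true(all(frac >= 0.005 & frac <= 0.5))
})

test_that("benchmark presets record truth and leave the reference intact", {
  cfg <- simulation_config(n_genes = 120L, n_cells = 300L, seed = 11L)
  ds <- simulate_benchmark(cfg, preset = "signal", inject_into = 2L)
  expect_length(ds$truth, cfg$n_perturbed_genes)
  ref <- generate_background(cfg$n_genes, cfg$n_cells,
                             colodiff:::.child_seed(11L, 1L), cfg,
                             prefix = "a",
                             gene_params = colodiff:::background_gene_params(
                               cfg$n_genes, colodiff:::.child_seed(11L, 0L),
                               cfg))
  expect_identical(unname(ds$counts1), unname(ref))
  # bit-identical regeneration from (config, seed)
  ds2 <- simulate_benchmark(cfg, preset = "signal", inject_into = 2L)
  expect_identical(ds$counts1, ds2$counts1)
  expect_identical(ds$counts2, ds2$counts2)
  expect_identical(ds$truth, ds2$truth)

  demo <- simulate_benchmark(simulation_config(n_genes = 220L,
                                               n_cells = 300L,
                                               n_perturbed_genes = 8L,
                                               seed = 12L),
                             preset = "demo")
  expect_named(demo$modules, c("private1a", "private1b", "private2a",
                               "private2b", "sharedA", "sharedB"))
  expect_true(all(lengths(demo$modules) == 8L))
  # private neighborhoods of the same condition are disjoint
  expect_length(intersect(demo$neighborhoods$private1a_cond1$members,
                          demo$neighborhoods$private1b_cond1$members), 0L)
  expect_length(intersect(demo$neighborhoods$private2a_cond2$members,
                          demo$neighborhoods$private2b_cond2$members), 0L)
  # shared modules are injected into both conditions
  expect_true(all(c("sharedA_cond1", "sharedA_cond2") %in%
                    names(demo$neighborhoods)))
})
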