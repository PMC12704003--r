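test_that("the adaptive kernel follows its closed form", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  K <- adaptive_kernel(D, k_local = 1)
  expect_equal(K$sigma, c(1, 1, 1))
  expect_equal(K$K["a", "b"], exp(-1))
  expect_equal(K$K["a", "c"], exp(-4))
  expect_equal(unname(diag(K$K)), rep(1, 3))
  # symmetric for arbitrary (even asymmetric-bandwidth) inputs
  set.seed(10)
  pts <- matrix(rnorm(40), 20)
  Dr <- as.matrix(dist(pts))
  dimnames(Dr) <- list(sprintf("g%d", 1:20), sprintf("g%d", 1:20))
  Kr <- adaptive_kernel(Dr, k_local = 3)
  expect_equal(Kr$K, t(Kr$K))
  expect_true(all(Kr$K > 0 & Kr$K <= 1))
  # duplicate gene distributions: zero bandwidth is repaired with warning
  Dd <- Dr; Dd[1, 2] <- Dd[2, 1] <- 0
  expect_warning(adaptive_kernel(Dd, k_local = 1), "bandwidth")
})

test_that("the normalized operator has the stochastic-similarity spectrum", {
  set.seed(11)
  Dr <- as.matrix(dist(matrix(rnorm(60), 30)))
  dimnames(Dr) <- list(sprintf("g%d", 1:30), sprintf("g%d", 1:30))
  L <- normalized_operator(adaptive_kernel(Dr, k_local = 4))
  es <- eigen(L$L, symmetric = TRUE)
  expect_equal(es$values[1], 1, tolerance = 1e-10)
  expect_true(all(abs(es$values) <= 1 + 1e-10))
  # Perron eigenvector is proportional to sqrt(degrees)
  v <- es$vectors[, 1] * sign(es$vectors[1, 1])
  ref <- sqrt(L$degrees) / sqrt(sum(L$degrees))
  expect_equal(v, unname(ref), tolerance = 1e-8)
  # identity kernel maps to the identity operator
  I5 <- diag(5)
  dimnames(I5) <- list(letters[1:5], letters[1:5])
  expect_equal(unname(normalized_operator(I5)$L), diag(5))
})

test_that("knee detection matches hand-computed examples in both flavors", {
  for (m in c("gap", "chord")) {
    expect_identical(knee_index(c(10, 9, 1, 0.9, 0.8, 0.7, 0.6, 0.5,
                                  0.4, 0.3), method = m), 2L)
    expect_identical(knee_index(c(5, 1, 0.98, 0.96, 0.94, 0.92, 0.9,
                                  0.88, 0.86, 0.84), method = m), 1L)
    expect_identical(knee_index(seq(10, 1, length.out = 12), method = m),
                     1L)
    expect_identical(knee_index(rep(2, 10), method = m), 1L)
  }
  expect_error(knee_index(c(1, 2, 3)), "descending")
  expect_error(knee_index(c(2, 1)), "3 values")
})

test_that("the differential operator shares the generalized spectrum", {
  set.seed(12)
  mkop <- function(p) {
    Dr <- as.matrix(dist(matrix(rnorm(2 * p), p)))
    dimnames(Dr) <- list(sprintf("g%d", 1:p), sprintf("g%d", 1:p))
    normalized_operator(adaptive_kernel(Dr, k_local = 3))
  }
  for (rep in 1:5) {
    L1 <- mkop(12); L2 <- mkop(12)
    Q <- differential_operator(L1, L2)
    vals <- eigen(Q$Q, symmetric = TRUE, only.values = TRUE)$values
    ref <- generalized_eigen_oracle(L1$L, L2$L + Q$c_reg * diag(12))
    expect_equal(vals, ref, tolerance = 1e-8)
    expect_true(all(eigen(L2$L + Q$c_reg * diag(12),
                          only.values = TRUE)$values > 0))
  }
  # equal operators: spectrum is lambda / (lambda + c), strictly
  # increasing in lambda and everywhere below 1
  L <- mkop(15)
  Q <- differential_operator(L, L)
  lam <- sort(eigen(L$L, only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(eigen(Q$Q, symmetric = TRUE, only.values = TRUE)$values,
               lam / (lam + Q$c_reg), tolerance = 1e-9)
  expect_identical(spectral_select(Q)$n_sig, 0L)
  # gene-order mismatch is refused
  L2 <- mkop(15)
  L2perm <- L2
  L2perm$L <- L2$L[15:1, 15:1]
  expect_error(differential_operator(L, L2perm), "gene")
})

test_that("component selection fixes signs and respects degeneracy", {
  # two tight gene blocks exist in condition 1 only; the kernel
  # neighborhood (k_local) reaches beyond the blocks so within-block
  # affinities saturate, as in the full pipeline
  mkD <- function(blocks, seed) {
    set.seed(seed)
    p <- 40
    D <- as.matrix(dist(matrix(rnorm(3 * p), p))) * 2 + 6
    for (idx in blocks) D[idx, idx] <- 0.1
    diag(D) <- 0
    ids <- sprintf("g%02d", seq_len(p))
    dimnames(D) <- list(ids, ids)
    D
  }
  D1 <- mkD(list(1:8, 9:16), 13)
  D2 <- mkD(list(), 14)
  ids <- rownames(D1)
  L1 <- normalized_operator(adaptive_kernel(D1, 10))
  L2 <- normalized_operator(adaptive_kernel(D2, 10))
  spec <- spectral_select(differential_operator(L1, L2))
  # the planted structure is certified (eigenvalues above 1) and every
  # selected component loads on block genes
  expect_gte(spec$n_sig, 1L)
  expect_true(all(spec$values[seq_len(spec$n_sig)] > 1))
  tops <- unique(unlist(lapply(seq_len(spec$n_sig), function(l)
    ids[order(-abs(spec$vectors[, l]))[1:8]])))
  expect_true(all(tops %in% ids[1:16]))
  # sign convention: largest-magnitude loading is positive
  for (l in 1:4)
    expect_gt(spec$vectors[which.max(abs(spec$vectors[, l])), l], 0)
  # reversing the direction: the blocks are dense in the denominator now,
  # so no component certifies differential structure the other way
  spec_sw <- spectral_select(differential_operator(L2, L1))
  expect_identical(spec_sw$n_sig, 0L)
})

test_that("locfdr calling is calibrated and catches planted outliers", {
  # moment standardization yields exact mean-0 sd-1 z-scores
  set.seed(14)
  x <- rnorm(300, 5, 3)
  r <- locfdr_select(x, standardize = "moment")
  expect_equal(mean(r$z), 0, tolerance = 1e-12)
  expect_equal(sd(r$z), 1, tolerance = 1e-12)
  # planted outliers: all ten flagged, nulls essentially untouched
  for (s in 1:3) {
    set.seed(s)
    z <- c(rnorm(990), rnorm(10, 8, 0.1))
    r <- locfdr_select(z)
    expect_identical(sum(r$significant[991:1000]), 10L)
    expect_lte(sum(r$significant[1:990]), 2L)
  }
  # pure null: flagged fraction stays at the percent level
  set.seed(15)
  fl <- replicate(10, mean(locfdr_select(rnorm(500))$significant))
  expect_lt(mean(fl), 0.01)
  expect_error(locfdr_select(rep(1, 100)), "spread")
  expect_error(locfdr_select(rnorm(20)), "50")
})
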