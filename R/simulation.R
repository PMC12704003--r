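# Fully synthetic two-condition benchmark: a negative-binomial background
# with log-normal gene means and library-size factors plus a smooth
# low-dimensional latent manifold (without it, cell-cell distances
# concentrate and "neighborhood" has no geometric meaning), and injected
# co-localized signals confined to a cell neighborhood picked in
# top-10-PC space. Inside the neighborhood injected genes draw from
# NB(mu_signal, theta) x Bernoulli(1 - p_dropout); outside from
# NB(mu_noise, theta) x Bernoulli(p_outside) x Bernoulli(1 - p_dropout),
# with p_outside capped so the expected number of expressing cells outside
# never exceeds the number inside. Every entry is sampled independently
# per gene and cell, so co-localization is carried by location only.

#' Simulation configuration
#'
#' Defaults reproduce the benchmark conditions: neighborhoods covering 10%
#' of cells, dropout 0.4, 15 perturbed genes, outside-expression baseline
#' 0.3; the background draws gene means from a log-normal centered near
#' 0.1 counts/cell with unit-scale spread, library-size factors from a
#' log-normal with sdlog 0.3, and NB dispersion 2 -- which places typical
#' genes in the 0.5--50% expression-fraction band used by the analysis.
#'
#' @param n_genes,n_cells Background dimensions per condition.
#' @param neighborhood_frac Fraction of cells in an injected neighborhood.
#' @param p_dropout Dropout probability applied to injected entries.
#' @param n_perturbed_genes Genes per injected module.
#' @param p_outside_baseline Baseline outside-expression fraction.
#' @param mean_log_mu,mean_log_sd Log-normal parameters of gene means.
#' @param dispersion Shared NB dispersion (size) of the background.
#' @param libsize_sd sdlog of the cell library-size factors.
#' @param n_latent,latent_sd,latent_frac Latent manifold: number of latent
#'   cell dimensions, the scale of gene loadings on them, and the fraction
#'   of genes carrying loadings. Cells get standard-normal latent
#'   coordinates and loaded genes modulate their NB mean smoothly along
#'   them, giving the simulated manifold real geometry.
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 1000L, n_cells = 1000L,
                              neighborhood_frac = 0.10, p_dropout = 0.4,
                              n_perturbed_genes = 15L,
                              p_outside_baseline = 0.3,
                              mean_log_mu = log(0.1), mean_log_sd = 1.2,
                              dispersion = 2, libsize_sd = 0.3,
                              n_latent = 3L, latent_sd = 0.6,
                              latent_frac = 0.5, seed = 1L) {
  stopifnot(neighborhood_frac > 0, neighborhood_frac < 1,
            p_dropout >= 0, p_dropout <= 1,
            p_outside_baseline > 0, p_outside_baseline < 1,
            n_genes >= 1, n_cells >= 2, n_perturbed_genes >= 1,
            dispersion > 0)
  structure(as.list(environment()), class = "sim_config")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(list = ".Random.seed", envir = globalenv()))
  force(expr)
}

# deterministic child seeds derived from a master seed (kept below 2^31)
.child_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 7919L + stream * 104729L
}

#' Draw the gene-level background parameters
#'
#' Gene base means (log-normal) and latent-manifold loadings. Drawing
#' these once and reusing them for both conditions makes the conditions
#' biologically identical populations, so that only injected signals --
#' not background structure -- differ between them.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param config A `sim_config`.
#' @return A list with `mu_g` (base means) and `beta` (genes x latent
#'   loading matrix).
#' @export
background_gene_params <- function(n_genes, seed,
                                   config = simulation_config()) {
  .with_seed(seed, {
    mu_g <- rlnorm(n_genes, config$mean_log_mu, config$mean_log_sd)
    beta <- matrix(rnorm(n_genes * config$n_latent, 0, config$latent_sd),
                   n_genes)
    beta[runif(n_genes) > config$latent_frac, ] <- 0
    list(mu_g = mu_g, beta = beta)
  })
}

#' Generate a negative-binomial background count matrix
#'
#' Counts are `NB(mu = gene_mean x latent modulation x cell_factor,
#' size = dispersion)`: gene base means come from a log-normal, cells lie
#' on a smooth latent manifold (standard-normal coordinates) that loaded
#' genes follow, and library-size factors are log-normal. Deterministic
#' given the seed.
#'
#' @param n_genes,n_cells Dimensions.
#' @param seed Integer seed.
#' @param config A `sim_config` supplying the distribution parameters.
#' @param prefix Gene/cell ID prefix (used to keep the two conditions'
#'   cell IDs distinct).
#' @param gene_params Optional shared gene-level parameters from
#'   [background_gene_params()]; drawn fresh from `seed` when `NULL`.
#' @return An integer matrix, genes x cells, with IDs.
#' @export
generate_background <- function(n_genes, n_cells, seed,
                                config = simulation_config(),
                                prefix = "c", gene_params = NULL) {
  if (is.null(gene_params))
    gene_params <- background_gene_params(n_genes, seed + 1L, config)
  stopifnot(length(gene_params$mu_g) == n_genes)
  .with_seed(seed, {
    sf <- rlnorm(n_cells, 0, config$libsize_sd)
    # smooth latent manifold: loaded genes modulate their mean along the
    # cells' latent coordinates (mean-preserving in expectation)
    gamma <- matrix(rnorm(n_cells * config$n_latent), n_cells)
    beta <- gene_params$beta
    lfc <- beta %*% t(gamma) - 0.5 * rowSums(beta^2)
    mu <- (gene_params$mu_g * exp(lfc)) * rep(sf, each = n_genes)
    counts <- matrix(
      rnbinom(n_genes * n_cells, size = config$dispersion, mu = mu),
      nrow = n_genes)
    dimnames(counts) <- list(
      sprintf("g%04d", seq_len(n_genes)),
      sprintf("%s%04d", prefix, seq_len(n_cells)))
    storage.mode(counts) <- "integer"
    attr(counts, "latent") <- gamma
    counts
  })
}

# neighborhood anchored at a point of the shared latent space: the cells
# nearest to the anchor in this condition's latent coordinates. Used by
# the demo preset so that a "shared" module occupies the same manifold
# region in both conditions.
.latent_neighborhood <- function(counts, anchor, frac) {
  gamma <- attr(counts, "latent")
  if (is.null(gamma))
    stop("counts carry no latent coordinates", call. = FALSE)
  size <- round(frac * ncol(counts))
  d <- sqrt(colSums((t(gamma) - anchor)^2))
  members <- order(d, seq_len(ncol(counts)))[seq_len(size)]
  structure(list(core = members[1L], members = members,
                 cell_ids = colnames(counts)[members], anchor = anchor),
            class = "cell_neighborhood")
}

#' Pick a cell neighborhood around a random core cell
#'
#' The neighborhood is the core cell plus its nearest cells by Euclidean
#' distance in the top-10-PC space of the log-normalized matrix, sized
#' `round(frac x n_cells)`.
#'
#' @param counts Raw counts for one condition.
#' @param frac Neighborhood fraction of all cells.
#' @param seed Integer seed (core-cell draw).
#' @param exclude Optional cell indices the neighborhood must avoid; the
#'   core is redrawn until the member set is disjoint from them.
#' @return A list of class `cell_neighborhood` with `core`, `members`
#'   (indices) and `cell_ids`.
#' @export
pick_neighborhood <- function(counts, frac, seed, exclude = integer()) {
  n <- ncol(counts)
  size <- round(frac * n)
  if (size < 2L) stop("neighborhood would have fewer than 2 cells",
                      call. = FALSE)
  expr <- log_normalize(counts)
  pc <- .pca_coords(expr, n_components = min(10L, n - 1L),
                    n_hvg = min(2000L, nrow(expr)))
  .with_seed(seed, {
    pool <- setdiff(seq_len(n), exclude)
    for (attempt in seq_len(200L)) {
      core <- sample(pool, 1L)
      d <- sqrt(colSums((t(pc) - pc[core, ])^2))
      members <- order(d, seq_len(n))[seq_len(size)]
      if (length(intersect(members, exclude)) == 0L) break
      if (attempt == 200L)
        stop("could not place a neighborhood disjoint from 'exclude'",
             call. = FALSE)
    }
    structure(list(core = core, members = members,
                   cell_ids = colnames(counts)[members]),
              class = "cell_neighborhood")
  })
}

#' Candidate genes eligible for signal injection
#'
#' Raw-count criteria: expressed in 0.5--50% of cells of the test
#' condition, detected in at least one cell of the other condition, and
#' variance greater than mean (negative-binomial-like dispersion).
#'
#' @param counts_test Condition receiving the signal.
#' @param counts_other The other condition (shared gene universe).
#' @return Sorted character vector of candidate gene IDs.
#' @export
candidate_genes <- function(counts_test, counts_other) {
  shared <- intersect(rownames(counts_test), rownames(counts_other))
  ct <- counts_test[shared, , drop = FALSE]
  co <- counts_other[shared, , drop = FALSE]
  frac <- rowMeans(ct > 0)
  mu <- rowMeans(ct)
  v <- apply(ct, 1L, var)
  ok <- frac >= 0.005 & frac <= 0.5 & rowSums(co > 0) >= 1L & v > mu
  if (!any(ok)) stop("no candidate genes", call. = FALSE)
  sort(shared[ok])
}

# moment-based NB parameters of the injection models, from the raw counts
.injection_params <- function(counts) {
  mu_g <- rowMeans(counts)
  var_g <- apply(counts, 1L, var)
  est <- var_g > mu_g & mu_g > 0
  if (!any(est))
    stop("no genes with variance above mean; cannot estimate dispersion",
         call. = FALSE)
  theta_g <- mu_g[est]^2 / (var_g[est] - mu_g[est])
  list(mu_signal = unname(quantile(mu_g, 0.95)),
       mu_noise = unname(median(mu_g)),
       theta = median(theta_g))
}

#' Inject a co-localized signal into selected genes
#'
#' Replaces the selected genes' rows: inside the neighborhood entries draw
#' from `NB(mu_signal, theta) x Bernoulli(1 - p_dropout)`, outside from
#' `NB(mu_noise, theta) x Bernoulli(p_outside) x Bernoulli(1 - p_dropout)`
#' with `p_outside = min(p_outside_baseline, |nb| / n_outside)`.
#' `mu_signal` / `mu_noise` are the 95th percentile / median of gene-wise
#' raw-count means and `theta` the median moment dispersion.
#'
#' @param counts Raw counts to modify.
#' @param nb A `cell_neighborhood`.
#' @param genes Genes to perturb (subset of [candidate_genes()]).
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return The modified count matrix.
#' @export
inject_signal <- function(counts, nb, genes, config, seed) {
  stopifnot(inherits(nb, "cell_neighborhood"),
            all(genes %in% rownames(counts)))
  par <- .injection_params(counts)
  n <- ncol(counts)
  inside <- nb$members
  n_out <- n - length(inside)
  p_outside <- min(config$p_outside_baseline, length(inside) / n_out)
  keep <- 1 - config$p_dropout
  .with_seed(seed, {
    for (g in genes) {
      xin <- rnbinom(length(inside), size = par$theta, mu = par$mu_signal) *
        rbinom(length(inside), 1L, keep)
      xout <- rnbinom(n_out, size = par$theta, mu = par$mu_noise) *
        rbinom(n_out, 1L, p_outside) * rbinom(n_out, 1L, keep)
      row <- integer(n)
      row[inside] <- as.integer(xin)
      row[-inside] <- as.integer(xout)
      counts[g, ] <- row
    }
    counts
  })
}

#' Simulate a two-condition benchmark dataset
#'
#' `preset = "signal"` draws two independent backgrounds and injects one
#' co-localized module into the condition named by `inject_into`, leaving
#' the other untouched (the reference). `preset = "demo"` builds the
#' six-module layout: two private modules per condition in disjoint
#' neighborhoods plus two shared modules injected into both conditions.
#'
#' @param config A `sim_config`; its `seed` drives everything.
#' @param preset `"signal"` or `"demo"`.
#' @param inject_into Condition receiving the signal(s) for
#'   `preset = "signal"` (1 or 2).
#' @return A list of class `sim_dataset` with `counts1`, `counts2`,
#'   `truth` (injected gene IDs; for `"demo"` a per-module named list),
#'   `neighborhoods`, `modules`, and `config`.
#' @export
simulate_benchmark <- function(config = simulation_config(),
                               preset = c("signal", "demo"),
                               inject_into = 2L) {
  preset <- match.arg(preset)
  stopifnot(inherits(config, "sim_config"), inject_into %in% 1:2)
  seed <- config$seed
  gp <- background_gene_params(config$n_genes, .child_seed(seed, 0L), config)
  counts1 <- generate_background(config$n_genes, config$n_cells,
                                 .child_seed(seed, 1L), config, prefix = "a",
                                 gene_params = gp)
  counts2 <- generate_background(config$n_genes, config$n_cells,
                                 .child_seed(seed, 2L), config, prefix = "b",
                                 gene_params = gp)
  both <- list(counts1, counts2)
  if (preset == "signal") {
    test <- inject_into; other <- 3L - inject_into
    cand <- candidate_genes(both[[test]], both[[other]])
    genes <- .with_seed(.child_seed(seed, 3L),
                        sample(cand, min(config$n_perturbed_genes,
                                         length(cand))))
    nb <- pick_neighborhood(both[[test]], config$neighborhood_frac,
                            .child_seed(seed, 4L))
    both[[test]] <- inject_signal(both[[test]], nb, genes, config,
                                  .child_seed(seed, 5L))
    out <- list(counts1 = both[[1L]], counts2 = both[[2L]],
                truth = sort(genes),
                neighborhoods = list(nb),
                modules = list(signal = sort(genes)),
                injected_condition = test, config = config)
  } else {
    # six modules: private 1a/1b, private 2a/2b, shared A/B
    cand <- intersect(candidate_genes(counts1, counts2),
                      candidate_genes(counts2, counts1))
    need <- 6L * config$n_perturbed_genes
    if (length(cand) < need)
      stop("not enough candidate genes for the demo preset", call. = FALSE)
    picked <- .with_seed(.child_seed(seed, 3L), sample(cand, need))
    mod <- split(picked, rep(c("private1a", "private1b", "private2a",
                               "private2b", "sharedA", "sharedB"),
                             each = config$n_perturbed_genes))
    nbs <- list()
    plan <- list(private1a = 1L, private1b = 1L, private2a = 2L,
                 private2b = 2L, sharedA = 1:2, sharedB = 1:2)
    # anchors live in the shared latent space so that a shared module
    # occupies the same manifold region in both conditions. The two
    # private neighborhoods of a condition must be disjoint, as must the
    # two shared ones (in both conditions); private/shared pairs may
    # touch. A best-of-32 farthest-point anchor draw keeps all
    # neighborhoods spread out regardless.
    gamma1 <- attr(counts1, "latent")
    group_of <- c(private1a = 1L, private1b = 1L, private2a = 2L,
                  private2b = 2L, sharedA = 3L, sharedB = 3L)
    taken <- list(`1` = list(integer(), integer()),
                  `2` = list(integer(), integer()),
                  `3` = list(integer(), integer()))
    anchors <- list()
    stream <- 10L
    for (m in names(plan)) {
      conds <- plan[[m]]
      grp <- group_of[[m]]
      nb_m <- .with_seed(.child_seed(seed, stream), {
        for (attempt in seq_len(200L)) {
          props <- gamma1[sample(nrow(gamma1), 32L), , drop = FALSE]
          anchor <- if (length(anchors) == 0L) props[1L, ] else {
            amat <- do.call(rbind, anchors)
            mind <- apply(props, 1L, function(p)
              min(sqrt(rowSums((amat - rep(p, each = nrow(amat)))^2))))
            props[which.max(mind), ]
          }
          cand_nb <- lapply(conds, function(cond)
            .latent_neighborhood(both[[cond]], anchor,
                                 config$neighborhood_frac))
          clash <- any(vapply(seq_along(conds), function(s)
            length(intersect(cand_nb[[s]]$members,
                             taken[[grp]][[conds[s]]])) > 0L, TRUE))
          if (!clash) break
          if (attempt == 200L)
            stop("could not place disjoint demo neighborhoods; ",
                 "lower neighborhood_frac", call. = FALSE)
        }
        cand_nb
      })
      anchors[[m]] <- nb_m[[1L]]$anchor
      for (s in seq_along(conds)) {
        cond <- conds[s]
        taken[[grp]][[cond]] <- union(taken[[grp]][[cond]],
                                      nb_m[[s]]$members)
        both[[cond]] <- inject_signal(both[[cond]], nb_m[[s]], mod[[m]],
                                      config, .child_seed(seed, stream + s))
        nbs[[paste0(m, "_cond", cond)]] <- nb_m[[s]]
      }
      stream <- stream + 3L
    }
    out <- list(counts1 = both[[1L]], counts2 = both[[2L]],
                truth = list(private1 = sort(c(mod$private1a, mod$private1b)),
                             private2 = sort(c(mod$private2a, mod$private2b)),
                             shared = sort(c(mod$sharedA, mod$sharedB))),
                neighborhoods = nbs,
                modules = lapply(mod, sort),
                config = config)
  }
  structure(out, class = "sim_dataset")
}
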