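# Grouping of significant genes into co-localized modules on the OT
# distance submatrix: average-linkage dendrogram, dynamic cutting (static
# height scan with small-cluster merging honoring a minimum size), a
# median + 3 x MAD intra-module distance outlier filter, importance
# scoring by eigenvector assignment, and per-cell activity scores.

# dynamic tree cut, "tree" variant: cut at a height quantile mapped from
# deep_split; clusters below min_size are merged into their closest
# cluster when the average inter-cluster distance is below the cut height,
# else left unassigned (label 0)
.cut_tree_dynamic <- function(hc, dmat, min_size, deep_split) {
  if (!deep_split %in% 0:4)
    stop("deep_split must be an integer in 0..4", call. = FALSE)
  h <- quantile(hc$height, probs = 0.95 - 0.05 * deep_split, names = FALSE)
  labels <- cutree(hc, h = h)
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size & names(sizes) != "0"]
    if (length(small) == 0L) break
    merged_any <- FALSE
    for (lab in small) {
      idx <- which(labels == lab)
      others <- setdiff(unique(labels), c(lab, 0L))
      if (length(others) == 0L) { labels[idx] <- 0L; next }
      avg <- vapply(others, function(o) {
        mean(dmat[idx, labels == o, drop = FALSE])
      }, 0)
      if (min(avg) <= h) {
        labels[idx] <- others[which.min(avg)]
        merged_any <- TRUE
      } else {
        labels[idx] <- 0L
      }
    }
    if (!merged_any) break
  }
  labels
}

#' Assemble significant genes into co-localized modules
#'
#' Average-linkage hierarchical clustering of the significant genes on
#' their OT distance submatrix, dynamic tree cutting, per-module removal of
#' genes whose mean intra-module distance exceeds
#' `median + outlier_mads x MAD` (MAD with the 1.4826 consistency
#' constant, single pass), and removal of modules below `min_size`.
#'
#' @param sig_genes Character vector of significant gene IDs.
#' @param D_sub OT distance submatrix among those genes, from the same
#'   condition whose operator was the numerator.
#' @param min_size Minimum retained module size, default 5.
#' @param outlier_mads MAD multiplier of the outlier filter, default 3.
#' @param deep_split Cut depth 0..4 (deeper gives more, smaller clusters).
#' @return A list of class `module_set`: `modules` (list of `module_id`,
#'   `gene_ids`), `outlier_genes`, `unassigned_genes`.
#' @export
assemble_modules <- function(sig_genes, D_sub, min_size = 5L,
                             outlier_mads = 3, deep_split = 0L) {
  sig_genes <- sort(unique(sig_genes))
  empty <- structure(list(modules = list(), outlier_genes = character(),
                          unassigned_genes = sig_genes),
                     class = "module_set")
  if (length(sig_genes) < min_size) {
    warning("fewer than min_size significant genes; no modules assembled")
    return(empty)
  }
  dmat <- D_sub[sig_genes, sig_genes, drop = FALSE]
  hc <- hclust(as.dist(dmat), method = "average")
  labels <- .cut_tree_dynamic(hc, dmat, min_size, deep_split)
  outliers <- character()
  modules <- list()
  for (lab in sort(setdiff(unique(labels), 0L))) {
    members <- sig_genes[labels == lab]
    if (length(members) >= 2L) {
      sub <- dmat[members, members, drop = FALSE]
      mean_d <- rowSums(sub) / (length(members) - 1L)
      cut_at <- median(mean_d) + outlier_mads * mad(mean_d)
      drop <- mean_d > cut_at
      outliers <- c(outliers, members[drop])
      members <- members[!drop]
    }
    if (length(members) >= min_size)
      modules[[length(modules) + 1L]] <-
        list(module_id = paste0("M", length(modules) + 1L),
             gene_ids = members)
  }
  assigned <- unlist(lapply(modules, `[[`, "gene_ids"))
  structure(list(modules = modules, outlier_genes = outliers,
                 unassigned_genes = setdiff(sig_genes,
                                            c(assigned, outliers))),
            class = "module_set")
}

#' Score module importance from the differential spectrum
#'
#' Each gene is uniquely assigned to the highest-ranked eigenvector that
#' called it significant; for module m, `c_{m,l}` is the fraction of its
#' genes assigned to eigenvector l and the importance is
#' `w_m = sum_l c_{m,l} * lambda_hat_l`, with eigenvalues normalized to
#' sum to 1 over the selected components so that `w_m` lies in `[0, 1]`.
#' Modules are returned sorted by importance, descending.
#'
#' @param modules A `module_set` from [assemble_modules()].
#' @param spec The `spectral_result` the genes were called from.
#' @param sig_table The matching [spectral_significance()] table.
#' @return The `module_set` with `eigenvector_fractions` and `importance`
#'   filled in for every module.
#' @export
module_importance <- function(modules, spec, sig_table) {
  stopifnot(inherits(modules, "module_set"),
            inherits(spec, "spectral_result"))
  if (spec$n_sig == 0L) stop("no selected eigenvectors", call. = FALSE)
  lam <- spec$values[seq_len(spec$n_sig)]
  lam_hat <- lam / sum(lam)
  assign_of <- setNames(sig_table$assigned_eigenvector, sig_table$gene_id)
  for (i in seq_along(modules$modules)) {
    genes <- modules$modules[[i]]$gene_ids
    ev <- assign_of[genes]
    if (anyNA(ev))
      stop("module gene without a contributing eigenvector: ",
           paste(genes[is.na(ev)], collapse = ", "), call. = FALSE)
    frac <- tabulate(ev, nbins = spec$n_sig) / length(ev)
    modules$modules[[i]]$eigenvector_fractions <- frac
    modules$modules[[i]]$importance <- sum(frac * lam_hat)
  }
  ord <- order(-vapply(modules$modules, `[[`, 0, "importance"),
               vapply(modules$modules, `[[`, "", "module_id"))
  modules$modules <- modules$modules[ord]
  modules
}

#' Per-cell module activity scores
#'
#' `method = "binned_control"` computes the mean module-gene expression
#' minus the mean expression of seeded control genes drawn from
#' expression-matched bins (`n_ctrl` controls per module gene, from
#' `n_bins` equal-frequency bins of the gene mean); `method = "mean"` is
#' the plain mean module-gene expression. Raw scores are z-normalized
#' across cells and min-max scaled to `[0, 1]`; constant raw scores give
#' all zeros.
#'
#' @param expr Log-normalized matrix for one condition.
#' @param module_genes Character vector of module gene IDs.
#' @param n_bins,n_ctrl Binned-control parameters, defaults 24 and 100.
#' @param seed Integer seed for the control draw.
#' @param method `"binned_control"` or `"mean"`.
#' @return A named numeric vector of per-cell activities in `[0, 1]`.
#' @export
module_activity <- function(expr, module_genes, n_bins = 24L, n_ctrl = 100L,
                            seed = 1L, method = c("binned_control", "mean")) {
  method <- match.arg(method)
  if (length(module_genes) == 0L) stop("empty module", call. = FALSE)
  missing <- setdiff(module_genes, rownames(expr))
  if (length(missing))
    stop("module genes absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  raw <- colMeans(expr[module_genes, , drop = FALSE])
  if (method == "binned_control") {
    mu <- rowMeans(expr)
    n_bins <- min(n_bins, max(1L, floor(nrow(expr) / 2)))
    br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
    bin <- if (length(br) > 2L) cut(mu, breaks = br, include.lowest = TRUE)
           else factor(rep(1L, length(mu)))
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    ctrl <- unlist(lapply(module_genes, function(g) {
      pool <- rownames(expr)[bin == bin[match(g, rownames(expr))]]
      sample(pool, min(n_ctrl, length(pool)))
    }))
    raw <- raw - colMeans(expr[ctrl, , drop = FALSE])
  }
  if (!isTRUE(sd(raw) > 0))
    return(setNames(rep(0, ncol(expr)), colnames(expr)))
  z <- (raw - mean(raw)) / sd(raw)
  setNames((z - min(z)) / (max(z) - min(z)), colnames(expr))
}
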