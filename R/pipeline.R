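# Full two-condition analysis: normalization and gene selection, per-
# condition cell graphs and OT gene distance matrices, both directional
# differential operators, spectral gene calling, and module assembly.

#' Run the full differential co-localization analysis
#'
#' Executes the three-step workflow on two raw count matrices and returns
#' both directions: `cond1` holds structure strong in condition 1 relative
#' to condition 2 (numerator condition 1), `cond2` the reverse.
#'
#' @param counts1,counts2 Raw count matrices (genes x cells) sharing a
#'   gene-ID universe.
#' @param k Cell-graph neighbors, default 10.
#' @param n_components Embedding dimensionality (or `"auto"` with the
#'   diffusion map).
#' @param embedding `"diffusion_map"` or `"pca"`.
#' @param n_hvg Per-condition highly-variable-gene cap for the analysis
#'   gene set, default 500.
#' @param min_frac,max_frac Expression-fraction band for the gene set.
#' @param scale_factor Log-normalization scale factor.
#' @param k_local Adaptive-kernel neighbor index on the gene graph.
#' @param fdr_threshold Local-FDR cutoff for significance.
#' @param min_module_size,deep_split,outlier_mads Module assembly
#'   parameters (see [assemble_modules()]).
#' @param force_genes Genes added to the analysis set regardless of the
#'   filters (used by benchmarks to keep injected genes in play), provided
#'   they are detected in both conditions.
#' @param distances Optional pre-computed list `list(D1, D2)` matching the
#'   selected gene set, to reuse cached OT distances.
#' @param seed Seed for the seeded downstream steps (module activity).
#' @return A list of class `colodiff_result` with `gene_set`, `D1`, `D2`,
#'   per-direction `spectral`, `significance` and `modules`, and the
#'   parameters used.
#' @export
colodiff_run <- function(counts1, counts2, k = 10L, n_components = 10L,
                         embedding = c("diffusion_map", "pca"),
                         n_hvg = 500L, min_frac = 0.005, max_frac = 0.5,
                         scale_factor = 1e4, k_local = 10L,
                         fdr_threshold = 0.2, min_module_size = 5L,
                         deep_split = 0L, outlier_mads = 3,
                         force_genes = character(), distances = NULL,
                         seed = 1L) {
  embedding <- match.arg(embedding)
  .stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  # the only cell QC in scope: cells with zero total count cannot be
  # normalized or placed on the manifold and are dropped up front
  for (nm in c("counts1", "counts2")) {
    cc <- get(nm)
    empty <- colSums(cc) == 0
    if (any(empty)) {
      message("dropping ", sum(empty), " zero-count cell(s) from ", nm)
      assign(nm, cc[, !empty, drop = FALSE])
    }
  }
  expr1 <- .stage("normalize", log_normalize(counts1, scale_factor))
  expr2 <- .stage("normalize", log_normalize(counts2, scale_factor))
  gs <- .stage("gene_selection",
               select_analysis_genes(expr1, expr2, n_hvg = n_hvg,
                                     min_frac = min_frac,
                                     max_frac = max_frac))
  genes <- gs$gene_ids
  if (length(force_genes)) {
    ok <- force_genes[rowSums(counts1[force_genes, , drop = FALSE] > 0) > 0 &
                      rowSums(counts2[force_genes, , drop = FALSE] > 0) > 0]
    genes <- sort(union(genes, ok))
  }
  if (is.null(distances)) {
    D <- lapply(list(expr1, expr2), function(e) {
      emb <- .stage("cell_graph",
                    embed_cells(e, method = embedding,
                                n_components = n_components))
      C <- .stage("cell_graph", cost_matrix(knn_graph(emb, k = k)))
      .stage("gene_transport", pairwise_ot(e, genes, C))
    })
  } else {
    D <- distances
    for (Dk in D)
      if (!identical(rownames(Dk), genes))
        stop("[gene_transport] cached distances do not match the gene set",
             call. = FALSE)
  }
  L1 <- .stage("differential", normalized_operator(adaptive_kernel(D[[1L]],
                                                                   k_local)))
  L2 <- .stage("differential", normalized_operator(adaptive_kernel(D[[2L]],
                                                                   k_local)))
  exprs <- list(expr1, expr2)
  directions <- list()
  for (cond in 1:2) {
    num <- if (cond == 1L) L1 else L2
    den <- if (cond == 1L) L2 else L1
    spec <- .stage("differential",
                   spectral_select(differential_operator(num, den)))
    sig <- .stage("significance",
                  spectral_significance(spec, fdr_threshold))
    sig_genes <- sig$gene_id[sig$significant]
    mods <- if (length(sig_genes) >= min_module_size) {
      m <- .stage("modules",
                  assemble_modules(sig_genes,
                                   D[[cond]][sig_genes, sig_genes,
                                             drop = FALSE],
                                   min_size = min_module_size,
                                   outlier_mads = outlier_mads,
                                   deep_split = deep_split))
      if (length(m$modules) && spec$n_sig > 0L)
        m <- module_importance(m, spec, sig)
      for (i in seq_along(m$modules))
        m$modules[[i]]$activity <- module_activity(
          exprs[[cond]], m$modules[[i]]$gene_ids, seed = seed)
      m
    } else {
      structure(list(modules = list(), outlier_genes = character(),
                     unassigned_genes = sig_genes),
                class = "module_set")
    }
    directions[[paste0("cond", cond)]] <-
      list(spectral = spec, significance = sig, modules = mods)
  }
  structure(list(gene_set = gs, genes = genes, D1 = D[[1L]], D2 = D[[2L]],
                 directions = directions,
                 params = list(k = k, n_components = n_components,
                               embedding = embedding, n_hvg = n_hvg,
                               min_frac = min_frac, max_frac = max_frac,
                               scale_factor = scale_factor,
                               k_local = k_local,
                               fdr_threshold = fdr_threshold,
                               min_module_size = min_module_size,
                               deep_split = deep_split,
                               outlier_mads = outlier_mads, seed = seed)),
            class = "colodiff_result")
}

#' @export
print.colodiff_result <- function(x, ...) {
  cat("colodiff result:", length(x$genes), "analysis genes\n")
  for (d in names(x$directions)) {
    dd <- x$directions[[d]]
    cat(sprintf(
      "  %s: %d selected eigenvector(s), %d significant gene(s), %d module(s)\n",
      d, dd$spectral$n_sig, sum(dd$significance$significant),
      length(dd$modules$modules)))
  }
  invisible(x)
}

#' Write an analysis result to a directory
#'
#' Emits per-direction eigenvalue tables, per-gene significance tables and
#' module membership/summary/activity TSVs, the OT distance matrices, and
#' a `provenance.json` recording every parameter used.
#'
#' @param result A `colodiff_result`.
#' @param dir Output directory (created if needed).
#' @param write_distances Also write the (possibly large) gene distance
#'   matrices as TSV, default TRUE.
#' @return Invisibly, `dir`.
#' @export
write_result <- function(result, dir, write_distances = TRUE) {
  stopifnot(inherits(result, "colodiff_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write.table(df, file.path(dir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  if (write_distances) {
    for (cond in 1:2) {
      Dk <- result[[paste0("D", cond)]]
      tsv(data.frame(gene_id = rownames(Dk), Dk, check.names = FALSE),
          sprintf("distances_cond%d.tsv", cond))
    }
  }
  for (d in names(result$directions)) {
    dd <- result$directions[[d]]
    tsv(data.frame(index = seq_along(dd$spectral$values),
                   eigenvalue = dd$spectral$values,
                   selected = seq_along(dd$spectral$values) <=
                     dd$spectral$n_sig),
        sprintf("eigenvalues_%s.tsv", d))
    tsv(dd$significance, sprintf("genes_%s.tsv", d))
    tsv(rank_genes(dd$spectral), sprintf("ranking_%s.tsv", d))
    mods <- dd$modules$modules
    if (length(mods)) {
      tsv(do.call(rbind, lapply(mods, function(m)
        data.frame(module_id = m$module_id, gene_id = m$gene_ids,
                   stringsAsFactors = FALSE))),
        sprintf("module_members_%s.tsv", d))
      tsv(do.call(rbind, lapply(mods, function(m)
        data.frame(module_id = m$module_id, size = length(m$gene_ids),
                   importance = m$importance %||% NA_real_,
                   stringsAsFactors = FALSE))),
        sprintf("module_summary_%s.tsv", d))
      act <- do.call(cbind, lapply(mods, `[[`, "activity"))
      colnames(act) <- vapply(mods, `[[`, "", "module_id")
      tsv(data.frame(cell_id = rownames(act) %||%
                       seq_len(nrow(act)), act, check.names = FALSE),
          sprintf("module_activity_%s.tsv", d))
    }
  }
  jsonlite::write_json(result$params,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
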