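# Benchmark evaluation: gene ranking from the differential spectrum,
# normalized AUPRC (average precision rescaled so random performance sits
# at 0 and perfect detection at 1), Jaccard overlap of gene sets, and a
# robustness sweep over graph-construction parameters.

#' Rank genes by the first differential eigenvector
#'
#' Genes are ordered by the absolute loading of the top eigenvector of the
#' differential operator, descending; ties break lexicographically by
#' gene ID. With `use_all_selected = TRUE` the score is the maximum
#' absolute loading over all knee-selected eigenvectors instead.
#'
#' @param spec A `spectral_result` from [spectral_select()].
#' @param use_all_selected Score on all selected eigenvectors, not just
#'   the first.
#' @return A data frame of class `ranked_genes` with `gene_id` and
#'   `score`, ordered.
#' @export
rank_genes <- function(spec, use_all_selected = FALSE) {
  stopifnot(inherits(spec, "spectral_result"))
  if (ncol(spec$vectors) < 1L) stop("no eigenvectors", call. = FALSE)
  score <- if (use_all_selected && spec$n_sig > 1L)
    apply(abs(spec$vectors[, seq_len(spec$n_sig), drop = FALSE]), 1L, max)
  else abs(spec$vectors[, 1L])
  ord <- order(-score, spec$gene_ids)
  structure(data.frame(gene_id = spec$gene_ids[ord],
                       score = unname(score[ord]),
                       stringsAsFactors = FALSE),
            class = c("ranked_genes", "data.frame"))
}

#' Normalized area under the precision-recall curve
#'
#' AUPRC is computed as average precision (the sum of precision at each
#' positive's rank times the recall increment) and normalized as
#' `(AUPRC - p) / (1 - p)` with `p` the positive fraction, so 0
#' corresponds to random performance and 1 to perfect detection.
#'
#' @param ranking Character vector of gene IDs in rank order, or a
#'   `ranked_genes` data frame.
#' @param positives Character vector of true-positive gene IDs (or a
#'   `gene_set`), a strict non-empty subset of the ranking.
#' @return A list with `auprc`, `p_pos` and `normalized`.
#' @export
normalized_auprc <- function(ranking, positives) {
  if (inherits(ranking, "ranked_genes")) ranking <- ranking$gene_id
  if (inherits(positives, "gene_set")) positives <- positives$gene_ids
  n <- length(ranking)
  if (anyDuplicated(ranking)) stop("ranking has duplicates", call. = FALSE)
  if (!all(positives %in% ranking))
    stop("positives must be a subset of the ranking", call. = FALSE)
  npos <- length(unique(positives))
  if (npos == 0L || npos >= n)
    stop("need 0 < |positives| < |ranking|", call. = FALSE)
  is_pos <- ranking %in% positives
  ranks <- which(is_pos)
  auprc <- mean(seq_along(ranks) / ranks)   # average precision
  p <- npos / n
  list(auprc = auprc, p_pos = p, normalized = (auprc - p) / (1 - p))
}

#' Jaccard index of two gene sets
#'
#' `|a intersect b| / |a union b|`; defined as 1 when both sets are empty.
#'
#' @param a,b Character vectors (or `gene_set` objects).
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  if (inherits(a, "gene_set")) a <- a$gene_ids
  if (inherits(b, "gene_set")) b <- b$gene_ids
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Robustness sweep over graph-construction parameters
#'
#' Re-runs the full analysis over a grid of neighbor counts, embedding
#' dimensionalities and embedding methods, and reports the Jaccard index
#' of each setting's significant-gene set against the default setting's,
#' separately per direction.
#'
#' @param counts1,counts2 Raw count matrices.
#' @param k_values,n_components_values,embeddings Grid values; the first
#'   entry of each is the default setting.
#' @param ... Further arguments passed to [colodiff_run()].
#' @return A data frame with one row per non-default grid setting and per
#'   direction: the setting, set sizes and the Jaccard index.
#' @export
robustness_sweep <- function(counts1, counts2,
                             k_values = c(10L, 5L, 15L),
                             n_components_values = c(10L, 5L, 15L),
                             embeddings = "pca", ...) {
  grid <- expand.grid(k = k_values, n_components = n_components_values,
                      embedding = embeddings,
                      stringsAsFactors = FALSE)
  sig_sets <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    res <- colodiff_run(counts1, counts2, k = grid$k[r],
                        n_components = grid$n_components[r],
                        embedding = grid$embedding[r], ...)
    sig_sets[[r]] <- lapply(res$directions, function(d)
      d$significance$gene_id[d$significance$significant])
  }
  ref <- sig_sets[[1L]]
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    do.call(rbind, lapply(names(ref), function(dir)
      data.frame(k = grid$k[r], n_components = grid$n_components[r],
                 embedding = grid$embedding[r], direction = dir,
                 n_sig = length(sig_sets[[r]][[dir]]),
                 n_sig_default = length(ref[[dir]]),
                 jaccard = jaccard_index(sig_sets[[r]][[dir]], ref[[dir]]),
                 stringsAsFactors = FALSE)))
  }))
  rownames(out) <- NULL
  out
}
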