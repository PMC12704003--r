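# Step 1: each gene's expression becomes a probability distribution over
# cells, and pairwise optimal-transport distances are computed with the
# cell-graph shortest-path matrix as ground cost. The solver is an exact
# transportation simplex (src/transport.cpp); zero-mass cells are dropped
# from each gene's support, which leaves the optimum unchanged and makes
# the per-pair problems small.

#' Normalize a gene's expression into a distribution over cells
#'
#' @param expr Log-normalized matrix from [log_normalize()].
#' @param gene_id Gene row to convert.
#' @return A list of class `gene_distribution` with `support` (cell
#'   indices with positive expression), `mass` (positive weights summing
#'   to 1) and `gene_id`.
#' @export
gene_distribution <- function(expr, gene_id) {
  if (!gene_id %in% rownames(expr))
    stop("gene not present: ", gene_id, call. = FALSE)
  x <- expr[gene_id, ]
  support <- which(x > 0)
  if (length(support) == 0L)
    stop("gene has no expressing cells: ", gene_id, call. = FALSE)
  mass <- x[support] / sum(x[support])
  structure(list(support = unname(support), mass = unname(mass),
                 gene_id = gene_id),
            class = "gene_distribution")
}

#' Exact optimal-transport distance between two gene distributions
#'
#' Solves the discrete transportation problem restricted to the two
#' supports' cost submatrix with an exact network (transportation) simplex.
#'
#' @param gi,gj `gene_distribution` objects.
#' @param C Cell-cell cost matrix (see [cost_matrix()]).
#' @return The optimal transport cost (a non-negative scalar).
#' @export
ot_distance <- function(gi, gj, C) {
  stopifnot(inherits(gi, "gene_distribution"),
            inherits(gj, "gene_distribution"))
  n <- nrow(C)
  if (max(gi$support) > n || max(gj$support) > n)
    stop("support indices exceed the cost matrix dimension", call. = FALSE)
  .emd_cpp(gi$mass, gj$mass, C[gi$support, gj$support, drop = FALSE])
}

#' Pairwise gene-gene optimal-transport distance matrix
#'
#' Computes [ot_distance()] for every gene pair of a gene set over one
#' condition's cost matrix. The whole double loop runs in compiled code;
#' the result is independent of gene order up to simultaneous permutation.
#'
#' @param expr Log-normalized matrix for one condition.
#' @param genes Character vector of gene IDs, or a `gene_set` from
#'   [select_analysis_genes()].
#' @param C Cost matrix for the same condition's cells.
#' @return A symmetric genes x genes distance matrix with zero diagonal.
#' @export
pairwise_ot <- function(expr, genes, C) {
  if (inherits(genes, "gene_set")) genes <- genes$gene_ids
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("genes not in the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  zero <- genes[rowSums(expr[genes, , drop = FALSE] > 0) == 0]
  if (length(zero))
    stop("genes with no expressing cells (drop them first): ",
         paste(zero, collapse = ", "), call. = FALSE)
  dists <- lapply(genes, function(g) gene_distribution(expr, g))
  D <- .pairwise_emd_cpp(C,
                         lapply(dists, `[[`, "support"),
                         lapply(dists, `[[`, "mass"))
  dimnames(D) <- list(genes, genes)
  D
}
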