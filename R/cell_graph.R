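# Cell embedding, kNN cell graph, and the all-pairs shortest-path cost
# matrix used as OT ground cost. Both embeddings start from the scaled
# top-HVG matrix reduced to its leading principal components; the diffusion
# map is built on top of that PC space with a locally scaled Gaussian
# affinity (bandwidth = distance to the k-th neighbor) and symmetric
# normalization, eigenvectors scaled by their eigenvalues.

.scale_rows <- function(x, clip = 10) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  s[s == 0] <- 1
  z <- (x - mu) / s
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

.pca_coords <- function(expr, n_components, n_hvg = 2000L) {
  hvgs <- .top_hvgs(expr, n_hvg)
  z <- .scale_rows(expr[hvgs, , drop = FALSE])
  pc <- prcomp(t(z), center = TRUE, scale. = FALSE, rank. = n_components)
  coords <- pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
  rownames(coords) <- colnames(expr)
  coords
}

# locally scaled symmetric affinity between rows of coords
.local_affinity <- function(coords, k_local = 10L) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  k_local <- min(k_local, n - 1L)
  sigma <- apply(d, 1L, function(r) sort(r[-which.min(r)])[k_local])
  if (any(sigma == 0)) {
    pos <- min(sigma[sigma > 0], d[d > 0])
    sigma[sigma == 0] <- pos
  }
  w <- 0.5 * (exp(-(d / sigma)^2) + exp(-t(t(d) / sigma)^2))
  0.5 * (w + t(w))
}

#' Embed cells in a low-dimensional space
#'
#' Builds a per-condition cell embedding from the scaled top-HVG expression
#' matrix. `method = "pca"` returns the leading principal components;
#' `method = "diffusion_map"` builds a locally scaled Gaussian affinity on
#' the top-10-PC coordinates, symmetric-normalizes it, and returns the
#' leading non-trivial eigenvectors scaled by their eigenvalues.
#'
#' @param expr Log-normalized matrix from [log_normalize()].
#' @param method `"diffusion_map"` or `"pca"`.
#' @param n_components Number of components, or `"auto"` (diffusion map
#'   only) to pick the knee of the affinity-operator eigenvalue spectrum.
#' @param n_hvg Genes entering the embedding (top highly variable).
#' @param k_local Neighbor index setting the adaptive kernel bandwidth.
#' @return A cells x d coordinate matrix with attribute `method`.
#' @export
embed_cells <- function(expr, method = c("diffusion_map", "pca"),
                        n_components = 10L, n_hvg = 2000L, k_local = 10L) {
  method <- match.arg(method)
  n <- ncol(expr)
  auto <- identical(n_components, "auto")
  if (!auto) {
    n_components <- as.integer(.check_scalar(n_components, "n_components"))
    if (n < n_components + 1L)
      stop("need at least n_components + 1 cells", call. = FALSE)
  }
  if (method == "pca") {
    if (auto) stop("n_components = 'auto' requires the diffusion map",
                   call. = FALSE)
    coords <- .pca_coords(expr, n_components, n_hvg)
  } else {
    base <- .pca_coords(expr, 10L, n_hvg)
    w <- .local_affinity(base, k_local)
    a <- rowSums(w)
    lsym <- w / sqrt(outer(a, a))
    es <- eigen(lsym, symmetric = TRUE)
    # drop the trivial Perron component; diffusion coordinates are the
    # degree-rescaled eigenvectors weighted by their eigenvalues
    nn <- nrow(lsym)
    navail <- nn - 1L
    if (auto) {
      scan <- es$values[2:min(nn, 31L)]
      n_components <- knee_index(scan, method = "chord")
    }
    n_components <- min(n_components, navail)
    sel <- seq(2L, 1L + n_components)
    psi <- es$vectors[, sel, drop = FALSE] / sqrt(a)
    coords <- sweep(psi, 2L, es$values[sel], "*")
    rownames(coords) <- colnames(expr)
    colnames(coords) <- paste0("DC", seq_len(ncol(coords)))
  }
  attr(coords, "method") <- method
  coords
}

#' Build a k-nearest-neighbor cell graph
#'
#' Union-symmetrized kNN graph over Euclidean distances in the embedding.
#' If the graph is disconnected, components are repeatedly bridged by their
#' single shortest inter-component pair so that shortest-path costs stay
#' finite. Neighbor ties break by cell index.
#'
#' @param embedding Cells x d coordinate matrix (see [embed_cells()]).
#' @param k Neighbors per cell, default 10.
#' @return A list of class `cell_graph` with the `igraph` object, the edge
#'   list (`i`, `j`, `length`), `k`, `n_cells` and the cell IDs.
#' @export
knn_graph <- function(embedding, k = 10L) {
  k <- as.integer(.check_scalar(k, "k"))
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of cells",
                   call. = FALSE)
  d <- as.matrix(dist(embedding))
  edges <- matrix(0L, nrow = 0L, ncol = 2L)
  nb <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))    # self first (distance 0), ties by index
    ord[ord != i][seq_len(k)]
  }, integer(k)))
  if (k == 1L) nb <- matrix(nb, ncol = 1L)
  pairs <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  pairs <- t(apply(pairs, 1L, sort))
  pairs <- unique(pairs)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- d[pairs]
  # connectivity repair: bridge the closest inter-component pair until whole
  repeat {
    comp <- igraph::components(g)
    if (comp$no == 1L) break
    main <- which(comp$membership == which.max(comp$csize))
    rest <- which(comp$membership != which.max(comp$csize))
    sub <- d[main, rest, drop = FALSE]
    hit <- arrayInd(which.min(sub), dim(sub))
    vi <- main[hit[1L]]; vj <- rest[hit[2L]]
    g <- igraph::add_edges(g, c(vi, vj), weight = d[vi, vj])
    pairs <- rbind(pairs, sort(c(vi, vj)))
  }
  structure(list(
    graph = g,
    edges = data.frame(i = pairs[, 1L], j = pairs[, 2L],
                       length = d[pairs]),
    k = k, n_cells = n, cell_ids = rownames(embedding)
  ), class = "cell_graph")
}

#' All-pairs shortest-path cost matrix of a cell graph
#'
#' @param graph A `cell_graph` from [knn_graph()].
#' @return A symmetric cells x cells matrix of geodesic distances with zero
#'   diagonal; the OT ground cost.
#' @export
cost_matrix <- function(graph) {
  stopifnot(inherits(graph, "cell_graph"))
  if (igraph::components(graph$graph)$no != 1L)
    stop("cell graph is disconnected; rebuild it with knn_graph()",
         call. = FALSE)
  C <- igraph::distances(graph$graph, weights = igraph::E(graph$graph)$weight)
  dimnames(C) <- list(graph$cell_ids, graph$cell_ids)
  C
}
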