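# Steps 2-3: gene graphs from OT distances via a locally adaptive Gaussian
# kernel, degree-normalized operators, directional differential operators
# with a spectral-filter regularizer, knee-point component selection, and
# local-FDR gene calling on standardized eigenvector loadings.

#' Locally adaptive Gaussian kernel on a gene distance matrix
#'
#' `K_ij = (exp(-D_ij^2 / s_i^2) + exp(-D_ij^2 / s_j^2)) / 2` where `s_i`
#' is gene i's distance to its `k_local`-th nearest other gene.
#'
#' @param D Symmetric gene-gene distance matrix (see [pairwise_ot()]).
#' @param k_local Neighbor index for the adaptive bandwidth, default 10.
#' @return A list of class `kernel_matrix` with `K` (symmetric, unit
#'   diagonal), `sigma` and `k_local`.
#' @export
adaptive_kernel <- function(D, k_local = 10L) {
  p <- nrow(D)
  k_local <- as.integer(.check_scalar(k_local, "k_local"))
  if (p < k_local + 1L)
    stop("need at least k_local + 1 genes", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric", call. = FALSE)
  sigma <- vapply(seq_len(p), function(i) sort(D[i, -i])[k_local], 0)
  if (any(sigma == 0)) {
    warning("zero adaptive bandwidth (duplicate gene distributions); ",
            "substituting the smallest positive bandwidth")
    sigma[sigma == 0] <- min(sigma[sigma > 0], D[D > 0])
  }
  K <- 0.5 * (exp(-(D / sigma)^2) + exp(-t(t(D) / sigma)^2))
  K <- 0.5 * (K + t(K))
  diag(K) <- 1
  dimnames(K) <- dimnames(D)
  structure(list(K = K, sigma = sigma, k_local = k_local),
            class = "kernel_matrix")
}

#' Degree-symmetrized graph operator
#'
#' `L = A^{-1/2} K A^{-1/2}` with `A` the diagonal degree matrix of the
#' kernel. Similar to a row-stochastic matrix, so its spectrum lies in
#' `[-1, 1]` with top eigenvalue exactly 1.
#'
#' @param K A `kernel_matrix` from [adaptive_kernel()] (or a plain
#'   symmetric non-negative matrix).
#' @return A list of class `graph_operator` with `L` and `degrees`.
#' @export
normalized_operator <- function(K) {
  km <- if (inherits(K, "kernel_matrix")) K$K else K
  a <- rowSums(km)
  if (any(a <= 0)) stop("zero degree in kernel matrix", call. = FALSE)
  L <- km / sqrt(outer(a, a))
  L <- 0.5 * (L + t(L))
  dimnames(L) <- dimnames(km)
  structure(list(L = L, degrees = a), class = "graph_operator")
}

#' Knee point of a descending value sequence
#'
#' Returns the number of values above the spectral knee, scanning a
#' prefix of the sequence (its first half, at least 10 points, capped at
#' its length) so that numerical wiggle in the flat tail cannot attract
#' the knee. Two flavors serve two shapes of spectrum:
#' \describe{
#'   \item{`"gap"`}{the classic eigengap heuristic -- the index maximizing
#'     `values[l] - values[l + 1]`. Right for spectra with a few dominant
#'     components followed by a cliff, as in differential-operator
#'     component selection. A gap only counts as a knee when it dominates
#'     the typical (median) gap of the prefix by the factor `dominance`;
#'     a smooth spectrum with no dominant cliff falls back to a single
#'     component, which keeps structureless (null) spectra from
#'     contributing several noise components.}
#'   \item{`"chord"`}{the index just before the point with maximum
#'     perpendicular distance to the chord joining the prefix's
#'     endpoints. Right for smoothly decaying spectra where the knee is
#'     the steep-to-flat transition, as when choosing the regularizer
#'     from a graph operator's spectrum or counting diffusion
#'     components.}
#' }
#' Linear or constant sequences fall back to 1 in both flavors.
#'
#' @param values Numeric vector, non-increasing, length at least 3.
#' @param method `"gap"` (default) or `"chord"`.
#' @param dominance Dominance factor of the `"gap"` flavor, default 8.
#' @return The knee index (at least 1).
#' @export
knee_index <- function(values, method = c("gap", "chord"), dominance = 8) {
  method <- match.arg(method)
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (any(diff(values) > 1e-10))
    stop("values must be sorted in descending order", call. = FALSE)
  prefix <- min(length(values), max(10L, floor(length(values) / 2)))
  if (method == "gap") {
    gaps <- -diff(values[seq_len(prefix)])
    if (max(gaps) - min(gaps) <= 1e-12) return(1L)
    if (max(gaps) < dominance * median(gaps)) return(1L)
    which.max(gaps)
  } else {
    y <- values[seq_len(prefix)]
    x <- seq_len(prefix)
    dx <- prefix - 1L
    dy <- y[prefix] - y[1L]
    dist <- abs(dy * (x - 1L) - dx * (y - y[1L])) / sqrt(dx^2 + dy^2)
    if (max(dist) <= 1e-12) return(1L)
    max(1L, which.max(dist) - 1L)
  }
}

#' Directional differential graph operator
#'
#' Contrasts two per-condition graph operators. Maximizing the generalized
#' Rayleigh quotient `v' L_num v / v' (L_den + c I) v` exposes gene sets
#' densely connected in the numerator condition relative to the denominator
#' one; its maximizers are the top eigenvectors of the symmetric operator
#' `Q = (L_den + c I)^{-1/2} L_num (L_den + c I)^{-1/2}`.
#'
#' The regularizer `c` is the denominator spectrum's eigenvalue at its knee
#' point (a spectral filter that stops weak components of `L_den` from
#' being amplified), floored at `-lambda_min(L_den) + eps` so the shifted
#' operator stays positive definite.
#'
#' @param L_num,L_den `graph_operator` objects over the same ordered genes.
#' @param eps Positive-definiteness floor, default `1e-8`.
#' @return A list of class `diff_operator` with `Q`, `c_reg`, the
#'   denominator spectrum and the knee index used.
#' @export
differential_operator <- function(L_num, L_den, eps = 1e-8) {
  stopifnot(inherits(L_num, "graph_operator"),
            inherits(L_den, "graph_operator"))
  gn <- rownames(L_num$L); gd <- rownames(L_den$L)
  if (!identical(dim(L_num$L), dim(L_den$L)) ||
      (!is.null(gn) && !identical(gn, gd)))
    stop("the two operators must share the same ordered gene set",
         call. = FALSE)
  den_values <- eigen(L_den$L, symmetric = TRUE, only.values = TRUE)$values
  knee <- knee_index(den_values, method = "chord")
  c_reg <- max(den_values[knee], -min(den_values) + eps)
  es <- eigen(L_den$L + c_reg * diag(nrow(L_den$L)), symmetric = TRUE)
  inv_sqrt <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  Q <- inv_sqrt %*% L_num$L %*% inv_sqrt
  Q <- 0.5 * (Q + t(Q))
  dimnames(Q) <- dimnames(L_num$L)
  structure(list(Q = Q, c_reg = c_reg, den_knee = knee,
                 den_values = den_values),
            class = "diff_operator")
}

#' Eigendecomposition and component selection of a differential operator
#'
#' Full symmetric eigendecomposition with eigenvalues in descending
#' order; the number of significant components is the knee of the
#' spectrum, additionally gated by the requirement that a component's
#' eigenvalue exceed 1: when the two conditions' operators coincide the
#' spectrum of `Q` is `lambda / (lambda + c) < 1`, so only eigenvalues
#' above 1 certify connectivity in the numerator condition beyond the
#' regularized denominator, and a structureless spectrum selects nothing.
#' Each eigenvector's sign is fixed so its largest-magnitude loading is
#' positive. A flat (all-equal) spectrum yields 0 significant components.
#'
#' @param Qop A `diff_operator` from [differential_operator()].
#' @return A list of class `spectral_result` with `values`, `vectors`
#'   (columns, sign-fixed), `n_sig` and `gene_ids`.
#' @export
spectral_select <- function(Qop) {
  stopifnot(inherits(Qop, "diff_operator"))
  es <- eigen(Qop$Q, symmetric = TRUE)
  vals <- es$values
  vecs <- es$vectors
  for (l in seq_len(ncol(vecs))) {
    peak <- which.max(abs(vecs[, l]))
    if (vecs[peak, l] < 0) vecs[, l] <- -vecs[, l]
  }
  n_sig <- if (max(vals) - min(vals) <= 1e-10) 0L
           else min(knee_index(vals), sum(vals > 1))
  rownames(vecs) <- rownames(Qop$Q)
  structure(list(values = vals, vectors = vecs, n_sig = n_sig,
                 gene_ids = rownames(Qop$Q), c_reg = Qop$c_reg),
            class = "spectral_result")
}

#' Local false discovery rate calling on eigenvector loadings
#'
#' Loadings are z-standardized robustly (median centering, MAD scale with
#' the 1.4826 consistency constant) so that the null bulk sits at unit
#' scale even when a few genes carry most of the loading mass -- the
#' regime eigenvectors of a differential operator live in, where a
#' moment-based scale would compress the null and invalidate the
#' theoretical null. The mixture density `f(z)` is estimated by a Poisson
#' fit of histogram counts on a natural-spline basis over the central
#' window `|z| <= fit_window`; the null is the theoretical standard
#' normal, with the null proportion `pi0` estimated by central matching
#' (the central peak of `f(z)/phi(z)`, capped at 1). Genes with
#' `fdr(z) = pi0 * phi(z) / f(z)` below `fdr_threshold` on either tail
#' are significant; genes beyond the fit window carry essentially no null
#' density and get fdr 0.
#'
#' @param loadings Numeric vector of at least 50 loadings (density
#'   estimation needs mass), named by gene if available.
#' @param fdr_threshold Local-FDR significance cutoff, default 0.2.
#' @param n_bins,df Histogram bins and spline degrees of freedom.
#' @param fit_window Half-width of the z window used for density
#'   estimation, default 8 (the standard-normal null is numerically zero
#'   beyond it).
#' @param standardize `"robust"` (median/MAD, default) or `"moment"`
#'   (mean/sd).
#' @return A list with `z`, `fdr`, `significant` (logical), and `pi0`.
#' @export
locfdr_select <- function(loadings, fdr_threshold = 0.2, n_bins = 120L,
                          df = 7L, fit_window = 8,
                          standardize = c("robust", "moment")) {
  standardize <- match.arg(standardize)
  if (length(loadings) < 50L)
    stop("need at least 50 loadings for density estimation", call. = FALSE)
  if (standardize == "robust") {
    ctr <- median(loadings)
    s <- mad(loadings)
    if (!isTRUE(s > 0)) s <- sd(loadings)   # MAD degenerate: fall back
  } else {
    ctr <- mean(loadings)
    s <- sd(loadings)
  }
  if (!isTRUE(s > 0)) stop("loadings have zero spread", call. = FALSE)
  z <- (loadings - ctr) / s
  inside <- abs(z) <= fit_window
  if (sum(inside) < 50L) inside <- rep(TRUE, length(z))
  zf <- z[inside]
  br <- seq(min(zf) - 1e-8, max(zf) + 1e-8, length.out = n_bins + 1L)
  mid <- (br[-1L] + br[-length(br)]) / 2
  width <- diff(br)[1L]
  counts <- tabulate(findInterval(zf, br, rightmost.closed = TRUE), n_bins)
  fit <- suppressWarnings(glm(counts ~ splines::ns(mid, df = df),
                              family = poisson(),
                              control = list(maxit = 100L)))
  dens_at <- function(zz) {
    lam <- predict(fit, newdata = data.frame(mid = zz), type = "response")
    pmax(lam, 1e-12) / (length(zf) * width)
  }
  # central matching against the theoretical null: where the mixture is
  # null-dominated the ratio f/phi approaches pi0 from below, so take the
  # central peak of the ratio, capped at 1
  central <- seq(-1, 1, length.out = 41L)
  central <- central[central >= min(zf) & central <= max(zf)]
  if (length(central) == 0L) central <- 0
  pi0 <- min(1, max(dens_at(central) / dnorm(central)))
  fdr <- rep(0, length(z))
  fdr[inside] <- pmin(1, pi0 * dnorm(z[inside]) / dens_at(z[inside]))
  names(fdr) <- names(loadings)
  list(z = z, fdr = fdr, significant = fdr < fdr_threshold, pi0 = pi0)
}

#' Per-gene significance table over the selected eigenvectors
#'
#' Runs [locfdr_select()] on each knee-selected eigenvector of a
#' `spectral_result` and combines the calls: a gene is significant if it is
#' called on any selected eigenvector, and is assigned to the
#' highest-ranked (lowest-index) eigenvector that calls it.
#'
#' @param spec A `spectral_result` from [spectral_select()].
#' @param fdr_threshold Local-FDR cutoff passed to [locfdr_select()].
#' @return A data frame with one row per gene: `gene_id`, per-eigenvector
#'   `z` / `fdr` columns, `significant`, and `assigned_eigenvector`
#'   (`NA` for non-significant genes).
#' @export
spectral_significance <- function(spec, fdr_threshold = 0.2) {
  stopifnot(inherits(spec, "spectral_result"))
  p <- length(spec$gene_ids)
  out <- data.frame(gene_id = spec$gene_ids, stringsAsFactors = FALSE)
  sig_any <- rep(FALSE, p)
  assigned <- rep(NA_integer_, p)
  for (l in seq_len(spec$n_sig)) {
    res <- locfdr_select(setNames(spec$vectors[, l], spec$gene_ids),
                         fdr_threshold = fdr_threshold)
    out[[paste0("z", l)]] <- res$z
    out[[paste0("fdr", l)]] <- res$fdr
    newly <- res$significant & is.na(assigned)
    assigned[newly] <- l
    sig_any <- sig_any | res$significant
  }
  out$significant <- sig_any
  out$assigned_eigenvector <- assigned
  out
}
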