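# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths.

# batched generic-LP oracle for the transportation problem, solved with
# scipy.optimize.linprog (HiGHS) through the system python
lp_oracle_batch <- function(instances) {
  script <- file.path(tempdir(), "colodiff_lp_oracle.py")
  if (!file.exists(script)) writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "out = []",
    "with open(sys.argv[1]) as fh:",
    "    batch = json.load(fh)",
    "for inst in batch:",
    "    a = np.asarray(inst['a'], float).ravel()",
    "    b = np.asarray(inst['b'], float).ravel()",
    "    C = np.asarray(inst['C'], float).reshape(len(a), len(b))",
    "    m, n = len(a), len(b)",
    "    Aeq = []",
    "    for i in range(m):",
    "        r = np.zeros((m, n)); r[i, :] = 1; Aeq.append(r.ravel())",
    "    for j in range(n):",
    "        r = np.zeros((m, n)); r[:, j] = 1; Aeq.append(r.ravel())",
    "    res = linprog(C.ravel(), A_eq=np.array(Aeq),",
    "                  b_eq=np.concatenate([a, b]),",
    "                  bounds=(0, None), method='highs')",
    "    out.append(res.fun)",
    "print(json.dumps(out))"), script)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(instances, function(x)
      list(a = x$a, b = x$b, C = as.vector(t(x$C)))),
    f, digits = NA)
  out <- system2("python", c(script, f), stdout = TRUE)
  as.numeric(jsonlite::fromJSON(out[length(out)]))
}

# all-pairs shortest paths by exhaustive simple-path enumeration (n small)
brute_cost_matrix <- function(w) {
  n <- nrow(w)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  for (s in seq_len(n)) {
    dfs <- function(node, visited, len) {
      if (len < best[s, node]) best[s, node] <<- len
      for (k in seq_len(n)) {
        if (is.finite(w[node, k]) && !visited[k]) {
          visited[k] <- TRUE
          dfs(k, visited, len + w[node, k])
          visited[k] <- FALSE
        }
      }
    }
    v <- rep(FALSE, n); v[s] <- TRUE
    dfs(s, v, 0)
  }
  best
}

# generalized eigenvalues of (A, B) through the non-symmetric route,
# independent of the package's symmetric factorization
generalized_eigen_oracle <- function(A, B) {
  sort(Re(eigen(solve(B, A), only.values = TRUE)$values),
       decreasing = TRUE)
}

# average precision by direct prefix enumeration (n small)
brute_average_precision <- function(ranked_is_pos) {
  n <- length(ranked_is_pos)
  npos <- sum(ranked_is_pos)
  hits <- 0; ap <- 0
  for (k in seq_len(n)) {
    if (ranked_is_pos[k]) {
      hits <- hits + 1
      ap <- ap + hits / k
    }
  }
  ap / npos
}

# small deterministic count matrix with IDs (existing dimnames are kept)
tiny_counts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "integer"
  rownames(m) <- genes %||% rownames(m) %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- cells %||% colnames(m) %||% sprintf("c%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# block-structured gene distance matrix: tight within-block distances on a
# loose background
block_dist <- function(sizes, within = 0.1, between = 10, jitter = 0.01,
                       seed = 20) {
  set.seed(seed)
  p <- sum(sizes)
  D <- matrix(between, p, p) + matrix(runif(p * p, 0, jitter), p, p)
  D <- (D + t(D)) / 2
  start <- cumsum(c(1, sizes))
  for (b in seq_along(sizes)) {
    idx <- start[b]:(start[b + 1] - 1)
    D[idx, idx] <- within
  }
  diag(D) <- 0
  ids <- sprintf("g%02d", seq_len(p))
  dimnames(D) <- list(ids, ids)
  D
}
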