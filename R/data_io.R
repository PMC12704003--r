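# Count/expression matrices are plain base matrices, genes x cells, with
# mandatory unique dimnames. Raw counts are integer-valued; log-normalized
# expression carries its scale factor in attr "scale_factor".

.validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes x cells)", call. = FALSE)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("counts must have at least one gene and one cell", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene row names and cell column names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs in counts", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell IDs in counts", call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  invisible(counts)
}

#' Read a gene-by-cell count matrix
#'
#' Reads raw counts either from a 10x-style Matrix-Market triplet layout
#' (a directory holding `matrix.mtx`, `features.tsv` and `barcodes.tsv`)
#' or from a dense TSV with gene rows, cell columns and a header row of
#' cell IDs.
#'
#' @param path Directory (for `format = "mtx"`) or file (for
#'   `format = "tsv"`).
#' @param format Either `"mtx"` (Matrix-Market triplet + ID files) or
#'   `"tsv"` (dense tab-separated matrix).
#' @return An integer matrix, genes x cells, with gene/cell IDs as dimnames.
#' @export
read_counts <- function(path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx_file <- file.path(path, "matrix.mtx")
    feat_file <- file.path(path, "features.tsv")
    bc_file <- file.path(path, "barcodes.tsv")
    for (f in c(mtx_file, feat_file, bc_file))
      if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
    m <- Matrix::readMM(mtx_file)
    tm <- methods::as(m, "TsparseMatrix")
    key <- paste(tm@i, tm@j)
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1L]
      stop(sprintf("duplicate triplet entry for gene %d, cell %d",
                   tm@i[d] + 1L, tm@j[d] + 1L), call. = FALSE)
    }
    vals <- if (methods::is(tm, "ngTMatrix")) rep(1, length(tm@i)) else tm@x
    if (any(vals != round(vals)))
      stop("non-integer value in Matrix-Market file", call. = FALSE)
    genes <- read.delim(feat_file, header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    cells <- read.delim(bc_file, header = FALSE,
                        stringsAsFactors = FALSE)[[1L]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("ID files do not match the Matrix-Market header dimensions",
           call. = FALSE)
    counts <- as.matrix(m)
    dimnames(counts) <- list(genes, cells)
  } else {
    if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
    df <- read.delim(path, header = TRUE, row.names = 1L,
                     check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as.matrix(df)
  }
  storage.mode(counts) <- "double"
  .validate_counts(counts)
  storage.mode(counts) <- "integer"
  counts
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: writes either the 10x-style triplet layout or
#' a dense TSV. Round-trips preserve values and IDs exactly.
#'
#' @param counts Integer matrix, genes x cells, with dimnames.
#' @inheritParams read_counts
#' @return Invisibly, the path written to.
#' @export
write_counts <- function(counts, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  .validate_counts(counts)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::Matrix(unname(counts), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(counts), file.path(path, "features.tsv"))
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization followed by `log1p`:
#' `ln(1 + count / cell_total * scale_factor)`.
#'
#' @param counts Integer matrix, genes x cells.
#' @param scale_factor Positive scalar, default `1e4`.
#' @return A numeric matrix of the same shape with attribute
#'   `scale_factor`; entries are zero exactly where counts are zero.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  .validate_counts(counts)
  .check_scalar(scale_factor, "scale_factor")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  expr <- log1p(sweep(counts, 2L, totals, "/") * scale_factor)
  attr(expr, "scale_factor") <- scale_factor
  expr
}

# Highly-variable-gene scores: dispersion (variance / mean) of the
# log-normalized values, z-standardized within equal-frequency bins of the
# gene mean. Deterministic; ties in the final ranking break by gene ID.
.hvg_scores <- function(expr, n_bins = 20L) {
  mu <- rowMeans(expr)
  v <- apply(expr, 1L, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1L, min(n_bins, max(1L, floor(nrow(expr) / 5))))
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- if (length(br) > 2L) cut(mu, breaks = br, include.lowest = TRUE)
         else factor(rep(1L, length(mu)))
  z <- disp
  for (b in levels(bin)) {
    idx <- which(bin == b)
    s <- sd(disp[idx])
    z[idx] <- if (length(idx) > 1L && isTRUE(s > 0))
      (disp[idx] - mean(disp[idx])) / s else 0
  }
  names(z) <- rownames(expr)
  z
}

.top_hvgs <- function(expr, n_hvg) {
  z <- .hvg_scores(expr)
  ord <- order(-z, names(z))            # ties at the boundary: gene ID order
  names(z)[ord][seq_len(min(n_hvg, length(z)))]
}

#' Select the analysis gene set from two conditions
#'
#' Per condition, keeps genes expressed in `min_frac`--`max_frac` of cells
#' that also rank among the top `n_hvg` highly variable genes of that
#' condition; genes undetected (zero expressing cells) in either condition
#' are excluded throughout. The returned set is the union of the two
#' per-condition sets, ordered lexicographically.
#'
#' @param expr1,expr2 Log-normalized matrices from [log_normalize()]; gene
#'   universes are inner-joined on row names before filtering.
#' @param n_hvg Number of top highly variable genes retained per condition.
#' @param min_frac,max_frac Admissible expression-fraction band.
#' @return A list of class `gene_set` with `gene_ids` (sorted) and a
#'   `provenance` data frame recording which filters each gene passed in
#'   which condition.
#' @export
select_analysis_genes <- function(expr1, expr2, n_hvg = 500L,
                                  min_frac = 0.005, max_frac = 0.5) {
  shared <- intersect(rownames(expr1), rownames(expr2))
  if (length(shared) == 0L)
    stop("the two conditions share no gene IDs", call. = FALSE)
  shared <- sort(shared)
  e1 <- expr1[shared, , drop = FALSE]
  e2 <- expr2[shared, , drop = FALSE]
  frac1 <- rowMeans(e1 > 0); frac2 <- rowMeans(e2 > 0)
  det1 <- frac1 > 0; det2 <- frac2 > 0
  hvg1 <- shared %in% .top_hvgs(e1, n_hvg)
  hvg2 <- shared %in% .top_hvgs(e2, n_hvg)
  band1 <- frac1 >= min_frac & frac1 <= max_frac
  band2 <- frac2 >= min_frac & frac2 <= max_frac
  pass1 <- band1 & hvg1
  pass2 <- band2 & hvg2
  keep <- (pass1 | pass2) & det1 & det2
  if (!any(keep))
    stop("no genes pass the filters; loosen n_hvg or the fraction band",
         call. = FALSE)
  prov <- data.frame(gene_id = shared, frac1 = frac1, frac2 = frac2,
                     hvg1 = hvg1, hvg2 = hvg2,
                     passed1 = pass1, passed2 = pass2,
                     detected1 = det1, detected2 = det2,
                     selected = keep, row.names = NULL,
                     stringsAsFactors = FALSE)
  structure(list(gene_ids = shared[keep], provenance = prov),
            class = "gene_set")
}
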