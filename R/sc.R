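#' UMI count matrix container
#'
#' Genes x cells nonnegative integer counts (sparse) with a cell-type label
#' per cell.
#'
#' @param counts A genes x cells matrix or Matrix of nonnegative integers,
#'   with gene rownames and cell-barcode colnames.
#' @param cell_labels Character or factor of length `ncol(counts)`: cluster /
#'   cell-type assignment per cell.
#' @return An object of class `umi_matrix`: list with `counts` (dgCMatrix)
#'   and `cell_labels` (named factor).
#' @export
umi_matrix <- function(counts, cell_labels) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts need gene rownames and cell-barcode colnames")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop("counts must be nonnegative integers")
  }
  if (length(cell_labels) != ncol(counts)) {
    stop("one cell label per cell required")
  }
  structure(list(counts = counts,
                 cell_labels = stats::setNames(factor(cell_labels),
                                               colnames(counts))),
            class = "umi_matrix")
}

#' @export
print.umi_matrix <- function(x, ...) {
  cat(sprintf("umi_matrix: %d genes x %d cells; labels: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(levels(x$cell_labels), collapse = ", ")))
  invisible(x)
}

#' Remove cells with too few unique transcripts
#'
#' Cells with fewer than `min_umi` total UMIs are removed (cells exactly at
#' the threshold are kept); the gene axis is unchanged.
#'
#' @param m A `umi_matrix`.
#' @param min_umi Minimum per-cell UMI total (default 1000).
#' @return The filtered `umi_matrix`.
#' @export
filter_cells_min_umi <- function(m, min_umi = 1000L) {
  totals <- Matrix::colSums(m$counts)
  keep <- totals >= min_umi
  if (!any(keep)) stop("all cells fall below the UMI threshold")
  umi_matrix(m$counts[, keep, drop = FALSE], m$cell_labels[keep])
}

#' Exclude cells by label
#'
#' Label-driven removal step, e.g. discarding a contaminating astrocyte-like
#' subcluster before marker analysis.
#'
#' @param m A `umi_matrix`.
#' @param labels Character vector of labels to drop.
#' @return The filtered `umi_matrix`.
#' @export
exclude_cell_labels <- function(m, labels) {
  keep <- !(as.character(m$cell_labels) %in% labels)
  if (!any(keep)) stop("exclusion removes every cell")
  umi_matrix(m$counts[, keep, drop = FALSE], droplevels(m$cell_labels[keep]))
}

#' Binomial test for expression specificity
#'
#' With `k` the number of in-cluster cells expressing the gene (count > 0),
#' `n` the cluster size and `p_out` the out-of-cluster expressing fraction
#' (floored at `1 / (n_out + 1)` to avoid a zero-probability degeneracy),
#' returns the upper-tail binomial probability `P(X >= k)` for
#' `X ~ Bin(n, p_out)` — small when the gene is expressed far more often
#' inside the cluster than outside.
#'
#' @param m A `umi_matrix`.
#' @param cluster A cell label present in `m`.
#' @param gene A gene symbol present in `m`.
#' @return Upper-tail p-value.
#' @export
binomial_specificity <- function(m, cluster, gene) {
  if (!gene %in% rownames(m$counts)) stop("unknown gene: ", gene)
  if (!cluster %in% m$cell_labels) stop("unknown or empty cluster: ", cluster)
  inside <- m$cell_labels == cluster
  if (all(inside)) stop("no cells outside the cluster")
  x <- m$counts[gene, ]
  k <- sum(x[inside] > 0)
  n <- sum(inside)
  n_out <- sum(!inside)
  p_out <- max(sum(x[!inside] > 0) / n_out, 1 / (n_out + 1))
  stats::pbinom(k - 1L, n, p_out, lower.tail = FALSE)
}

# Vectorised two-sided Mann-Whitney U over matrix rows (normal approximation
# with tie correction and continuity correction, as in
# wilcox.test(exact = FALSE, correct = TRUE)). Returns p per row; rows where
# every value is tied give p = 1.
rank_sum_rows <- function(X, idx_a) {
  na <- length(idx_a)
  n <- ncol(X)
  nb <- n - na
  apply(X, 1L, function(x) {
    r <- rank(x)
    U <- sum(r[idx_a]) - na * (na + 1) / 2
    tie_counts <- tabulate(match(x, unique(x)))
    tie_term <- sum(tie_counts^3 - tie_counts)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- U - na * nb / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

#' Subsampling-equalized single-cell differential expression
#'
#' Differential expression between two groups of cells in which sampling
#' depth is equalized before testing: (i) the larger group is downsampled
#' without replacement to the smaller group's cell count; (ii) the group
#' with the higher mean transcripts/cell has each cell's counts binomially
#' thinned so the group means match; (iii) counts are size-factor normalized
#' (per-cell library-size factors by default, or scran deconvolution
#' factors); (iv) each gene is tested with a two-sided Mann-Whitney U test;
#' (v) p-values are Benjamini-Hochberg adjusted across genes. Fold changes
#' are computed from pseudocounted normalized group means. Subsampling is
#' anchored to sorted cell barcodes so cell order never affects the result.
#'
#' @param m A `umi_matrix`.
#' @param group_a,group_b Character vectors of cell barcodes (>= 2 each).
#' @param seed Integer seed driving all subsampling randomness.
#' @param normalization `"library"` (default) or `"scran"`.
#' @return Data frame with `gene`, `mean_a`, `mean_b`, `log2fc`, `p`, `q`.
#' @export
subsampled_de <- function(m, group_a, group_b, seed,
                          normalization = c("library", "scran")) {
  normalization <- match.arg(normalization)
  missing <- setdiff(c(group_a, group_b), colnames(m$counts))
  if (length(missing) > 0L) {
    stop("unknown cell barcode(s): ", paste(missing, collapse = ", "))
  }
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 cells")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  group_a <- sort(group_a)
  group_b <- sort(group_b)
  n_keep <- min(length(group_a), length(group_b))
  if (length(group_a) > n_keep) group_a <- sort(sample(group_a, n_keep))
  if (length(group_b) > n_keep) group_b <- sort(sample(group_b, n_keep))

  A <- as.matrix(m$counts[, group_a, drop = FALSE])
  B <- as.matrix(m$counts[, group_b, drop = FALSE])
  # duplicated barcodes across groups are allowed (self-comparison is a
  # legitimate null); make the column sets distinct for downstream math
  colnames(A) <- paste0("a_", seq_len(ncol(A)))
  colnames(B) <- paste0("b_", seq_len(ncol(B)))

  mean_a <- mean(colSums(A)); mean_b <- mean(colSums(B))
  if (mean_a > mean_b && mean_a > 0) {
    A[] <- stats::rbinom(length(A), A, mean_b / mean_a)
  } else if (mean_b > mean_a && mean_b > 0) {
    B[] <- stats::rbinom(length(B), B, mean_a / mean_b)
  }

  X <- cbind(A, B)
  totals <- colSums(X)
  if (any(totals == 0)) totals[totals == 0] <- 1
  sf <- switch(normalization,
               library = totals / mean(totals),
               scran = {
                 f <- scran::calculateSumFactors(X)
                 f / mean(f)
               })
  Xn <- sweep(X, 2L, sf, "/")

  idx_a <- seq_len(ncol(A))
  ma <- rowMeans(Xn[, idx_a, drop = FALSE])
  mb <- rowMeans(Xn[, -idx_a, drop = FALSE])
  p <- rank_sum_rows(Xn, idx_a)
  data.frame(gene = rownames(m$counts),
             mean_a = ma, mean_b = mb,
             log2fc = log2((ma + 1) / (mb + 1)),
             p = unname(p), q = bh_adjust(unname(p)),
             row.names = NULL)
}

#' Expression bounds from the DA-neuron expression distribution
#'
#' Computes, per gene, the mean log2 library-size-normalized expression over
#' the given cells, drops genes never detected, and returns the mean +/- one
#' standard deviation of that per-gene distribution. The lower bound is the
#' conservative threshold for considering a gene expressed; the upper bound
#' marks high expression.
#'
#' @param m A `umi_matrix` restricted to the reference (e.g. DA-neuron)
#'   cells.
#' @return A list of class `expression_bounds`: `lower`, `upper`, `center`,
#'   `sd`, `scale = "log"`, and the named per-gene `means` used.
#' @export
expression_bounds <- function(m) {
  totals <- Matrix::colSums(m$counts)
  totals[totals == 0] <- 1
  sf <- totals / mean(totals)
  norm <- sweep(as.matrix(m$counts), 2L, sf, "/")
  keep <- Matrix::rowSums(m$counts) > 0
  if (sum(keep) < 2L) stop("need >= 2 genes with nonzero counts")
  gm <- rowMeans(log2(norm[keep, , drop = FALSE] + 1))
  s <- stats::sd(gm)
  if (s == 0) {
    warning("degenerate expression distribution: lower = upper = mean")
  }
  structure(list(lower = mean(gm) - s, upper = mean(gm) + s,
                 center = mean(gm), sd = s, scale = "log", means = gm),
            class = "expression_bounds")
}

#' Select marker genes from a specificity differential result
#'
#' Markers are genes more than eightfold specific for the target population:
#' strictly `log2fc > 3` and strictly `q < 0.01`.
#'
#' @param de Data frame with at least `gene`, `log2fc`, `q`.
#' @param lfc_min,q_max Strict thresholds (defaults 3 and 0.01).
#' @return The marker subset of `de`, ordered by decreasing `log2fc`.
#' @export
select_markers <- function(de, lfc_min = 3, q_max = 0.01) {
  out <- de[de$log2fc > lfc_min & de$q < q_max, , drop = FALSE]
  out <- out[order(-out$log2fc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a UMI count matrix from MTX triplet files
#'
#' @param mtx_path MatrixMarket file of counts (genes x cells).
#' @param genes_path One gene symbol per line (first tab-separated field
#'   used).
#' @param barcodes_path One cell barcode per line.
#' @param labels_path Optional TSV with columns `barcode`, `label`; when
#'   absent all cells are labelled `"unassigned"`.
#' @return A `umi_matrix`.
#' @export
read_umi_mtx <- function(mtx_path, genes_path, barcodes_path,
                         labels_path = NULL) {
  counts <- Matrix::readMM(mtx_path)
  genes <- vapply(strsplit(readLines(genes_path), "\t"), `[[`, character(1L), 1L)
  barcodes <- readLines(barcodes_path)
  if (nrow(counts) != length(genes) || ncol(counts) != length(barcodes)) {
    stop("MTX dimensions disagree with gene/barcode lists")
  }
  dimnames(counts) <- list(genes, barcodes)
  labels <- rep("unassigned", length(barcodes))
  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    idx <- match(barcodes, lab$barcode)
    if (anyNA(idx)) stop("barcode(s) missing from label table")
    labels <- lab$label[idx]
  }
  umi_matrix(counts, labels)
}

#' Write a UMI count matrix as MTX triplet files
#'
#' @param m A `umi_matrix`.
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`, `labels.tsv`.
#' @return `dir`, invisibly.
#' @export
write_umi_mtx <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(barcode = colnames(m$counts),
               label = as.character(m$cell_labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
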