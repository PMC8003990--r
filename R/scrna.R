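#' Read a 10x-style MTX triplet
#'
#' Sparse genes x cells count matrix from `matrix.mtx`, `features.tsv`
#' (first column = gene ids) and `barcodes.tsv`.
#'
#' @param dir directory containing the three files, or explicit paths via
#'   the other arguments.
#' @param mtx,features,barcodes optional explicit paths.
#' @return A `dgCMatrix` with gene ids as rownames and barcodes as colnames.
#' @export
read_10x_triplet <- function(dir = NULL, mtx = NULL, features = NULL,
                             barcodes = NULL) {
  if (!is.null(dir)) {
    mtx <- file.path(dir, "matrix.mtx")
    features <- file.path(dir, "features.tsv")
    barcodes <- file.path(dir, "barcodes.tsv")
  }
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feat <- utils::read.delim(features, header = FALSE, stringsAsFactors = FALSE)
  bc <- utils::read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feat) != nrow(m) || nrow(bc) != ncol(m))
    stop("features/barcodes do not match matrix dimensions")
  rownames(m) <- feat[[1]]
  colnames(m) <- bc[[1]]
  m
}

#' Label podocytes by marker gating
#'
#' A cell is labelled podocyte iff its raw count is above zero for every
#' marker gene; all remaining cells are labelled other. Labelling is
#' order-independent and idempotent.
#'
#' @param mat genes x cells count matrix.
#' @param markers marker gene ids (default Wt1, Nphs1, Nphs2, Mafb).
#' @return Character vector of labels (`"podocyte"`/`"other"`), one per
#'   cell, named by barcode.
#' @export
label_podocytes <- function(mat, markers = c("Wt1", "Nphs1", "Nphs2", "Mafb")) {
  missing <- setdiff(markers, rownames(mat))
  if (length(missing))
    stop("marker gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (ncol(mat) == 0L) return(stats::setNames(character(0), character(0)))
  sub <- as.matrix(mat[markers, , drop = FALSE])
  lab <- ifelse(colSums(sub > 0) == length(markers), "podocyte", "other")
  stats::setNames(lab, colnames(mat))
}

## two-sided rank-sum p-value; exact enumeration when both groups <= 8
## (handles ties), else normal approximation with tie and continuity
## correction.
rank_sum_test <- function(x, y, method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (method == "exact" || (method == "auto" && n1 <= 8 && n2 <= 8)) {
    sums <- utils::combn(N, n1, FUN = function(idx) sum(r[idx]))
    p <- 2 * min(mean(sums <= w), mean(sums >= w))
    return(list(statistic = w, p = min(1, p)))
  }
  ties <- table(r)
  mu <- n1 * (N + 1) / 2
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(list(statistic = w, p = 1))
  z <- (abs(w - mu) - 0.5) / sqrt(sig2)
  list(statistic = w, p = min(1, 2 * stats::pnorm(-z)))
}

#' Per-gene Wilcoxon test of podocyte-specific expression
#'
#' Counts are CPM-normalized per cell and log1p-transformed, then each gene
#' is tested podocytes vs all other cells with a two-sided Wilcoxon
#' rank-sum test (exact enumeration when both groups have at most 8 cells,
#' normal approximation with tie correction otherwise). q-values are
#' Benjamini-Hochberg across tested genes. A gene is `detected` if nonzero
#' in at least `min_cells` cells; genes absent from the matrix are reported
#' undetected with NA statistics.
#'
#' @param mat genes x cells count matrix.
#' @param labels per-cell labels from [label_podocytes()].
#' @param gene_ids genes to test (default: all rows).
#' @param min_cells detection threshold (default 3).
#' @return data.frame: `gene`, `n_podocyte_expr`, `n_other_expr`,
#'   `statistic`, `p`, `q`, `detected`.
#' @export
wilcoxon_specificity <- function(mat, labels, gene_ids = NULL, min_cells = 3L) {
  if (is.null(gene_ids)) gene_ids <- rownames(mat)
  pod <- names(labels)[labels == "podocyte"]
  oth <- names(labels)[labels == "other"]
  if (length(pod) < 1L || length(oth) < 1L)
    stop("need at least one podocyte and one other cell")
  cpm <- sweep(as.matrix(mat), 2, pmax(Matrix::colSums(mat), 1), "/") * 1e6
  lcpm <- log1p(cpm)
  rows <- lapply(gene_ids, function(g) {
    if (!g %in% rownames(mat))
      return(data.frame(gene = g, n_podocyte_expr = 0L, n_other_expr = 0L,
                        statistic = NA_real_, p = NA_real_,
                        detected = FALSE, stringsAsFactors = FALSE))
    raw <- mat[g, ]
    tst <- rank_sum_test(lcpm[g, pod], lcpm[g, oth])
    data.frame(gene = g,
               n_podocyte_expr = sum(raw[pod] > 0),
               n_other_expr = sum(raw[oth] > 0),
               statistic = tst$statistic, p = tst$p,
               detected = sum(raw > 0) >= min_cells,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[c("gene", "n_podocyte_expr", "n_other_expr", "statistic", "p", "q",
        "detected")]
}
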