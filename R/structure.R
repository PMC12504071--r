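# population-structure summaries from per-CNVR copy-number matrices:
# genomic relationship matrix, PCA, neighbor-joining tree

# accept a cnvr_set (regions x samples matrices) or a plain numeric
# matrix with samples in columns; returns samples x features
as_sample_matrix <- function(x) {
  m <- if (inherits(x, "cnvr_set")) x$cn_mean else as.matrix(x)
  if (is.null(colnames(m))) stop("sample names are required (columns)")
  t(m)
}

#' Genomic relationship matrix from copy numbers
#'
#' Centered cross-product kinship estimator: each CNVR column is centered
#' by its mean (missing entries are mean-imputed first) and
#' `K = W %*% t(W) / m` with `m` the number of CNVRs.  K is symmetric and
#' positive semidefinite by construction.
#'
#' @param x a `cnvr_set` or a numeric matrix with samples in columns.
#' @return samples-by-samples relationship matrix.
#' @export
grm <- function(x) {
  W <- as_sample_matrix(x)
  if (nrow(W) < 2L) stop("at least two samples are required")
  for (j in seq_len(ncol(W))) {
    mu <- mean(W[, j], na.rm = TRUE)
    W[is.na(W[, j]), j] <- mu
    W[, j] <- W[, j] - mu
  }
  if (all(W == 0)) warning("zero-variance copy-number matrix; K is all zeros")
  K <- W %*% t(W) / ncol(W)
  dimnames(K) <- list(rownames(W), rownames(W))
  K
}

#' PCA of the per-CNVR copy-number matrix
#'
#' Eigen-decomposition of the centered sample covariance (missing entries
#' mean-imputed, as in [grm()]); components are ordered by decreasing
#' variance and the variance explained by each is its eigenvalue as a
#' percentage of the trace, so the percentages sum to 100 over all
#' components.
#'
#' @param x a `cnvr_set` or a numeric matrix with samples in columns.
#' @return list with `scores` (samples x components), `var_explained`
#'   (percent per component) and `sdev`.
#' @export
cn_pca <- function(x) {
  W <- as_sample_matrix(x)
  if (nrow(W) < 3L) stop("PCA needs at least three samples")
  for (j in seq_len(ncol(W))) {
    W[is.na(W[, j]), j] <- mean(W[, j], na.rm = TRUE)
  }
  p <- stats::prcomp(W, center = TRUE, scale. = FALSE)
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, var_explained = ve, sdev = p$sdev)
}

#' Neighbor-joining tree from copy-number distances
#'
#' Pairwise distance between samples is the mean absolute copy-number
#' difference over CNVRs where both are non-missing (a Manhattan-type
#' distance, robust to single large regions); the tree is built by
#' neighbor joining and can be serialized as Newick with
#' [ape::write.tree()].
#'
#' @param x a `cnvr_set` or a numeric matrix with samples in columns.
#' @param method `"manhattan"` (mean absolute difference, default) or
#'   `"euclidean"` (root mean squared difference).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(x, method = c("manhattan", "euclidean")) {
  method <- match.arg(method)
  W <- as_sample_matrix(x)
  if (nrow(W) < 3L) stop("a tree needs at least three samples")
  D <- cn_dist(W, method)
  ape::nj(stats::as.dist(D))
}

cn_dist <- function(W, method = "manhattan") {
  n <- nrow(W)
  D <- matrix(0, n, n, dimnames = list(rownames(W), rownames(W)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- W[i, ] - W[j, ]
      d <- d[!is.na(d)]
      if (length(d) == 0L) stop("samples share no informative CNVR")
      D[i, j] <- D[j, i] <- if (method == "manhattan") mean(abs(d)) else
        sqrt(mean(d^2))
    }
  }
  D
}

#' Does an unrooted tree contain a given tip bipartition?
#'
#' Checks whether some internal edge of `tree` separates `tips` from all
#' remaining tips — e.g. whether two populations fall on two branches.
#'
#' @param tree an `ape::phylo` tree.
#' @param tips character vector of tip labels on one side of the split.
#' @return logical.
#' @export
has_bipartition <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  other <- setdiff(tree$tip.label, tips)
  if (length(tips) < 2L || length(other) < 2L) return(TRUE)
  rooted <- ape::root(tree, outgroup = tips[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, other)
}
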