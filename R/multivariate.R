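#' PCA of the compound Z matrix
#'
#' Principal component analysis of the (compound x descriptor.time) Z
#' matrix: columns are mean-centered but not rescaled — Z-scores are
#' already standardized by construction, so rescaling would only inflate
#' noise columns (correlation-mode PCA is available via `scale.`). The
#' smallest number of components whose cumulative variance fraction
#' reaches `var_threshold` is retained.
#'
#' @param z numeric matrix, rows = samples (compounds), >= 2 rows, no
#'   missing values.
#' @param var_threshold cumulative variance fraction to retain (default
#'   0.95).
#' @param scale. rescale columns to unit variance first (default FALSE).
#' @return Object of class `pca_model`: `loadings`, `scores`,
#'   `eigenvalues`, `var_frac`, `cum_var`, `n_retained`, `n_nonzero`.
#' @export
pca_reduce <- function(z, var_threshold = 0.95, scale. = FALSE) {
  z <- as.matrix(z)
  if (nrow(z) < 2) stop_input("PCA needs at least 2 samples")
  if (anyNA(z)) stop_input("Z matrix must not contain missing values")
  if (var_threshold <= 0 || var_threshold > 1)
    stop_input("var_threshold must be in (0, 1]")
  p <- stats::prcomp(z, center = TRUE, scale. = scale.)
  ev <- p$sdev^2
  tot <- sum(ev)
  if (tot == 0) stop_input("Z matrix has zero total variance")
  var_frac <- ev / tot
  cum_var <- cumsum(var_frac)
  n_nonzero <- sum(ev > max(ev) * 1e-9)
  n_retained <- which(cum_var >= var_threshold - 1e-12)[1]
  structure(list(
    loadings = p$rotation, scores = p$x, eigenvalues = ev,
    var_frac = var_frac, cum_var = cum_var, center = p$center,
    n_retained = n_retained, n_nonzero = n_nonzero,
    var_threshold = var_threshold), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", length(x$eigenvalues), "components (", x$n_nonzero,
      "non-zero );", x$n_retained, "retained at",
      sprintf(">= %.0f%%", 100 * x$var_threshold), "cumulative variance\n")
  invisible(x)
}

#' Ward hierarchical clustering of compound profiles
#'
#' Agglomerative clustering with Euclidean base distance and Ward's
#' minimum-variance criterion (`stats::hclust`, method `"ward.D2"`): each
#' merge minimizes the increase in total within-cluster sum of squares;
#' the reported merge height is `sqrt(2 * delta SSE)`, non-decreasing
#' along the tree.
#'
#' @param scores numeric matrix of sample coordinates (e.g. retained PC
#'   scores), rows named by sample; row names must be unique.
#' @return Object of class `ward_clustering`: `hclust` (the tree),
#'   `heights`, `labels`, `scores`.
#' @export
ward_cluster <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stop_input("clustering needs at least 2 samples")
  ids <- rownames(scores) %||% paste0("s", seq_len(nrow(scores)))
  if (anyDuplicated(ids)) stop_input("duplicate sample ids")
  rownames(scores) <- ids
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  structure(list(hclust = hc, heights = hc$height, labels = ids,
                 scores = scores), class = "ward_clustering")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat("<ward_clustering>", length(x$labels), "samples; merge heights",
      sprintf("%.3g .. %.3g", min(x$heights), max(x$heights)), "\n")
  invisible(x)
}

#' Flatten a cluster tree
#'
#' `"largest_gap"` cuts below the largest difference between successive
#' merge heights, the automatic stand-in for a by-eye dendrogram cut: if
#' the largest gap follows the i-th of the n-1 merges, the tree is cut
#' into n - i clusters. When every merge sits at the same height (e.g.
#' all samples identical) the rule returns a single cluster. `"fixed_k"`
#' is the standard k-cluster cut.
#'
#' @param clustering a [ward_cluster()] result.
#' @param mode `"largest_gap"` (default) or `"fixed_k"`.
#' @param k number of clusters for `"fixed_k"`, in 1..n.
#' @return Named integer vector of cluster labels; the chosen k is in
#'   attribute `"k"`.
#' @export
cut_clusters <- function(clustering, mode = c("largest_gap", "fixed_k"),
                         k = NULL) {
  mode <- match.arg(mode)
  if (!inherits(clustering, "ward_clustering"))
    stop_input("clustering must come from ward_cluster()")
  n <- length(clustering$labels)
  h <- clustering$heights
  if (mode == "fixed_k") {
    if (is.null(k) || k < 1 || k > n) stop_input("k must be in 1..", n)
  } else {
    gaps <- diff(c(0, h))[-1]          # gaps between successive merges
    if (length(h) == 1 || max(gaps) <= 0) {
      k <- if (max(h) == 0) 1L else 2L
    } else {
      i <- which.max(gaps)             # largest gap after merge i
      k <- n - i
    }
  }
  labels <- stats::cutree(clustering$hclust, k = k)
  attr(labels, "k") <- k
  attr(labels, "mode") <- mode
  labels
}

#' Correlation structure of the Z-score descriptors
#'
#' Pearson correlation between descriptor.time columns of the Z matrix
#' across compounds, followed by hierarchical clustering of the `1 - r`
#' distance. Group counts are reported at two cut levels: major groups at
#' the largest merge-height gap and minor groups at the largest gap below
#' it (a finer partition). Zero-variance columns are excluded.
#'
#' @param z compound x descriptor.time Z matrix with >= 3 rows.
#' @param method linkage for the correlation tree (default `"average"`).
#' @return List of class `descriptor_correlation`: `correlation` matrix,
#'   `hclust`, `k_major`, `k_minor`, `labels_major`, `labels_minor`,
#'   `excluded` column names.
#' @export
descriptor_correlation_clusters <- function(z, method = "average") {
  z <- as.matrix(z)
  if (nrow(z) < 3) stop_input("need >= 3 compounds for column correlations")
  sds <- apply(z, 2, stats::sd)
  excluded <- colnames(z)[sds == 0]
  if (length(excluded))
    message("excluding ", length(excluded), " zero-variance column(s)")
  z <- z[, sds > 0, drop = FALSE]
  if (ncol(z) < 2) stop_input("fewer than 2 non-degenerate columns")
  r <- stats::cor(z)
  hc <- stats::hclust(stats::as.dist(1 - r), method = method)
  h <- hc$height
  n <- ncol(z)
  gaps <- diff(h)
  if (length(h) < 2 || max(gaps) <= 0) {
    k_major <- if (max(h) == 0) 1L else 2L
    k_minor <- k_major
  } else {
    i <- which.max(gaps)
    k_major <- n - i
    below <- if (i > 1) gaps[seq_len(i - 1)] else numeric(0)
    k_minor <- if (length(below) && max(below) > 0) n - which.max(below)
               else k_major
  }
  structure(list(
    correlation = r, hclust = hc, k_major = k_major, k_minor = k_minor,
    labels_major = stats::cutree(hc, k_major),
    labels_minor = stats::cutree(hc, k_minor),
    excluded = excluded), class = "descriptor_correlation")
}

#' @export
print.descriptor_correlation <- function(x, ...) {
  cat("<descriptor_correlation>", ncol(x$correlation), "columns;",
      x$k_major, "major /", x$k_minor, "minor groups\n")
  invisible(x)
}
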