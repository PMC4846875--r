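#' Fit a mechanism-of-action profile to a per-cell feature table
#'
#' The full profiling pipeline as one fitting step: per-cell descriptor
#' distributions of each compound are compared with the control by the
#' signed two-sample KS statistic, standardized against a bootstrap
#' control null into Z-scores, filtered for replicate reliability
#' (Pearson r > `reliability_threshold` across compounds), assembled into
#' the compound x descriptor.time Z matrix, reduced by PCA to the
#' components explaining `var_threshold` of the variance, and clustered
#' with Ward linkage on Euclidean distances; the dendrogram is flattened
#' at the largest merge-height gap (or a fixed k).
#'
#' @param features per-cell feature table (see [compute_z_profiles()]).
#' @param control control compound label (default `"DMSO"`).
#' @param n_boot bootstrap iterations for the null SD.
#' @param reliability_threshold replicate-correlation retention threshold.
#' @param var_threshold cumulative PCA variance to retain.
#' @param cut dendrogram flattening mode, `"largest_gap"` or `"fixed_k"`.
#' @param k cluster count for `"fixed_k"`.
#' @param combine replicate combination for the Z matrix (`"mean"` or
#'   `"concat"`).
#' @param comparator bootstrap comparator (see [bootstrap_null_std()]).
#' @param seed integer seed for all randomness in the fit.
#' @return Object of class `moa_profile` with components `z` (long
#'   profile), `reliability`, `z_matrix`, `pca`, `clustering`, `clusters`
#'   and the call; see [summary.moa_profile()].
#' @export
#' @examples
#' \donttest{
#' panel <- generate_panel(panel_config(n_compounds = 4,
#'   n_cells_per_condition = 150, time_points_min = c(0, 30),
#'   rng_seed = 7))
#' fit <- moa_profile(panel$features, n_boot = 200, seed = 7)
#' fit
#' }
moa_profile <- function(features, control = "DMSO", n_boot = 1000,
                        reliability_threshold = 0.4, var_threshold = 0.95,
                        cut = c("largest_gap", "fixed_k"), k = NULL,
                        combine = c("mean", "concat"),
                        comparator = c("pair", "resample"), seed = 1) {
  cut <- match.arg(cut)
  combine <- match.arg(combine)
  comparator <- match.arg(comparator)
  z <- compute_z_profiles(features, control = control, n_boot = n_boot,
                          seed = seed, comparator = comparator)
  rel <- reliability_filter(z, threshold = reliability_threshold)
  if (!any(rel$retained))
    stop_input("no descriptor passed the reliability filter")
  zm <- assemble_z_matrix(z, retained = rel, combine = combine)
  pca <- pca_reduce(zm, var_threshold = var_threshold)
  scores <- pca$scores[, seq_len(pca$n_retained), drop = FALSE]
  clustering <- ward_cluster(scores)
  clusters <- cut_clusters(clustering, mode = cut, k = k)
  structure(list(
    call = match.call(), z = z, reliability = rel, z_matrix = zm,
    pca = pca, clustering = clustering, clusters = clusters,
    control = control,
    params = list(n_boot = n_boot,
                  reliability_threshold = reliability_threshold,
                  var_threshold = var_threshold, cut = cut, k = k,
                  combine = combine, comparator = comparator, seed = seed)),
    class = "moa_profile")
}

#' @export
print.moa_profile <- function(x, ...) {
  cat("Mechanism-of-action profile\n")
  cat("  compounds:       ", nrow(x$z_matrix), " (incl. ", x$control, ")\n",
      sep = "")
  cat("  Z columns:       ", ncol(x$z_matrix), " retained of ",
      nrow(x$reliability), " (r > ",
      attr(x$reliability, "threshold"), ")\n", sep = "")
  cat("  PCs retained:    ", x$pca$n_retained, " of ", x$pca$n_nonzero,
      " non-zero (", sprintf("%.1f%%", 100 * x$pca$cum_var[x$pca$n_retained]),
      " variance)\n", sep = "")
  cat("  clusters:        ", attr(x$clusters, "k"), " (",
      attr(x$clusters, "mode"), " cut)\n", sep = "")
  invisible(x)
}

#' Summarize a fitted mechanism-of-action profile
#'
#' @param object a [moa_profile()] fit.
#' @param ... unused.
#' @return A list of class `summary.moa_profile` with cluster membership,
#'   retained-descriptor counts per time point and the PCA variance table.
#' @export
summary.moa_profile <- function(object, ...) {
  cl <- split(names(object$clusters), object$clusters)
  rel <- object$reliability
  retained_by_time <- table(rel$time_min[rel$retained])
  structure(list(
    clusters = cl,
    k = attr(object$clusters, "k"),
    retained_by_time = retained_by_time,
    n_columns = ncol(object$z_matrix),
    variance = data.frame(pc = seq_along(object$pca$var_frac),
                          var_frac = object$pca$var_frac,
                          cum_var = object$pca$cum_var)[
                            seq_len(object$pca$n_nonzero), ],
    n_retained_pc = object$pca$n_retained,
    z_range = range(object$z_matrix)), class = "summary.moa_profile")
}

#' @export
print.summary.moa_profile <- function(x, ...) {
  cat("Clusters (k =", x$k, "):\n")
  for (i in seq_along(x$clusters))
    cat("  ", i, ": ", paste(x$clusters[[i]], collapse = ", "), "\n", sep = "")
  cat("Retained descriptor columns:", x$n_columns, "\n")
  cat("Retained per time point:\n")
  print(x$retained_by_time)
  cat(sprintf("PCs: %d retained (%.1f%% variance); Z range [%.1f, %.1f]\n",
              x$n_retained_pc, 100 * x$variance$cum_var[x$n_retained_pc],
              x$z_range[1], x$z_range[2]))
  invisible(x)
}

#' @export
#' @describeIn moa_profile the compound-by-descriptor Z matrix of the fit.
coef.moa_profile <- function(object, ...) object$z_matrix

#' Plot a mechanism-of-action profile
#'
#' @param x a [moa_profile()] fit.
#' @param type `"dendrogram"` (Ward tree with the applied cut) or
#'   `"scores"` (samples on the first two PCs, colored by cluster).
#' @param ... passed to the underlying base plotting call.
#' @export
plot.moa_profile <- function(x, type = c("dendrogram", "scores"), ...) {
  type <- match.arg(type)
  if (type == "dendrogram") {
    hc <- x$clustering$hclust
    plot(hc, ylab = "Ward merge height", xlab = "", sub = "",
         main = "Compound clustering", ...)
    k <- attr(x$clusters, "k")
    if (k > 1 && k < length(x$clusters)) stats::rect.hclust(hc, k = k)
  } else {
    s <- x$pca$scores
    plot(s[, 1], s[, 2], col = x$clusters, pch = 19,
         xlab = sprintf("PC1 (%.0f%%)", 100 * x$pca$var_frac[1]),
         ylab = sprintf("PC2 (%.0f%%)", 100 * x$pca$var_frac[2]),
         main = "Compound Z profiles", ...)
    graphics::text(s[, 1], s[, 2], rownames(s), pos = 3, cex = 0.7)
  }
  invisible(x)
}
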