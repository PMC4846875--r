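#' Signed-KS Z profiles for every compound, descriptor and time point
#'
#' For each (descriptor, time point, replicate), compares every compound's
#' per-cell values with the same replicate's control cells by the signed
#' two-sample KS statistic and standardizes by the bootstrap control null
#' SD. A held-out control-vs-control comparison (random half-split of the
#' control cells) provides the control's own row. Bootstrap substreams are
#' derived deterministically from `seed`, so results do not depend on
#' execution order.
#'
#' @param features per-cell feature table: metadata columns (`compound`,
#'   `time_min`, `replicate`) plus one column per descriptor (e.g. from
#'   [generate_panel()] or [compute_cell_features()]).
#' @param control compound label of the vehicle control (default "DMSO").
#' @param n_boot bootstrap iterations for the null SD (default 1000).
#' @param seed integer run seed for all bootstrap randomness.
#' @param comparator see [bootstrap_null_std()].
#' @return Object of class `z_profile`: long data.frame with columns
#'   `compound, descriptor, time_min, replicate, signed_d, null_std, z`
#'   (`z` is `NA` for degenerate descriptors), with the degenerate
#'   (descriptor, time, replicate) entries recorded in the
#'   `"degenerate"` attribute.
#' @export
compute_z_profiles <- function(features, control = "DMSO", n_boot = 1000,
                               seed = 1, comparator = "pair") {
  need <- c("compound", "time_min", "replicate")
  if (!all(need %in% colnames(features)))
    stop_input("features must have columns ", paste(need, collapse = ", "))
  if (!control %in% features$compound)
    stop_input("control compound '", control, "' absent from features")
  descriptors <- descriptor_columns(features)
  if (!length(descriptors)) stop_input("no descriptor columns found")
  times <- sort(unique(features$time_min))
  reps <- sort(unique(features$replicate))
  compounds <- setdiff(unique(features$compound), control)
  rows <- vector("list", 0L)
  degen <- vector("list", 0L)
  for (ti in seq_along(times)) for (ri in seq_along(reps)) {
    sel_tr <- features$time_min == times[ti] & features$replicate == reps[ri]
    ctrl_block <- features[sel_tr & features$compound == control, , drop = FALSE]
    if (!nrow(ctrl_block))
      stop_input("no control cells at time ", times[ti], ", replicate ",
                 reps[ri])
    sub_seed <- mix_seed(seed, ti * 1000L + ri)
    for (d in descriptors) {
      ctrl <- ctrl_block[[d]]
      ns <- bootstrap_null_std(ctrl, n_boot = n_boot, seed = sub_seed,
                               comparator = comparator)
      if (ns$degenerate)
        degen[[length(degen) + 1L]] <- data.frame(
          descriptor = d, time_min = times[ti], replicate = reps[ri])
      for (cp in c(compounds, control)) {
        if (cp == control) {
          # held-out half-vs-half split of the control cells
          idx <- withr::with_seed(
            mix_seed(seed, ti * 100000L + ri * 10L + 7L),
            sample.int(length(ctrl), floor(length(ctrl) / 2)))
          sk <- signed_ks(ctrl[idx], ctrl[-idx])
        } else {
          trt <- features[[d]][sel_tr & features$compound == cp]
          if (!length(trt))
            stop_input("no cells for compound ", cp, " at time ", times[ti],
                       ", replicate ", reps[ri])
          sk <- signed_ks(trt, ctrl)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cp, descriptor = d, time_min = times[ti],
          replicate = reps[ri], signed_d = sk$signed_d, null_std = ns$std,
          z = if (ns$degenerate) NA_real_ else sk$signed_d / ns$std,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "control") <- control
  attr(out, "degenerate") <- if (length(degen)) do.call(rbind, degen) else
    data.frame(descriptor = character(0), time_min = numeric(0),
               replicate = numeric(0))
  class(out) <- c("z_profile", "data.frame")
  out
}

z_column_name <- function(descriptor, time_min) {
  paste0(descriptor, "@", time_min)
}

# compound x column Z matrix for one replicate of a z_profile
replicate_z_matrix <- function(z, replicate, include_control = FALSE) {
  ctrl <- attr(z, "control")
  zz <- z[z$replicate == replicate, , drop = FALSE]
  if (!include_control) zz <- zz[zz$compound != ctrl, , drop = FALSE]
  cols <- z_column_name(zz$descriptor, zz$time_min)
  compounds <- unique(zz$compound)
  colnames_u <- unique(cols)
  m <- matrix(NA_real_, length(compounds), length(colnames_u),
              dimnames = list(compounds, colnames_u))
  m[cbind(match(zz$compound, compounds), match(cols, colnames_u))] <- zz$z
  m
}

#' Replicate-reliability filter of descriptors
#'
#' A descriptor (at one time point) is kept only when its Z-scores agree
#' across two independent replicate experiments: the Pearson correlation of
#' the replicate-1 and replicate-2 Z vectors across compounds must exceed
#' the threshold (default 0.4). Columns with zero variance or missing Z in
#' either replicate are dropped (r undefined).
#'
#' @param z a `z_profile` from [compute_z_profiles()] with exactly two
#'   replicates, or a matrix (compounds x descriptor\@time) for replicate 1.
#' @param z2 second replicate matrix when matrices are given.
#' @param threshold retention threshold on Pearson r (strictly greater
#'   retained; default 0.4).
#' @return Object of class `reliability_report`: data.frame with
#'   `column, descriptor, time_min, r, retained`.
#' @export
reliability_filter <- function(z, z2 = NULL, threshold = 0.4) {
  if (inherits(z, "z_profile")) {
    reps <- sort(unique(z$replicate))
    if (length(reps) != 2)
      stop_input("reliability filtering needs exactly 2 replicates, found ",
                 length(reps))
    m1 <- replicate_z_matrix(z, reps[1])
    m2 <- replicate_z_matrix(z, reps[2])
  } else {
    if (is.null(z2)) stop_input("provide a z_profile or two matrices")
    m1 <- as.matrix(z); m2 <- as.matrix(z2)
  }
  if (!identical(dimnames(m1), dimnames(m2)))
    stop_input("replicates do not cover the same compounds/descriptors")
  r <- rep(NA_real_, ncol(m1))
  for (j in seq_len(ncol(m1))) {
    x <- m1[, j]; y <- m2[, j]
    if (!anyNA(c(x, y)) && stats::sd(x) > 0 && stats::sd(y) > 0)
      r[j] <- stats::cor(x, y)
  }
  cols <- colnames(m1)
  parts <- strsplit(cols, "@", fixed = TRUE)
  out <- data.frame(
    column = cols,
    descriptor = vapply(parts, function(p) paste(p[-length(p)], collapse = "@"), ""),
    time_min = as.numeric(vapply(parts, function(p) p[length(p)], "")),
    r = r,
    retained = !is.na(r) & r > threshold,
    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "n_dropped_undefined") <- sum(is.na(r))
  class(out) <- c("reliability_report", "data.frame")
  out
}

#' Assemble the compound-by-descriptor Z matrix
#'
#' Builds the matrix fed to PCA and clustering: rows are compounds plus the
#' control (whose row comes from the held-out control-vs-control split),
#' columns are the retained (descriptor, time) pairs, replicate Z-scores
#' combined by their mean (or concatenated as separate columns).
#'
#' @param z a `z_profile` from [compute_z_profiles()].
#' @param retained a `reliability_report`, a character vector of
#'   `descriptor@time` column names, or `NULL` for all non-degenerate
#'   columns.
#' @param combine `"mean"` (default) or `"concat"`.
#' @return Numeric matrix with compound row names and `descriptor@time`
#'   (`...@rep` if concatenated) column names; attribute `"columns"` maps
#'   columns to descriptor and time.
#' @export
assemble_z_matrix <- function(z, retained = NULL, combine = c("mean", "concat")) {
  combine <- match.arg(combine)
  if (!inherits(z, "z_profile")) stop_input("z must be a z_profile")
  if (inherits(retained, "reliability_report"))
    retained <- retained$column[retained$retained]
  all_cols <- unique(z_column_name(z$descriptor, z$time_min))
  if (is.null(retained)) {
    bad <- unique(z_column_name(z$descriptor[is.na(z$z)],
                                z$time_min[is.na(z$z)]))
    retained <- setdiff(all_cols, bad)
  }
  missing_cols <- setdiff(retained, all_cols)
  if (length(missing_cols))
    stop_input("columns absent from the Z profile: ",
               paste(utils::head(missing_cols, 5), collapse = ", "))
  reps <- sort(unique(z$replicate))
  mats <- lapply(reps, function(r)
    replicate_z_matrix(z, r, include_control = TRUE)[, retained, drop = FALSE])
  if (combine == "mean") {
    m <- Reduce(`+`, mats) / length(mats)
  } else {
    m <- do.call(cbind, lapply(seq_along(mats), function(i) {
      x <- mats[[i]]
      colnames(x) <- paste0(colnames(x), "@r", reps[i])
      x
    }))
  }
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop_input("Z matrix has missing entries, e.g. compound ",
               rownames(m)[miss[1, 1]], ", column ", colnames(m)[miss[1, 2]])
  }
  parts <- strsplit(colnames(m), "@", fixed = TRUE)
  attr(m, "columns") <- data.frame(
    column = colnames(m),
    descriptor = vapply(parts, `[[`, "", 1),
    time_min = as.numeric(vapply(parts, `[[`, "", 2)))
  attr(m, "control") <- attr(z, "control")
  m
}
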