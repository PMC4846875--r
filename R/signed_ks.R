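#' Signed two-sample Kolmogorov-Smirnov statistic
#'
#' The two-sample KS distance with a sign carrying the direction of the
#' treated-vs-control shift: `D_plus = sup_x (F_control - F_treated)` and
#' `D_minus = sup_x (F_treated - F_control)` are the exact suprema of the
#' ECDF differences over all pooled sample points; the statistic is
#' `+max(D_plus, D_minus)` when `D_plus >= D_minus` (treated shifted
#' toward larger values) and `-max(...)` otherwise. An exact tie between
#' `D_plus` and `D_minus` takes the positive sign (a measure-zero case for
#' continuous data). Ties within and across samples are handled exactly
#' through the pooled ECDFs.
#'
#' @param treated,control non-empty numeric vectors of per-cell values.
#' @return Object of class `signed_ks`: list with `d_plus`, `d_minus`,
#'   `signed_d`, `n_treated`, `n_control`.
#' @export
#' @examples
#' signed_ks(c(4, 5, 6), c(1, 2, 3))$signed_d   #  1
#' signed_ks(c(1, 3), c(2, 4))$signed_d         # -0.5
signed_ks <- function(treated, control) {
  if (!length(treated) || !length(control))
    stop_input("samples must be non-empty")
  if (anyNA(treated) || anyNA(control) ||
      any(!is.finite(treated)) || any(!is.finite(control)))
    stop_input("samples must be finite")
  n_t <- length(treated); n_c <- length(control)
  w <- c(treated, control)
  o <- order(w)
  is_t <- rep(c(TRUE, FALSE), c(n_t, n_c))[o]
  # exact integer counts below each pooled point: no cumulative float drift,
  # so exact ties between D+ and D- stay exact
  z <- cumsum(is_t) / n_t - cumsum(!is_t) / n_c   # F_treated - F_control
  ws <- w[o]
  last_of_run <- c(diff(ws) != 0, TRUE)    # evaluate at the end of tied runs
  z <- z[last_of_run]
  d_minus <- max(c(z, 0))
  d_plus <- max(c(-z, 0))
  structure(list(
    d_plus = d_plus, d_minus = d_minus,
    signed_d = if (d_plus >= d_minus) d_plus else -d_minus,
    n_treated = n_t, n_control = n_c), class = "signed_ks")
}

#' @export
print.signed_ks <- function(x, ...) {
  cat(sprintf("<signed_ks> D = %+.4f (D+ %.4f, D- %.4f; n = %d vs %d)\n",
              x$signed_d, x$d_plus, x$d_minus, x$n_treated, x$n_control))
  invisible(x)
}

# Signed KS from multinomial resample counts on the support of the sorted
# unique control values. `c_t` is a k x B count matrix for the "treated"
# role; `ref` is either a k x B count matrix (pair comparator) or a single
# count vector (resample-vs-original). Returns B signed values. Exactly
# equivalent to signed_ks() on the expanded resamples because both ECDFs
# step only at the shared support points.
ks_signed_from_counts <- function(c_t, ref, n_t, n_ref) {
  cum_t <- apply(c_t, 2, cumsum)
  cum_r <- if (is.matrix(ref)) apply(ref, 2, cumsum) else cumsum(ref)
  # integer cumulative counts divided once: exact ties preserved
  z <- cum_t / n_t - if (is.matrix(ref)) cum_r / n_ref else
    matrix(cum_r / n_ref, nrow(c_t), ncol(c_t))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  B <- ncol(z)
  d_minus <- pmax(z[cbind(max.col(t(z), ties.method = "first"),
                          seq_len(B))], 0)
  zn <- -z
  d_plus <- pmax(zn[cbind(max.col(t(zn), ties.method = "first"),
                          seq_len(B))], 0)
  ifelse(d_plus >= d_minus, d_plus, -d_minus)
}

.null_std_cache <- new.env(parent = emptyenv())

#' Bootstrap null standard deviation of the signed KS statistic
#'
#' Estimates the spread of the signed KS statistic under the null (no
#' compound effect) by resampling the control sample with replacement
#' `n_boot` times. The default `"pair"` comparator draws two independent
#' resamples per iteration and compares them, which reproduces the
#' sampling noise of a treated-vs-control comparison at equal sample
#' sizes; `"resample"` compares each resample against the original control
#' ECDF (one-sample scaling, smaller by about sqrt(2)).
#'
#' A constant control sample has no distributional spread: the result is
#' `std = 0` with `degenerate = TRUE`, and such descriptors are excluded
#' downstream rather than producing infinite Z-scores.
#'
#' Under resampling, the null distribution of the statistic depends on the
#' control sample only through the multiplicity pattern of its sorted
#' values, so results are memoized on that pattern (disable with
#' `cache = FALSE`).
#'
#' @param control numeric control sample (length >= 2).
#' @param n_boot number of bootstrap iterations (default 1000).
#' @param seed integer seed; the estimate is deterministic given it.
#' @param comparator `"pair"` (default) or `"resample"`.
#' @param size resample size (defaults to the control size; set to the
#'   treated sample size if it differs substantially).
#' @param cache memoize on the control's multiplicity pattern.
#' @return Object of class `null_std`: list with `std`, `degenerate`,
#'   `n_boot`, `comparator`, `n_control`, `size`.
#' @export
bootstrap_null_std <- function(control, n_boot = 1000, seed = 1,
                               comparator = c("pair", "resample"),
                               size = length(control), cache = TRUE) {
  comparator <- match.arg(comparator)
  if (length(control) < 2) stop_input("control sample must have length >= 2")
  if (anyNA(control) || any(!is.finite(control)))
    stop_input("control sample must be finite")
  mult <- tabulate(match(control, sort(unique(control))))
  res <- list(std = 0, degenerate = TRUE, n_boot = n_boot,
              comparator = comparator, n_control = length(control),
              size = size)
  class(res) <- "null_std"
  if (length(mult) == 1L) return(res)   # constant sample
  key <- paste(comparator, n_boot, seed, size, paste(mult, collapse = ","),
               sep = "|")
  if (cache && !is.null(.null_std_cache[[key]])) {
    res$std <- .null_std_cache[[key]]
    res$degenerate <- FALSE
    return(res)
  }
  d <- withr::with_seed(seed, {
    prob <- mult / length(control)
    c1 <- stats::rmultinom(n_boot, size, prob)
    if (comparator == "pair") {
      c2 <- stats::rmultinom(n_boot, size, prob)
      ks_signed_from_counts(c1, c2, size, size)
    } else {
      ks_signed_from_counts(c1, mult, size, length(control))
    }
  })
  res$std <- stats::sd(d)
  res$degenerate <- FALSE
  if (cache) .null_std_cache[[key]] <- res$std
  res
}

#' @export
print.null_std <- function(x, ...) {
  cat(sprintf("<null_std> std = %.5f (%s, n_boot = %d, n = %d%s)\n",
              x$std, x$comparator, x$n_boot, x$n_control,
              if (x$degenerate) ", DEGENERATE" else ""))
  invisible(x)
}

#' Standardized Z-score of a signed KS statistic
#'
#' Divides the signed KS statistic by the bootstrap-estimated control
#' standard deviation, so that control-vs-control comparisons have Z with
#' mean ~ 0 and SD ~ 1.
#'
#' @param signed_d a [signed_ks()] result or a bare signed statistic.
#' @param null_std a [bootstrap_null_std()] result or a bare positive SD.
#' @return The Z value, or `NA` (with a warning) when the null SD is
#'   degenerate — degenerate descriptors are excluded, never +/-Inf.
#' @export
z_score <- function(signed_d, null_std) {
  d <- if (inherits(signed_d, "signed_ks")) signed_d$signed_d else signed_d
  s <- if (inherits(null_std, "null_std")) null_std$std else null_std
  if (!is.finite(s) || s <= 0) {
    warning("degenerate null std; descriptor should be excluded")
    return(NA_real_)
  }
  d / s
}
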