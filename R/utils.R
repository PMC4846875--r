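#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_input(name, " must be a numeric matrix")
  if (anyNA(x) || any(!is.finite(x)))
    stop_input(name, " contains NA/NaN/Inf pixels")
  if (any(x < 0))
    stop_input(name, " contains negative intensities")
  invisible(x)
}

# Deterministic substream seed from a run seed and a stream index.
# Kept strictly below 2^31 - 1 so it is always a valid integer seed.
mix_seed <- function(seed, index) {
  s <- (as.double(seed) %% 1000003) * 2057 + as.double(index) * 7919 + 12345
  as.integer(s %% 2147483647)
}

# Metadata columns of a per-cell feature table; everything else is a descriptor.
FEATURE_META_COLS <- c("cell_id", "batch_id", "compound", "time_min",
                       "replicate", "well")

descriptor_columns <- function(features) {
  setdiff(colnames(features), FEATURE_META_COLS)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to score recovery of the synthetic panel's mechanism groups.
#'
#' @param a,b vectors of cluster labels (same length); any atomic type.
#' @return A number in \[-1, 1\]; 1 means identical partitions, 0 the
#'   expectation under independent random labelings.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_input("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
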