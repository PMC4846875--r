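#' Define a single image descriptor
#'
#' A descriptor is one quantitative per-cell read-out: a statistic of one
#' (or, for colocalization, two) fluorescence channels over one cellular
#' region. The regions follow the high-content screening convention:
#' `nucleus`, `cell`, `cytoplasm` (cell minus nucleus), `perinuclear`
#' (ring around the nucleus) and `pm` (plasma-membrane ring at the cell
#' edge).
#'
#' @param name unique descriptor name, e.g. `"Nucleus_pERK_mean"`.
#' @param region one of `"nucleus"`, `"cell"`, `"cytoplasm"`,
#'   `"perinuclear"`, `"pm"`. Ratio descriptors use the fixed
#'   perinuclear/PM pair and ignore this argument beyond validation.
#' @param channel primary channel name.
#' @param statistic one of `"mean"`, `"integrated"`, `"object_count"`,
#'   `"coloc_count"`, `"ratio_perinuclear_pm"`.
#' @param channel2 second channel, required for `"coloc_count"` only.
#' @return A one-row data.frame with columns
#'   `name, region, channel, channel2, statistic`.
#' @export
descriptor_def <- function(name, region, channel, statistic, channel2 = NA_character_) {
  regions <- c("nucleus", "cell", "cytoplasm", "perinuclear", "pm")
  stats_ok <- c("mean", "integrated", "object_count", "coloc_count",
                "ratio_perinuclear_pm")
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_input("descriptor name must be a non-empty string")
  if (!region %in% regions)
    stop_input("unknown region '", region, "' in descriptor '", name, "'")
  if (!statistic %in% stats_ok)
    stop_input("unknown statistic '", statistic, "' in descriptor '", name, "'")
  if (statistic == "coloc_count" && is.na(channel2))
    stop_input("coloc_count descriptor '", name, "' needs two channels")
  if (statistic != "coloc_count" && !is.na(channel2))
    stop_input("descriptor '", name, "' references two channels but is not coloc_count")
  data.frame(name = name, region = region, channel = channel,
             channel2 = channel2, statistic = statistic,
             stringsAsFactors = FALSE)
}

#' Default descriptor catalogue
#'
#' A documented stand-in for a full screening descriptor list: region x
#' channel mean intensities, whole-cell integrated intensities, endosome
#' object counts per ring region, a PM EGFR/transferrin colocalization
#' count, and the perinuclear/PM intensity ratio of the receptor channel.
#' The catalogue size is configurable by adding or dropping rows; all
#' downstream code treats it as data.
#'
#' @param channels marker channel names; the first is taken as the
#'   receptor (EGFR-like) trafficking channel, the last as the recycling
#'   (transferrin-like) channel.
#' @return data.frame of descriptor definitions (one row each), unique names.
#' @export
#' @examples
#' cat <- default_descriptor_catalogue()
#' nrow(cat)
default_descriptor_catalogue <- function(channels = c("EGFR", "pERK", "pAkt", "Tfn")) {
  if (length(channels) < 2) stop_input("need at least two channels")
  rec <- channels[1]                     # trafficking receptor channel
  rcy <- channels[length(channels)]      # recycling marker channel
  rows <- list()
  for (ch in channels)
    for (rg in c("nucleus", "cytoplasm", "perinuclear", "pm"))
      rows[[length(rows) + 1L]] <- descriptor_def(
        sprintf("%s_%s_mean", toupper_first(rg), ch), rg, ch, "mean")
  for (ch in channels)
    rows[[length(rows) + 1L]] <- descriptor_def(
      sprintf("Cell_%s_integrated", ch), "cell", ch, "integrated")
  rows[[length(rows) + 1L]] <- descriptor_def(
    sprintf("%s_ratio_perinuclear_PM", rec), "perinuclear", rec,
    "ratio_perinuclear_pm")
  for (rg in c("perinuclear", "pm", "cytoplasm"))
    rows[[length(rows) + 1L]] <- descriptor_def(
      sprintf("%s_endosome_%s_count", toupper_first(rg), rec), rg, rec,
      "object_count")
  rows[[length(rows) + 1L]] <- descriptor_def(
    sprintf("PM_endosome_%s_count", rcy), "pm", rcy, "object_count")
  rows[[length(rows) + 1L]] <- descriptor_def(
    sprintf("PM_endosome_%s_%s_count", rec, rcy), "pm", rec, "coloc_count",
    channel2 = rcy)
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$name)) stop_input("descriptor names are not unique")
  out
}

toupper_first <- function(x) {
  x <- ifelse(x == "pm", "PM", x)
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}

validate_catalogue <- function(catalogue) {
  need <- c("name", "region", "channel", "channel2", "statistic")
  if (!is.data.frame(catalogue) || !all(need %in% colnames(catalogue)))
    stop_input("catalogue must be a data.frame built from descriptor_def()")
  if (anyDuplicated(catalogue$name))
    stop_input("catalogue has duplicated descriptor names")
  invisible(catalogue)
}
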