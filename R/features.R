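region_matrix <- function(seg, region) {
  switch(region, nucleus = seg$nucleus, cell = seg$cell,
         cytoplasm = seg$cytoplasm, perinuclear = seg$perinuclear,
         pm = seg$pm, stop_input("unknown region '", region, "'"))
}

# Per-cell sum and area of one channel over one region label matrix.
region_sums <- function(lab, channel, n_cells) {
  sums <- areas <- numeric(n_cells)
  sel <- lab > 0
  if (any(sel)) {
    s <- rowsum(channel[sel], lab[sel])
    ids <- as.integer(rownames(s))
    sums[ids] <- s[, 1]
    areas[ids] <- tabulate(lab[sel], nbins = n_cells)[ids]
  }
  list(sum = sums, area = areas)
}

#' Compute the per-cell descriptor table of one field
#'
#' Evaluates every descriptor of the catalogue over a segmented image:
#' integrated intensity is the pixel sum of the channel over the region,
#' mean is sum/area, object and colocalization counts come from detected
#' endosome objects (assigned to regions by centroid), and the
#' perinuclear/PM ratio divides the per-cell perinuclear pixel sum by the
#' PM pixel sum. Regions of zero area give missing means; cells with an
#' undefined ratio keep `NA` there and are reported in the
#' `"flagged_cells"` attribute.
#'
#' @param seg a [derive_regions()] result.
#' @param channels named list of intensity matrices (names must cover the
#'   catalogue's channels).
#' @param endosomes named list of [detect_endosomes()] results, one per
#'   channel needing count descriptors.
#' @param catalogue descriptor catalogue data.frame.
#' @param min_overlap_frac overlap fraction for colocalization counts.
#' @return data.frame: one row per cell (`cell_id` column plus one column
#'   per descriptor).
#' @export
compute_cell_features <- function(seg, channels, endosomes = NULL,
                                  catalogue = default_descriptor_catalogue(),
                                  min_overlap_frac = 0.5) {
  if (!inherits(seg, "segmentation_labels"))
    stop_input("seg must come from derive_regions()")
  validate_catalogue(catalogue)
  n_cells <- max(seg$cell)
  out <- data.frame(cell_id = seq_len(n_cells))
  flagged <- integer(0)
  for (i in seq_len(nrow(catalogue))) {
    desc <- catalogue[i, ]
    ch <- channels[[desc$channel]]
    if (is.null(ch) && desc$statistic %in% c("mean", "integrated",
                                             "ratio_perinuclear_pm"))
      stop_input("channel '", desc$channel, "' missing for descriptor '",
                 desc$name, "'")
    val <- switch(
      desc$statistic,
      integrated = region_sums(region_matrix(seg, desc$region), ch, n_cells)$sum,
      mean = {
        rs <- region_sums(region_matrix(seg, desc$region), ch, n_cells)
        ifelse(rs$area > 0, rs$sum / rs$area, NA_real_)
      },
      ratio_perinuclear_pm = {
        ps <- region_sums(seg$perinuclear, ch, n_cells)$sum
        ms <- region_sums(seg$pm, ch, n_cells)$sum
        r <- ifelse(ms > 0, ps / ms, NA_real_)
        flagged <- union(flagged, which(is.na(r)))
        r
      },
      object_count = {
        eo <- endosomes[[desc$channel]]
        if (is.null(eo))
          stop_input("endosome objects for channel '", desc$channel,
                     "' missing for descriptor '", desc$name, "'")
        obj <- eo$objects
        obj <- obj[!is.na(obj$region) & obj$region == desc$region, , drop = FALSE]
        tabulate(obj$cell, nbins = n_cells)
      },
      coloc_count = {
        ea <- endosomes[[desc$channel]]; eb <- endosomes[[desc$channel2]]
        if (is.null(ea) || is.null(eb))
          stop_input("endosome objects missing for coloc descriptor '",
                     desc$name, "'")
        cc <- coloc_count(ea, eb, min_overlap_frac, region = desc$region)
        v <- integer(n_cells)
        v[as.integer(names(cc))] <- cc
        v
      })
    out[[desc$name]] <- val
  }
  attr(out, "flagged_cells") <- flagged
  out
}

#' Segment one field and measure its per-cell descriptor table
#'
#' Convenience wrapper chaining the image pipeline on one multi-channel
#' field: nucleus segmentation on the DNA channel, cell propagation on the
#' receptor channel, ring-region derivation, endosome detection on the
#' requested channels and descriptor extraction.
#'
#' @param image a [render_cell_image()] result or a named list of channel
#'   matrices including `DNA` and the catalogue's channels.
#' @param catalogue descriptor catalogue restricted to available channels.
#' @param expand_px,shrink_px ring radii, see [derive_regions()].
#' @param tophat_radius,min_intensity endosome detection parameters; for
#'   rendered synthetic fields a robust absolute threshold is half the
#'   renderer's spot amplitude.
#' @param endosome_channels channels on which to detect endosome objects.
#' @param min_nucleus_area nucleus area filter in px.
#' @param lambda propagation regularization.
#' @return The [compute_cell_features()] table plus a `"segmentation"`
#'   attribute holding the [derive_regions()] labels.
#' @export
measure_field <- function(image,
                          catalogue = default_descriptor_catalogue(
                            channels = c("EGFR", "pERK", "Tfn")),
                          expand_px = 7, shrink_px = 5, tophat_radius = 5,
                          min_intensity = 80, endosome_channels = c("EGFR", "Tfn"),
                          min_nucleus_area = 30, lambda = 0.05) {
  channels <- if (inherits(image, "synthetic_cell_image")) image$channels
              else image
  if (!"DNA" %in% names(channels)) stop_input("image lacks a DNA channel")
  nuc <- segment_nuclei(channels$DNA, min_area = min_nucleus_area)
  cells <- propagate_cells(nuc, channels$EGFR, lambda = lambda)
  seg <- derive_regions(nuc, cells, expand_px = expand_px,
                        shrink_px = shrink_px)
  eo <- lapply(channels[intersect(endosome_channels, names(channels))],
               detect_endosomes, seg = seg, tophat_radius = tophat_radius,
               min_intensity = min_intensity)
  out <- compute_cell_features(seg, channels, endosomes = eo,
                               catalogue = catalogue)
  attr(out, "segmentation") <- seg
  out
}

#' Count colocalized objects per cell
#'
#' Counts the objects of set A whose pixel overlap with the union of set-B
#' objects covers at least `min_overlap_frac` of the A-object's area. Both
#' sets must come from the same image.
#'
#' @param objects_a,objects_b [detect_endosomes()] results.
#' @param min_overlap_frac required overlap fraction in \[0, 1\].
#' @param region optionally restrict the counted A objects to one region.
#' @return Named integer vector of counts, one entry per cell that owns at
#'   least one (qualifying) A object; empty sets give an empty vector.
#' @export
coloc_count <- function(objects_a, objects_b, min_overlap_frac = 0.5,
                        region = NULL) {
  if (!inherits(objects_a, "endosome_objects") ||
      !inherits(objects_b, "endosome_objects"))
    stop_input("both object sets must come from detect_endosomes()")
  if (!identical(objects_a$dim, objects_b$dim))
    stop_input("object sets come from images of different shape")
  obj <- objects_a$objects
  px <- objects_a$pixels
  if (!is.null(region)) {
    keep <- !is.na(obj$region) & obj$region == region
    obj <- obj[keep, , drop = FALSE]
    px <- px[keep]
  }
  if (!nrow(obj)) return(stats::setNames(integer(0), character(0)))
  union_b <- unique(unlist(objects_b$pixels))
  hit <- vapply(px, function(p) mean(p %in% union_b) >= min_overlap_frac,
                logical(1))
  counts <- table(factor(obj$cell[hit], levels = sort(unique(obj$cell))))
  stats::setNames(as.integer(counts), names(counts))
}

#' Perinuclear-vs-PM regression slope per batch
#'
#' Ordinary least-squares slope (with intercept) of per-cell perinuclear
#' mean intensity on PM mean intensity for one channel — the
#' trafficking read-out whose time course peaks when the receptor reaches
#' the perinuclear compartment. Computed per batch when a `batch_id`
#' column is present.
#'
#' @param features per-cell feature table containing
#'   `Perinuclear_<channel>_mean` and `PM_<channel>_mean` columns.
#' @param channel channel name (default `"EGFR"`).
#' @return Named numeric vector of slopes (one per batch, or a single
#'   unnamed value without batch structure). Batches with fewer than 3
#'   complete cells or zero PM-intensity variance give `NA`.
#' @export
perinuclear_pm_slope <- function(features, channel = "EGFR") {
  ycol <- sprintf("Perinuclear_%s_mean", channel)
  xcol <- sprintf("PM_%s_mean", channel)
  if (!all(c(xcol, ycol) %in% colnames(features)))
    stop_input("features lack ", ycol, " / ", xcol, " columns")
  slope1 <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) return(NA_real_)
    dx <- x - mean(x)
    if (all(dx == 0)) return(NA_real_)
    sum(dx * (y - mean(y))) / sum(dx^2)
  }
  if ("batch_id" %in% colnames(features)) {
    vapply(split(features, features$batch_id),
           function(d) slope1(d[[xcol]], d[[ycol]]), numeric(1))
  } else {
    slope1(features[[xcol]], features[[ycol]])
  }
}
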