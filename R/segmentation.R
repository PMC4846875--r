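as_mat <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.array(x) && length(dim(x)) > 2) x <- x[, , 1]
  x
}

#' Segment nuclei from the DNA channel
#'
#' Gaussian smoothing, Otsu threshold, hole filling and connected-component
#' labeling, followed by an area filter and removal of border-touching
#' objects. A constant image yields zero nuclei.
#'
#' @param dna_channel numeric matrix of non-negative finite intensities.
#' @param min_area,max_area area filter in px^2.
#' @param smooth_sigma Gaussian smoothing sigma in px (0 = none).
#' @param remove_border drop nuclei touching the image border.
#' @return Integer label matrix (0 = background, k = nucleus k), labels
#'   consecutive from 1.
#' @export
segment_nuclei <- function(dna_channel, min_area = 40, max_area = Inf,
                           smooth_sigma = 1, remove_border = TRUE) {
  check_image(dna_channel, "dna_channel")
  rng <- range(dna_channel)
  if (diff(rng) == 0) return(matrix(0L, nrow(dna_channel), ncol(dna_channel)))
  img <- (dna_channel - rng[1]) / diff(rng)
  if (smooth_sigma > 0) img <- as_mat(EBImage::gblur(img, sigma = smooth_sigma))
  th <- EBImage::otsu(EBImage::Image(img), range = range(img))
  bw <- img > th
  bw <- as_mat(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  lab <- as_mat(EBImage::bwlabel(bw))
  filter_labels(lab, min_area, max_area, remove_border)
}

filter_labels <- function(lab, min_area, max_area, remove_border) {
  lab <- as_mat(lab)
  if (max(lab) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  areas <- tabulate(lab, nbins = max(lab))
  keep <- which(areas >= min_area & areas <= max_area)
  if (remove_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- setdiff(keep, border)
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  new_id <- integer(max(lab))
  new_id[sort(keep)] <- seq_along(keep)
  sel <- lab > 0
  out[sel] <- new_id[lab[sel]]
  out
}

.shift_mat <- function(m, dx, dy, fill) {
  n <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  xs <- max(1, 1 + dx):min(nr, nr + dx)
  ys <- max(1, 1 + dy):min(nc, nc + dy)
  n[xs, ys] <- m[xs - dx, ys - dy]
  n
}

#' Grow cell outlines from nucleus seeds by cost propagation
#'
#' Seeded region growing over the foreground of a guide (cell-marker)
#' channel: each foreground pixel is assigned to the seed reachable with
#' minimal accumulated step cost, where one step from pixel p to an
#' 8-neighbour q costs `(1 - lambda) * |I(p) - I(q)| + lambda * d(p, q)`
#' with `d` the Euclidean step length. Small `lambda` makes boundaries
#' follow intensity ridges of the guide channel; large `lambda` approaches
#' a nearest-seed (distance) partition. Seed pixels keep their label.
#' Cost ties between competing labels are resolved by a fixed neighbour
#' scan order, so results are deterministic.
#'
#' @param nucleus_labels integer label matrix of seeds (see
#'   [segment_nuclei()]).
#' @param guide_channel numeric intensity matrix, same shape.
#' @param lambda regularization in \[0, 1\] blending intensity-gradient
#'   cost with Euclidean step cost (default 0.05).
#' @param mask logical foreground matrix; default Otsu on the guide
#'   channel with hole filling, united with the seeds. Cells touching the
#'   image border are kept.
#' @param max_sweeps relaxation sweep cap.
#' @return Integer cell label matrix with `cell(k)` a superset of
#'   `nucleus(k)`; all foreground pixels reachable from a seed are
#'   assigned. No seeds gives an all-zero labeling.
#' @export
propagate_cells <- function(nucleus_labels, guide_channel, lambda = 0.05,
                            mask = NULL, max_sweeps = 2000) {
  check_image(guide_channel, "guide_channel")
  nucleus_labels <- as_mat(nucleus_labels)
  if (!all(dim(nucleus_labels) == dim(guide_channel)))
    stop_input("nucleus_labels and guide_channel differ in shape")
  if (lambda < 0 || lambda > 1) stop_input("lambda must be in [0, 1]")
  if (max(nucleus_labels) == 0)
    return(matrix(0L, nrow(guide_channel), ncol(guide_channel)))
  if (is.null(mask)) {
    rng <- range(guide_channel)
    if (diff(rng) == 0) {
      mask <- matrix(TRUE, nrow(guide_channel), ncol(guide_channel))
    } else {
      img <- (guide_channel - rng[1]) / diff(rng)
      th <- EBImage::otsu(EBImage::Image(img), range = range(img))
      mask <- as_mat(EBImage::fillHull(EBImage::Image((img > th) * 1))) > 0
    }
  }
  mask <- mask | nucleus_labels > 0

  cost <- matrix(Inf, nrow(guide_channel), ncol(guide_channel))
  lab <- nucleus_labels
  cost[nucleus_labels > 0] <- 0
  offsets <- cbind(dx = c(1, -1, 0, 0, 1, 1, -1, -1),
                   dy = c(0, 0, 1, -1, 1, -1, 1, -1))
  step_len <- sqrt(offsets[, 1]^2 + offsets[, 2]^2)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (o in seq_len(nrow(offsets))) {
      nb_cost <- .shift_mat(cost, offsets[o, 1], offsets[o, 2], Inf)
      nb_lab <- .shift_mat(lab, offsets[o, 1], offsets[o, 2], 0L)
      nb_int <- .shift_mat(guide_channel, offsets[o, 1], offsets[o, 2], Inf)
      cand <- nb_cost + (1 - lambda) * abs(guide_channel - nb_int) +
        lambda * step_len[o]
      upd <- mask & nb_lab > 0 & cand < cost - 1e-12
      if (any(upd)) {
        cost[upd] <- cand[upd]
        lab[upd] <- nb_lab[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (changed) warning("propagation did not converge within max_sweeps")
  lab
}

#' Per-cell region labels derived from nucleus and cell masks
#'
#' Builds the full region scheme used for descriptor extraction:
#' `cytoplasm(k) = cell(k) \ nucleus(k)` exactly; `perinuclear(k)` is the
#' nucleus dilated by a Euclidean disc of radius `expand_px`, minus the
#' nucleus, clipped to the cell; `pm(k)` is the cell minus its erosion by a
#' disc of radius `shrink_px` (the whole cell when the erosion empties).
#' Distances are computed within the image: pixels beyond the border are
#' neither foreground nor background.
#'
#' @param nucleus_labels,cell_labels consistent integer label matrices
#'   (every nucleus pixel of cell k is a cell pixel of cell k).
#' @param expand_px,shrink_px disc radii in px (>= 0). Defaults follow the
#'   7-px nucleus expansion / 5-px cell shrinkage convention.
#' @return Object of class `segmentation_labels`: list of integer label
#'   matrices `nucleus`, `cell`, `cytoplasm`, `perinuclear`, `pm`.
#' @export
derive_regions <- function(nucleus_labels, cell_labels, expand_px = 7,
                           shrink_px = 5) {
  nucleus_labels <- as_mat(nucleus_labels); cell_labels <- as_mat(cell_labels)
  if (expand_px < 0 || shrink_px < 0) stop_input("radii must be >= 0")
  if (!all(dim(nucleus_labels) == dim(cell_labels)))
    stop_input("label images differ in shape")
  bad <- nucleus_labels > 0 & nucleus_labels != cell_labels
  if (any(bad))
    stop_input("inconsistent labels: nucleus pixels outside their cell")
  nr <- nrow(cell_labels); nc <- ncol(cell_labels)
  cyto <- peri <- pm <- matrix(0L, nr, nc)
  sel <- cell_labels > 0 & nucleus_labels == 0
  cyto[sel] <- cell_labels[sel]
  for (k in seq_len(max(cell_labels))) {
    idx <- which(cell_labels == k, arr.ind = TRUE)
    if (!nrow(idx)) next
    pad <- ceiling(expand_px) + 1
    x0 <- max(1, min(idx[, 1]) - pad); x1 <- min(nr, max(idx[, 1]) + pad)
    y0 <- max(1, min(idx[, 2]) - pad); y1 <- min(nc, max(idx[, 2]) + pad)
    cm <- cell_labels[x0:x1, y0:y1] == k
    nm <- nucleus_labels[x0:x1, y0:y1] == k
    if (any(nm) && expand_px > 0) {
      d_nuc <- as_mat(EBImage::distmap(EBImage::Image(1 - nm)))
      ring <- d_nuc <= expand_px & !nm & cm
      peri[x0:x1, y0:y1][ring] <- k
    }
    if (shrink_px > 0) {
      d_cell <- as_mat(EBImage::distmap(EBImage::Image(cm * 1)))
      band <- cm & d_cell <= shrink_px
    } else {
      band <- cm & FALSE
    }
    pm[x0:x1, y0:y1][band] <- k
  }
  structure(list(nucleus = nucleus_labels, cell = cell_labels,
                 cytoplasm = cyto, perinuclear = peri, pm = pm,
                 expand_px = expand_px, shrink_px = shrink_px),
            class = "segmentation_labels")
}

#' @export
print.segmentation_labels <- function(x, ...) {
  cat("<segmentation_labels>", max(x$cell), "cells,",
      nrow(x$cell), "x", ncol(x$cell), "px; expand", x$expand_px,
      "px / shrink", x$shrink_px, "px\n")
  invisible(x)
}

# Grayscale erosion/dilation with a Euclidean disc: min/max filter over
# all integer offsets within radius r. Pixels beyond the image border are
# ignored (treated as +Inf for erosion, -Inf for dilation).
disc_offsets <- function(r) {
  g <- expand.grid(dx = -floor(r):floor(r), dy = -floor(r):floor(r))
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

gray_filter <- function(m, r, op = c("erode", "dilate")) {
  op <- match.arg(op)
  fill <- if (op == "erode") Inf else -Inf
  comb <- if (op == "erode") pmin else pmax
  off <- disc_offsets(r)
  out <- matrix(fill, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- comb(out, .shift_mat(m, off$dx[i], off$dy[i], fill))
  out
}

#' White top-hat transform with a disc structuring element
#'
#' Image minus its grayscale opening (erosion then dilation) with a
#' Euclidean disc of the given radius; enhances bright structures smaller
#' than the disc.
#'
#' @param channel numeric intensity matrix.
#' @param radius disc radius in px.
#' @return Non-negative matrix of the same shape.
#' @export
white_tophat <- function(channel, radius) {
  check_image(channel, "channel")
  opened <- gray_filter(gray_filter(channel, radius, "erode"), radius, "dilate")
  pmax(channel - opened, 0)
}

#' Detect endosome-like spots by white top-hat enhancement
#'
#' White top-hat (image minus its grayscale opening with a disc) enhances
#' bright objects smaller than the structuring element; enhanced pixels
#' above a threshold are labeled into connected components and each object
#' is assigned to the cell and region containing its centroid
#' (priority PM > perinuclear > cytoplasm > nucleus where rings overlap).
#'
#' @param channel numeric intensity matrix.
#' @param seg optional [derive_regions()] result; without it objects are
#'   returned unassigned (cell 0). With it, objects whose centroid lies
#'   outside every cell are dropped.
#' @param tophat_radius disc radius in px (>= 1).
#' @param min_intensity absolute threshold on the top-hat image; default
#'   `NULL` uses mean + `k_sd` * SD of the top-hat background, defined as
#'   the positive top-hat response below its 90th percentile (flat regions
#'   respond exactly 0 and carry no information about the response floor),
#'   and floored at `1e-6 * max(tophat)` so numerical residues of
#'   noise-free images never count as objects.
#' @param k_sd multiplier for the adaptive threshold.
#' @param min_area smallest accepted object area in px (sub-resolution
#'   fragments are discarded; default 4, i.e. smaller than any
#'   diffraction-limited spot).
#' @return Object of class `endosome_objects`: `objects` data.frame
#'   (object, cell, region, area, x, y, integrated) plus per-object pixel
#'   index sets. Zero objects is a valid result.
#' @export
detect_endosomes <- function(channel, seg = NULL, tophat_radius = 5,
                             min_intensity = NULL, k_sd = 3, min_area = 4) {
  check_image(channel, "channel")
  if (tophat_radius < 1) stop_input("tophat_radius must be >= 1")
  th <- white_tophat(channel, tophat_radius)
  if (is.null(min_intensity)) {
    pos <- th[th > 0]
    bg <- if (length(pos)) pos[pos <= stats::quantile(pos, 0.9)] else pos
    min_intensity <- if (length(bg) > 1) mean(bg) + k_sd * stats::sd(bg) else 0
    if (!is.finite(min_intensity)) min_intensity <- 0
    min_intensity <- max(min_intensity, 1e-6 * max(th, 0))
  }
  lab <- as_mat(EBImage::bwlabel(th > min_intensity))
  lab <- filter_labels(lab, min_area, Inf, remove_border = FALSE)
  n_obj <- max(lab)
  objects <- data.frame(object = integer(0), cell = integer(0),
                        region = character(0), area = integer(0),
                        x = numeric(0), y = numeric(0),
                        integrated = numeric(0), stringsAsFactors = FALSE)
  pixels <- list()
  if (n_obj > 0) {
    idx <- which(lab > 0)
    ids <- lab[idx]
    xs <- (idx - 1) %% nrow(lab) + 1
    ys <- (idx - 1) %/% nrow(lab) + 1
    ord <- order(ids)
    pixels <- split(idx[ord], ids[ord])
    cx <- tapply(xs, ids, mean); cy <- tapply(ys, ids, mean)
    area <- tabulate(ids, nbins = n_obj)
    integ <- tapply(channel[idx], ids, sum)
    cells <- regions <- rep(NA, n_obj)
    for (o in seq_len(n_obj)) {
      px <- round(cx[o]); py <- round(cy[o])
      if (!is.null(seg)) {
        cells[o] <- seg$cell[px, py]
        regions[o] <- if (cells[o] == 0) NA_character_ else
          if (seg$pm[px, py] == cells[o]) "pm" else
          if (seg$perinuclear[px, py] == cells[o]) "perinuclear" else
          if (seg$cytoplasm[px, py] == cells[o]) "cytoplasm" else "nucleus"
      } else cells[o] <- 0L
    }
    objects <- data.frame(object = seq_len(n_obj), cell = as.integer(cells),
                          region = as.character(regions),
                          area = area, x = as.numeric(cx), y = as.numeric(cy),
                          integrated = as.numeric(integ),
                          stringsAsFactors = FALSE)
    if (!is.null(seg)) {
      keep <- objects$cell > 0
      pixels <- pixels[keep]
      objects <- objects[keep, , drop = FALSE]
      objects$object <- seq_len(nrow(objects))
      rownames(objects) <- NULL
    }
  }
  structure(list(objects = objects, pixels = unname(pixels),
                 dim = dim(channel), threshold = min_intensity),
            class = "endosome_objects")
}

#' @export
print.endosome_objects <- function(x, ...) {
  cat("<endosome_objects>", nrow(x$objects), "objects in",
      length(unique(x$objects$cell[x$objects$cell > 0])), "cells\n")
  invisible(x)
}
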