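#' Render a synthetic multi-channel cell image with ground truth
#'
#' Draws non-overlapping cells as mildly deformed ellipses with concentric
#' elliptical nuclei on a flat background, then composes four fluorescence
#' channels: `DNA` (nuclear stain), `EGFR` (cell body with perinuclear and
#' plasma-membrane weighting plus Gaussian endosome spots), `Tfn`
#' (PM-retained recycling marker, optionally sharing colocalized spots)
#' and `pERK` (cytoplasmic/nuclear signalling marker). Structural signal
#' (bands, body) is Gaussian-blurred like a diffraction-limited image, so
#' endosome spots are the only spot-scale structures a top-hat filter
#' enhances. The returned ground truth exactly matches the rendered
#' content and is the reference for segmentation and feature tests.
#'
#' @param n_cells number of cells to place (0 gives blank channels).
#' @param spot_counts integer vector of endosome spots per cell (recycled
#'   if shorter than `n_cells`; default 4 each).
#' @param width,height frame size in pixels.
#' @param cell_radius range of the cell semi-major axis, pixels.
#' @param nucleus_scale nucleus semi-axes as a fraction of the cell's.
#' @param spot_sigma Gaussian sigma of endosome spots, pixels.
#' @param spot_intensity peak amplitude added per spot.
#' @param spot_min_dist minimum spacing between spot centres in one cell.
#' @param cell_intensity receptor-channel intensity of the cell body.
#' @param nucleus_dna DNA-channel intensity inside nuclei.
#' @param perinuclear_weight,pm_weight multiplicative boost of the receptor
#'   channel in the perinuclear band / PM band.
#' @param tfn_pm_intensity recycling-marker intensity in the PM band.
#' @param coloc_frac probability that an endosome spot also appears in the
#'   `Tfn` channel (colocalized vesicle).
#' @param structure_sigma blur sigma (px) applied to the structural signal
#'   of each channel before spots are added (0 = sharp bands).
#' @param background additive background level (all channels).
#' @param noise_sd Gaussian read-noise SD (0 = noise free).
#' @param seed optional integer seed (uses and restores the RNG state).
#' @param max_tries placement retries per cell before failing.
#' @return Object of class `synthetic_cell_image`: list with `channels`
#'   (named list of numeric matrices) and `truth` (`nucleus` and `cell`
#'   label matrices, `cells` and `spots` data.frames).
#' @export
#' @examples
#' img <- render_cell_image(3, spot_counts = c(0, 2, 5), seed = 1)
#' img$truth$cells$n_spots
render_cell_image <- function(n_cells, spot_counts = NULL,
                              width = 256, height = 256,
                              cell_radius = c(14, 20), nucleus_scale = 0.45,
                              spot_sigma = 2, spot_intensity = 160,
                              spot_min_dist = 12,
                              cell_intensity = 90, nucleus_dna = 400,
                              perinuclear_weight = 1.5, pm_weight = 1.2,
                              tfn_pm_intensity = 120, coloc_frac = 0.5,
                              structure_sigma = 3,
                              background = 10, noise_sd = 0,
                              seed = NULL, max_tries = 400) {
  if (n_cells < 0) stop_input("n_cells must be >= 0")
  if (!is.null(seed))
    return(withr::with_seed(seed, render_cell_image(
      n_cells, spot_counts, width, height, cell_radius, nucleus_scale,
      spot_sigma, spot_intensity, spot_min_dist, cell_intensity, nucleus_dna,
      perinuclear_weight, pm_weight, tfn_pm_intensity, coloc_frac,
      structure_sigma, background, noise_sd,
      seed = NULL, max_tries = max_tries)))

  if (is.null(spot_counts)) spot_counts <- rep(4L, max(n_cells, 1L))
  spot_counts <- rep_len(as.integer(spot_counts), max(n_cells, 1L))

  blank <- matrix(0, width, height)
  nuc_lab <- cell_lab <- matrix(0L, width, height)
  dna <- egfr <- tfn <- perk <- blank
  cells <- data.frame(cell = integer(0), cx = numeric(0), cy = numeric(0),
                      area = numeric(0), nucleus_area = numeric(0),
                      n_spots = integer(0))
  spots <- data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
                      in_tfn = logical(0))

  margin <- max(cell_radius) + 3
  if (margin * 2 >= min(width, height) && n_cells > 0)
    stop_input("frame too small for the requested cell size")
  xs <- matrix(rep(seq_len(width), height), width, height)
  ys <- matrix(rep(seq_len(height), each = width), width, height)

  k <- 0L
  while (k < n_cells) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cx <- stats::runif(1, margin, width - margin)
      cy <- stats::runif(1, margin, height - margin)
      a <- stats::runif(1, cell_radius[1], cell_radius[2])
      b <- a * stats::runif(1, 0.7, 1)
      th <- stats::runif(1, 0, pi)
      ph <- stats::runif(1, 0, 2 * pi)
      u <- .ellipse_u(xs, ys, cx, cy, a, b, th)
      phi <- atan2(ys - cy, xs - cx)
      edge <- 1 + 0.08 * sin(3 * phi + ph)   # deformed ellipse boundary
      cm <- u <= edge
      if (!any(cm & cell_lab > 0)) {
        un <- .ellipse_u(xs, ys, cx, cy, a * nucleus_scale, b * nucleus_scale, th)
        nm <- un <= 1
        k <- k + 1L
        cell_lab[cm] <- k
        nuc_lab[nm] <- k
        # receptor channel: body + perinuclear band (just outside the
        # nucleus) + PM band (outer 15% of the cell radius)
        peri <- cm & !nm & un <= 1.8
        pm <- cm & u > 0.85 * edge
        egfr[cm] <- egfr[cm] + cell_intensity
        egfr[peri] <- egfr[peri] + cell_intensity * perinuclear_weight
        egfr[pm] <- egfr[pm] + cell_intensity * pm_weight
        dna[nm] <- dna[nm] + nucleus_dna
        tfn[cm] <- tfn[cm] + 40
        tfn[pm] <- tfn[pm] + tfn_pm_intensity
        perk[cm] <- perk[cm] + 60
        perk[nm] <- perk[nm] + 20
        # endosome spots inside this cell, pairwise spacing bounded below
        nsp <- spot_counts[k]
        if (nsp > 0) {
          idx <- which(cm & un > 1)  # spots in the cytoplasmic area
          if (!length(idx)) idx <- which(cm)
          pts <- matrix(numeric(0), 0, 2)
          tries <- 0L
          while (nrow(pts) < nsp && tries < 50L * nsp) {
            tries <- tries + 1L
            i <- idx[sample.int(length(idx), 1)]
            p <- c(xs[i], ys[i])
            if (!nrow(pts) ||
                min(sqrt(colSums((t(pts) - p)^2))) >= spot_min_dist)
              pts <- rbind(pts, p)
          }
          while (nrow(pts) < nsp) {   # relax spacing if the cell is crowded
            i <- idx[sample.int(length(idx), 1)]
            pts <- rbind(pts, c(xs[i], ys[i]))
          }
          spots <- rbind(spots, data.frame(
            cell = k, x = pts[, 1], y = pts[, 2],
            in_tfn = stats::runif(nrow(pts)) < coloc_frac))
        }
        cells <- rbind(cells, data.frame(
          cell = k, cx = cx, cy = cy, area = sum(cm), nucleus_area = sum(nm),
          n_spots = nsp))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_input("could not place ", n_cells, " non-overlapping cells in a ",
                 width, "x", height, " frame after ", max_tries, " tries")
  }

  smooth <- function(ch) {
    if (structure_sigma > 0 && any(ch > 0))
      ch <- as_mat(EBImage::gblur(ch, sigma = structure_sigma))
    ch
  }
  egfr <- smooth(egfr); tfn <- smooth(tfn); perk <- smooth(perk)
  dna <- if (structure_sigma > 0 && any(dna > 0))
    as_mat(EBImage::gblur(dna, sigma = min(structure_sigma, 1.5))) else dna
  for (s in seq_len(nrow(spots))) {
    g <- spot_intensity *
      exp(-((xs - spots$x[s])^2 + (ys - spots$y[s])^2) / (2 * spot_sigma^2))
    egfr <- egfr + g
    if (spots$in_tfn[s]) tfn <- tfn + g
  }
  finish <- function(ch) {
    ch <- ch + background
    if (noise_sd > 0) ch <- ch + stats::rnorm(length(ch), 0, noise_sd)
    pmax(matrix(ch, width, height), 0)
  }
  structure(list(
    channels = list(DNA = finish(dna), EGFR = finish(egfr),
                    Tfn = finish(tfn), pERK = finish(perk)),
    truth = list(nucleus = nuc_lab, cell = cell_lab, cells = cells,
                 spots = spots),
    dim = c(width, height)), class = "synthetic_cell_image")
}

.ellipse_u <- function(xs, ys, cx, cy, a, b, theta) {
  dx <- xs - cx; dy <- ys - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  sqrt((xr / a)^2 + (yr / b)^2)
}

#' @export
print.synthetic_cell_image <- function(x, ...) {
  cat("<synthetic_cell_image>", x$dim[1], "x", x$dim[2], "px,",
      nrow(x$truth$cells), "cells,", nrow(x$truth$spots), "spots\n")
  invisible(x)
}
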