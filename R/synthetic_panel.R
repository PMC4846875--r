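# Control-condition kinetics of the synthetic screen.
#
# Baselines emulate an EGF-stimulated receptor trafficking time course:
# after stimulation the receptor channel moves from the plasma membrane to
# the perinuclear region (ratio maximal at 30 min) and is then degraded;
# ERK phosphorylation peaks early (5 min), Akt phosphorylation slightly
# later; the recycling (transferrin-like) marker stays largely at the PM.
# Values are interpolated piecewise-linearly between the anchor time
# points for arbitrary time lists.
.anchor_times <- c(0, 5, 30, 60, 180)

.time_profile <- function(anchors, t) {
  stats::approx(.anchor_times, anchors, xout = t, rule = 2)$y
}

# Per-(descriptor, time) control distribution. Intensities are log-normal
# (positive, right-skewed) with a common cell-to-cell CV; counts are
# Poisson. Unknown user-added descriptors get flat generic baselines.
control_baseline <- function(desc, time_min, cv = 0.35) {
  t <- time_min
  is_count <- desc$statistic %in% c("object_count", "coloc_count")
  if (is_count) {
    lam <- switch(
      desc$name,
      Perinuclear_endosome_EGFR_count = 6 * .time_profile(c(.2, .8, 1, .8, .5), t),
      PM_endosome_EGFR_count          = 5 * .time_profile(c(.4, 1, .7, .6, .5), t),
      Cytoplasm_endosome_EGFR_count   = 8 * .time_profile(c(.3, .9, 1, .8, .6), t),
      PM_endosome_Tfn_count           = 6 * .time_profile(c(1, 1, .9, .9, .85), t),
      PM_endosome_EGFR_Tfn_count      = 3 * .time_profile(c(.3, .9, 1, .8, .6), t),
      5)
    return(list(type = "poisson", lambda = lam))
  }
  base <- c(nucleus = 50, cytoplasm = 110, perinuclear = 110, pm = 120,
            cell = 50000)[desc$region]
  mult <- switch(
    desc$channel,
    EGFR = {
      p <- .time_profile(c(.6, 1.4, 2.2, 1.6, .9), t)   # perinuclear accumulation
      q <- .time_profile(c(1.6, 1.2, .8, .9, 1), t)     # PM depletion
      g <- .time_profile(c(1, 1, .95, .8, .55), t)      # degradation
      switch(desc$region, perinuclear = p, pm = q, cell = g,
             cytoplasm = g, nucleus = 0.6)
    },
    pERK = .time_profile(c(.5, 2, 1.5, 1, .7), t),
    pAkt = .time_profile(c(.5, 1.8, 1.8, 1.2, .8), t),
    Tfn = switch(desc$region, pm = .time_profile(c(1, 1.1, 1, .95, .9), t), 0.8),
    1)
  m <- base * mult
  if (desc$statistic == "ratio_perinuclear_pm" && desc$channel == "EGFR") {
    p <- .time_profile(c(.6, 1.4, 2.2, 1.6, .9), t)
    q <- .time_profile(c(1.6, 1.2, .8, .9, 1), t)
    m <- p / q
  } else if (desc$statistic == "ratio_perinuclear_pm") {
    m <- 1
  }
  list(type = "lognormal", mean = m, sd = m * cv)
}

# Compound effects switch on after stimulation: inactive at the 0-min
# (pre-EGF) point, most of the effect by 5 min, full effect from 30 min.
effect_activation <- function(time_min) {
  .time_profile(c(0, 0.7, 1, 1, 1), time_min)
}

#' Configure a synthetic compound screen
#'
#' Describes a plate of compounds x time points x replicates with known
#' mechanism ground truth. The generator draws per-cell descriptor values
#' (feature-table mode, the default) or renders multi-channel cell images
#' (image mode) from condition-dependent control baselines plus archetype
#' effect vectors.
#'
#' @param n_compounds number of treated compounds (default 14).
#' @param include_control add a DMSO control mapped to the null archetype.
#' @param time_points_min strictly increasing time points in minutes,
#'   starting at 0 (default `c(0, 5, 30, 60, 180)`).
#' @param n_cells_per_condition cells sampled per (compound, time,
#'   replicate) batch; >= 50 (default 600, within the 500-1000 cells a
#'   screen typically measures per condition).
#' @param n_replicates independent replicate experiments (default 2).
#' @param mechanism_groups list of [mechanism_archetype()]; must contain a
#'   `"null"` archetype. Compounds are assigned to groups in contiguous,
#'   near-equal blocks.
#' @param image_mode if `TRUE`, `generate_panel()` renders images instead
#'   of drawing feature tables.
#' @param rng_seed integer run seed; all randomness is a pure function of
#'   the config and this seed.
#' @param catalogue descriptor catalogue (see
#'   [default_descriptor_catalogue()]).
#' @param cv cell-to-cell coefficient of variation of intensity
#'   descriptors in the control condition.
#' @param potency_levels deterministic per-compound potency multipliers,
#'   cycled over compounds within a group, giving within-group spread.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_compounds = 14,
                         include_control = TRUE,
                         time_points_min = c(0, 5, 30, 60, 180),
                         n_cells_per_condition = 600,
                         n_replicates = 2,
                         mechanism_groups = default_archetypes(),
                         image_mode = FALSE,
                         rng_seed = 1,
                         catalogue = default_descriptor_catalogue(),
                         cv = 0.35,
                         potency_levels = c(0.9, 1.0, 1.1)) {
  if (n_compounds < 1) stop_input("n_compounds must be >= 1")
  if (length(time_points_min) == 0)
    stop_input("time_points_min must not be empty")
  if (any(diff(time_points_min) <= 0))
    stop_input("time_points_min must be strictly increasing")
  if (time_points_min[1] != 0)
    stop_input("time_points_min must include 0 as its first point")
  if (n_cells_per_condition < 50)
    stop_input("n_cells_per_condition must be >= 50")
  if (n_replicates < 1) stop_input("n_replicates must be >= 1")
  validate_catalogue(catalogue)
  if (!length(mechanism_groups) ||
      !all(vapply(mechanism_groups, inherits, TRUE, "mechanism_archetype")))
    stop_input("mechanism_groups must be a list of mechanism_archetype objects")
  gnames <- vapply(mechanism_groups, `[[`, "", "name")
  if (anyDuplicated(gnames)) stop_input("mechanism group names must be unique")
  if (include_control && !"null" %in% gnames)
    stop_input("mechanism_groups must contain a 'null' archetype for the control")
  for (g in mechanism_groups) {
    bad <- setdiff(c(names(g$shifts), names(g$scales)), catalogue$name)
    if (length(bad))
      stop_input("effect_vector of archetype '", g$name,
                 "' names unknown descriptors: ", paste(bad, collapse = ", "))
  }
  # contiguous near-equal blocks of compounds per archetype
  cuts <- round(seq(0, n_compounds, length.out = length(mechanism_groups) + 1))
  group_of <- rep(gnames, times = diff(cuts))
  compounds <- sprintf("cmpd%02d", seq_len(n_compounds))
  potency <- rep_len(potency_levels, n_compounds)
  structure(list(
    n_compounds = n_compounds, include_control = include_control,
    time_points_min = time_points_min,
    n_cells_per_condition = n_cells_per_condition,
    n_replicates = n_replicates, mechanism_groups = mechanism_groups,
    image_mode = image_mode, rng_seed = rng_seed, catalogue = catalogue,
    cv = cv, compounds = compounds, group_of = group_of, potency = potency
  ), class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("<panel_config>", x$n_compounds, "compounds",
      if (x$include_control) "+ control", "|",
      length(x$time_points_min), "time points |", x$n_replicates,
      "replicates |", x$n_cells_per_condition, "cells/condition |",
      nrow(x$catalogue), "descriptors |",
      if (x$image_mode) "image mode" else "feature-table mode", "\n")
  invisible(x)
}

# Draw one batch of per-cell descriptor values for a given archetype.
sample_batch_features <- function(config, archetype, potency, time_min, n_cells) {
  act <- effect_activation(time_min) * potency
  cols <- vector("list", nrow(config$catalogue))
  names(cols) <- config$catalogue$name
  for (i in seq_len(nrow(config$catalogue))) {
    desc <- config$catalogue[i, ]
    bl <- control_baseline(desc, time_min, cv = config$cv)
    shift <- unname(archetype$shifts[desc$name])
    if (is.na(shift %||% NA)) shift <- 0
    scale <- unname(archetype$scales[desc$name])
    if (is.na(scale %||% NA)) scale <- 1
    shift_eff <- shift * act
    scale_eff <- 1 + (scale - 1) * act
    if (bl$type == "poisson") {
      lam <- max(0, (bl$lambda + shift_eff * sqrt(bl$lambda)) * scale_eff)
      cols[[i]] <- stats::rpois(n_cells, lam)
    } else {
      sdlog <- sqrt(log(1 + (bl$sd / bl$mean)^2))
      meanlog <- log(bl$mean) - sdlog^2 / 2
      x <- stats::rlnorm(n_cells, meanlog, sdlog)
      x <- bl$mean + (x - bl$mean) * scale_eff + shift_eff * bl$sd
      cols[[i]] <- pmax(x, 0)
    }
  }
  as.data.frame(cols, check.names = FALSE)
}

#' Generate a synthetic compound panel
#'
#' Produces one batch per (compound, time point, replicate) — plus control
#' batches when configured — together with a plate map and the mechanism
#' ground truth. In feature-table mode each batch contributes
#' `n_cells_per_condition` rows to a single per-cell feature table; in
#' image mode each batch is a rendered multi-channel field with ground
#' truth (see [render_cell_image()]). Identical configs and seeds
#' reproduce identical output.
#'
#' @param config a [panel_config()].
#' @return An object of class `synthetic_panel`: list with `plate_map`
#'   (batch_id, compound, time_min, replicate, well), `features` (per-cell
#'   table, feature-table mode), `images` (named list, image mode),
#'   `truth` (compound, group, potency) and `config`.
#' @export
#' @examples
#' cfg <- panel_config(n_compounds = 2, n_cells_per_condition = 60,
#'                     time_points_min = c(0, 30), n_replicates = 2)
#' panel <- generate_panel(cfg)
#' dim(panel$features)
generate_panel <- function(config) {
  if (!inherits(config, "panel_config"))
    stop_input("config must be a panel_config object")
  compounds <- config$compounds
  groups <- config$group_of
  potency <- config$potency
  if (config$include_control) {
    compounds <- c(compounds, "DMSO")
    groups <- c(groups, "null")
    potency <- c(potency, 0)
  }
  arch_by_name <- stats::setNames(config$mechanism_groups,
                                  vapply(config$mechanism_groups, `[[`, "", "name"))
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      time_min = config$time_points_min,
                      compound = compounds,
                      stringsAsFactors = FALSE)
  n_batch <- nrow(grid)
  wells_per_plate <- length(compounds) * length(config$time_points_min)
  plate_map <- data.frame(
    batch_id = sprintf("b%03d", seq_len(n_batch)),
    compound = grid$compound, time_min = grid$time_min,
    replicate = grid$replicate,
    well = well_name(((seq_len(n_batch) - 1L) %/% config$n_replicates) %%
                       wells_per_plate),
    stringsAsFactors = FALSE)

  truth <- data.frame(compound = compounds, group = groups, potency = potency,
                      stringsAsFactors = FALSE)
  out <- list(plate_map = plate_map, truth = truth, config = config)

  feat <- vector("list", n_batch)
  imgs <- if (config$image_mode) vector("list", n_batch)
  for (b in seq_len(n_batch)) {
    arch <- arch_by_name[[groups[match(grid$compound[b], compounds)]]]
    pot <- potency[match(grid$compound[b], compounds)]
    if (grid$compound[b] == "DMSO") pot <- 0
    withr::with_seed(mix_seed(config$rng_seed, b), {
      if (config$image_mode) {
        imgs[[b]] <- render_batch_image(config, arch, pot, grid$time_min[b])
      } else {
        x <- sample_batch_features(config, arch, pot, grid$time_min[b],
                                   config$n_cells_per_condition)
        meta <- data.frame(
          cell_id = sprintf("%s_c%04d", plate_map$batch_id[b],
                            seq_len(config$n_cells_per_condition)),
          batch_id = plate_map$batch_id[b], compound = grid$compound[b],
          time_min = grid$time_min[b], replicate = grid$replicate[b],
          well = plate_map$well[b], stringsAsFactors = FALSE)
        feat[[b]] <- cbind(meta, x)
      }
    })
  }
  if (config$image_mode) {
    names(imgs) <- plate_map$batch_id
    out$images <- imgs
  } else {
    out$features <- do.call(rbind, feat)
    rownames(out$features) <- NULL
  }
  class(out) <- "synthetic_panel"
  out
}

well_name <- function(idx0) {
  paste0(LETTERS[idx0 %/% 12 + 1], sprintf("%02d", idx0 %% 12 + 1))
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("<synthetic_panel>", nrow(x$plate_map), "batches,",
      length(unique(x$plate_map$compound)), "compounds,",
      length(unique(x$plate_map$time_min)), "time points,",
      max(x$plate_map$replicate), "replicates\n")
  if (!is.null(x$features))
    cat("  feature table:", nrow(x$features), "cells x",
        length(descriptor_columns(x$features)), "descriptors\n")
  if (!is.null(x$images))
    cat("  images:", length(x$images), "rendered fields\n")
  invisible(x)
}

# Image-mode batch: maps a reduced set of archetype effects onto rendering
# knobs (receptor perinuclear/PM weighting, endosome rate, recycling-marker
# PM intensity). Coarser than feature-table mode; used for small-scale
# integration of segmentation + feature extraction.
render_batch_image <- function(config, archetype, potency, time_min) {
  act <- effect_activation(time_min) * potency
  sh <- function(d) {
    v <- unname(archetype$shifts[d]); if (is.na(v %||% NA)) 0 else v * act
  }
  p <- .time_profile(c(.6, 1.4, 2.2, 1.6, .9), time_min)
  q <- .time_profile(c(1.6, 1.2, .8, .9, 1), time_min)
  lam <- max(0.2, 6 * .time_profile(c(.2, .8, 1, .8, .5), time_min) *
               (1 + 0.25 * sh("Perinuclear_endosome_EGFR_count")))
  n_cells <- min(config$n_cells_per_condition, 30L)
  side <- max(192L, as.integer(ceiling(sqrt(n_cells)) * 56L))
  render_cell_image(
    n_cells = n_cells,
    spot_counts = stats::rpois(n_cells, lam),
    width = side, height = side,
    perinuclear_weight = max(0, p * (1 + 0.2 * sh("Perinuclear_EGFR_mean"))),
    pm_weight = max(0, q * (1 + 0.2 * sh("PM_EGFR_mean"))),
    tfn_pm_intensity = max(0, 120 * (1 + 0.2 * sh("PM_Tfn_mean"))),
    noise_sd = 2)
}
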