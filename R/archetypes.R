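#' Construct a mechanism archetype
#'
#' An archetype is a vector of per-descriptor effect sizes shared by all
#' synthetic compounds of one mechanism class: a location shift in units
#' of the control SD and a multiplicative scale factor, both applied to
#' the per-cell descriptor distribution. Effects ramp in over time with
#' the panel's activation schedule (no compound acts at the 0-min,
#' pre-stimulation point).
#'
#' @param name archetype label; `"null"`-named archetypes must carry no
#'   effects (all shifts 0, all scales 1).
#' @param shifts named numeric vector: descriptor name -> location shift in
#'   control-SD units. Descriptors not named are unshifted.
#' @param scales named numeric vector: descriptor name -> scale factor
#'   (> 0). Descriptors not named keep scale 1.
#' @return An object of class `mechanism_archetype`.
#' @export
mechanism_archetype <- function(name, shifts = numeric(0), scales = numeric(0)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_input("archetype name must be a non-empty string")
  if (length(shifts) && is.null(names(shifts)))
    stop_input("shifts must be a named vector in archetype '", name, "'")
  if (length(scales) && is.null(names(scales)))
    stop_input("scales must be a named vector in archetype '", name, "'")
  if (any(scales <= 0))
    stop_input("scale factors must be positive in archetype '", name, "'")
  if (identical(name, "null") && (any(shifts != 0) || any(scales != 1)))
    stop_input("the null archetype must have shift 0 and scale 1 everywhere")
  structure(list(name = name, shifts = shifts, scales = scales),
            class = "mechanism_archetype")
}

#' Default mechanism archetypes
#'
#' Four groups mirroring the broad phenotype classes a receptor-trafficking
#' screen distinguishes: compounds with no measurable effect (`null`), an
#' Akt-axis block (loss of pAkt signal with mildly reduced receptor
#' endocytosis), a receptor block (loss of both pERK and pAkt signalling,
#' receptor retained at the plasma membrane, few endosomes), and a
#' trafficking block (signalling intact, receptor and transferrin retained
#' at the PM, endosomes accumulate there instead of the perinuclear
#' region). Effect sizes are free parameters of the generator, chosen to
#' be of realistic single-cell magnitude (0.3-1.8 control SD), not claims
#' about any real compound.
#'
#' @return list of [mechanism_archetype()] objects, first one null.
#' @export
default_archetypes <- function() {
  list(
    mechanism_archetype("null"),
    mechanism_archetype(
      "akt_axis",
      shifts = c(PM_pAkt_mean = -1.8, Cytoplasm_pAkt_mean = -1.5,
                 Nucleus_pAkt_mean = -1.0, Perinuclear_pAkt_mean = -1.2,
                 Cell_pAkt_integrated = -1.6,
                 Perinuclear_endosome_EGFR_count = -0.8,
                 Cytoplasm_endosome_EGFR_count = -0.6,
                 EGFR_ratio_perinuclear_PM = -0.5),
      scales = c(PM_pAkt_mean = 0.7, Cytoplasm_pAkt_mean = 0.8)),
    mechanism_archetype(
      "receptor_block",
      shifts = c(Nucleus_pERK_mean = -1.8, Cytoplasm_pERK_mean = -1.5,
                 Cell_pERK_integrated = -1.6, PM_pAkt_mean = -1.2,
                 Cytoplasm_pAkt_mean = -1.0,
                 EGFR_ratio_perinuclear_PM = -1.5,
                 Perinuclear_EGFR_mean = -1.2, PM_EGFR_mean = 1.2,
                 Perinuclear_endosome_EGFR_count = -1.5,
                 Cytoplasm_endosome_EGFR_count = -1.2,
                 PM_endosome_EGFR_Tfn_count = -0.8),
      scales = c(Nucleus_pERK_mean = 0.7, Cytoplasm_pERK_mean = 0.7)),
    mechanism_archetype(
      "trafficking_block",
      shifts = c(EGFR_ratio_perinuclear_PM = -1.2,
                 Perinuclear_EGFR_mean = -1.0, PM_EGFR_mean = 1.5,
                 Cell_EGFR_integrated = 0.8, PM_Tfn_mean = 1.5,
                 PM_endosome_Tfn_count = 1.0, PM_endosome_EGFR_count = 1.2,
                 PM_endosome_EGFR_Tfn_count = 1.0,
                 Perinuclear_endosome_EGFR_count = -1.0,
                 Nucleus_pERK_mean = 0.3),
      scales = c(PM_EGFR_mean = 1.3))
  )
}

#' @export
print.mechanism_archetype <- function(x, ...) {
  cat("<mechanism_archetype>", x$name, "-", length(x$shifts),
      "shifted /", length(x$scales), "rescaled descriptors\n")
  invisible(x)
}
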