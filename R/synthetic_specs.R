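# Specifications for synthetic microtissues and plates. The generator
# emulates the screen's study conditions: two-channel (actin, nuclei)
# multi-section stacks, 25 % buffer-control wells distributed across the
# plate, and treatments dosed at six concentrations in quadruplicate.

#' Describe one synthetic organoid
#'
#' @param center numeric length-3 (x, y, z): footprint centre in pixels and
#'   centre section (1-based, may be fractional).
#' @param radius spheroid radius in pixels (>= 2); the central-section
#'   footprint has area ~ pi * radius^2 and the object spans
#'   `2 * radius / zscale` sections.
#' @param elongation footprint major/minor axis ratio (>= 1); area-preserving
#'   (semi-axes `radius * sqrt(elongation)` and `radius / sqrt(elongation)`).
#' @param orientation footprint rotation angle in radians.
#' @param n_branches number of radial arms (>= 0).
#' @param branch_length arm length in pixels beyond the footprint boundary.
#' @param branch_angles optional arm directions in radians (sampled when NULL).
#' @param hollow if `TRUE`, a concentric lumen is carved out (actin ring).
#' @param lumen_frac lumen semi-axis as a fraction of the organoid's (< 1).
#' @param nuclei_count number of child nuclei (>= 1).
#' @param nuclei_placement `"boundary"` places nuclei in a shell at
#'   `boundary_depth` pixels from the mask boundary (polarised phenotype);
#'   `"uniform"` scatters them uniformly inside the footprint.
#' @param boundary_depth target nucleus-to-boundary distance in pixels.
#' @param nucleus_radius nucleus blob radius in pixels.
#' @return an object of class `organoid_spec`.
#' @export
organoid_spec <- function(center, radius, elongation = 1, orientation = 0,
                          n_branches = 0, branch_length = 0,
                          branch_angles = NULL, hollow = FALSE,
                          lumen_frac = 0.55, nuclei_count = 1,
                          nuclei_placement = c("boundary", "uniform"),
                          boundary_depth = 2, nucleus_radius = 3) {
  nuclei_placement <- match.arg(nuclei_placement)
  if (length(center) != 3L) stopf("center must be (x, y, z)")
  if (radius < 2) stopf("organoid radius must be >= 2 px (got %.2f)", radius)
  if (elongation < 1) stopf("elongation must be >= 1")
  if (n_branches < 0 || branch_length < 0) stopf("branch parameters must be non-negative")
  if (hollow && lumen_frac >= 1) stopf("a lumen must be smaller than the organoid")
  if (nuclei_count < 1) stopf("nuclei_count must be >= 1")
  structure(list(center = as.numeric(center), radius = radius,
                 elongation = elongation, orientation = orientation,
                 n_branches = as.integer(n_branches),
                 branch_length = branch_length, branch_angles = branch_angles,
                 hollow = isTRUE(hollow), lumen_frac = lumen_frac,
                 nuclei_count = as.integer(nuclei_count),
                 nuclei_placement = nuclei_placement,
                 boundary_depth = boundary_depth,
                 nucleus_radius = nucleus_radius),
            class = "organoid_spec")
}

#' Default stack geometry
#'
#' Desk-scale geometry: 8 sections of 256 x 256 pixels with a z spacing of
#' 6 pixels per section. The screen's acquisition geometry (20 sections of
#' 1344 x 1024) can be requested explicitly via the arguments.
#'
#' @param sections,height,width stack dimensions.
#' @param zscale physical z spacing between sections, in pixel units.
#' @return geometry list.
#' @export
stack_geometry <- function(sections = 8L, height = 256L, width = 256L,
                           zscale = 6) {
  if (sections < 1 || height < 8 || width < 8) stopf("geometry must be positive")
  list(sections = as.integer(sections), height = as.integer(height),
       width = as.integer(width), zscale = zscale)
}

#' Baseline organoid population parameters of a well
#'
#' Per-well sampling distributions for the organoid dials. Values are chosen
#' to emulate a moderately invasive untreated culture: slightly irregular
#' organoids (target roundness 0.72) carrying two short arms, with nuclei in
#' a mid-depth shell. Dials are sampled homoscedastically in the measured
#' feature's own units (e.g. footprint area rather than radius), so treatment
#' effects shift well means without inflating within-well dispersion.
#'
#' @param n_organoids organoids per well.
#' @param area_mean,area_sd central-section footprint area (px^2).
#' @param roundness_mean,roundness_sd target roundness (minor/major ratio).
#' @param n_branches arms per organoid.
#' @param branch_length_mean,branch_length_sd arm length (px).
#' @param nucleus_depth_mean,nucleus_depth_sd nucleus shell depth (px).
#' @param nuclei_min,nuclei_max nuclei per organoid (uniform integer).
#' @param nucleus_radius nucleus blob radius (px).
#' @param nuclei_placement see [organoid_spec()].
#' @param hollow render a lumen.
#' @return list of baseline parameters.
#' @export
well_baseline <- function(n_organoids = 8L, area_mean = 620, area_sd = 110,
                          roundness_mean = 0.72, roundness_sd = 0.05,
                          n_branches = 2L, branch_length_mean = 9,
                          branch_length_sd = 1.8, nucleus_depth_mean = 4.5,
                          nucleus_depth_sd = 1.1, nuclei_min = 7L,
                          nuclei_max = 9L, nucleus_radius = 3,
                          nuclei_placement = "boundary", hollow = FALSE) {
  as.list(environment())
}

#' Dose-response effect templates
#'
#' A template maps phenotype dials to dose-response slopes: at normalised
#' dose `t` in `[0, 1]` (low to high), a dial's well-level target is
#' `baseline + slope * t^2`. The quadratic ramp keeps low doses close to
#' no-effect, as treated wells in the screen behaved. The two defaults mirror
#' the opposing phenotypes of the anti-CDCP1 antibody groups: `anti_invasive`
#' produces rounder, smaller, less branched organoids with nuclei pulled to
#' the boundary (polarised, lumen-like), `pro_invasive` the opposite.
#'
#' @return named list of templates; each template is a named numeric vector
#'   of slopes over dials `area`, `roundness`, `branch_length`,
#'   `nucleus_depth`, `n_organoids`.
#' @export
effect_templates <- function() {
  list(
    none = c(area = 0, roundness = 0, branch_length = 0,
             nucleus_depth = 0, n_organoids = 0),
    anti_invasive = c(area = -185, roundness = 0.20, branch_length = -7,
                      nucleus_depth = -2.6, n_organoids = 0),
    pro_invasive = c(area = 150, roundness = -0.18, branch_length = 7,
                     nucleus_depth = 2.8, n_organoids = 0),
    growth_inhib = c(area = -160, roundness = 0, branch_length = 0,
                     nucleus_depth = 0, n_organoids = 0)
  )
}

#' Describe a synthetic assay plate
#'
#' @param treatments list of treatments; each is a list with `id`, `doses`
#'   (ordered low to high), `replicates`, and `effect` (a slope vector as in
#'   [effect_templates()], or the name of a built-in template).
#' @param buffer_fraction proportion of buffer-control wells (default 0.25);
#'   `buffer_fraction * n_wells` must be an integer >= 2.
#' @param geometry stack geometry, see [stack_geometry()].
#' @param baseline well baseline, see [well_baseline()].
#' @param noise_sd additive Gaussian imaging noise (on the [0, 1] intensity
#'   scale).
#' @param seed integer seed; the plate is a pure function of (spec, seed).
#' @return an object of class `plate_spec`.
#' @export
plate_spec <- function(treatments, buffer_fraction = 0.25,
                       geometry = stack_geometry(),
                       baseline = well_baseline(), noise_sd = 0.02,
                       seed = 1L) {
  tmpl <- effect_templates()
  treatments <- lapply(treatments, function(tr) {
    if (is.null(tr$id) || is.null(tr$doses) || is.null(tr$replicates)) {
      stopf("each treatment needs id, doses and replicates")
    }
    if (tr$replicates < 1) stopf("replicate count must be >= 1")
    if (is.character(tr$effect)) {
      if (!tr$effect %in% names(tmpl)) stopf("unknown effect template '%s'", tr$effect)
      tr$effect <- tmpl[[tr$effect]]
    }
    miss <- setdiff(names(tmpl$none), names(tr$effect))
    tr$effect <- c(tr$effect, tmpl$none[miss])[names(tmpl$none)]
    tr
  })
  n_treat <- sum(vapply(treatments, function(tr) length(tr$doses) * tr$replicates,
                        numeric(1)))
  n_wells <- n_treat / (1 - buffer_fraction)
  n_buffer <- buffer_fraction * n_wells
  if (abs(n_buffer - round(n_buffer)) > 1e-9 || round(n_buffer) < 2) {
    stopf("buffer_fraction * n_wells must be an integer >= 2 (got %.3f)", n_buffer)
  }
  structure(list(treatments = treatments,
                 buffer_fraction = buffer_fraction,
                 n_wells = as.integer(round(n_wells)),
                 n_buffer = as.integer(round(n_buffer)),
                 geometry = geometry, baseline = baseline,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "plate_spec")
}

#' The default screen-mimic plate
#'
#' A small antibody panel at six doses in quadruplicate plus 25 % buffer
#' controls (128 wells): two treatments with opposing invasion phenotypes
#' (`anti_invasive`, `pro_invasive`), one purely growth-inhibiting treatment
#' and one inactive binder. The panel width matters: the accumulative
#' selection cutoff is a frequency over all pairwise comparisons, and it
#' separates recurrent phenotype features from pair-specific chance
#' separations only when enough (treatment, dose) pairs contribute.
#'
#' @param seed integer seed.
#' @param geometry stack geometry.
#' @return a [plate_spec()].
#' @export
default_plate_spec <- function(seed = 1L,
                               geometry = stack_geometry(8L, 320L, 320L, 6)) {
  doses <- c(0.1, 0.3, 1, 3, 10, 30)
  plate_spec(
    treatments = list(
      list(id = "anti_invasive", doses = doses, replicates = 4L,
           effect = "anti_invasive"),
      list(id = "pro_invasive", doses = doses, replicates = 4L,
           effect = "pro_invasive"),
      list(id = "growth_inhib", doses = doses, replicates = 4L,
           effect = "growth_inhib"),
      list(id = "inactive", doses = doses, replicates = 4L,
           effect = "none")
    ),
    buffer_fraction = 0.25, geometry = geometry, seed = seed
  )
}

#' Plate map of a plate specification
#'
#' Buffer wells are interleaved across the plate (every fourth well at the
#' default fraction), mirroring controls being distributed across assay
#' plates.
#'
#' @param plate a [plate_spec()].
#' @return data.frame with columns `well`, `role`, `treatment`, `dose`,
#'   `replicate`.
#' @export
plate_map <- function(plate) {
  stopifnot(inherits(plate, "plate_spec"))
  rows <- list()
  for (tr in plate$treatments) {
    for (d in tr$doses) {
      for (r in seq_len(tr$replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          role = "treatment", treatment = tr$id, dose = d, replicate = r)
      }
    }
  }
  treat <- do.call(rbind, rows)
  n <- plate$n_wells
  nb <- plate$n_buffer
  # spread buffer wells evenly across the well sequence
  buf_pos <- unique(round(seq(1, n, length.out = nb)))
  while (length(buf_pos) < nb) {
    cand <- setdiff(seq_len(n), buf_pos)
    buf_pos <- sort(c(buf_pos, cand[1]))
  }
  map <- data.frame(well = sprintf("W%03d", seq_len(n)), role = "treatment",
                    treatment = NA_character_, dose = NA_real_,
                    replicate = NA_integer_, stringsAsFactors = FALSE)
  map$role[buf_pos] <- "buffer"
  ti <- setdiff(seq_len(n), buf_pos)
  map$treatment[ti] <- treat$treatment
  map$dose[ti] <- treat$dose
  map$replicate[ti] <- treat$replicate
  map
}
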