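# Streaming plate driver: generate (or load), segment and featurize one well
# at a time, so a full plate never holds more than one stack in memory.

#' Profile a synthetic plate into a raw feature table
#'
#' Renders each well of the plate specification, segments it and extracts the
#' 294-entry feature vector, discarding the stack before the next well.
#'
#' @param plate a [plate_spec()].
#' @param sharpness_min,min_overlap_ratio,max_dist segmentation parameters,
#'   see [segment_well()].
#' @param actin_params,nuclei_params per-channel segmentation overrides.
#' @param progress print one line per well.
#' @return list with `table` (wells x 294 matrix, rownames = well ids) and
#'   `map` (plate map data.frame).
#' @export
profile_plate <- function(plate, sharpness_min = 0.2, min_overlap_ratio = 0.5,
                          max_dist = 5, actin_params = list(),
                          nuclei_params = list(), progress = FALSE) {
  gp <- generate_plate(plate, render = FALSE)
  nm <- feature_vector_names()
  tab <- matrix(NA_real_, nrow(gp$map), length(nm),
                dimnames = list(gp$map$well, nm))
  for (i in seq_len(nrow(gp$map))) {
    wl <- gp$map$well[i]
    r <- render_well_stack(gp$well_specs[[wl]], plate$geometry,
                           noise_sd = plate$noise_sd,
                           seed = gp$well_seeds[[wl]])
    seg <- segment_well(r$stack, actin_params = actin_params,
                        nuclei_params = nuclei_params,
                        sharpness_min = sharpness_min,
                        min_overlap_ratio = min_overlap_ratio,
                        max_dist = max_dist)
    tab[wl, ] <- extract_feature_battery(r$stack, seg)
    if (progress) {
      message(sprintf("profiled %s (%d/%d): %d organoids", wl, i,
                      nrow(gp$map), length(seg$organoids)))
    }
  }
  list(table = tab, map = gp$map)
}
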