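# Shared fixtures, computed once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small clean three-organoid well with nuclei (noise-free twin included)
fixture_specs <- function() {
  list(
    organoid_spec(c(60, 60, 4), 14, elongation = 1.3, n_branches = 2,
                  branch_length = 8, nuclei_count = 5, boundary_depth = 4),
    organoid_spec(c(160, 80, 5), 13, nuclei_count = 5, boundary_depth = 4),
    organoid_spec(c(100, 180, 3), 15, elongation = 1.5, n_branches = 2,
                  branch_length = 10, nuclei_count = 5, boundary_depth = 4)
  )
}

fixture_clean_well <- function() {
  cached("clean_well", render_well_stack(fixture_specs(),
                                         stack_geometry(8, 256, 256),
                                         noise_sd = 0, seed = 11))
}

fixture_noisy_well <- function() {
  cached("noisy_well", render_well_stack(fixture_specs(),
                                         stack_geometry(8, 256, 256),
                                         noise_sd = 0.02, seed = 11))
}

fixture_clean_seg <- function() {
  cached("clean_seg", segment_well(fixture_clean_well()$stack))
}

# small 16-well plate for pipeline tests: 2 treatments x 3 doses x 2 reps
# + 4 buffer wells, tiny geometry
fixture_small_config <- function(out_dir, reps = 5L) {
  pipeline_config(
    seed = 7L,
    out_dir = out_dir,
    plate = list(treatments = list(
      list(id = "anti", doses = c(1, 3, 10), replicates = 2L,
           effect = "anti_invasive"),
      list(id = "pro", doses = c(1, 3, 10), replicates = 2L,
           effect = "pro_invasive")),
      baseline = list(n_organoids = 3L, area_mean = 320, area_sd = 60,
                      branch_length_mean = 6, branch_length_sd = 1.2,
                      nuclei_min = 4L, nuclei_max = 6L)),
    geometry = list(sections = 5L, height = 144L, width = 144L, zscale = 5),
    selection = list(n_repetitions = reps, num_trees = 100L),
    clustering = list(k_max = 4L),
    write_figures = FALSE
  )
}

# the default screen-mimic plate profile (expensive; shared by the
# feature-selection and end-to-end acceptance checks)
fixture_screen_mimic <- function() {
  cached("screen_mimic", {
    pp <- profile_plate(default_plate_spec(seed = 1L))
    zt <- suppressMessages(zscore_normalize(pp$table, pp$map))
    list(pp = pp, ztable = zt)
  })
}

fixture_screen_mimic_selection <- function() {
  cached("screen_mimic_selection", {
    fx <- fixture_screen_mimic()
    run_accumulative_selection(fx$ztable, fx$pp$map, k = 10L,
                               n_bootstrap = 30L, n_repetitions = 50L,
                               cutoff = 0.05, seed = 1L)
  })
}
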