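# Synthetic microtissue generator: determinism, ground-truth consistency,
# plate semantics and the planted feature-table simulator.

test_that("rendering is a pure function of (spec, seed)", {
  sp <- organoid_spec(c(40, 40, 3), 12, nuclei_count = 4)
  g <- stack_geometry(6, 96, 96)
  r1 <- render_well_stack(list(sp), g, noise_sd = 0.02, seed = 7)
  r2 <- render_well_stack(list(sp), g, noise_sd = 0.02, seed = 7)
  expect_identical(r1$stack, r2$stack)
  expect_identical(r1$ground_truth$nuclei, r2$ground_truth$nuclei)
  r3 <- render_well_stack(list(sp), g, noise_sd = 0.02, seed = 8)
  expect_false(identical(r1$stack$actin, r3$stack$actin))
})

test_that("noise-free rendering thresholds back to the exact voxel set", {
  sp <- organoid_spec(c(48, 48, 3), 14, nuclei_count = 3)
  r <- render_well_stack(list(sp), stack_geometry(6, 96, 96), noise_sd = 0,
                         seed = 3)
  half <- (0.45 + 0.05) / 2      # half-maximum between body and background
  for (si in 1:6) {
    rec <- r$stack$actin[, , si] >= half
    expect_identical(which(rec), which(r$ground_truth$labels[, , si] == 1L))
  }
})

test_that("ground truth bookkeeping matches the specs", {
  specs <- list(
    organoid_spec(c(30, 30, 3), 10, nuclei_count = 5),
    organoid_spec(c(90, 30, 3), 10, nuclei_count = 5),
    organoid_spec(c(60, 90, 3), 10, nuclei_count = 5))
  r <- render_well_stack(specs, stack_geometry(6, 128, 128), seed = 5)
  expect_setequal(unique(as.vector(r$ground_truth$labels[r$ground_truth$labels > 0])),
                  1:3)
  expect_equal(nrow(r$ground_truth$nuclei), 15)
  expect_equal(sort(unique(r$ground_truth$nuclei$object_id)), 1:3)
})

test_that("a spec outside the canvas is rejected and identified", {
  specs <- list(organoid_spec(c(30, 30, 3), 10),
                organoid_spec(c(5, 5, 3), 10))
  expect_error(render_well_stack(specs, stack_geometry(6, 96, 96)),
               "spec 2")
})

test_that("dial monotonicity holds in the ground truth", {
  g <- stack_geometry(5, 128, 128)
  major <- vapply(c(1, 1.6, 2.4), function(e) {
    sp <- organoid_spec(c(64, 64, 3), 12, elongation = e)
    r <- render_well_stack(list(sp), g, seed = 2)
    major_axis(ground_truth_masks(r$ground_truth, 1)[[3]])
  }, numeric(1))
  expect_true(all(diff(major) > 0))

  branches <- vapply(c(0, 2, 4), function(nb) {
    sp <- organoid_spec(c(64, 64, 3), 12, n_branches = nb, branch_length = 10)
    r <- render_well_stack(list(sp), g, seed = 2)
    bb <- mask_bbox_matrix(ground_truth_masks(r$ground_truth, 1)[[3]])
    skeleton_stats(bb$m)$n_branches
  }, numeric(1))
  expect_true(all(diff(branches) > 0))
})

test_that("plate map honours the buffer fraction and dose layout", {
  plate <- plate_spec(
    treatments = list(list(id = "t1", doses = c(1, 3, 10), replicates = 4L,
                           effect = "anti_invasive")),
    buffer_fraction = 0.25)
  expect_equal(plate$n_wells, 16L)
  map <- plate_map(plate)
  expect_equal(sum(map$role == "buffer"), 4L)       # 0.25 * 16
  expect_equal(sum(map$role == "treatment"), 12L)
  tm <- map[map$role == "treatment", ]
  expect_equal(as.vector(table(tm$dose)), c(4L, 4L, 4L))
  # buffer wells are interleaved, not contiguous
  expect_gt(diff(range(which(map$role == "buffer"))), 4L)
})

test_that("an invalid buffer fraction is rejected", {
  expect_error(plate_spec(
    treatments = list(list(id = "t1", doses = 1:5, replicates = 1L,
                           effect = "none")),
    buffer_fraction = 0.25), "integer")
})

test_that("the invasive template raises ground-truth elongation at top dose", {
  plate <- plate_spec(
    treatments = list(list(id = "pro", doses = c(1, 3, 10), replicates = 4L,
                           effect = "pro_invasive")),
    buffer_fraction = 0.25, seed = 4,
    geometry = stack_geometry(6, 256, 256),
    baseline = well_baseline(n_organoids = 4L))
  gp <- generate_plate(plate, render = FALSE)
  elong_of <- function(wells) {
    mean(unlist(lapply(gp$well_specs[wells],
                       function(specs) vapply(specs, `[[`, 0, "elongation"))))
  }
  top <- gp$map$well[gp$map$role == "treatment" & gp$map$dose == 10]
  buf <- gp$map$well[gp$map$role == "buffer"]
  expect_gt(elong_of(top), elong_of(buf))
})

test_that("a zero-slope template is statistically indistinguishable from buffer", {
  plate <- plate_spec(
    treatments = list(list(id = "null", doses = c(1, 10), replicates = 6L,
                           effect = "none")),
    buffer_fraction = 0.25, seed = 9,
    geometry = stack_geometry(4, 128, 128),
    baseline = well_baseline(n_organoids = 3L, area_mean = 300, area_sd = 60,
                             branch_length_mean = 6, nuclei_min = 4L,
                             nuclei_max = 6L))
  pp <- profile_plate(plate)
  buf <- pp$table[pp$map$well[pp$map$role == "buffer"], , drop = FALSE]
  trt <- pp$table[pp$map$well[pp$map$role == "treatment"], , drop = FALSE]
  pvals <- vapply(seq_len(ncol(pp$table)), function(j) {
    x <- buf[, j]; y <- trt[, j]
    if (stats::sd(c(x, y)) < 1e-10 || anyNA(c(x, y))) return(1)
    stats::t.test(x, y)$p.value
  }, numeric(1))
  # at alpha = 0.001 over 294 features, expect ~0.3 significant by chance
  expect_lte(sum(pvals < 0.001), 5)
})

test_that("simulate_feature_table plants separable structure", {
  tpl <- list(c(f = -5), c(f = 5))
  sim <- simulate_feature_table(tpl, n_per_class = 20, n_noise_features = 10,
                                seed = 2)
  # a midpoint threshold on the informative feature classifies all rows
  pred <- ifelse(sim$table[, "f"] > 0, 2L, 1L)
  expect_equal(pred, sim$labels, ignore_attr = TRUE)
})

test_that("pure-noise columns obey the normal-theory mean bound", {
  tpl <- list(c(f = 0), c(f = 0))
  sim <- simulate_feature_table(tpl, n_per_class = 25, n_noise_features = 294,
                                seed = 6)
  n <- nrow(sim$table)
  cm <- colMeans(sim$table)
  expect_true(all(abs(cm) < 4 / sqrt(n)))
})

test_that("the table simulator is deterministic and validates inputs", {
  tpl <- list(c(a = 1, b = 0), c(a = -1, b = 2))
  s1 <- simulate_feature_table(tpl, n_per_class = 5, seed = 3)
  s2 <- simulate_feature_table(tpl, n_per_class = 5, seed = 3)
  expect_identical(s1, s2)
  expect_equal(ncol(s1$table), 294)
  expect_error(simulate_feature_table(tpl[1], n_per_class = 5), "two class")
})

test_that("generate_plate is deterministic given the plate seed", {
  plate <- plate_spec(
    treatments = list(list(id = "t", doses = c(1, 10), replicates = 3L,
                           effect = "pro_invasive")),
    buffer_fraction = 0.25, seed = 12,
    geometry = stack_geometry(4, 160, 160),
    baseline = well_baseline(n_organoids = 3L))
  g1 <- generate_plate(plate, render = FALSE)
  g2 <- generate_plate(plate, render = FALSE)
  expect_identical(g1$well_specs, g2$well_specs)
})
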