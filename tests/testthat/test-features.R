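# The six formula-defined features against independent brute-force oracles,
# plus battery shape, aggregation conventions and buffer normalization.

disk_px <- function(r, cx = r + 2, cy = r + 2) {
  g <- expand.grid(x = seq_len(2 * r + 4), y = seq_len(2 * r + 4))
  px <- g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, ]
  as.matrix(px)
}

test_that("invasion inhibition matches the printed formula on constructed masks", {
  row9 <- cbind(x = 1:9, y = rep(1L, 9))          # area 9, major axis 8
  expect_equal(invasion_inhibition(row9), 36 / (64 * pi), tolerance = 1e-12)
  d20 <- disk_px(20)
  expect_gte(invasion_inhibition(d20), 0.95)
  expect_lte(invasion_inhibition(d20), 1.10)
  expect_error(invasion_inhibition(cbind(3L, 3L)), "single-pixel")
})

test_that("the six features agree with brute-force oracles on random masks", {
  n_ok <- 0
  for (s in 1:60) {
    px <- random_blob(s)
    expect_identical(per_organoid_size(px), bf_size(px))
    expect_equal(major_axis(px), bf_major_axis(px), tolerance = 1e-9)
    expect_equal(invasion_inhibition(px), bf_invasion_inhibition(px),
                 tolerance = 1e-9)
    # polarity at three interior points
    set.seed(s + 1000)
    ctr <- px[sample.int(nrow(px), min(3, nrow(px))), , drop = FALSE]
    got <- cell_polarity(px, ctr)
    want <- bf_polarity(px, ctr)
    expect_equal(got$mean, want$mean, tolerance = 1e-9)
    expect_equal(got$sd, want$sd, tolerance = 1e-9)
    # branching: independent path walk on the same skeleton
    sk <- skeletonize(mask_to_matrix64(px))
    expect_equal(skeleton_stats(sk)$mean_branch_length, bf_branching(sk),
                 tolerance = 1e-9)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 50)
})

test_that("per-organoid size is exact pixel counting", {
  expect_equal(per_organoid_size(as.matrix(expand.grid(1:3, 1:3))), 9)
  expect_equal(per_organoid_size(cbind(5L, 5L)), 1)
  d10 <- disk_px(10)
  expect_equal(per_organoid_size(d10), bf_size(d10))
})

test_that("total proliferation accumulates section areas", {
  m5 <- section_mask(as.matrix(expand.grid(x = 1:5, y = 1L)), 1)
  m7 <- section_mask(as.matrix(expand.grid(x = 1:7, y = 3L)), 1)
  masks <- list()
  for (s in 1:3) {
    masks <- c(masks, list(section_mask(m5$pixels, s), section_mask(m7$pixels, s)))
  }
  expect_equal(total_proliferation(masks), (5 + 7) * 3)
  expect_equal(total_proliferation(list()), 0)
  seg <- fixture_clean_seg()
  expect_equal(total_proliferation(seg$actin_masks),
               sum(vapply(seg$actin_masks, per_organoid_size, numeric(1))))
})

test_that("organoid count follows the printed per-section sum", {
  px <- as.matrix(expand.grid(x = 1:4, y = 1:4))
  masks <- list()
  for (s in 1:3) {
    masks <- c(masks, list(section_mask(px, s),
                           section_mask(px + 10L, s)))
  }
  linked <- link_sections_by_overlap(masks, width = 30)
  all_masks <- unlist(lapply(linked, `[[`, "masks"), recursive = FALSE)
  expect_equal(organoid_count(all_masks), 6)                   # 2 organoids x 3 sections
  expect_equal(organoid_count(all_masks, distinct = TRUE), 2)  # prose reading
  expect_equal(organoid_count(list()), 0)
  expect_equal(organoid_count(list(section_mask(px, 1))), 1)
})

test_that("cell polarity reflects nucleus position relative to the boundary", {
  d10 <- disk_px(10)
  centre <- matrix(c(12, 12), 1)                 # disk centre
  cp <- cell_polarity(d10, centre)
  expect_gte(cp$mean, 8.5)
  expect_lte(cp$mean, 10)
  expect_equal(cp$sd, 0)
  pb <- boundary_pixels(d10)
  on_edge <- matrix(pb[1, ], 1)
  expect_equal(cell_polarity(d10, on_edge)$mean, 0)
  expect_error(cell_polarity(d10, matrix(numeric(0), 0, 2)), "without nuclei")
})

test_that("hollow boundary-lined organoids score lower polarity than solid scattered ones", {
  g <- stack_geometry(5, 128, 128)
  hollow <- organoid_spec(c(64, 64, 3), 16, hollow = TRUE, nuclei_count = 8,
                          nuclei_placement = "boundary", boundary_depth = 2)
  solid <- organoid_spec(c(64, 64, 3), 16, nuclei_count = 8,
                         nuclei_placement = "uniform")
  pol_of <- function(sp) {
    r <- render_well_stack(list(sp), g, noise_sd = 0, seed = 31)
    seg <- segment_well(r$stack)
    means <- c(); sds <- c()
    for (ob in seg$organoids) for (m in ob$masks) {
      ch <- ob$children[ob$children$section == m$section, ]
      if (nrow(ch)) {
        cp <- cell_polarity(m, cbind(ch$x, ch$y))
        means <- c(means, cp$mean); sds <- c(sds, cp$sd)
      }
    }
    c(mean(means), mean(sds))
  }
  ph <- pol_of(hollow); ps <- pol_of(solid)
  expect_lt(ph[1], ps[1])
  expect_lt(ph[2], ps[2])
})

test_that("branching follows the skeleton-graph convention on hand-built masks", {
  # plus: four 1-px arms, each extending 6 px beyond the centre pixel; the
  # junction cluster (centre + 4 diagonal-adjacent pixels) is excluded from
  # arm length, leaving 5 counted pixels per arm
  m <- matrix(0L, 17, 17); m[9, 3:15] <- 1L; m[3:15, 9] <- 1L
  st <- skeleton_stats(m)
  expect_equal(st$n_branches, 4)
  expect_equal(st$mean_branch_length, 5)
  # T: arms of 9, 5 and 5 pixels beyond the junction; cluster absorbs 2, 1, 1
  t <- matrix(0L, 15, 15); t[3:11, 8] <- 1L; t[11, 3:13] <- 1L
  stt <- skeleton_stats(t)
  expect_equal(stt$n_branches, 3)
  expect_equal(stt$mean_branch_length, mean(c(7, 4, 4)))
  # compact disk and bare segment have no branch
  expect_equal(organoid_branching(disk_px(9)), 0)
  seg7 <- cbind(x = 2:8, y = rep(4L, 7))
  expect_equal(organoid_branching(seg7), 0)
})

test_that("invasion inhibition is dilation-invariant and size scales quadratically", {
  # discretisation error of the major axis is ~1.2/d, so the 5 % invariance
  # band applies to masks whose major axis is not tiny; tested on a disk, an
  # ellipse and the two largest random blobs
  dil2 <- function(px) {
    rbind(cbind(2L * px[, 1], 2L * px[, 2]),
          cbind(2L * px[, 1] - 1L, 2L * px[, 2]),
          cbind(2L * px[, 1], 2L * px[, 2] - 1L),
          cbind(2L * px[, 1] - 1L, 2L * px[, 2] - 1L))
  }
  g <- as.matrix(expand.grid(x = 1:60, y = 1:60))
  masks <- list(
    g[(g[, 1] - 25)^2 + (g[, 2] - 25)^2 <= 18^2, ],          # disk r = 18
    g[((g[, 1] - 31) / 28)^2 + ((g[, 2] - 25) / 13)^2 <= 1, ], # ellipse
    random_blob(1), random_blob(25))
  for (px in masks) {
    big <- dil2(px)
    expect_equal(per_organoid_size(big), 4 * per_organoid_size(px))
    expect_lte(abs(invasion_inhibition(big) - invasion_inhibition(px)) /
                 invasion_inhibition(px), 0.05)
  }
})

test_that("phenotype dials move their features in the documented direction", {
  g <- stack_geometry(5, 128, 128)
  ii_of <- function(e) {
    sp <- organoid_spec(c(64, 64, 3), 13, elongation = e)
    r <- render_well_stack(list(sp), g, seed = 17)
    mean(vapply(ground_truth_masks(r$ground_truth, 1), invasion_inhibition,
                numeric(1)))
  }
  ii <- vapply(c(1, 1.7, 2.6), ii_of, numeric(1))
  expect_true(all(diff(ii) < 0))
  br_of <- function(nb) {
    sp <- organoid_spec(c(64, 64, 3), 13, n_branches = nb, branch_length = 9)
    r <- render_well_stack(list(sp), g, seed = 18)
    mean(vapply(ground_truth_masks(r$ground_truth, 1), organoid_branching,
                numeric(1)))
  }
  expect_gt(br_of(3), br_of(0))
})

test_that("the battery yields exactly 294 stably named entries", {
  r <- fixture_noisy_well()
  fv <- extract_feature_battery(r$stack)
  expect_length(fv, 294)
  expect_identical(names(fv), feature_vector_names())
  fv2 <- extract_feature_battery(r$stack)
  expect_identical(fv, fv2)                       # determinism
})

test_that("single-observation wells aggregate with SD zero", {
  sp <- organoid_spec(c(48, 48, 3), 12, nuclei_count = 4, boundary_depth = 3)
  g <- stack_geometry(6, 96, 96, zscale = 30)     # one section intersected
  r <- render_well_stack(list(sp), g, noise_sd = 0.01, seed = 13)
  seg <- segment_well(r$stack)
  expect_length(seg$actin_masks, 1)
  fv <- extract_feature_battery(r$stack, seg)
  actin_sd <- fv[grep("^actin\\..*\\.sd$", names(fv))]
  expect_true(all(actin_sd == 0, na.rm = TRUE))
})

test_that("z-score normalization is defined by the buffer wells", {
  tab <- matrix(c(1, 2, 3, 10,
                  5, 5, 5, 5,
                  2, 4, 6, 0), ncol = 3,
                dimnames = list(c("b1", "b2", "b3", "t1"),
                                c("f1", "const", "f3")))
  map <- data.frame(well = c("b1", "b2", "b3", "t1"),
                    role = c("buffer", "buffer", "buffer", "treatment"))
  z <- suppressMessages(zscore_normalize(tab, map))
  expect_equal(unname(z[c("b1", "b2", "b3"), "f1"]), c(-1, 0, 1))
  expect_identical(attr(z, "excluded"), "const")  # excluded, not NaN
  expect_false(anyNA(z))
  # buffer mean 0, SD 1 per retained feature
  expect_equal(unname(colMeans(z[1:3, ])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z[1:3, ], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(zscore_normalize(tab, map[4, , drop = FALSE]), "buffer")
})
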