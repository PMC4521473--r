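# Ward clustering, validity indices against hand-computed oracles, signed
# signatures, dose-label sequences and the general class.

planted_profiles <- function(k, n_per = 20, sep = 8, seed = 2) {
  ctr <- lapply(seq_len(k), function(i) {
    v <- rep(0, 6); v[(i - 1) %% 6 + 1] <- sep
    stats::setNames(v, letters[1:6])
  })
  simulate_feature_table(ctr, n_per_class = n_per, n_noise_features = 0,
                         seed = seed)
}

test_that("ward clustering recovers separable structure", {
  x <- matrix(c(rnorm(10, -10), rnorm(10, 10)), ncol = 1)
  wc <- ward_cluster(x, 2)
  expect_equal(length(unique(wc$labels[1:10])), 1)
  expect_equal(length(unique(wc$labels[11:20])), 1)
  expect_false(wc$labels[1] == wc$labels[20])
  # duplicate observations always share a label
  y <- rbind(x, x[3, , drop = FALSE])
  wcy <- ward_cluster(y, 2)
  expect_equal(unname(wcy$labels[21]), unname(wcy$labels[3]))
})

test_that("five well-separated planted classes are recovered perfectly", {
  sim <- planted_profiles(5, sep = 8, seed = 3)
  wc <- ward_cluster(sim$table, 5)
  expect_equal(mclust::adjustedRandIndex(wc$labels, sim$labels), 1)
})

test_that("k is rejected outside 2..n-1", {
  x <- matrix(rnorm(12), 6, 2)
  expect_error(ward_cluster(x, 1), "k must")
  expect_error(ward_cluster(x, 6), "k must")
})

test_that("both validity indices match hand-computed values", {
  # two 1-D clusters {0, 1} and {10, 11}: S1 = S2 = 0.5, centroids 0.5 and
  # 10.5 so M12 = 10; DB = (0.5 + 0.5) / 10 = 0.1
  # B = 2*(0.5-5.5)^2 + 2*(10.5-5.5)^2 = 100, W = 1 -> CH = (100/1)/(1/2) = 200
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(davies_bouldin(x, lab), 0.1, tolerance = 1e-9)
  expect_equal(calinski_harabasz(x, lab), 200, tolerance = 1e-9)
})

test_that("choose_k returns the planted class count", {
  sim5 <- planted_profiles(5, sep = 8, seed = 4)
  expect_equal(choose_k(sim5$table)$k, 5)
  sim2 <- planted_profiles(2, sep = 8, seed = 5)
  expect_equal(choose_k(sim2$table)$k, 2)
})

test_that("cluster recovery holds across seeds", {
  # at 4-SD per-axis separation the count is always recovered and agreement
  # is near-perfect; perfect label agreement needs wider separation (6 SD),
  # where single-point confusions vanish
  for (s in 1:10) {
    sim <- planted_profiles(5, n_per = 20, sep = 4, seed = 100 + s)
    ck <- choose_k(sim$table)
    expect_equal(ck$k, 5)
    wc <- ward_cluster(sim$table, 5)
    expect_gte(mclust::adjustedRandIndex(wc$labels, sim$labels), 0.94)
    sim6 <- planted_profiles(5, n_per = 20, sep = 6, seed = 300 + s)
    wc6 <- ward_cluster(sim6$table, 5)
    expect_equal(mclust::adjustedRandIndex(wc6$labels, sim6$labels), 1)
  }
})

test_that("class signatures follow the signed partition formula", {
  nm <- letters[1:6]
  sig1 <- class_signature(matrix(rep(1, 6), 1, dimnames = list(NULL, nm)))
  expect_equal(unname(sig1$percent), rep(100 / 6, 6))
  sig2 <- class_signature(matrix(c(2, 1, 1, 0, 0, 0), 1,
                                 dimnames = list(NULL, nm)))
  expect_equal(unname(sig2$percent), c(50, 25, 25, 0, 0, 0))
  # signed values outside [0, 100] are legal
  sig3 <- class_signature(matrix(c(3, -1, 0, 0, 0, 0), 1,
                                 dimnames = list(NULL, nm)))
  expect_equal(unname(sig3$percent[1:2]), c(150, -50))
  expect_equal(sum(sig3$percent), 100)
  # sum F = 0: flagged undefined, raw F reported
  sig0 <- class_signature(matrix(c(1, -1, 0, 0, 0, 0), 1,
                                 dimnames = list(NULL, nm)))
  expect_false(sig0$defined)
  expect_true(all(is.na(sig0$percent)))
  expect_equal(unname(sig0$F), c(1, -1, 0, 0, 0, 0))
})

test_that("every defined signature sums to 100 percent", {
  sim <- planted_profiles(4, sep = 6, seed = 9)
  wc <- ward_cluster(sim$table, 4)
  for (ki in 1:4) {
    sig <- class_signature(sim$table[wc$labels == ki, , drop = FALSE])
    if (sig$defined) expect_equal(sum(sig$percent), 100, tolerance = 1e-9)
  }
})

fixture_model <- function() {
  cached("cluster_model_fix", {
    # 3 treatments x 4 doses averaged from 2 replicates, 2 planted classes
    set.seed(31)
    wells <- sprintf("W%02d", 1:28)
    map <- data.frame(
      well = wells,
      role = c(rep("buffer", 4), rep("treatment", 24)),
      treatment = c(rep(NA, 4), rep(c("tA", "tB", "tC"), each = 8)),
      dose = c(rep(NA, 4), rep(rep(c(1, 3, 10, 30), each = 2), 3)),
      replicate = c(rep(NA, 4), rep(1:2, 12)))
    z <- matrix(rnorm(28 * 6, 0, 0.1), 28, 6,
                dimnames = list(wells, letters[1:6]))
    trt <- map$role == "treatment"
    up <- trt & map$treatment %in% c("tA") & map$dose >= 3
    dn <- trt & map$treatment %in% c("tB") & map$dose >= 3
    z[up, 1] <- z[up, 1] + 6      # class 1: high feature a
    z[dn, 2] <- z[dn, 2] + 6      # class 2: high feature b
    model <- cluster_phenotypes(z, map, letters[1:6], k = 3)
    list(model = model, map = map, z = z)
  })
}

test_that("dose labels use nearest centroids with a no-effect floor", {
  fx <- fixture_model()
  model <- fx$model
  # a profile equal to a class centroid gets that class
  cl <- rownames(model$centroids)[1]
  d2 <- colSums((t(model$centroids) - model$centroids[1, ])^2)
  expect_equal(names(which.min(d2)), cl)
  seqA <- assign_dose_labels("tA", model, effect_floor = 1)
  seqB <- assign_dose_labels("tB", model, effect_floor = 1)
  expect_length(seqA$labels, 4)
  # low doses fall below the effect floor
  expect_equal(seqA$labels[1], "no-effect")
  # high doses of opposite treatments land in different classes
  expect_false(seqA$labels[4] == seqB$labels[4])
  expect_false(seqA$general == seqB$general)
  # a null treatment is no-effect throughout
  seqC <- assign_dose_labels("tC", model, effect_floor = 1)
  expect_equal(seqC$general, "no-effect")
  expect_error(assign_dose_labels("missing", model), "no profiles")
})

test_that("the general class follows prevalence with the stated tie-break", {
  expect_equal(assign_general_class(c("B", "B", "B", "A", "no-effect",
                                      "no-effect")), "B")
  expect_equal(assign_general_class(c("A", "A", "E", "E", "no-effect", "E")),
               "E")
  # tie between A and E: E occurs at the higher dose
  expect_equal(assign_general_class(c("A", "A", "E", "E", "no-effect",
                                      "no-effect")), "E")
  expect_equal(assign_general_class(rep("no-effect", 6)), "no-effect")
  expect_error(assign_general_class(character(0)), "empty")
})

test_that("sequences are invariant under cluster relabelling", {
  fx <- fixture_model()
  model <- fx$model
  perm <- c(A = "B", B = "C", C = "A")
  model2 <- model
  model2$labels <- stats::setNames(perm[model$labels], names(model$labels))
  rownames(model2$centroids) <- unname(perm[rownames(model$centroids)])
  s1 <- assign_dose_labels("tA", model, effect_floor = 1)$labels
  s2 <- assign_dose_labels("tA", model2, effect_floor = 1)$labels
  mapped <- ifelse(s1 == "no-effect", "no-effect", unname(perm[s1]))
  expect_equal(s2, mapped)
})

test_that("the stability diagnostic is perfect for well-separated classes", {
  sim <- planted_profiles(3, n_per = 10, sep = 9, seed = 12)
  wc <- ward_cluster(sim$table, 3, seed = 5)
  expect_equal(wc$stability, 1)
})
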