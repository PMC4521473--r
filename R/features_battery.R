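# The full per-well feature battery: 70 morphological features per channel
# plus 7 two-channel correlative features, each aggregated per well by mean
# and standard deviation, giving (70 * 2 + 7) * 2 = 294 named values.
#
# The battery is deliberately non-redundant: each morphological degree of
# freedom is represented by exactly one descriptor (the formula-defined
# features: size, roundness, branching, and the per-well totals), and the
# remaining per-object descriptors are intensity and texture statistics.
# To keep those statistics blind to geometry, they are computed on fixed-size
# deterministic subsamples of the mask's eroded interior (boundary pixels
# carry shape information through the perimeter/area ratio, and sample-size
# effects -- entropy, extremes, estimator variance -- would otherwise
# duplicate size information); texture is measured on a fixed square patch at
# the mask's interior centre. A JSON sidecar with every definition ships in
# `inst/extdata/feature_definitions.json`.

.haralick_names <- as.vector(outer(
  c("h.asm", "h.con", "h.cor", "h.var", "h.idm", "h.sav", "h.sva", "h.sen",
    "h.ent", "h.dva", "h.den", "h.f12", "h.f13"),
  c("s1", "s2"), paste, sep = "."))

#' Base feature names of the battery
#'
#' @return list with `per_object` (65 per-object/per-section descriptors),
#'   `per_well` (5 per-well descriptors; together 70 per channel) and `corr`
#'   (7 two-channel correlative descriptors).
#' @export
battery_base_names <- function() {
  list(
    per_object = c(
      "area", "invasion_inhibition", "organoid_branching",
      "int_mean", "int_sd", "int_cv", "int_min", "int_max", "int_range",
      "int_median", "int_mad", "int_q05", "int_q10", "int_q25", "int_q75",
      "int_q90", "int_q95", "int_iqr", "int_skewness", "int_kurtosis",
      "int_entropy", "int_energy",
      "int_trimmed_mean", "local_range_mean", "acf_diag",
      "int_diff_mean", "bg_contrast",
      "grad_mean", "grad_sd", "grad_max", "grad_median", "lap_mean", "lap_sd",
      "acf_x", "acf_y",
      "radial_q1", "radial_q2", "radial_q3", "radial_q4",
      .haralick_names),
    per_well = c("total_proliferation", "organoid_count", "n_objects_3d",
                 "bg_noise_sd", "focus_retained_frac"),
    corr = c("cell_polarity", "cell_polarity_sd", "nuclei_per_organoid",
             "nuclei_area_per_organoid", "channel_correlation",
             "nuclei_peak_intensity", "unassigned_nuclei_fraction")
  )
}

#' Names of the full 294-entry well feature vector
#'
#' Stable across wells; pairs of `.mean` / `.sd` aggregates per base feature.
#'
#' @return character vector of length 294.
#' @export
feature_vector_names <- function() {
  b <- battery_base_names()
  per_channel <- c(b$per_object, b$per_well)
  nm <- c(paste0("actin.", rep(per_channel, each = 2), c(".mean", ".sd")),
          paste0("nuclei.", rep(per_channel, each = 2), c(".mean", ".sd")),
          paste0("corr.", rep(b$corr, each = 2), c(".mean", ".sd")))
  stopifnot(length(nm) == 294L)
  nm
}

skewness0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

kurtosis0 <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}

entropy32 <- function(x) {
  r <- range(x)
  if (diff(r) < 1e-12) return(0)
  p <- tabulate(pmin(32L, 1L + floor((x - r[1]) / diff(r) * 32)), 32L)
  p <- p[p > 0] / length(x)
  -sum(p * log(p))
}

# deterministic evenly spaced subsample of 1..n
subsample_idx <- function(n, m) {
  if (n <= m) seq_len(n) else unique(round(seq(1, n, length.out = m)))
}

# per-object descriptors of one mask (everything except the haralick block);
# intensity statistics use a fixed-size subsample of the eroded interior so
# they carry neither mask-size nor boundary-shape information
per_mask_features <- function(mask, img, n_px = 128L, n_bd = 64L) {
  px <- mask_pixels(mask)
  h <- nrow(img); w <- ncol(img)
  akey <- px[, 2] * (w + 1L) + px[, 1]
  # eroded interior: pixels at least 3 px (distance transform) from background
  bb <- mask_bbox_matrix(mask)
  dm <- as.matrix(EBImage::distmap(bb$m))
  dv <- dm[cbind(px[, 2] - bb$y0 + 1L, px[, 1] - bb$x0 + 1L)]
  core <- px[dv >= 3, , drop = FALSE]
  if (nrow(core) < 16L) core <- px
  sub <- core[subsample_idx(nrow(core), n_px), , drop = FALSE]
  v <- img[cbind(sub[, 2], sub[, 1])]
  q <- stats::quantile(v, c(0.05, 0.10, 0.25, 0.75, 0.90, 0.95), names = FALSE)
  m <- mean(v); s <- sd0(v)
  # local background: expanded bounding box minus the mask, subsampled
  x0 <- max(1L, min(px[, 1]) - 4L); x1 <- min(w, max(px[, 1]) + 4L)
  y0 <- max(1L, min(px[, 2]) - 4L); y1 <- min(h, max(px[, 2]) + 4L)
  bgi <- expand.grid(x = x0:x1, y = y0:y1)
  bgi <- bgi[!((bgi$y * (w + 1L) + bgi$x) %in% akey), , drop = FALSE]
  bgi <- bgi[subsample_idx(nrow(bgi), n_bd), , drop = FALSE]
  bg_mean <- if (nrow(bgi)) mean(img[cbind(bgi$y, bgi$x)]) else 0
  east <- img[cbind(sub[, 2], pmin(sub[, 1] + 1L, w))]
  west <- img[cbind(sub[, 2], pmax(sub[, 1] - 1L, 1L))]
  south <- img[cbind(pmin(sub[, 2] + 1L, h), sub[, 1])]
  north <- img[cbind(pmax(sub[, 2] - 1L, 1L), sub[, 1])]
  gx <- (east - west) / 2
  gy <- (south - north) / 2
  g <- sqrt(gx^2 + gy^2)
  lap <- east + west + south + north - 4 * v
  local_range <- pmax(east, west, south, north, v) -
    pmin(east, west, south, north, v)
  acf_dir <- function(dx, dy) {
    x2 <- sub[, 1] + dx; y2 <- sub[, 2] + dy
    ok <- (y2 * (w + 1L) + x2) %in% akey &
      x2 >= 1L & x2 <= w & y2 >= 1L & y2 <= h
    if (sum(ok) < 3) return(0)
    a <- v[ok]; b <- img[cbind(y2[ok], x2[ok])]
    if (sd0(a) == 0 || sd0(b) == 0) return(0)
    stats::cor(a, b)
  }
  # distance-to-boundary quartile rings (scaled per object), each ring
  # represented by a fixed-size subsample
  dmax <- max(dv)
  ring <- if (dmax > 0) pmin(4L, 1L + floor(dv / dmax * 4)) else rep(1L, nrow(px))
  ring_mean <- vapply(1:4, function(k) {
    rk <- which(ring == k)
    if (!length(rk) || m == 0) return(1)
    rk <- rk[subsample_idx(length(rk), 32L)]
    mean(img[cbind(px[rk, 2], px[rk, 1])]) / m
  }, numeric(1))
  c(area = nrow(px),
    invasion_inhibition = if (nrow(px) >= 2) invasion_inhibition(px) else NA_real_,
    organoid_branching = organoid_branching(px),
    int_mean = m, int_sd = s, int_cv = if (m != 0) s / m else 0,
    int_min = min(v), int_max = max(v), int_range = diff(range(v)),
    int_median = stats::median(v), int_mad = stats::mad(v),
    int_q05 = q[1], int_q10 = q[2], int_q25 = q[3], int_q75 = q[4],
    int_q90 = q[5], int_q95 = q[6], int_iqr = q[4] - q[3],
    int_skewness = skewness0(v), int_kurtosis = kurtosis0(v),
    int_entropy = entropy32(v),
    int_energy = if (diff(range(v)) > 0)
      mean(((v - min(v)) / diff(range(v)))^2) else 0,
    int_trimmed_mean = mean(v, trim = 0.1),
    local_range_mean = mean(local_range),
    acf_diag = acf_dir(1L, 1L),
    int_diff_mean = mean(abs(east - v)),
    bg_contrast = m - bg_mean,
    grad_mean = mean(g), grad_sd = sd0(g), grad_max = max(g),
    grad_median = stats::median(g), lap_mean = mean(abs(lap)),
    lap_sd = sd0(lap),
    acf_x = acf_dir(1L, 0L), acf_y = acf_dir(0L, 1L),
    radial_q1 = ring_mean[1], radial_q2 = ring_mean[2],
    radial_q3 = ring_mean[3], radial_q4 = ring_mean[4])
}

# texture block: Haralick features on a fixed square patch centred at the
# mask's interior centre (distance-transform argmax). Masks too small to
# contain the patch yield NA (excluded from the well aggregate).
haralick_block <- function(masks, arr, half_width = 4L) {
  out <- matrix(NA_real_, length(masks), 26L,
                dimnames = list(NULL, .haralick_names))
  if (!length(masks)) return(out)
  for (i in seq_along(masks)) {
    mask <- masks[[i]]
    px <- mask$pixels
    bb <- mask_bbox_matrix(mask)
    dm <- as.matrix(EBImage::distmap(bb$m))
    ctr <- which(dm == max(dm), arr.ind = TRUE)[1, ]
    cx <- ctr[2] + bb$x0 - 1L; cy <- ctr[1] + bb$y0 - 1L
    xs <- (cx - half_width):(cx + half_width)
    ys <- (cy - half_width):(cy + half_width)
    if (min(xs) < 1L || min(ys) < 1L || max(xs) > dim(arr)[2] ||
        max(ys) > dim(arr)[1]) next
    patch_keys <- rep(ys, each = length(xs)) * (dim(arr)[2] + 1L) +
      rep(xs, times = length(ys))
    if (!all(patch_keys %in% (px[, 2] * (dim(arr)[2] + 1L) + px[, 1]))) next
    ref <- pmin(pmax(arr[ys, xs, mask$section], 0), 1)
    lab <- matrix(1L, length(ys), length(xs))
    hf <- tryCatch(EBImage::computeFeatures.haralick(lab, ref = ref),
                   error = function(e) NULL)
    if (!is.null(hf) && ncol(hf) == 26L) out[i, ] <- hf[1, ]
  }
  out
}

channel_observation_matrix <- function(masks, arr, half_width = 4L) {
  b <- battery_base_names()$per_object
  if (!length(masks)) {
    return(matrix(NA_real_, 0, length(b), dimnames = list(NULL, b)))
  }
  core <- t(vapply(masks, function(m) per_mask_features(m, arr[, , m$section]),
                   numeric(39)))
  hh <- haralick_block(masks, arr, half_width = half_width)
  obs <- cbind(core, hh)
  colnames(obs) <- b
  obs
}

channel_well_features <- function(masks, arr, organoid_like_count,
                                  retained_fraction) {
  mid <- ceiling(dim(arr)[3] / 2)
  img <- arr[, , mid]
  # background noise estimated away from any mask (inflated bounding boxes)
  excl <- matrix(FALSE, nrow(img), ncol(img))
  for (m in masks) {
    px <- m$pixels
    x0 <- max(1L, min(px[, 1]) - 8L); x1 <- min(ncol(img), max(px[, 1]) + 8L)
    y0 <- max(1L, min(px[, 2]) - 8L); y1 <- min(nrow(img), max(px[, 2]) + 8L)
    excl[y0:y1, x0:x1] <- TRUE
  }
  bgv <- img[!excl]
  c(total_proliferation = total_proliferation(masks),
    organoid_count = organoid_count(masks),
    n_objects_3d = organoid_like_count,
    bg_noise_sd = if (length(bgv) > 1) stats::mad(bgv) else 0,
    focus_retained_frac = retained_fraction)
}

# correlative observations; each element a numeric vector of per-observation
# values. Polarity observations are pooled per linked organoid (over its
# sections), so each observation rests on the organoid's full, size-
# independent complement of nuclei.
correlative_observations <- function(seg, stack) {
  pol_mean <- numeric(0); pol_sd <- numeric(0)
  chan_cor <- numeric(0); npo <- numeric(0); nao <- numeric(0)
  peak <- numeric(0)
  w <- stack$geometry$width
  for (ob in seg$organoids) {
    ch <- ob$children
    npo <- c(npo, if (is.null(ch)) 0 else nrow(ch))
    nao <- c(nao, if (is.null(ch) || !nrow(ch)) 0 else sum(ch$area))
    if (!is.null(ch) && nrow(ch)) {
      pk <- vapply(seq_len(nrow(ch)), function(i) {
        stack$nuclei[round(ch$y[i]), round(ch$x[i]), ch$section[i]]
      }, numeric(1))
      peak <- c(peak, mean(pk))
    }
    dists <- numeric(0)
    for (m in ob$masks) {
      sub <- m$pixels[subsample_idx(nrow(m$pixels), 128L), , drop = FALSE]
      a <- stack$actin[, , m$section][cbind(sub[, 2], sub[, 1])]
      n <- stack$nuclei[, , m$section][cbind(sub[, 2], sub[, 1])]
      if (length(a) >= 3 && sd0(a) > 0 && sd0(n) > 0) {
        chan_cor <- c(chan_cor, stats::cor(a, n))
      }
      if (!is.null(ch) && nrow(ch)) {
        in_sec <- ch[ch$section == m$section, , drop = FALSE]
        if (nrow(in_sec)) {
          cp <- cell_polarity(m, cbind(in_sec$x, in_sec$y))
          dists <- c(dists, cp$distances)
        }
      }
    }
    if (length(dists)) {
      pol_mean <- c(pol_mean, mean(dists))
      pol_sd <- c(pol_sd, sd0(dists))
    }
  }
  n_nuc <- nrow(seg$nuclei)
  unafrac <- if (n_nuc) length(seg$unassigned) / n_nuc else 0
  list(cell_polarity = pol_mean, cell_polarity_sd = pol_sd,
       nuclei_per_organoid = npo, nuclei_area_per_organoid = nao,
       channel_correlation = chan_cor, nuclei_peak_intensity = peak,
       unassigned_nuclei_fraction = unafrac)   # per-well scalar
}

#' Extract the full 294-entry feature vector of one well
#'
#' Computes 70 morphological features per channel (65 per-object/per-section
#' descriptors plus 5 per-well descriptors) and 7 two-channel correlative
#' features, then aggregates object observations per well by mean and
#' standard deviation. Per-well features enter with their SD aggregate fixed
#' at 0; the SD of a single observation is 0 by convention. A well without
#' any segmented organoid yields missing (NA) object aggregates.
#'
#' @param stack an `image_stack`.
#' @param seg result of [segment_well()]; computed when omitted.
#' @return named numeric vector of length 294 (see [feature_vector_names()]),
#'   with attribute `n_observations`.
#' @export
extract_feature_battery <- function(stack, seg = NULL) {
  if (is.null(seg)) seg <- segment_well(stack)
  agg <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) c(NA_real_, NA_real_) else c(mean(x), sd0(x))
  }
  out <- numeric(0)
  for (chan in c("actin", "nuclei")) {
    masks <- if (chan == "actin") seg$actin_masks else seg$nuclei_masks
    arr <- stack[[chan]]
    obs <- channel_observation_matrix(masks, arr,
                                      half_width = if (chan == "actin") 4L else 1L)
    per_obj <- as.vector(apply(obs, 2, agg))
    n3d <- if (chan == "actin") length(seg$organoids) else {
      length(link_sections_by_overlap(masks, width = stack$geometry$width))
    }
    pw <- channel_well_features(masks, arr, n3d, seg$retained_fraction)
    per_well <- as.vector(rbind(pw, 0))
    out <- c(out, per_obj, per_well)
  }
  co <- correlative_observations(seg, stack)
  corr <- unlist(lapply(battery_base_names()$corr, function(nm) {
    x <- co[[nm]]
    if (nm == "unassigned_nuclei_fraction") c(x, 0) else agg(x)
  }))
  out <- c(out, corr)
  names(out) <- feature_vector_names()
  attr(out, "n_observations") <- length(seg$actin_masks)
  out
}

#' Z-score normalize a feature table against buffer controls
#'
#' Each feature is centred and scaled by the mean and sample SD of the
#' buffer-control wells across the experiment. Features whose buffer SD is
#' (numerically) zero or undefined cannot be normalized and are excluded from
#' the returned table; their names are recorded in the `excluded` attribute
#' and reported via a message.
#'
#' @param table numeric matrix, wells x features, rownames = well ids.
#' @param map plate map data.frame with columns `well` and `role`.
#' @param tol SD below which a feature counts as constant.
#' @return normalized matrix (attributes `excluded`, `center`, `scale`).
#' @export
zscore_normalize <- function(table, map, tol = 1e-8) {
  buf <- map$well[map$role == "buffer"]
  buf <- intersect(buf, rownames(table))
  if (length(buf) < 2L) stopf("z-score normalization needs >= 2 buffer wells")
  ctr <- apply(table[buf, , drop = FALSE], 2, mean)
  scl <- apply(table[buf, , drop = FALSE], 2, stats::sd)
  bad <- !is.finite(ctr) | !is.finite(scl) | scl < tol
  excluded <- colnames(table)[bad]
  if (length(excluded)) {
    message(sprintf("zscore_normalize: excluding %d constant/undefined feature(s) among buffer wells",
                    length(excluded)))
  }
  keep <- which(!bad)
  z <- sweep(sweep(table[, keep, drop = FALSE], 2, ctr[keep], "-"),
             2, scl[keep], "/")
  attr(z, "excluded") <- excluded
  attr(z, "center") <- ctr[keep]
  attr(z, "scale") <- scl[keep]
  z
}
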