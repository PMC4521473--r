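# Per-section segmentation, out-of-focus filtering, overlap-ratio linking of
# section masks into 3-D organoid objects, and assignment of nuclei as
# children of their parent organoid.
#
# The per-section segmenter is a documented substitute for the screen
# software's proprietary method: rolling-ball style background subtraction
# (morphological opening), a channel-global Otsu threshold with a robust
# noise floor, 8-connected components, and a watershed split of touching
# blobs for the nuclei channel.

default_segmentation_params <- function(channel = c("actin", "nuclei")) {
  channel <- match.arg(channel)
  if (channel == "actin") {
    list(min_area = 20L, bg_radius = 21L, noise_k = 6, watershed = FALSE,
         threshold = NULL, pre_subtracted = FALSE)
  } else {
    list(min_area = 12L, bg_radius = 11L, noise_k = 6, watershed = TRUE,
         threshold = NULL, pre_subtracted = FALSE)
  }
}

# merge 4-connected labels that touch diagonally, yielding 8-connectivity
merge_diagonal_labels <- function(lab) {
  mx <- max(lab)
  if (mx < 2L) return(lab)
  parent <- uf_new(mx)
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nrow(lab) - 1L),
             if (off[2] > 0) seq_len(ncol(lab) - 1L) else 2L:ncol(lab)]
    b <- lab[2L:nrow(lab),
             if (off[2] > 0) 2L:ncol(lab) else seq_len(ncol(lab) - 1L)]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(pairs))) {
        parent <- uf_union(parent, pairs[i, 1], pairs[i, 2])
      }
    }
  }
  comp <- uf_components(parent)
  out <- lab
  out[lab > 0L] <- comp[lab[lab > 0L]]
  out
}

# rolling-ball style background subtraction (grayscale opening with a disc)
bg_subtract <- function(img, bg_radius) {
  bg <- as.matrix(EBImage::opening(
    img, EBImage::makeBrush(2L * as.integer(bg_radius) + 1L, "disc")))
  pmin(pmax(img - bg, 0), 1)
}

# Otsu threshold with a robust noise floor: plain Otsu splits the noise band
# on (near-)empty images, so the threshold is kept above median + k * MAD.
robust_threshold <- function(sub, noise_k) {
  th <- EBImage::otsu(EBImage::Image(matrix(sub, ncol = 1)), range = c(0, 1))
  max(th, stats::median(sub) + noise_k * stats::mad(sub))
}

#' Segment one section image into masks
#'
#' Background is estimated by grayscale opening with a disc (rolling-ball
#' style) and subtracted; an Otsu threshold binarises the section, with a
#' robust noise floor (`median + noise_k * MAD` of the background-subtracted
#' image) guarding against Otsu splitting the noise band on near-empty
#' sections; 8-connected components above the minimum area become masks. For
#' the nuclei channel, touching blobs are additionally split by a watershed
#' on the distance map. A constant or blank section yields an empty list.
#' [segment_well()] passes a single channel-global threshold (computed from
#' the pooled background-subtracted stack) via `params$threshold`, so all
#' sections of a well are binarised consistently.
#'
#' @param img numeric matrix (rows = y, columns = x) on the `[0, 1]` scale.
#' @param channel `"actin"` or `"nuclei"`.
#' @param params list overriding [default_segmentation_params()]:
#'   `min_area`, `bg_radius`, `noise_k`, `watershed`, `threshold`
#'   (absolute threshold on the background-subtracted image; computed when
#'   NULL), `pre_subtracted` (skip background subtraction).
#' @param section 1-based section index recorded on the masks.
#' @return list of [section_mask()]; each carries a `centroid` attribute.
#' @export
segment_section <- function(img, channel = "actin", params = list(),
                            section = 1L) {
  if (!all(is.finite(img))) stopf("section image has non-finite intensities")
  p <- utils::modifyList(default_segmentation_params(channel), params)
  rng <- range(img)
  if (diff(rng) < 1e-9) return(list())
  sub <- if (isTRUE(p$pre_subtracted)) img else bg_subtract(img, p$bg_radius)
  th <- if (is.null(p$threshold)) robust_threshold(sub, p$noise_k) else p$threshold
  bw <- matrix(as.integer(sub > th), nrow(img), ncol(img))
  if (!any(bw == 1L)) return(list())
  if (isTRUE(p$watershed)) {
    lab <- EBImage::imageData(EBImage::watershed(EBImage::distmap(bw), tolerance = 1))
    lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  } else {
    lab <- matrix(as.integer(EBImage::imageData(EBImage::bwlabel(bw))),
                  nrow(img), ncol(img))
    lab <- merge_diagonal_labels(lab)
  }
  masks <- list()
  for (id in setdiff(sort(unique(as.integer(lab))), 0L)) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < p$min_area) next
    m <- section_mask(cbind(idx[, 2], idx[, 1]), section = section,
                      channel = channel)
    attr(m, "centroid") <- c(x = mean(idx[, 2]), y = mean(idx[, 1]))
    masks[[length(masks) + 1L]] <- m
  }
  masks
}

# boundary sharpness of one mask: mean gradient magnitude on the boundary,
# normalised by the mean interior intensity
mask_sharpness <- function(mask, img) {
  px <- mask_pixels(mask)
  pb <- boundary_pixels(mask)
  h <- nrow(img); w <- ncol(img)
  gx <- (img[cbind(pb[, 2], pmin(pb[, 1] + 1L, w))] -
           img[cbind(pb[, 2], pmax(pb[, 1] - 1L, 1L))]) / 2
  gy <- (img[cbind(pmin(pb[, 2] + 1L, h), pb[, 1])] -
           img[cbind(pmax(pb[, 2] - 1L, 1L), pb[, 1])]) / 2
  g <- mean(sqrt(gx^2 + gy^2))
  interior <- mean(img[cbind(px[, 2], px[, 1])])
  if (interior <= 0) return(0)
  g / interior
}

#' Discard out-of-focus section masks
#'
#' A mask is discarded when its boundary sharpness score (mean gradient
#' magnitude along the mask boundary divided by the mean interior intensity)
#' falls below `sharpness_min`. The default threshold of 0.2 was calibrated
#' on synthetic fixtures: in-focus boundaries of rendered organoids score
#' around 0.4 and sections blurred with a sigma >= 3 px Gaussian fall below
#' 0.1.
#'
#' @param masks list of [section_mask()] (possibly several sections).
#' @param images the stack array (`height x width x sections`) or a single
#'   section matrix.
#' @param sharpness_min minimum retained sharpness score.
#' @return the retained masks.
#' @export
filter_out_of_focus <- function(masks, images, sharpness_min = 0.2) {
  if (!length(masks) || sharpness_min <= 0) return(masks)
  get_img <- function(si) {
    if (length(dim(images)) == 3L) images[, , si] else images
  }
  keep <- vapply(masks, function(m) {
    is.finite(sharpness_min) &&
      mask_sharpness(m, get_img(m$section)) >= sharpness_min
  }, logical(1))
  masks[keep]
}

#' Link section masks into 3-D organoid objects by overlap ratio
#'
#' Masks in adjacent sections are merged into one object when their overlap
#' ratio `|A intersect B| / min(|A|, |B|)` is at least `min_overlap_ratio`;
#' linking is transitive, and every mask ends up in exactly one object.
#'
#' @param masks list of [section_mask()] from one channel of one well.
#' @param min_overlap_ratio minimum overlap ratio (default 0.5).
#' @param width canvas width (used to key pixels; defaults to the extent of
#'   the masks).
#' @return list of `organoid_object`s: each has `object_id`, `masks`
#'   (ordered by section, each carrying an `object_id` attribute) and an
#'   empty `children` slot.
#' @export
link_sections_by_overlap <- function(masks, min_overlap_ratio = 0.5,
                                     width = NULL) {
  if (!length(masks)) return(list())
  if (is.null(width)) {
    width <- max(vapply(masks, function(m) max(m$pixels[, 1]), numeric(1))) + 1L
  }
  keys <- lapply(masks, function(m) m$pixels[, 2] * width + m$pixels[, 1])
  secs <- vapply(masks, function(m) m$section, integer(1))
  parent <- uf_new(length(masks))
  for (s in sort(unique(secs))) {
    ia <- which(secs == s); ib <- which(secs == s + 1L)
    if (!length(ia) || !length(ib)) next
    for (i in ia) for (j in ib) {
      inter <- sum(keys[[i]] %in% keys[[j]])
      if (inter == 0L) next
      ratio <- inter / min(length(keys[[i]]), length(keys[[j]]))
      if (ratio >= min_overlap_ratio) parent <- uf_union(parent, i, j)
    }
  }
  comp <- uf_components(parent)
  objs <- vector("list", max(comp))
  for (oid in seq_len(max(comp))) {
    mi <- which(comp == oid)
    mi <- mi[order(secs[mi])]
    ms <- masks[mi]
    for (k in seq_along(ms)) attr(ms[[k]], "object_id") <- oid
    objs[[oid]] <- structure(list(object_id = oid, masks = ms,
                                  children = NULL),
                             class = "organoid_object")
  }
  objs
}

#' Extract nucleus objects from nuclei-channel masks
#'
#' @param masks nuclei-channel [section_mask()] list.
#' @return data.frame with `nucleus_id`, `section`, `x`, `y` (mass centre)
#'   and `area`.
#' @export
nucleus_objects <- function(masks) {
  if (!length(masks)) {
    return(data.frame(nucleus_id = integer(), section = integer(),
                      x = numeric(), y = numeric(), area = integer()))
  }
  do.call(rbind, lapply(seq_along(masks), function(i) {
    px <- masks[[i]]$pixels
    data.frame(nucleus_id = i, section = masks[[i]]$section,
               x = mean(px[, 1]), y = mean(px[, 2]), area = nrow(px))
  }))
}

#' Assign nuclei as children of organoids
#'
#' A nucleus is attached to the organoid whose same-section mask contains its
#' mass centre; when no mask contains it, to the nearest mask within
#' `max_dist` pixels; otherwise it is left unassigned. Each nucleus gets at
#' most one parent.
#'
#' @param organoids list of `organoid_object`s (actin channel).
#' @param nuclei data.frame from [nucleus_objects()].
#' @param max_dist maximum centre-to-mask distance for fallback assignment.
#' @return list with `organoids` (children filled in as rows of `nuclei`
#'   plus a `parent` column) and `unassigned` (nucleus ids).
#' @export
assign_nuclei <- function(organoids, nuclei, max_dist = 5) {
  parent <- rep(NA_integer_, nrow(nuclei))
  if (nrow(nuclei) && length(organoids)) {
    for (i in seq_len(nrow(nuclei))) {
      s <- nuclei$section[i]
      cx <- nuclei$x[i]; cy <- nuclei$y[i]
      best <- NA_integer_; best_d <- Inf
      for (ob in organoids) {
        for (m in ob$masks) {
          if (m$section != s) next
          px <- m$pixels
          hit <- any(abs(px[, 1] - cx) <= 0.5 & abs(px[, 2] - cy) <= 0.5)
          if (hit) { best <- ob$object_id; best_d <- 0; break }
          d <- sqrt(min((px[, 1] - cx)^2 + (px[, 2] - cy)^2))
          if (d < best_d) { best_d <- d; best <- ob$object_id }
        }
        if (identical(best_d, 0)) break
      }
      if (is.finite(best_d) && (best_d == 0 || best_d <= max_dist)) {
        parent[i] <- best
      }
    }
  }
  nuclei$parent <- parent
  organoids <- lapply(organoids, function(ob) {
    ob$children <- nuclei[!is.na(parent) & parent == ob$object_id, ,
                          drop = FALSE]
    ob
  })
  list(organoids = organoids, nuclei = nuclei,
       unassigned = nuclei$nucleus_id[is.na(parent)])
}

#' Segment a whole well
#'
#' Runs the full per-well flow: background subtraction per section, one
#' channel-global Otsu threshold over the pooled stack (so mask extents do
#' not drift between sections), per-section labelling of both channels,
#' out-of-focus filtering, overlap-ratio linking of actin masks into
#' organoids, nucleus extraction and parent assignment.
#'
#' @param stack an `image_stack`.
#' @param actin_params,nuclei_params per-channel overrides of
#'   [default_segmentation_params()].
#' @param sharpness_min focus threshold, see [filter_out_of_focus()].
#' @param min_overlap_ratio see [link_sections_by_overlap()].
#' @param max_dist see [assign_nuclei()].
#' @return list with `organoids`, `nuclei`, `actin_masks`, `nuclei_masks`,
#'   `retained_fraction` (masks surviving the focus filter) and `unassigned`.
#' @export
segment_well <- function(stack, actin_params = list(), nuclei_params = list(),
                         sharpness_min = 0.2, min_overlap_ratio = 0.5,
                         max_dist = 5) {
  s <- stack$geometry$sections
  seg_channel <- function(arr, channel, params) {
    p <- utils::modifyList(default_segmentation_params(channel), params)
    subs <- lapply(seq_len(s), function(si) bg_subtract(arr[, , si], p$bg_radius))
    if (is.null(p$threshold)) {
      p$threshold <- robust_threshold(unlist(subs), p$noise_k)
    }
    p$pre_subtracted <- TRUE
    out <- list()
    for (si in seq_len(s)) {
      out <- c(out, segment_section(subs[[si]], channel, p, section = si))
    }
    out
  }
  actin_masks <- seg_channel(stack$actin, "actin", actin_params)
  nuclei_masks <- seg_channel(stack$nuclei, "nuclei", nuclei_params)
  n_before <- length(actin_masks) + length(nuclei_masks)
  actin_masks <- filter_out_of_focus(actin_masks, stack$actin, sharpness_min)
  nuclei_masks <- filter_out_of_focus(nuclei_masks, stack$nuclei, sharpness_min)
  n_after <- length(actin_masks) + length(nuclei_masks)
  organoids <- link_sections_by_overlap(actin_masks, min_overlap_ratio,
                                        width = stack$geometry$width)
  nuc <- nucleus_objects(nuclei_masks)
  asg <- assign_nuclei(organoids, nuc, max_dist = max_dist)
  list(organoids = asg$organoids, nuclei = asg$nuclei,
       actin_masks = actin_masks, nuclei_masks = nuclei_masks,
       retained_fraction = if (n_before) n_after / n_before else 1,
       unassigned = asg$unassigned)
}
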