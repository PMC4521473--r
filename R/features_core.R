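# The six formula-defined morphology features, operating on per-section
# binary masks. A mask is a set of pixel centres at integer (x, y)
# coordinates; distances are Euclidean between pixel centres and the boundary
# is defined by 8-adjacency to background (the canvas edge counts as
# background).

#' Construct a per-section mask
#'
#' @param pixels two-column integer matrix of (x, y) pixel coordinates.
#' @param section 0-based section (z) index.
#' @param channel "actin" or "nuclei".
#' @return an object of class `section_mask`.
#' @export
section_mask <- function(pixels, section = 0L, channel = "actin") {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L || nrow(pixels) < 1L) {
    stopf("a section mask needs a non-empty two-column (x, y) pixel matrix")
  }
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("x", "y")
  structure(list(pixels = pixels, section = as.integer(section),
                 channel = channel),
            class = "section_mask")
}

mask_pixels <- function(mask) {
  if (inherits(mask, "section_mask")) mask$pixels else {
    px <- as.matrix(mask)
    colnames(px) <- c("x", "y")
    px
  }
}

#' Binary bounding-box matrix of a mask
#'
#' Renders the mask's pixel set into a binary matrix over its bounding box
#' with a 1-pixel background pad.
#'
#' @inheritParams per_organoid_size
#' @return list with `m` (binary matrix, rows = y, cols = x) and offsets
#'   `x0`, `y0` mapping matrix indices back to pixel coordinates
#'   (`x = col + x0 - 1`, `y = row + y0 - 1`).
#' @export
mask_bbox_matrix <- function(mask) {
  px <- mask_pixels(mask)
  x0 <- min(px[, 1]) - 1L; y0 <- min(px[, 2]) - 1L
  m <- matrix(0L, max(px[, 2]) - y0 + 2L, max(px[, 1]) - x0 + 2L)
  m[cbind(px[, 2] - y0 + 1L, px[, 1] - x0 + 1L)] <- 1L
  list(m = m, x0 = x0, y0 = y0)
}

#' Per-organoid size
#'
#' The geometric area of an organoid's section mask: its pixel count.
#'
#' @param mask a [section_mask()] or (x, y) pixel matrix.
#' @return area in pixels.
#' @export
per_organoid_size <- function(mask) {
  nrow(mask_pixels(mask))
}

#' Major axis of a mask
#'
#' Maximum Euclidean distance between any two pixel centres. The maximum is
#' attained on the convex hull, which is used to avoid the full quadratic
#' search on large masks.
#'
#' @inheritParams per_organoid_size
#' @return distance in pixels (0 for a single-pixel mask).
#' @export
major_axis <- function(mask) {
  px <- mask_pixels(mask)
  if (nrow(px) == 1L) return(0)
  pts <- px
  if (nrow(px) > 3L) {
    h <- grDevices::chull(px[, 1], px[, 2])
    pts <- px[h, , drop = FALSE]
  }
  d <- stats::dist(pts)
  max(d)
}

#' Invasion inhibition (per-organoid roundness)
#'
#' `4 * area / (pi * major_axis^2)`: close to 1 for a disk, lower for
#' elongated or branched (invasive) shapes.
#'
#' @inheritParams per_organoid_size
#' @return dimensionless roundness value.
#' @export
invasion_inhibition <- function(mask) {
  px <- mask_pixels(mask)
  if (nrow(px) < 2L) {
    stopf("invasion inhibition is undefined for a single-pixel mask (major axis = 0)")
  }
  d <- major_axis(px)
  4 * nrow(px) / (pi * d^2)
}

#' Total proliferation of a well
#'
#' Accumulated organoid mask area over the whole stack:
#' the sum of [per_organoid_size()] over every retained section mask.
#'
#' @param masks list of section masks (actin channel) from one well.
#' @return total area in pixels.
#' @export
total_proliferation <- function(masks) {
  if (!length(masks)) return(0)
  sum(vapply(masks, per_organoid_size, numeric(1)))
}

#' Organoid count of a well
#'
#' As printed in the defining formula, the sum over sections of the
#' per-section organoid mask count `n_i`; a 3-D object spanning several
#' sections contributes once per section. The alternative reading (count of
#' distinct linked 3-D objects) is available via `distinct = TRUE`.
#'
#' @param masks list of section masks (actin channel) from one well.
#' @param distinct if `TRUE`, count distinct linked objects instead; this
#'   requires masks carrying an `object_id` attribute (as produced by
#'   [link_sections_by_overlap()]).
#' @return organoid count.
#' @export
organoid_count <- function(masks, distinct = FALSE) {
  if (!length(masks)) return(0L)
  if (!distinct) return(length(masks))
  ids <- vapply(masks, function(m) {
    id <- attr(m, "object_id")
    if (is.null(id)) NA_integer_ else as.integer(id)
  }, integer(1))
  if (anyNA(ids)) stopf("distinct organoid count needs linked masks with object ids")
  length(unique(ids))
}

#' Boundary pixels of a mask
#'
#' Mask pixels 8-adjacent to at least one background pixel (the canvas edge
#' counts as background).
#'
#' @inheritParams per_organoid_size
#' @return two-column (x, y) matrix of boundary pixel centres.
#' @export
boundary_pixels <- function(mask) {
  bb <- mask_bbox_matrix(mask)
  m <- bb$m
  nb <- Reduce(`+`, lapply(.zs_off, function(o) shift_mat(m, -o[1], -o[2])))
  edge <- m == 1L & nb < 8L
  idx <- which(edge, arr.ind = TRUE)
  cbind(x = idx[, 2] + bb$x0 - 1L, y = idx[, 1] + bb$y0 - 1L)
}

#' Cell polarity of one organoid section
#'
#' For each child nucleus, the shortest Euclidean distance from its mass
#' centre to any boundary pixel of the organoid's section mask; the feature
#' is the mean of these minima and their standard deviation. A hollow,
#' polarised organoid (nuclei lining a lumen near the boundary) yields a low
#' mean with a low standard deviation; a solid organoid with scattered nuclei
#' yields higher values of both.
#'
#' @param mask the organoid's section mask.
#' @param nuclei_centers two-column (x, y) matrix of nucleus mass centres in
#'   the same section.
#' @return list with `mean`, `sd` (0 for a single nucleus) and `distances`.
#' @export
cell_polarity <- function(mask, nuclei_centers) {
  nc <- as.matrix(nuclei_centers)
  if (!nrow(nc)) stopf("cell polarity is undefined without nuclei in the section")
  pb <- boundary_pixels(mask)
  d <- vapply(seq_len(nrow(nc)), function(i) {
    sqrt(min((pb[, 1] - nc[i, 1])^2 + (pb[, 2] - nc[i, 2])^2))
  }, numeric(1))
  list(mean = mean(d), sd = sd0(d), distances = d)
}

#' Organoid branching of a mask
#'
#' The mask is skeletonized and decomposed into a graph of vertices
#' (endpoints and junctions) and edges (skeleton pixel paths). A branch is an
#' edge with one and only one single-connected (degree-1) vertex; the feature
#' is the mean branch length in pixels, 0 when no branch exists (e.g. a
#' compact disk whose skeleton is a bare segment or point).
#'
#' @inheritParams per_organoid_size
#' @return mean branch length in pixels.
#' @export
organoid_branching <- function(mask) {
  bb <- mask_bbox_matrix(mask)
  skeleton_stats(bb$m)$mean_branch_length
}
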