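# Rendering of synthetic two-channel image stacks with exact ground truth.
# Organoids are spheroids (ellipsoidal footprint, spherical z profile) with
# optional radial arms and an optional concentric lumen; nuclei are small
# Gaussian-shaded blobs whose half-maximum contour is a disc of the nominal
# nucleus radius, so noise-free stacks threshold back to the exact voxel set.

.levels <- list(bg = 0.05, body = 0.45, nucleus = 0.65)

# quantize to the 16-bit grid so in-memory stacks round-trip through TIFF
quant16 <- function(x) round(pmin(pmax(x, 0), 1) * 65535) / 65535

rot_xy <- function(dx, dy, phi) {
  list(u = cos(phi) * dx + sin(phi) * dy,
       v = -sin(phi) * dx + cos(phi) * dy)
}

# semi-axes of the footprint of `spec` in section `s` (1-based), or NULL
# when the section does not intersect the organoid. Bodies are extruded
# ellipses: the cross-section is constant through the object's depth
# (2 * radius / zscale sections), truncated by the capture window. This
# mimics gel-embedded tissue extending through the imaged depth and keeps
# per-section measurements of one object homoscedastic, while the z extent
# still grows with object size.
section_axes <- function(spec, s, zscale) {
  dz <- (s - spec$center[3]) * zscale
  if (abs(dz) >= spec$radius) return(NULL)
  list(a = spec$radius * sqrt(spec$elongation),
       b = spec$radius / sqrt(spec$elongation),
       g = 1)
}

# pixel set (x, y matrix) of one organoid in one section
render_footprint <- function(spec, s, geom, arm_width = 5) {
  ax <- section_axes(spec, s, geom$zscale)
  if (is.null(ax)) return(NULL)
  cx <- spec$center[1]; cy <- spec$center[2]
  reach <- ceiling(ax$a + if (ax$g >= 0.75 && spec$n_branches > 0)
    spec$branch_length + arm_width else 0) + 1L
  xs <- max(1L, floor(cx - reach)):min(geom$width, ceiling(cx + reach))
  ys <- max(1L, floor(cy - reach)):min(geom$height, ceiling(cy + reach))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  rc <- rot_xy(gx - cx, gy - cy, spec$orientation)
  inside <- (rc$u / ax$a)^2 + (rc$v / ax$b)^2 <= 1
  if (spec$hollow) {
    la <- ax$a * spec$lumen_frac; lb <- ax$b * spec$lumen_frac
    inside <- inside & !((rc$u / la)^2 + (rc$v / lb)^2 <= 1)
  }
  if (spec$n_branches > 0 && ax$g >= 0.75 && spec$branch_length > 0) {
    ang <- spec$branch_angles
    for (th in ang) {
      base_u <- ax$a * cos(th); base_v <- ax$b * sin(th)
      nrm <- c(ax$b * cos(th), ax$a * sin(th))
      nrm <- nrm / sqrt(sum(nrm^2))
      tip_u <- base_u + spec$branch_length * nrm[1]
      tip_v <- base_v + spec$branch_length * nrm[2]
      du <- tip_u - base_u; dv <- tip_v - base_v
      seg2 <- du^2 + dv^2
      t <- pmin(1, pmax(0, ((rc$u - base_u) * du + (rc$v - base_v) * dv) / seg2))
      d2 <- (rc$u - (base_u + t * du))^2 + (rc$v - (base_v + t * dv))^2
      inside <- inside | d2 <= (arm_width / 2)^2
    }
  }
  if (!any(inside)) return(NULL)
  cbind(x = gx[inside], y = gy[inside])
}

# choose a nucleus position at `depth` px inside the section footprint,
# or uniformly inside it; returns c(x, y) or NULL when placement failed
place_nucleus <- function(spec, s, geom, existing, min_sep) {
  ax <- section_axes(spec, s, geom$zscale)
  if (is.null(ax)) return(NULL)
  cx <- spec$center[1]; cy <- spec$center[2]
  for (try in 1:40) {
    if (spec$nuclei_placement == "boundary") {
      th <- stats::runif(1, 0, 2 * pi)
      depth <- max(0.8, spec$boundary_depth + stats::rnorm(1, 0, 0.5))
      depth <- min(depth, 0.8 * ax$b)
      nrm <- c(ax$b * cos(th), ax$a * sin(th))
      nrm <- nrm / sqrt(sum(nrm^2))
      u <- ax$a * cos(th) - depth * nrm[1]
      v <- ax$b * sin(th) - depth * nrm[2]
    } else {
      r <- sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
      u <- 0.92 * ax$a * r * cos(th)
      v <- 0.92 * ax$b * r * sin(th)
    }
    x <- cx + cos(spec$orientation) * u - sin(spec$orientation) * v
    y <- cy + sin(spec$orientation) * u + cos(spec$orientation) * v
    rn <- spec$nucleus_radius
    if (x < rn + 1 || y < rn + 1 || x > geom$width - rn || y > geom$height - rn) next
    ok <- TRUE
    if (length(existing)) {
      for (e in existing) {
        if (e[1] == s && (e[2] - x)^2 + (e[3] - y)^2 < min_sep^2) { ok <- FALSE; break }
      }
    }
    if (ok) return(c(x, y))
  }
  NULL
}

#' Render one well's two-channel image stack
#'
#' Produces the actin channel (organoid bodies) and the nuclei channel
#' (nucleus blobs) together with exact ground truth. Identical inputs and
#' seed reproduce bit-identical stacks.
#'
#' @param specs list of [organoid_spec()].
#' @param geometry a [stack_geometry()].
#' @param noise_sd additive Gaussian noise SD on the `[0, 1]` intensity scale.
#' @param defocus_sections integer vector of 1-based section indices to blur
#'   (out-of-focus emulation).
#' @param seed integer seed.
#' @param defocus_sigma Gaussian blur sigma (px) for defocused sections.
#' @return list with `stack` (class `image_stack`: `actin` and `nuclei`
#'   arrays of dim `height x width x sections`, plus `geometry`) and
#'   `ground_truth` (class `ground_truth`: `labels` array of object ids,
#'   `nuclei` data.frame, `specs`).
#' @export
render_well_stack <- function(specs, geometry = stack_geometry(),
                              noise_sd = 0, defocus_sections = integer(0),
                              seed = 1L, defocus_sigma = 4) {
  if (inherits(specs, "organoid_spec")) specs <- list(specs)
  geom <- geometry
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    reach <- sp$radius * sqrt(sp$elongation) +
      (if (sp$n_branches > 0) sp$branch_length + 3 else 0)
    if (sp$center[1] - reach < 0.5 || sp$center[1] + reach > geom$width + 0.5 ||
        sp$center[2] - reach < 0.5 || sp$center[2] + reach > geom$height + 0.5) {
      stopf("organoid spec %d does not fit the canvas (centre %.1f,%.1f reach %.1f)",
            k, sp$center[1], sp$center[2], reach)
    }
  }
  with_seed(seed, {
    # sample arm directions for specs that left them open
    specs <- lapply(specs, function(sp) {
      if (sp$n_branches > 0 && is.null(sp$branch_angles)) {
        sp$branch_angles <- stats::runif(sp$n_branches, 0, 2 * pi)
      }
      sp
    })
    h <- geom$height; w <- geom$width; s <- geom$sections
    actin <- array(.levels$bg, c(h, w, s))
    nuc <- array(.levels$bg, c(h, w, s))
    labels <- array(0L, c(h, w, s))
    for (si in seq_len(s)) {
      for (k in seq_along(specs)) {
        px <- render_footprint(specs[[k]], si, geom)
        if (is.null(px)) next
        idx <- cbind(px[, 2], px[, 1], si)
        free <- labels[idx] == 0L          # first object wins a voxel
        if (!any(free)) next
        labels[idx[free, , drop = FALSE]] <- k
        aidx <- idx[free, , drop = FALSE]
        actin[aidx] <- .levels$body
      }
    }
    # nuclei: placed inside their parent's footprint, one section each
    nuclei <- list(); placed <- list()
    rnmax <- max(vapply(specs, function(sp) sp$nucleus_radius, numeric(1)))
    for (k in seq_along(specs)) {
      sp <- specs[[k]]
      cand <- integer(0)
      for (si in seq_len(s)) {
        ax <- section_axes(sp, si, geom$zscale)
        if (!is.null(ax) && ax$g >= 0.5) cand <- c(cand, si)
      }
      if (!length(cand)) cand <- which.min(abs(seq_len(s) - sp$center[3]))
      for (n in seq_len(sp$nuclei_count)) {
        si <- cand[sample.int(length(cand), 1L)]
        pos <- place_nucleus(sp, si, geom, placed, 2 * rnmax + 2)
        if (is.null(pos)) next
        placed[[length(placed) + 1L]] <- c(si, pos)
        rn <- sp$nucleus_radius
        xs <- max(1L, floor(pos[1] - rn)):min(w, ceiling(pos[1] + rn))
        ys <- max(1L, floor(pos[2] - rn)):min(h, ceiling(pos[2] + rn))
        gx <- rep(xs, times = length(ys)); gy <- rep(ys, each = length(xs))
        d2 <- (gx - pos[1])^2 + (gy - pos[2])^2
        inb <- d2 <= rn^2
        sigma <- rn / sqrt(2 * log(2))    # half-maximum exactly at rn
        val <- .levels$bg +
          (.levels$nucleus - .levels$bg) * exp(-d2[inb] / (2 * sigma^2))
        bidx <- cbind(gy[inb], gx[inb], si)
        nuc[bidx] <- pmax(nuc[bidx], val)
        nuclei[[length(nuclei) + 1L]] <- data.frame(
          nucleus_id = length(nuclei) + 1L, object_id = k, section = si,
          x = mean(gx[inb]), y = mean(gy[inb]),
          true_x = pos[1], true_y = pos[2], area = sum(inb))
      }
    }
    nuclei <- if (length(nuclei)) do.call(rbind, nuclei) else
      data.frame(nucleus_id = integer(), object_id = integer(),
                 section = integer(), x = numeric(), y = numeric(),
                 true_x = numeric(), true_y = numeric(), area = integer())
    if (noise_sd > 0) {
      actin <- actin + stats::rnorm(length(actin), 0, noise_sd)
      nuc <- nuc + stats::rnorm(length(nuc), 0, noise_sd)
    }
    for (si in intersect(defocus_sections, seq_len(s))) {
      actin[, , si] <- as.matrix(EBImage::gblur(actin[, , si], sigma = defocus_sigma))
      nuc[, , si] <- as.matrix(EBImage::gblur(nuc[, , si], sigma = defocus_sigma))
    }
    stack <- structure(list(actin = quant16(actin), nuclei = quant16(nuc),
                            geometry = geom), class = "image_stack")
    gt <- structure(list(labels = labels, nuclei = nuclei, specs = specs),
                    class = "ground_truth")
    list(stack = stack, ground_truth = gt)
  })
}

#' Ground-truth section masks of one object
#'
#' @param gt a `ground_truth` object.
#' @param object_id object id.
#' @return list of [section_mask()], one per section intersected.
#' @export
ground_truth_masks <- function(gt, object_id) {
  out <- list()
  for (si in seq_len(dim(gt$labels)[3])) {
    idx <- which(gt$labels[, , si] == object_id, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[length(out) + 1L]] <- section_mask(cbind(idx[, 2], idx[, 1]),
                                              section = si, channel = "actin")
    }
  }
  out
}

# sample per-well organoid specs from a baseline, with dial shifts applied.
# Parameters are sampled first; centres are then rejection-sampled with a
# pairwise separation that keeps every organoid's arms clear of its
# neighbours' bodies, so objects never merge in the rendered stack.
sample_well_specs <- function(baseline, shift, geom) {
  n <- max(1L, as.integer(round(baseline$n_organoids + shift[["n_organoids"]])))
  par <- vector("list", n)
  for (k in seq_len(n)) {
    area <- max(120, stats::rnorm(1, baseline$area_mean + shift[["area"]],
                                  baseline$area_sd))
    round_t <- stats::rnorm(1, baseline$roundness_mean + shift[["roundness"]],
                            baseline$roundness_sd)
    round_t <- min(0.98, max(0.30, round_t))
    bl <- if (baseline$n_branches > 0) {
      max(0, stats::rnorm(1, baseline$branch_length_mean +
                            shift[["branch_length"]],
                          baseline$branch_length_sd))
    } else 0
    rr <- sqrt(area / pi)
    par[[k]] <- list(radius = rr, roundness = round_t, branch_length = bl,
                     a = rr / sqrt(round_t))   # footprint major semi-axis
  }
  reach <- vapply(par, function(p) p$a + p$branch_length + 3, numeric(1))
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < 8000L) {
    tries <- tries + 1L
    k <- placed + 1L
    m <- reach[k] + 1
    if (geom$width - m <= m || geom$height - m <= m) break
    p <- c(stats::runif(1, m, geom$width - m),
           stats::runif(1, m, geom$height - m))
    ok <- TRUE
    for (j in seq_len(placed)) {
      sep <- par[[k]]$a + par[[j]]$a +
        max(par[[k]]$branch_length, par[[j]]$branch_length) + 3
      if ((centers[j, 1] - p[1])^2 + (centers[j, 2] - p[2])^2 < sep^2) {
        ok <- FALSE; break
      }
    }
    if (ok) {
      centers[k, ] <- p
      placed <- placed + 1L
    }
  }
  specs <- vector("list", placed)
  for (k in seq_len(placed)) {
    depth <- max(0.8, stats::rnorm(1, baseline$nucleus_depth_mean +
                                     shift[["nucleus_depth"]],
                                   baseline$nucleus_depth_sd))
    zc <- stats::runif(1, 1.5, geom$sections - 0.5)
    specs[[k]] <- organoid_spec(
      center = c(centers[k, 1], centers[k, 2], zc), radius = par[[k]]$radius,
      elongation = 1 / par[[k]]$roundness,
      orientation = stats::runif(1, 0, pi),
      n_branches = baseline$n_branches,
      branch_length = par[[k]]$branch_length,
      hollow = isTRUE(baseline$hollow),
      nuclei_count = sample(baseline$nuclei_min:baseline$nuclei_max, 1L),
      nuclei_placement = baseline$nuclei_placement,
      boundary_depth = depth, nucleus_radius = baseline$nucleus_radius)
  }
  specs
}

# dial shifts of one treatment at one dose (quadratic ramp over dose rank)
effect_shift <- function(effect, dose, doses) {
  t <- (match(dose, sort(doses)) - 1) / max(1, length(doses) - 1)
  effect * t^2
}

#' Generate a full synthetic plate
#'
#' Buffer wells are rendered from the unshifted baseline; treatment wells
#' have their phenotype dials moved along the treatment's effect template by
#' dose. With `render = FALSE` only the per-well organoid specifications are
#' generated (used by streaming drivers that render one well at a time).
#'
#' @param plate a [plate_spec()].
#' @param render if `FALSE`, return specs without rendering stacks.
#' @return list with `map` (plate map data.frame), `well_specs` (named list
#'   of per-well organoid spec lists), `well_seeds`, and, when rendered,
#'   `stacks` and `ground_truth` (named lists).
#' @export
generate_plate <- function(plate, render = TRUE) {
  stopifnot(inherits(plate, "plate_spec"))
  map <- plate_map(plate)
  effects <- stats::setNames(lapply(plate$treatments, `[[`, "effect"),
                             vapply(plate$treatments, `[[`, "", "id"))
  dose_sets <- stats::setNames(lapply(plate$treatments, `[[`, "doses"),
                               vapply(plate$treatments, `[[`, "", "id"))
  well_specs <- list(); well_seeds <- integer(0)
  for (i in seq_len(nrow(map))) {
    wseed <- derive_seed(plate$seed, i)
    shift <- effect_templates()$none
    if (map$role[i] == "treatment") {
      shift <- effect_shift(effects[[map$treatment[i]]], map$dose[i],
                            dose_sets[[map$treatment[i]]])
    }
    specs <- with_seed(wseed, sample_well_specs(plate$baseline, shift,
                                                plate$geometry))
    well_specs[[map$well[i]]] <- specs
    well_seeds[map$well[i]] <- derive_seed(wseed, 1L)
  }
  out <- list(map = map, well_specs = well_specs, well_seeds = well_seeds,
              plate = plate)
  if (render) {
    stacks <- list(); gts <- list()
    for (wl in map$well) {
      r <- render_well_stack(well_specs[[wl]], plate$geometry,
                             noise_sd = plate$noise_sd,
                             seed = well_seeds[[wl]])
      stacks[[wl]] <- r$stack
      gts[[wl]] <- r$ground_truth
    }
    out$stacks <- stacks
    out$ground_truth <- gts
  }
  out
}

#' Write an image stack as multi-page 16-bit TIFFs
#'
#' One file per channel (`<well>_actin.tif`, `<well>_nuclei.tif`), section
#' order equal to z order.
#'
#' @param stack an `image_stack`.
#' @param dir output directory.
#' @param well well id used in file names.
#' @return invisibly, the written paths.
#' @export
write_image_stack <- function(stack, dir, well) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in c("actin", "nuclei")) {
    arr <- stack[[ch]]
    pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
    p <- file.path(dir, sprintf("%s_%s.tif", well, ch))
    tiff::writeTIFF(pages, p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param dir directory holding the TIFFs.
#' @param well well id.
#' @param zscale z spacing (not stored in the TIFF).
#' @return an `image_stack`.
#' @export
read_image_stack <- function(dir, well, zscale = 6) {
  arrs <- lapply(c("actin", "nuclei"), function(ch) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", well, ch)),
                            all = TRUE)
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  })
  structure(list(actin = arrs[[1]], nuclei = arrs[[2]],
                 geometry = stack_geometry(dim(arrs[[1]])[3],
                                           dim(arrs[[1]])[1],
                                           dim(arrs[[1]])[2], zscale)),
            class = "image_stack")
}
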