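# Independent brute-force oracles for the formula-defined features.
# These deliberately avoid the package's implementation paths: exhaustive
# pairwise distances, set-lookup boundary detection, exhaustive
# boundary-distance search, and a breadth-first skeleton-path walk.

bf_size <- function(px) nrow(px)

bf_major_axis <- function(px) {
  if (nrow(px) < 2) return(0)
  best <- 0
  for (i in seq_len(nrow(px) - 1)) {
    d <- sqrt((px[i, 1] - px[(i + 1):nrow(px), 1])^2 +
                (px[i, 2] - px[(i + 1):nrow(px), 2])^2)
    best <- max(best, max(d))
  }
  best
}

bf_invasion_inhibition <- function(px) {
  4 * nrow(px) / (pi * bf_major_axis(px)^2)
}

# boundary by direct 8-neighbour set lookup
bf_boundary <- function(px) {
  key <- paste(px[, 1], px[, 2])
  off <- expand.grid(dx = -1:1, dy = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0), ]
  is_b <- vapply(seq_len(nrow(px)), function(i) {
    any(!(paste(px[i, 1] + off$dx, px[i, 2] + off$dy) %in% key))
  }, logical(1))
  px[is_b, , drop = FALSE]
}

bf_polarity <- function(px, centers) {
  pb <- bf_boundary(px)
  d <- vapply(seq_len(nrow(centers)), function(i) {
    min(sqrt((pb[, 1] - centers[i, 1])^2 + (pb[, 2] - centers[i, 2])^2))
  }, numeric(1))
  list(mean = mean(d), sd = if (length(d) > 1) stats::sd(d) else 0)
}

# independent branch extraction: BFS path walk on a skeleton matrix, with the
# same stated convention (junction pixels cluster; branch length counts arm
# pixels excluding the junction cluster, endpoint included)
bf_branch_lengths <- function(sk) {
  pts <- which(sk == 1, arr.ind = TRUE)
  if (!nrow(pts)) return(numeric(0))
  key <- paste(pts[, 1], pts[, 2])
  nb_of <- function(r, c) {
    out <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (paste(r + dr, c + dc) %in% key) out <- rbind(out, c(r + dr, c + dc))
    }
    out
  }
  degree <- vapply(seq_len(nrow(pts)), function(i) {
    nb <- nb_of(pts[i, 1], pts[i, 2]); if (is.null(nb)) 0L else nrow(nb)
  }, integer(1))
  deg_at <- function(r, c) degree[match(paste(r, c), key)]
  is_junction <- function(r, c) { d <- deg_at(r, c); !is.na(d) && d >= 3 }
  lens <- numeric(0)
  for (i in which(degree == 1)) {
    # walk from each endpoint until a junction-cluster pixel or another end
    path_len <- 1L
    prev <- pts[i, ]; cur <- NULL
    nb <- nb_of(prev[1], prev[2])
    if (is.null(nb)) next
    cur <- nb[1, ]
    hit_junction <- FALSE
    repeat {
      if (is_junction(cur[1], cur[2])) { hit_junction <- TRUE; break }
      if (deg_at(cur[1], cur[2]) == 1) break        # segment: other endpoint
      path_len <- path_len + 1L
      nxt <- NULL
      nb <- nb_of(cur[1], cur[2])
      for (j in seq_len(nrow(nb))) {
        if (!(nb[j, 1] == prev[1] && nb[j, 2] == prev[2])) { nxt <- nb[j, ]; break }
      }
      if (is.null(nxt)) break
      prev <- cur; cur <- nxt
    }
    if (hit_junction) lens <- c(lens, path_len)
  }
  lens
}

bf_branching <- function(sk) {
  lens <- bf_branch_lengths(sk)
  if (length(lens)) mean(lens) else 0
}

# random connected blob: union of overlapping discs on a small canvas
random_blob <- function(seed, max_dim = 64) {
  set.seed(seed)
  n_disc <- sample(2:5, 1)
  cx <- numeric(n_disc); cy <- numeric(n_disc); r <- numeric(n_disc)
  cx[1] <- runif(1, 20, max_dim - 20)
  cy[1] <- runif(1, 20, max_dim - 20)
  r[1] <- runif(1, 4, 10)
  for (i in seq_len(n_disc - 1) + 1) {
    th <- runif(1, 0, 2 * pi)
    d <- runif(1, 0, r[i - 1])
    cx[i] <- min(max_dim - 12, max(12, cx[i - 1] + d * cos(th)))
    cy[i] <- min(max_dim - 12, max(12, cy[i - 1] + d * sin(th)))
    r[i] <- runif(1, 3, 9)
  }
  gx <- rep(1:max_dim, times = max_dim)
  gy <- rep(1:max_dim, each = max_dim)
  inside <- rep(FALSE, length(gx))
  for (i in seq_len(n_disc)) {
    inside <- inside | ((gx - cx[i])^2 + (gy - cy[i])^2 <= r[i]^2)
  }
  px <- cbind(x = gx[inside], y = gy[inside])
  px
}

mask_to_matrix64 <- function(px, dim = 64) {
  m <- matrix(0L, dim, dim)
  m[cbind(px[, 2], px[, 1])] <- 1L
  m
}
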