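# Morphological skeletonization (Zhang-Suen thinning) and skeleton-graph
# branch analysis. The branching feature needs a 1-pixel-wide, 8-connected
# skeleton plus a graph decomposition into endpoint/junction vertices and
# pixel-path edges; both are implemented here on plain logical matrices.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbour offsets in clockwise order starting north (y grows downwards):
# P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW, P8=W, P9=NW
.zs_off <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

#' Skeletonize a binary mask by Zhang-Suen thinning
#'
#' Iteratively removes boundary pixels while preserving 8-connectivity until
#' a one-pixel-wide skeleton remains.
#'
#' @param m logical or 0/1 integer matrix (rows = y, columns = x).
#' @return integer matrix of the same shape, 1 on skeleton pixels.
#' @export
skeletonize <- function(m) {
  m <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  if (!any(m == 1L)) return(m)
  # pad so border arithmetic never truncates
  p <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- lapply(.zs_off, function(o) shift_mat(p, -o[1], -o[2]))
      B <- Reduce(`+`, nb)
      seqn <- c(nb, nb[1])
      A <- matrix(0L, nrow(p), ncol(p))
      for (i in 1:8) A <- A + as.integer(seqn[[i]] == 0L & seqn[[i + 1]] == 1L)
      if (step == 1) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]] == 0L   # P2*P4*P6
        c2 <- nb[[3]] * nb[[5]] * nb[[7]] == 0L   # P4*P6*P8
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]] == 0L   # P2*P4*P8
        c2 <- nb[[1]] * nb[[5]] * nb[[7]] == 0L   # P2*P6*P8
      }
      del <- p == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) {
        p[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L), drop = FALSE]
}

# Count of 8-neighbours on the skeleton, per skeleton pixel.
skel_degree <- function(sk) {
  nb <- Reduce(`+`, lapply(.zs_off, function(o) shift_mat(sk, -o[1], -o[2])))
  nb * sk
}

#' Decompose a skeleton into graph edges
#'
#' Vertices are skeleton pixels whose 8-neighbour count differs from 2:
#' endpoints (one neighbour) stay individual vertices, while 8-adjacent
#' junction pixels (three or more neighbours) are collapsed into a single
#' junction vertex, since a pixel-grid crossing is a small cluster rather
#' than one pixel. Edges are the pixel paths of degree-2 pixels connecting
#' vertices. An edge's `length` counts its interior path pixels plus one for
#' each endpoint vertex (the endpoint pixel belongs to the arm); junction
#' cluster pixels are not counted.
#'
#' @param sk skeleton matrix as returned by [skeletonize()].
#' @return data.frame with columns `end_a`, `end_b` (`"endpoint"` or
#'   `"junction"`) and `length`.
#' @export
skeleton_edges <- function(sk) {
  sk <- matrix(as.integer(sk != 0), nrow(sk), ncol(sk))
  empty <- data.frame(end_a = character(), end_b = character(),
                      length = numeric())
  if (!any(sk == 1L)) return(empty)
  deg <- skel_degree(sk)
  idx <- which(sk == 1L, arr.ind = TRUE)
  n_px <- nrow(idx)
  pid <- matrix(0L, nrow(sk), ncol(sk))
  pid[idx] <- seq_len(n_px)
  at_deg <- function(r, c) {
    if (r < 1 || c < 1 || r > nrow(sk) || c > ncol(sk) || pid[r, c] == 0L)
      return(-1L)
    deg[r, c]
  }
  nbrs <- function(r, c) {
    out <- list()
    for (o in .zs_off) {
      rr <- r + o[1]; cc <- c + o[2]
      if (at_deg(rr, cc) >= 0L) out[[length(out) + 1L]] <- c(rr, cc)
    }
    out
  }
  # vertex clusters: union 8-adjacent junction pixels; endpoints singletons
  cluster <- rep(0L, n_px)
  parent <- uf_new(n_px)
  is_vert <- deg[idx] != 2L
  is_junc <- deg[idx] >= 3L
  for (i in which(is_junc)) {
    r <- idx[i, 1]; c <- idx[i, 2]
    for (o in .zs_off) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || cc < 1 || rr > nrow(sk) || cc > ncol(sk)) next
      j <- pid[rr, cc]
      if (j > 0L && deg[rr, cc] >= 3L) parent <- uf_union(parent, i, j)
    }
  }
  comp <- uf_components(parent)
  cluster[is_vert] <- comp[is_vert]
  vert_type <- function(i) if (deg[idx[i, 1], idx[i, 2]] == 1L) "endpoint" else "junction"
  used <- new.env(parent = emptyenv())
  step_key <- function(a, b) paste(a[1], a[2], b[1], b[2])
  edges <- empty
  for (i in which(is_vert)) {
    v <- c(idx[i, 1], idx[i, 2])
    for (u in nbrs(v[1], v[2])) {
      ui <- pid[u[1], u[2]]
      if (is_vert[ui] && cluster[ui] == cluster[i]) next  # same junction cluster
      if (!is.null(get0(step_key(v, u), envir = used))) next
      assign(step_key(v, u), TRUE, envir = used)
      prev <- v; cur <- u; interior <- 0L
      while (at_deg(cur[1], cur[2]) == 2L) {
        interior <- interior + 1L
        nx <- NULL
        for (w in nbrs(cur[1], cur[2])) {
          if (!(w[1] == prev[1] && w[2] == prev[2])) { nx <- w; break }
        }
        if (is.null(nx)) break   # dangling chain (should not occur)
        assign(step_key(cur, nx), TRUE, envir = used)
        prev <- cur; cur <- nx
      }
      assign(step_key(cur, prev), TRUE, envir = used)
      ea <- vert_type(i)
      cur_i <- pid[cur[1], cur[2]]
      eb <- if (is_vert[cur_i]) vert_type(cur_i) else "endpoint"
      n_end <- (ea == "endpoint") + (eb == "endpoint")
      edges <- rbind(edges, data.frame(end_a = ea, end_b = eb,
                                       length = interior + n_end))
    }
  }
  edges
}

#' Skeleton summary statistics of a binary mask
#'
#' @param m binary mask matrix.
#' @return list with `skeleton_length` (skeleton pixel count), `n_branches`,
#'   `mean_branch_length` (0 when no branch exists), `max_branch_length`,
#'   `n_junctions`, `n_endpoints`. A branch is an edge with exactly one
#'   endpoint (degree-1) vertex.
#' @export
skeleton_stats <- function(m) {
  sk <- skeletonize(m)
  deg <- skel_degree(sk)
  on_sk <- sk == 1L
  ed <- skeleton_edges(sk)
  is_branch <- (ed$end_a == "endpoint") + (ed$end_b == "endpoint") == 1L
  bl <- ed$length[is_branch]
  list(
    skeleton_length = sum(on_sk),
    n_branches = length(bl),
    mean_branch_length = if (length(bl)) mean(bl) else 0,
    max_branch_length = if (length(bl)) max(bl) else 0,
    n_junctions = sum(deg[on_sk] >= 3L),
    n_endpoints = sum(deg[on_sk] == 1L)
  )
}
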