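# Phenotypic clustering of per-dose treatment profiles: Ward hierarchical
# clustering on the selected features, cluster count chosen by the
# Davies-Bouldin index (Calinski-Harabasz reported alongside), signed class
# signatures, and per-treatment dose-label sequences with a prevalence-based
# general class.

#' Average replicate wells into per-dose treatment profiles
#'
#' Replicates are averaged before clustering; each (treatment, dose) becomes
#' one observation.
#'
#' @param ztable normalized feature matrix (wells x features).
#' @param map plate map data.frame.
#' @param features columns to keep (e.g. the selected features).
#' @return list with `profiles` (matrix, rownames `treatment@dose`) and
#'   `meta` (data.frame of treatment and dose per row).
#' @export
dose_profiles <- function(ztable, map, features = colnames(ztable)) {
  features <- intersect(features, colnames(ztable))
  if (!length(features)) stopf("none of the requested features are present")
  tmap <- map[map$role == "treatment" & map$well %in% rownames(ztable), ,
              drop = FALSE]
  pairs <- unique(tmap[, c("treatment", "dose")])
  pairs <- pairs[order(pairs$treatment, pairs$dose), , drop = FALSE]
  prof <- t(vapply(seq_len(nrow(pairs)), function(i) {
    wells <- tmap$well[tmap$treatment == pairs$treatment[i] &
                         tmap$dose == pairs$dose[i]]
    colMeans(ztable[wells, features, drop = FALSE])
  }, numeric(length(features))))
  colnames(prof) <- features
  rownames(prof) <- sprintf("%s@%g", pairs$treatment, pairs$dose)
  list(profiles = prof, meta = pairs)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the maximal ratio `(S_i + S_j) / M_ij`, where `S_i`
#' is the mean Euclidean distance of cluster members to their centroid and
#' `M_ij` the distance between centroids. Lower is better.
#'
#' @param x observation matrix.
#' @param labels integer cluster labels.
#' @return the index value.
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  ks <- sort(unique(labels))
  cent <- do.call(rbind, lapply(ks, function(k) {
    colMeans(x[labels == k, , drop = FALSE])
  }))
  s <- vapply(seq_along(ks), function(i) {
    xi <- x[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums((xi - matrix(cent[i, ], nrow(xi), ncol(x),
                                   byrow = TRUE))^2)))
  }, numeric(1))
  r <- vapply(seq_along(ks), function(i) {
    max(vapply(seq_along(ks)[-i], function(j) {
      m <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (m == 0) Inf else (s[i] + s[j]) / m
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Calinski-Harabasz index
#'
#' `(B / (k - 1)) / (W / (n - k))` with `B` and `W` the between- and
#' within-cluster sums of squared Euclidean distances to centroids. Higher is
#' better.
#'
#' @inheritParams davies_bouldin
#' @return the index value.
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2L || n <= k) return(NA_real_)
  g <- colMeans(x)
  w <- 0; b <- 0
  for (ki in ks) {
    xi <- x[labels == ki, , drop = FALSE]
    ci <- colMeans(xi)
    w <- w + sum(sweep(xi, 2, ci)^2)
    b <- b + nrow(xi) * sum((ci - g)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# 2-fold stability diagnostic: split observations into halves, cluster each
# half, project the other half onto the nearest centroid, and score the
# agreement (adjusted Rand index) between projected and direct labels.
two_fold_stability <- function(x, k, seed = 1L) {
  n <- nrow(x)
  if (n < 2L * k) return(NA_real_)
  with_seed(seed, {
    idx <- sample.int(n)
    halves <- list(sort(idx[seq_len(floor(n / 2))]),
                   sort(idx[(floor(n / 2) + 1L):n]))
    lab <- lapply(halves, function(h) {
      stats::cutree(stats::hclust(stats::dist(x[h, , drop = FALSE]),
                                  method = "ward.D2"), k)
    })
    score <- vapply(1:2, function(a) {
      b <- 3L - a
      cent <- do.call(rbind, lapply(seq_len(k), function(ki) {
        colMeans(x[halves[[a]][lab[[a]] == ki], , drop = FALSE])
      }))
      proj <- vapply(halves[[b]], function(i) {
        which.min(colSums((t(cent) - x[i, ])^2))
      }, integer(1))
      mclust::adjustedRandIndex(proj, lab[[b]])
    }, numeric(1))
    mean(score)
  })
}

#' Ward hierarchical clustering of dose profiles
#'
#' Agglomerative Ward clustering (`ward.D2` on Euclidean distances) of
#' z-scored profiles, cut at `k` clusters, with a 2-fold stability score
#' reported as a diagnostic (it does not alter the clustering).
#'
#' @param profiles observation matrix (rows = per-dose profiles).
#' @param k number of clusters (2 <= k <= n - 1).
#' @param seed seed for the stability split.
#' @return list with `labels` (integer vector named by rownames), `hclust`,
#'   and `stability`.
#' @export
ward_cluster <- function(profiles, k, seed = 1L) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (k < 2L || k > n - 1L) {
    stopf("k must satisfy 2 <= k <= n - 1 (n = %d, k = %d)", n, k)
  }
  hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
  labels <- stats::cutree(hc, k)
  list(labels = labels, hclust = hc,
       stability = two_fold_stability(profiles, k, seed = seed))
}

#' Choose the cluster count by internal validity indices
#'
#' Computes the Davies-Bouldin and Calinski-Harabasz indices over `k_range`
#' for Ward clusterings and returns the Davies-Bouldin minimiser. When the
#' Calinski-Harabasz maximiser disagrees, both curves are still returned and
#' the Davies-Bouldin choice is taken (fixed, documented rule).
#'
#' @param profiles observation matrix.
#' @param k_range candidate cluster counts (default 2 to 10, truncated to
#'   n - 1).
#' @return list with `k`, `k_ch` (Calinski-Harabasz argmax), `db`, `ch`
#'   (named index curves) and `warning` (set for degenerate inputs).
#' @export
choose_k <- function(profiles, k_range = 2:10) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) stopf("need more observations than the smallest k")
  hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
  db <- ch <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    lab <- stats::cutree(hc, k_range[i])
    if (length(unique(lab)) < 2L) next
    db[i] <- davies_bouldin(profiles, lab)
    ch[i] <- calinski_harabasz(profiles, lab)
  }
  warn <- NULL
  if (all(!is.finite(db))) {
    warn <- "degenerate input: indices undefined, returning smallest k"
    k <- min(k_range)
  } else {
    k <- k_range[which.min(db)]
  }
  k_ch <- if (any(is.finite(ch))) k_range[which.max(ch)] else NA_integer_
  list(k = k, k_ch = k_ch, db = db, ch = ch, warning = warn)
}

#' Signed class signature
#'
#' For one phenotypic class, `F_i` is the mean z-score of feature `i` over
#' the class members and the partition size is `%(i) = F_i / sum_j F_j`
#' (in percent). Both are signed; individual `%(i)` values may fall outside
#' `[0, 100]`. When `sum_j F_j == 0` the partition is undefined: `percent`
#' is NA and `defined` is FALSE, with the raw `F` still reported.
#'
#' @param members matrix of member observations (rows) on the selected
#'   features.
#' @return list with `F` (named means), `percent` (named, sums to 100 when
#'   defined) and `defined`.
#' @export
class_signature <- function(members) {
  members <- as.matrix(members)
  if (!nrow(members)) stopf("a class signature needs at least one member")
  f <- colMeans(members)
  tot <- sum(f)
  if (abs(tot) < 1e-12) {
    list(F = f, percent = stats::setNames(rep(NA_real_, length(f)), names(f)),
         defined = FALSE)
  } else {
    list(F = f, percent = 100 * f / tot, defined = TRUE)
  }
}

#' Fit the phenotypic class model
#'
#' Clusters per-dose treatment profiles on the selected features into classes
#' labelled A, B, ... (in dendrogram order), with centroids, signed
#' signatures and index curves.
#'
#' @param ztable normalized feature matrix.
#' @param map plate map.
#' @param features selected feature names.
#' @param k cluster count; chosen by [choose_k()] when NULL.
#' @param k_range candidate counts for [choose_k()].
#' @param seed seed for the stability diagnostic.
#' @return object of class `cluster_model`: list with `k`, `labels` (class
#'   letter per profile), `centroids`, `signatures`, `profiles`, `meta`,
#'   `indices` (`choose_k` output or NULL), `hclust`, `stability`,
#'   `features`.
#' @export
cluster_phenotypes <- function(ztable, map, features, k = NULL,
                               k_range = 2:10, seed = 1L) {
  dp <- dose_profiles(ztable, map, features)
  indices <- NULL
  if (is.null(k)) {
    indices <- choose_k(dp$profiles, k_range)
    k <- indices$k
  }
  wc <- ward_cluster(dp$profiles, k, seed = seed)
  # letters in dendrogram order: first appearance along the tree ordering
  ord_first <- vapply(seq_len(k), function(ki) {
    min(match(which(wc$labels == ki), wc$hclust$order))
  }, numeric(1))
  letter_of <- stats::setNames(LETTERS[rank(ord_first)], seq_len(k))
  labels <- stats::setNames(letter_of[as.character(wc$labels)],
                            names(wc$labels))
  classes <- sort(unique(labels))
  centroids <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(dp$profiles[labels == cl, , drop = FALSE])
  }))
  rownames(centroids) <- classes
  colnames(centroids) <- colnames(dp$profiles)
  signatures <- lapply(stats::setNames(classes, classes), function(cl) {
    class_signature(dp$profiles[labels == cl, , drop = FALSE])
  })
  structure(list(k = k, labels = labels, centroids = centroids,
                 signatures = signatures, profiles = dp$profiles,
                 meta = dp$meta, indices = indices, hclust = wc$hclust,
                 stability = wc$stability, features = colnames(dp$profiles)),
            class = "cluster_model")
}

#' Assign a dose-label sequence to one treatment
#'
#' Each dose's profile receives the label of the nearest class centroid
#' (Euclidean distance); profiles whose root-mean-square z over the selected
#' features falls below `effect_floor` receive the distinguished
#' `"no-effect"` label. The RMS (rather than the raw norm) keeps the floor
#' calibrated in z units regardless of how many features were selected.
#'
#' @param treatment treatment id.
#' @param model a `cluster_model`.
#' @param effect_floor minimum RMS z of a profile for an effect (default 1).
#' @return object of class `class_sequence`: list with `treatment`, `doses`,
#'   `labels` (low to high dose) and `general` (see
#'   [assign_general_class()]).
#' @export
assign_dose_labels <- function(treatment, model, effect_floor = 1) {
  sel <- model$meta$treatment == treatment
  if (!any(sel)) stopf("treatment '%s' has no profiles", treatment)
  doses <- model$meta$dose[sel]
  ord <- order(doses)
  prof <- model$profiles[sel, , drop = FALSE][ord, , drop = FALSE]
  doses <- doses[ord]
  labels <- vapply(seq_len(nrow(prof)), function(i) {
    v <- prof[i, ]
    if (sqrt(mean(v^2)) < effect_floor) return("no-effect")
    d2 <- colSums((t(model$centroids) - v)^2)
    rownames(model$centroids)[which.min(d2)]
  }, character(1))
  structure(list(treatment = treatment, doses = doses, labels = labels,
                 general = assign_general_class(labels)),
            class = "class_sequence")
}

#' General phenotypic class of a dose-label sequence
#'
#' The most frequent non-"no-effect" label across the dose range; ties are
#' broken in favour of the label occurring at the highest dose; a sequence of
#' only "no-effect" labels yields "no-effect".
#'
#' @param labels character vector of class labels, ordered low to high dose
#'   (or a `class_sequence`).
#' @return a single class label.
#' @export
assign_general_class <- function(labels) {
  if (inherits(labels, "class_sequence")) labels <- labels$labels
  if (!length(labels)) stopf("empty label sequence")
  eff <- labels[labels != "no-effect"]
  if (!length(eff)) return("no-effect")
  tab <- table(eff)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  # tie: the tied label seen at the highest dose wins
  top[which.max(vapply(top, function(l) max(which(labels == l)), numeric(1)))]
}
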