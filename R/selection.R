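# Accumulative phenotypic learning: pairwise random-forest feature selection
# between each (treatment, dose) group and the buffer controls, stabilised by
# class-wise bootstrap resampling, accumulated into per-feature selection
# frequencies and thresholded at a frequency cutoff.

#' Per-repetition top-k random-forest feature selection for one pair
#'
#' For each repetition, `n_bootstrap` rows are drawn per class with
#' replacement (class-wise bootstrap), a random-forest classifier
#' (treatment vs buffer) is fitted, features are ranked by impurity
#' importance (ties broken by the canonical feature order), and the top `k`
#' features are recorded.
#'
#' @param treatment_rows,buffer_rows numeric matrices (wells x features) with
#'   identical column names and no missing values.
#' @param k number of features kept per repetition (default 10).
#' @param n_bootstrap rows drawn per class and repetition (default 30).
#' @param n_repetitions number of repetitions (default 500).
#' @param seed integer seed.
#' @param num_trees forest size (default 200).
#' @return list of length `n_repetitions`; each element a character vector of
#'   `k` distinct feature names.
#' @export
rf_top_k <- function(treatment_rows, buffer_rows, k = 10L, n_bootstrap = 30L,
                     n_repetitions = 500L, seed = 1L, num_trees = 200L) {
  if (!nrow(treatment_rows) || !nrow(buffer_rows)) {
    stopf("both classes need at least one row (treatment: %d, buffer: %d)",
          nrow(treatment_rows), nrow(buffer_rows))
  }
  if (nrow(treatment_rows) < 2L || nrow(buffer_rows) < 2L) {
    stopf("each class needs >= 2 rows for bootstrap validation")
  }
  stopifnot(identical(colnames(treatment_rows), colnames(buffer_rows)))
  if (anyNA(treatment_rows) || anyNA(buffer_rows)) {
    stopf("missing values must be removed before feature selection")
  }
  feats <- colnames(treatment_rows)
  if (k > length(feats)) stopf("k exceeds the number of features")
  with_seed(seed, {
    lapply(seq_len(n_repetitions), function(rep_i) {
      it <- sample.int(nrow(treatment_rows), n_bootstrap, replace = TRUE)
      ib <- sample.int(nrow(buffer_rows), n_bootstrap, replace = TRUE)
      x <- rbind(treatment_rows[it, , drop = FALSE],
                 buffer_rows[ib, , drop = FALSE])
      y <- factor(rep(c("treatment", "buffer"), each = n_bootstrap))
      fit <- ranger::ranger(
        x = as.data.frame(x), y = y, num.trees = num_trees,
        importance = "impurity", num.threads = 1,
        seed = derive_seed(seed, rep_i))
      imp <- fit$variable.importance[feats]
      imp[is.na(imp)] <- 0
      feats[order(-imp, seq_along(feats))[seq_len(k)]]
    })
  })
}

#' Accumulate selection frequencies over all pairwise comparisons
#'
#' The frequency of a feature is the proportion of all (pair x repetition)
#' draws whose top-k set contains it; frequencies over all features sum to k.
#'
#' @param comparisons list of [rf_top_k()] results (one per pairwise
#'   treatment-dose vs buffer comparison), or a single such result.
#' @param feature_names full feature universe; defaults to the union of
#'   selected names (features never selected then have frequency 0 only if
#'   listed here).
#' @return object of class `selection_result`: list with `frequency` (named,
#'   sorted decreasing), `n_draws`, `k`.
#' @export
accumulate_frequencies <- function(comparisons, feature_names = NULL) {
  if (length(comparisons) && is.character(comparisons[[1]])) {
    comparisons <- list(comparisons)
  }
  if (!length(comparisons)) stopf("at least one pairwise comparison is required")
  draws <- unlist(comparisons, recursive = FALSE)
  k <- length(draws[[1]])
  tab <- table(unlist(draws))
  freq <- as.numeric(tab) / length(draws)
  names(freq) <- names(tab)
  if (!is.null(feature_names)) {
    full <- stats::setNames(numeric(length(feature_names)), feature_names)
    full[names(freq)] <- freq
    freq <- full
  }
  freq <- freq[order(-freq, names(freq))]
  structure(list(frequency = freq, n_draws = length(draws), k = k),
            class = "selection_result")
}

#' Select features passing the frequency cutoff
#'
#' @param result a `selection_result` from [accumulate_frequencies()].
#' @param cutoff minimum selection frequency (default 0.05, i.e. a feature
#'   must enter the top-k in at least 5 percent of all draws).
#' @return character vector of selected feature names, by decreasing
#'   frequency.
#' @export
select_features <- function(result, cutoff = 0.05) {
  stopifnot(inherits(result, "selection_result"))
  names(result$frequency)[result$frequency >= cutoff & result$frequency > 0]
}

#' Run accumulative selection over a normalized plate table
#'
#' Performs one [rf_top_k()] comparison per (treatment, dose) pair against
#' the buffer controls, accumulates the frequencies, and applies the cutoff.
#' Columns containing missing values are dropped beforehand (k is not
#' rescaled).
#'
#' @param ztable normalized feature matrix (wells x features, rownames =
#'   well ids).
#' @param map plate map data.frame (`well`, `role`, `treatment`, `dose`).
#' @param k,n_bootstrap,n_repetitions,cutoff,num_trees see [rf_top_k()] and
#'   [select_features()].
#' @param seed integer seed.
#' @return list with `result` (`selection_result`), `selected`, `pairs`
#'   (data.frame of the comparisons run) and `dropped` (columns removed for
#'   missingness).
#' @export
run_accumulative_selection <- function(ztable, map, k = 10L, n_bootstrap = 30L,
                                       n_repetitions = 500L, cutoff = 0.05,
                                       seed = 1L, num_trees = 200L) {
  ok <- !apply(ztable, 2, anyNA)
  dropped <- colnames(ztable)[!ok]
  zt <- ztable[, ok, drop = FALSE]
  buffer <- zt[intersect(map$well[map$role == "buffer"], rownames(zt)), ,
               drop = FALSE]
  tmap <- map[map$role == "treatment", , drop = FALSE]
  pairs <- unique(tmap[, c("treatment", "dose")])
  pairs <- pairs[order(pairs$treatment, pairs$dose), , drop = FALSE]
  comparisons <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    wells <- tmap$well[tmap$treatment == pairs$treatment[i] &
                         tmap$dose == pairs$dose[i]]
    rows <- zt[intersect(wells, rownames(zt)), , drop = FALSE]
    if (!nrow(rows)) {
      stopf("no wells for pair %s @ %g", pairs$treatment[i], pairs$dose[i])
    }
    comparisons[[i]] <- rf_top_k(rows, buffer, k = k,
                                 n_bootstrap = n_bootstrap,
                                 n_repetitions = n_repetitions,
                                 seed = derive_seed(seed, i),
                                 num_trees = num_trees)
  }
  result <- accumulate_frequencies(comparisons, feature_names = colnames(zt))
  list(result = result, selected = select_features(result, cutoff),
       pairs = pairs, dropped = dropped)
}
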