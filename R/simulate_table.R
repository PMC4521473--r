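# Well-by-feature tables with planted class structure, used to exercise the
# feature-selection and clustering stages directly (without images).

#' The six canonical feature names
#'
#' Well-aggregate names of the six formula-defined morphology features.
#'
#' @return character vector of length 6.
#' @export
six_feature_names <- function() {
  c("actin.invasion_inhibition.mean", "actin.area.mean",
    "actin.total_proliferation.mean", "actin.organoid_count.mean",
    "actin.organoid_branching.mean", "corr.cell_polarity.mean")
}

#' Simulate a well-by-feature table with planted classes
#'
#' Informative columns are drawn as the class template centroid plus Gaussian
#' noise; the remaining columns are pure standard-normal noise, giving a
#' table on the z-score scale of a normalized screen.
#'
#' @param class_templates list of named numeric centroid vectors (all with the
#'   same names; default informative names are [six_feature_names()]).
#'   At least two templates are required.
#' @param n_per_class observations per class (>= 2).
#' @param n_noise_features number of pure-noise columns (default pads the
#'   table to 294 columns).
#' @param effect_sd noise SD around the centroid for informative columns.
#' @param seed integer seed.
#' @return list with `table` (numeric matrix, rows `obs_<i>`), `labels`
#'   (integer class of each row) and `informative` (column names carrying
#'   signal).
#' @export
simulate_feature_table <- function(class_templates, n_per_class = 20L,
                                   n_noise_features = NULL, effect_sd = 1,
                                   seed = 1L) {
  if (length(class_templates) < 2L) {
    stopf("at least two class templates are required (clustering is undefined otherwise)")
  }
  nm <- names(class_templates[[1]])
  if (is.null(nm)) {
    nm <- six_feature_names()[seq_along(class_templates[[1]])]
    class_templates <- lapply(class_templates, stats::setNames, nm)
  }
  if (n_per_class < 2L) stopf("n_per_class must be >= 2")
  p_inf <- length(nm)
  if (is.null(n_noise_features)) n_noise_features <- max(0L, 294L - p_inf)
  with_seed(seed, {
    k <- length(class_templates)
    n <- k * n_per_class
    labels <- rep(seq_len(k), each = n_per_class)
    inf <- matrix(NA_real_, n, p_inf, dimnames = list(NULL, nm))
    for (ci in seq_len(k)) {
      rows <- which(labels == ci)
      mu <- as.numeric(class_templates[[ci]][nm])
      inf[rows, ] <- matrix(rep(mu, each = length(rows)), length(rows)) +
        matrix(stats::rnorm(length(rows) * p_inf, 0, effect_sd), length(rows))
    }
    noise <- matrix(stats::rnorm(n * n_noise_features), n, n_noise_features)
    colnames(noise) <- sprintf("noise_%03d", seq_len(n_noise_features))
    tab <- cbind(inf, noise)
    rownames(tab) <- sprintf("obs_%03d", seq_len(n))
    list(table = tab, labels = labels, informative = nm)
  })
}
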