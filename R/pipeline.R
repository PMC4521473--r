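# Pipeline orchestration: simulate -> segment/featurize -> normalize ->
# select -> cluster -> classify, as a seeded, logged, resumable run with a
# written report bundle.

#' Build a pipeline configuration
#'
#' All stage defaults live here; unknown keys are rejected. The configuration
#' round-trips losslessly through YAML ([read_pipeline_config()] /
#' [write_pipeline_config()]).
#'
#' @param ... overrides of the defaults (nested lists are merged per key).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = "orgprofiler_run",
    simulate = TRUE,
    plate = list(preset = "screen_mimic"),
    geometry = list(sections = 8L, height = 320L, width = 320L, zscale = 6),
    segmentation = list(sharpness_min = 0.2, min_overlap_ratio = 0.5,
                        max_dist = 5),
    normalize = list(tol = 1e-8),
    selection = list(k = 10L, n_bootstrap = 30L, n_repetitions = 50L,
                     cutoff = 0.05, num_trees = 200L),
    clustering = list(k = NULL, k_min = 2L, k_max = 10L, effect_floor = 1),
    inputs = list(feature_table = NULL, plate_map = NULL),
    write_figures = TRUE
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stopf("unknown configuration key(s): %s",
                         paste(bad, collapse = ", "))
  # merge that keeps NULL-valued keys (modifyList would delete them, which
  # breaks the lossless YAML round-trip)
  merge_keep_null <- function(base, over) {
    for (nm2 in names(over)) base[nm2] <- over[nm2]
    base
  }
  for (nm in names(ov)) {
    if (nm == "plate") {
      # a custom plate replaces the preset wholesale
      defaults[[nm]] <- ov[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(ov[[nm]]) &&
               !is.null(names(defaults[[nm]]))) {
      bad2 <- setdiff(names(ov[[nm]]), names(defaults[[nm]]))
      if (length(bad2)) {
        stopf("unknown key(s) in '%s': %s", nm, paste(bad2, collapse = ", "))
      }
      defaults[[nm]] <- merge_keep_null(defaults[[nm]], ov[[nm]])
    } else {
      defaults[[nm]] <- ov[[nm]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path.
#' @param config a `pipeline_config`.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stable hash of an R object (used for stage manifests)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

log_stage <- function(con, stage, message, ...) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(message, ...))
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

plate_from_config <- function(config) {
  geom <- do.call(stack_geometry, config$geometry)
  if (identical(config$plate$preset, "screen_mimic")) {
    return(default_plate_spec(seed = config$seed, geometry = geom))
  }
  baseline <- do.call(well_baseline, config$plate$baseline %||% list())
  plate_spec(treatments = config$plate$treatments,
             buffer_fraction = config$plate$buffer_fraction %||% 0.25,
             geometry = geom, baseline = baseline,
             noise_sd = config$plate$noise_sd %||% 0.02, seed = config$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full profiling pipeline
#'
#' Executes simulate (or load) -> segment/featurize -> normalize -> select ->
#' cluster -> classify, writing every artifact plus a manifest (stage,
#' parameter hash, file checksums) under `config$out_dir`. Rerunning with an
#' unchanged configuration reuses the expensive feature-extraction stage when
#' its manifest and checksums still match. The run is a pure function of
#' (config, seed): identical configurations reproduce identical tables.
#'
#' @param config a [pipeline_config()].
#' @return report bundle: list with `features`, `map`, `ztable`, `selection`,
#'   `model`, `sequences`, `general_classes`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    log = file.path(config$out_dir, "pipeline.log"),
    manifest = file.path(config$out_dir, "manifest.json"),
    features = file.path(config$out_dir, "features_raw.csv"),
    map = file.path(config$out_dir, "plate_map.csv"),
    ztable = file.path(config$out_dir, "features_normalized.csv"),
    frequencies = file.path(config$out_dir, "selection_frequencies.csv"),
    selected = file.path(config$out_dir, "selected_features.json"),
    model = file.path(config$out_dir, "cluster_model.json"),
    sequences = file.path(config$out_dir, "class_sequences.csv"),
    dendrogram = file.path(config$out_dir, "dendrogram.pdf"),
    signatures = file.path(config$out_dir, "class_signatures.pdf")
  )
  con <- file(paths$log, open = "at")
  on.exit(close(con))

  # --- stage: features (simulate+segment+featurize, or load) ---------------
  feat_hash <- object_hash(list(config$seed, config$plate, config$geometry,
                                config$segmentation, config$simulate,
                                config$inputs))
  manifest <- if (file.exists(paths$manifest)) {
    jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  } else NULL
  reuse <- !is.null(manifest) &&
    identical(manifest$features$param_hash, feat_hash) &&
    file.exists(paths$features) && file.exists(paths$map) &&
    identical(unname(tools::md5sum(paths$features)),
              manifest$features$checksums[["features_raw.csv"]])
  if (reuse) {
    log_stage(con, "features", "reusing cached feature table (hash %s)", feat_hash)
    tab <- as.matrix(utils::read.csv(paths$features, row.names = 1,
                                     check.names = FALSE))
    map <- utils::read.csv(paths$map, stringsAsFactors = FALSE)
  } else if (isTRUE(config$simulate)) {
    log_stage(con, "features", "simulating plate (seed %d)", config$seed)
    plate <- plate_from_config(config)
    pp <- tryCatch(
      profile_plate(plate,
                    sharpness_min = config$segmentation$sharpness_min,
                    min_overlap_ratio = config$segmentation$min_overlap_ratio,
                    max_dist = config$segmentation$max_dist),
      error = function(e) stopf("stage 'features' failed: %s", conditionMessage(e)))
    tab <- pp$table; map <- pp$map
    utils::write.csv(tab, paths$features, row.names = TRUE)
    utils::write.csv(map, paths$map, row.names = FALSE)
  } else {
    miss <- c(if (is.null(config$inputs$feature_table)) "feature_table",
              if (is.null(config$inputs$plate_map)) "plate_map")
    if (length(miss)) {
      stopf("simulation disabled and missing input(s): %s",
            paste(miss, collapse = ", "))
    }
    log_stage(con, "features", "loading %s", config$inputs$feature_table)
    tab <- as.matrix(utils::read.csv(config$inputs$feature_table,
                                     row.names = 1, check.names = FALSE))
    map <- utils::read.csv(config$inputs$plate_map, stringsAsFactors = FALSE)
    utils::write.csv(tab, paths$features, row.names = TRUE)
    utils::write.csv(map, paths$map, row.names = FALSE)
  }

  # --- stage: normalize -----------------------------------------------------
  ztable <- tryCatch(
    zscore_normalize(tab, map, tol = config$normalize$tol),
    error = function(e) stopf("stage 'normalize' failed: %s", conditionMessage(e)))
  log_stage(con, "normalize", "%d features retained, %d excluded",
            ncol(ztable), length(attr(ztable, "excluded")))
  utils::write.csv(ztable, paths$ztable, row.names = TRUE)

  # --- stage: select --------------------------------------------------------
  sel <- tryCatch(
    run_accumulative_selection(
      ztable, map, k = config$selection$k,
      n_bootstrap = config$selection$n_bootstrap,
      n_repetitions = config$selection$n_repetitions,
      cutoff = config$selection$cutoff, seed = config$seed,
      num_trees = config$selection$num_trees),
    error = function(e) stopf("stage 'select' failed: %s", conditionMessage(e)))
  log_stage(con, "select", "%d features pass the %.0f%% cutoff",
            length(sel$selected), 100 * config$selection$cutoff)
  utils::write.csv(data.frame(feature = names(sel$result$frequency),
                              frequency = as.numeric(sel$result$frequency)),
                   paths$frequencies, row.names = FALSE)
  jsonlite::write_json(sel$selected, paths$selected, auto_unbox = FALSE)

  # --- stage: cluster -------------------------------------------------------
  model <- tryCatch(
    cluster_phenotypes(ztable, map, sel$selected, k = config$clustering$k,
                       k_range = config$clustering$k_min:config$clustering$k_max,
                       seed = config$seed),
    error = function(e) stopf("stage 'cluster' failed: %s", conditionMessage(e)))
  log_stage(con, "cluster", "k = %d classes (%s), stability %.3f", model$k,
            paste(sort(unique(model$labels)), collapse = ""), model$stability)
  jsonlite::write_json(list(
    k = model$k, features = model$features,
    labels = as.list(model$labels),
    centroids = as.data.frame(model$centroids),
    signatures = lapply(model$signatures, function(s)
      list(F = as.list(s$F), percent = as.list(s$percent),
           defined = s$defined)),
    stability = model$stability,
    indices = if (!is.null(model$indices))
      list(k_db = model$indices$k, k_ch = model$indices$k_ch,
           db = as.list(model$indices$db), ch = as.list(model$indices$ch))
  ), paths$model, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- stage: classify ------------------------------------------------------
  treatments <- unique(model$meta$treatment)
  sequences <- lapply(treatments, assign_dose_labels, model = model,
                      effect_floor = config$clustering$effect_floor)
  names(sequences) <- treatments
  seq_df <- do.call(rbind, lapply(sequences, function(s) {
    data.frame(treatment = s$treatment, dose = s$doses, label = s$labels,
               general = s$general)
  }))
  utils::write.csv(seq_df, paths$sequences, row.names = FALSE)
  general <- vapply(sequences, `[[`, "", "general")
  log_stage(con, "classify", "general classes: %s",
            paste(sprintf("%s=%s", names(general), general), collapse = ", "))

  if (isTRUE(config$write_figures)) {
    grDevices::pdf(paths$dendrogram, width = 8, height = 5)
    plot(model$hclust, main = "Ward clustering of per-dose profiles",
         xlab = "", sub = "")
    grDevices::dev.off()
    grDevices::pdf(paths$signatures, width = 8, height = 5)
    sig <- do.call(cbind, lapply(model$signatures, `[[`, "percent"))
    if (!is.null(sig)) {
      graphics::barplot(sig, beside = TRUE, legend.text = rownames(sig),
                        ylab = "partition size %(i)",
                        main = "Signed class signatures",
                        args.legend = list(cex = 0.6, x = "topright"))
    }
    grDevices::dev.off()
  }

  manifest <- list(
    features = list(param_hash = feat_hash,
                    checksums = as.list(tools::md5sum(paths$features))),
    seed = config$seed,
    written = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  names(manifest$features$checksums) <- basename(paths$features)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)

  list(features = tab, map = map, ztable = ztable, selection = sel,
       model = model, sequences = sequences, general_classes = general,
       paths = paths)
}
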