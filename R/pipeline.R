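# End-to-end orchestration: (synthetic or loaded) volumes -> segmentation
# -> per-B-scan texture features -> z-score/PCA -> SVM grid search.

#' Pipeline run configuration
#'
#' Collects the stage parameters of the whole pipeline. The configuration
#' round-trips losslessly through a YAML file ([save_run_config()] /
#' [load_run_config()]).
#'
#' @param out_dir output directory for feature tables, grid results and
#'   the run report.
#' @param seed single global seed; stage seeds are derived from it.
#' @param synthetic `NULL` to analyse existing data, or a list with fields
#'   `n_per_class`, `image_size`, `n_bscans`, `texture_contrast` for
#'   [generate_study()].
#' @param input `NULL`, or a list with `volume_paths` (named by sample id)
#'   and `manifest` (CSV path) when analysing data on disk.
#' @param segmentation list of [segmentation_params()] arguments.
#' @param texture list of [texture_config()] arguments.
#' @param classification list of [classification_config()] arguments
#'   (without `fold_seed`, which is derived from `seed`).
#' @param comparisons comparisons to classify (default
#'   `"tumorous_vs_healthy"`).
#' @param sweep also run the 15-subset feature-family sweep (default
#'   `FALSE`; expensive).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = "octex_run", seed = 1L,
                       synthetic = list(n_per_class = c(necrosis = 6L,
                                                        vital_tumor = 4L,
                                                        healthy = 4L),
                                        image_size = c(256L, 256L),
                                        n_bscans = 16L,
                                        texture_contrast = 1),
                       input = NULL,
                       segmentation = list(),
                       texture = list(),
                       classification = list(),
                       comparisons = "tumorous_vs_healthy",
                       sweep = FALSE) {
  if (is.null(synthetic) && is.null(input))
    stop("either `synthetic` or `input` must be given")
  # flatten yaml-style nested lists of scalars back to vectors so a
  # config compares equal after a file round trip
  norm <- function(l) {
    if (is.null(l)) return(NULL)
    lapply(l, function(x)
      if (is.list(x) && !any(vapply(x, is.list, logical(1)))) unlist(x)
      else x)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = norm(synthetic), input = norm(input),
                 segmentation = norm(segmentation), texture = norm(texture),
                 classification = norm(classification),
                 comparisons = unlist(comparisons), sweep = sweep),
            class = "run_config")
}

#' Save / load a run configuration (YAML)
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `save_run_config`: `path`, invisibly; `load_run_config`: the
#'   `run_config`.
#' @export
save_run_config <- function(config, path) {
  # yaml drops names of atomic vectors; store named vectors as maps
  to_tree <- function(x) {
    if (is.list(x)) lapply(x, to_tree)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_tree(unclass(config)), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

.log <- function(...) message("[octex] ", sprintf(...))

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (or load), segment, extract,
#' classify — writing `features.csv`, one `grid_<comparison>.json` per
#' comparison, optionally `sweep.csv`, and `report.json` into the output
#' directory. Identical configuration and seed give an identical report
#' and byte-identical feature tables.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly; the grid-search results are
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- acquire volumes and labels
  if (!is.null(config$synthetic)) {
    .log("generating synthetic study (seed %d)", config$seed)
    syn <- config$synthetic
    study <- generate_study(
      n_per_class = unlist(syn$n_per_class),
      image_size = unlist(syn$image_size),
      n_bscans = syn$n_bscans,
      texture_contrast = syn$texture_contrast,
      master_seed = config$seed)
    volumes <- study$volumes
    manifest <- study$manifest
  } else {
    manifest <- load_manifest(config$input$manifest)
    paths <- config$input$volume_paths
    volumes <- lapply(paths, load_volume)
    names(volumes) <- if (!is.null(names(paths))) names(paths) else
      vapply(volumes, function(v) v$sample_id, character(1))
  }
  manifest <- apply_inclusion_filter(manifest)
  excluded_samples <- manifest$sample_id[manifest$label == "excluded"]
  for (s in excluded_samples)
    .log("sample %s excluded: composition below inclusion thresholds", s)
  manifest <- manifest[manifest$label != "excluded", , drop = FALSE]

  # ---- segment + extract
  seg <- do.call(segmentation_params, config$segmentation)
  tex <- do.call(texture_config, config$texture)
  tables <- list()
  n_tiles <- 0L
  n_excluded_bscans <- 0L
  for (sid in manifest$sample_id) {
    vol <- volumes[[sid]]
    if (is.null(vol)) stop("segment stage: no volume for sample ", sid)
    tilesets <- segment_volume(vol, seg)
    empty <- attr(tilesets, "empty_bscans")
    n_excluded_bscans <- n_excluded_bscans + length(empty)
    for (b in empty)
      .log("sample %s B-scan %d excluded: no tiles within ROI", sid, b)
    n_tiles <- n_tiles + sum(vapply(tilesets, function(t) t$n_kept,
                                    integer(1)))
    lab <- manifest$label[manifest$sample_id == sid]
    tables[[sid]] <- extract_features(vol, tilesets, tex, label = lab,
                                      sample_id = sid)
  }
  features <- do.call(rbind, tables)
  rownames(features) <- NULL
  fpath <- file.path(config$out_dir, "features.csv")
  save_feature_table(features, fpath)
  .log("feature table: %d B-scans x 276 features -> %s", nrow(features),
       fpath)

  # ---- classify
  ccfg_args <- config$classification
  ccfg_args$fold_seed <- .hash_seed(config$seed, 101L)
  results <- list()
  report_cls <- list()
  for (cmp in config$comparisons) {
    ccfg_args$comparison <- cmp
    ccfg <- do.call(classification_config, ccfg_args)
    sub <- comparison_subset(features, cmp)
    res <- grid_search(sub, ccfg)
    results[[cmp]] <- res
    jsonlite::write_json(
      list(comparison = cmp,
           c_grid = ccfg$c_grid, gamma_grid = ccfg$gamma_grid,
           accuracy_grid = res$accuracy_grid,
           best_c = res$best_c, best_gamma = res$best_gamma,
           best_accuracy = res$best_accuracy,
           threshold = res$threshold,
           region_above_threshold = res$region_above_threshold),
      file.path(config$out_dir, paste0("grid_", cmp, ".json")),
      auto_unbox = TRUE, digits = NA)
    report_cls[[cmp]] <- list(best_accuracy = res$best_accuracy,
                              best_c = res$best_c,
                              best_gamma = res$best_gamma,
                              n_points_above_threshold =
                                nrow(res$region_above_threshold))
    .log("%s: best accuracy %.2f%% (c=%g, gamma=%g)", cmp,
         res$best_accuracy, res$best_c, res$best_gamma)
  }

  sweep_tab <- NULL
  if (isTRUE(config$sweep)) {
    ccfg <- do.call(classification_config, ccfg_args)
    sweep_tab <- run_feature_set_sweep(features, ccfg,
                                       comparisons = config$comparisons)
    utils::write.csv(sweep_tab, file.path(config$out_dir, "sweep.csv"),
                     row.names = FALSE)
  }

  report <- list(
    seed = config$seed,
    n_samples = nrow(manifest),
    n_excluded_samples = length(excluded_samples),
    samples_per_label = as.list(table(manifest$label)),
    n_bscans_total = sum(vapply(manifest$sample_id, function(s)
      n_bscans(volumes[[s]]), integer(1))),
    n_bscans_used = nrow(features),
    n_excluded_bscans = n_excluded_bscans,
    n_tiles = n_tiles,
    classification = report_cls)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(report, "results") <- results
  if (!is.null(sweep_tab)) attr(report, "sweep") <- sweep_tab
  invisible(report)
}
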