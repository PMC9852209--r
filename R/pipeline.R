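# End-to-end orchestration: simulate a cohort to disk, fit the full
# pipeline (preprocess -> discretize -> select -> train -> evaluate ->
# map clusters), and report. Every stage seeds its RNG from the global
# seed by a stable arithmetic fan-out, so stages can be rerun in
# isolation and identical configurations reproduce identical outputs.

#' Pipeline configuration
#'
#' Collects all paths and numeric settings of the pipeline in one
#' (YAML-serializable) list. Defaults mirror the package's standard
#' desk-scale study: the clustered survival preset on the default
#' phantom, 10-mm smoothing, profiles chosen over k = 2..6, m = 400
#' voxels retained per profile, a 10% stratified holdout and
#' informedness-maximizing hyper-parameter search.
#'
#' @param output_dir Directory for all artifacts.
#' @param volumes_dir,mask_path,cohort_path Input locations (filled by
#'   [run_simulate()] when simulating).
#' @param n_subjects,preset Cohort simulation settings.
#' @param fwhm_mm Smoothing width in mm (0 disables smoothing).
#' @param normalize Whether to intensity-normalize to the whole-brain
#'   mean.
#' @param k_range,restarts Survival discretization settings.
#' @param n_neighbors,kernel_width,m Voxel selection settings.
#' @param budget,folds,test_fraction Classifier settings.
#' @param min_extent,connectivity Cluster mapping settings.
#' @param seed Global seed fanned out to the stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir = "survoxel_run",
                            volumes_dir = file.path(output_dir, "volumes"),
                            mask_path = file.path(output_dir, "mask.nii.gz"),
                            cohort_path = file.path(output_dir, "cohort.tsv"),
                            n_subjects = 418L, preset = "clustered",
                            fwhm_mm = 10, normalize = TRUE,
                            k_range = 2:6, restarts = 20,
                            n_neighbors = 5, kernel_width = "auto", m = 400,
                            budget = 50, folds = 10, test_fraction = 0.1,
                            min_extent = 100, connectivity = 26,
                            seed = 0L) {
  cfg <- list(
    paths = list(output_dir = output_dir, volumes_dir = volumes_dir,
                 mask_path = mask_path, cohort_path = cohort_path),
    simulate = list(n_subjects = as.integer(n_subjects), preset = preset),
    preprocessing = list(fwhm_mm = fwhm_mm, normalize = normalize),
    discretization = list(k_range = as.integer(k_range),
                          restarts = as.integer(restarts)),
    selection = list(n_neighbors = as.integer(n_neighbors),
                     kernel_width = kernel_width, m = as.integer(m)),
    classification = list(budget = as.integer(budget),
                          folds = as.integer(folds),
                          test_fraction = test_fraction),
    clustering = list(min_extent = as.integer(min_extent),
                      connectivity = as.integer(connectivity)),
    seed = as.integer(seed))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()] object.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config`
#'   returns the configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("pipeline_config", "list"))
}

# deterministic per-stage seed below 2^31
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, split = 2L, discretize = 3L, select = 4L,
              train = 5L)
  off <- stages[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

write_manifest <- function(config, dir, stage) {
  cfg_path <- file.path(dir, "config.yaml")
  write_config(config, cfg_path)
  manifest <- list(stage = stage,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("survoxel")))
  jsonlite::write_json(manifest, file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a synthetic cohort to disk
#'
#' Draws survival times and clinical covariates, generates phantom
#' volumes, and writes the cohort TSV, the NIfTI volumes and mask,
#' ground-truth lesion masks, the configuration YAML and a manifest.
#'
#' @param config A [pipeline_config()] object.
#' @param phantom A [phantom_config()] (defaults to the package
#'   default geometry with the configured number of subjects).
#' @return Invisibly, a list with the cohort and the file layout.
#' @export
run_simulate <- function(config = pipeline_config(), phantom = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$paths
  dir.create(p$volumes_dir, recursive = TRUE, showWarnings = FALSE)
  truth_dir <- file.path(p$output_dir, "lesion_truth")
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(phantom)) phantom <- phantom_config(n_subjects = config$simulate$n_subjects)
  seed <- stage_seed(config$seed, "simulate")
  cohort <- simulate_cohort(config$simulate$n_subjects,
                            preset = config$simulate$preset, seed = seed)
  ph <- generate_phantom_volumes(phantom, cohort, seed = seed + 1L)
  write_cohort(cohort, p$cohort_path)
  write_volume(ph$mask, p$mask_path, affine = ph$affine)
  vol_paths <- character(length(ph$volumes))
  for (i in seq_along(ph$volumes)) {
    vol_paths[i] <- file.path(p$volumes_dir,
                              paste0(cohort$subject_id[i], ".nii.gz"))
    write_volume(ph$volumes[[i]], vol_paths[i])
  }
  for (l in seq_along(ph$lesion_truth)) {
    lt <- ph$lesion_truth[[l]]
    write_volume(array(as.integer(lt$mask), dim(lt$mask)),
                 file.path(truth_dir, sprintf("lesion_%02d_class%d.nii.gz",
                                              l, lt$class_id)),
                 affine = ph$affine)
  }
  write_manifest(config, p$output_dir, "simulate")
  message(sprintf("simulated %d subjects (%d masked voxels) into %s",
                  nrow(cohort), ph$mask$n_voxels, p$output_dir))
  invisible(list(cohort = cohort, volume_paths = vol_paths, phantom = ph))
}

preflight <- function(config) {
  p <- config$paths
  missing <- character(0)
  if (!file.exists(p$cohort_path)) missing <- c(missing, p$cohort_path)
  if (!file.exists(p$mask_path)) missing <- c(missing, p$mask_path)
  if (!dir.exists(p$volumes_dir)) missing <- c(missing, p$volumes_dir)
  if (length(missing))
    stop("missing inputs:\n  ", paste(missing, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

#' Fit the full pipeline
#'
#' Sequences the stages on existing inputs: load and preprocess the
#' volumes (smooth, normalize, mask), assemble the feature matrix,
#' discretize survival with [select_k()], split a stratified holdout,
#' rank voxels per profile on the training subjects only, train and
#' tune the one-against-all SVMs, evaluate on the holdout, and map each
#' profile's selected voxels to contiguous clusters. All artifacts are
#' written under the configured output directory.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with `partition`, `split`, `rankings`,
#'   `models`, `eval`, `clusters` and `features`.
#' @export
run_fit <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  preflight(config)
  p <- config$paths
  cohort <- read_cohort(p$cohort_path)
  mask <- load_mask(p$mask_path)
  t0 <- Sys.time()

  vols <- lapply(cohort$subject_id, function(id) {
    v <- load_volume(file.path(p$volumes_dir, paste0(id, ".nii.gz")),
                     subject_id = id, expected_shape = dim(mask$data))
    if (config$preprocessing$fwhm_mm > 0)
      v <- gaussian_smooth(v, config$preprocessing$fwhm_mm)
    if (isTRUE(config$preprocessing$normalize))
      v <- normalize_whole_brain(v, mask)
    v
  })
  features <- assemble_features(vols, mask)
  message(sprintf("preprocessed %d volumes -> %d x %d feature matrix [%.1fs]",
                  length(vols), nrow(features$values), ncol(features$values),
                  as.numeric(Sys.time() - t0, units = "secs")))

  sel <- select_k(cohort$survival_years, k_range = config$discretization$k_range,
                  restarts = config$discretization$restarts,
                  seed = stage_seed(config$seed, "discretize"))
  partition <- sel$partition
  message(sprintf("discretized survival: k = %d, VE = %.1f%%",
                  partition$k, 100 * partition$ve))

  split <- split_train_test(cohort$subject_id, partition$labels,
                            test_fraction = config$classification$test_fraction,
                            seed = stage_seed(config$seed, "split"))
  train_labels <- partition$labels[split$train_idx]

  rankings <- lapply(sort(unique(partition$labels)), function(cid) {
    class_aware_ranking(features$values[split$train_idx, , drop = FALSE],
                        train_labels, cid, m = config$selection$m,
                        n_neighbors = config$selection$n_neighbors,
                        kernel_width = config$selection$kernel_width)
  })

  models <- train_ova(features$values[split$train_idx, , drop = FALSE],
                      train_labels, rankings,
                      budget = config$classification$budget,
                      folds = config$classification$folds,
                      seed = stage_seed(config$seed, "train"))
  eval <- evaluate_holdout(models, features$values[split$test_idx, , drop = FALSE],
                           partition$labels[split$test_idx])

  clusters <- do.call(rbind, lapply(rankings, function(rk) {
    map_class_clusters(rk, features, partition$labels,
                       min_extent = config$clustering$min_extent,
                       connectivity = config$clustering$connectivity)
  }))

  # artifacts
  dir.create(p$output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(k = partition$k, ve = partition$ve, boundaries = partition$boundaries,
         labels = partition$labels, criterion = as.list(sel$criterion)),
    file.path(p$output_dir, "partition.json"), auto_unbox = TRUE, digits = NA)
  for (rk in rankings) {
    tab <- data.frame(voxel = rk$order,
                      i = features$voxel_index[rk$order, 1],
                      j = features$voxel_index[rk$order, 2],
                      k = features$voxel_index[rk$order, 3],
                      score = rk$scores[rk$order],
                      rank = seq_along(rk$order))
    utils::write.table(utils::head(tab, rk$m),
                       file.path(p$output_dir, sprintf("ranking_class%s.tsv", rk$class_id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    msk <- array(FALSE, features$grid_shape)
    msk[features$lin_index[rk$selected]] <- TRUE
    write_volume(array(as.integer(msk), dim(msk)),
                 file.path(p$output_dir, sprintf("selected_class%s.nii.gz", rk$class_id)),
                 affine = features$affine)
  }
  jsonlite::write_json(
    lapply(models, function(m) list(class_id = m$class_id, kernel = m$kernel,
                                    cost = m$cost, gamma = m$gamma,
                                    degree = m$degree,
                                    cv_informedness = m$cv_informedness,
                                    n_features = length(m$feature_set))),
    file.path(p$output_dir, "models.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(eval, file.path(p$output_dir, "eval.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(clusters, file.path(p$output_dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, p$output_dir, "fit")
  message(sprintf("fit complete [%.1fs total]",
                  as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(partition = partition, split = split, rankings = rankings,
                 models = models, eval = eval, clusters = clusters,
                 features = features))
}

#' Consolidated human-readable report of a fitted run
#'
#' Reads the artifacts written by [run_fit()] and prints the survival
#' partition, per-profile holdout metrics and the cluster table.
#'
#' @param output_dir Directory written by [run_fit()].
#' @return Invisibly, a list of the parsed artifacts.
#' @export
run_report <- function(output_dir) {
  part <- jsonlite::read_json(file.path(output_dir, "partition.json"),
                              simplifyVector = TRUE)
  eval <- jsonlite::read_json(file.path(output_dir, "eval.json"),
                              simplifyVector = TRUE)
  clusters <- utils::read.delim(file.path(output_dir, "clusters.tsv"))
  cat(sprintf("Survival discretization: k = %d profiles, VE = %.1f%%\n",
              part$k, 100 * part$ve))
  cat(sprintf("  boundaries (years): %s\n",
              paste(sprintf("%.2f", part$boundaries), collapse = ", ")))
  cat("Holdout performance (one-against-all):\n")
  for (i in seq_len(nrow(eval)))
    cat(sprintf("  class %s: error %.2f%%, informedness %.3f, c-statistic %.3f\n",
                eval$class_id[i], 100 * eval$error_rate[i],
                eval$informedness[i], eval$c_statistic[i]))
  cat(sprintf("Discriminant clusters (extent > threshold): %d\n", nrow(clusters)))
  if (nrow(clusters) > 0) {
    for (i in seq_len(nrow(clusters)))
      cat(sprintf("  class %s cluster %d: %d voxels, %s, peak (%g, %g, %g)\n",
                  clusters$class_id[i], clusters$cluster[i], clusters$extent[i],
                  clusters$direction[i], clusters$peak_x[i], clusters$peak_y[i],
                  clusters$peak_z[i]))
  }
  invisible(list(partition = part, eval = eval, clusters = clusters))
}
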