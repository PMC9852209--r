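# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# the default phantom study: 418 subjects, clustered survival preset,
# default geometry, smoothed and normalized feature matrix
default_phantom_study <- function(seed = 42) {
  key <- paste0("phantom_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- phantom_config()
  cohort <- simulate_cohort(cfg$n_subjects, preset = "clustered", seed = seed)
  ph <- generate_phantom_volumes(cfg, cohort, seed = seed + 1L)
  vols <- lapply(ph$volumes, function(v)
    normalize_whole_brain(gaussian_smooth(v, 10), ph$mask))
  features <- assemble_features(vols, ph$mask)
  out <- list(config = cfg, cohort = cohort, phantom = ph, features = features)
  .fixture_cache[[key]] <- out
  out
}

# truth columns (feature-matrix indices) of a class's planted lesions
lesion_truth_columns <- function(study, class_id) {
  lins <- unique(unlist(lapply(study$phantom$lesion_truth, function(l)
    if (l$class_id == class_id) which(l$mask))))
  which(study$features$lin_index %in% lins)
}

# a small balanced phantom with per-class sizes large enough for the
# default graph neighbourhood
balanced_phantom_features <- function(n_per_class = 20, seed = 1) {
  cohort <- data.frame(
    subject_id = sprintf("B%03d", seq_len(3 * n_per_class)),
    true_class = rep(1:3, each = n_per_class))
  cfg <- phantom_config(n_subjects = nrow(cohort))
  ph <- generate_phantom_volumes(cfg, cohort, seed = seed)
  vols <- lapply(ph$volumes, function(v)
    normalize_whole_brain(gaussian_smooth(v, 10), ph$mask))
  list(cohort = cohort, phantom = ph,
       features = assemble_features(vols, ph$mask))
}

# linearly separable binary toy problem
separable_toy <- function(n_per_class = 20, seed = 1) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    x <- rbind(matrix(rnorm(2 * n_per_class, 0, 0.3), ncol = 2),
               matrix(rnorm(2 * n_per_class, 5, 0.3), ncol = 2))
    y <- factor(rep(c("neg", "pos"), each = n_per_class),
                levels = c("neg", "pos"))
    list(x = x, y = y)
  })
}
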