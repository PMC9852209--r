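# One-against-all SVM classification on per-class voxel sets, tuned by
# cross-validated informedness (Youden's J) and evaluated on a
# stratified holdout.

#' Stratified train/test split
#'
#' Each class contributes `round(test_fraction * n_c)` subjects
#' (half away from zero, at least one, leaving at least one for
#' training) to the test set.
#'
#' @param subject_ids Vector of subject identifiers.
#' @param labels Class label per subject (every class needs >= 2
#'   members).
#' @param test_fraction Fraction held out (default 0.1).
#' @param seed Optional integer seed.
#' @return A list with `train` and `test` id vectors (and index vectors
#'   `train_idx`, `test_idx`).
#' @export
split_train_test <- function(subject_ids, labels, test_fraction = 0.1,
                             seed = NULL) {
  stopifnot(length(subject_ids) == length(labels))
  counts <- table(labels)
  if (any(counts < 2))
    stop("every class needs at least 2 members to split", call. = FALSE)
  with_seed(seed, {
    test_idx <- integer(0)
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      n_test <- min(max(1L, floor(test_fraction * length(idx) + 0.5)),
                    length(idx) - 1L)
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    test_idx <- sort(test_idx)
    train_idx <- setdiff(seq_along(labels), test_idx)
    list(train = subject_ids[train_idx], test = subject_ids[test_idx],
         train_idx = train_idx, test_idx = test_idx)
  })
}

#' Informedness (Youden's J) from a 2x2 confusion
#'
#' `J = sensitivity + specificity - 1 = TP/(TP+FN) + TN/(TN+FP) - 1`,
#' the chance-corrected gain of a binary classifier; equals twice the
#' balanced accuracy minus one.
#'
#' @param tp,fn,fp,tn Confusion counts; `tp + fn` and `tn + fp` must be
#'   positive. Alternatively pass a 2x2 matrix
#'   `rbind(c(tp, fn), c(fp, tn))` as `tp`.
#' @return J in \[-1, 1\].
#' @export
informedness <- function(tp, fn = NULL, fp = NULL, tn = NULL) {
  if (is.matrix(tp)) {
    stopifnot(all(dim(tp) == c(2, 2)))
    fn <- tp[1, 2]; fp <- tp[2, 1]; tn <- tp[2, 2]; tp <- tp[1, 1]
  }
  if (tp + fn <= 0) stop("no positive ground truth: J undefined", call. = FALSE)
  if (tn + fp <= 0) stop("no negative ground truth: J undefined", call. = FALSE)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Area under the ROC curve from decision values
#'
#' Rank statistic with midranks, so tied scores count one half: equals
#' the probability that a random positive outranks a random negative.
#'
#' @param scores Continuous decision values.
#' @param positive Logical vector marking the positive class.
#' @return AUROC in \[0, 1\], or `NA` when either class is absent.
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# stratified fold assignment
make_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    f[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  f
}

fit_svm <- function(x, y, cfg) {
  e1071::svm(x = x, y = y, kernel = cfg$kernel, cost = cfg$cost,
             gamma = cfg$gamma, degree = cfg$degree, coef0 = 1,
             scale = FALSE)
}

# decision values oriented so that larger means "pos"
decision_values <- function(model, x) {
  p <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], "pos")) 1 else -1
  list(pred = p, dv = sgn * as.numeric(dv))
}

confusion_counts <- function(truth_pos, pred_pos) {
  c(tp = sum(truth_pos & pred_pos), fn = sum(truth_pos & !pred_pos),
    fp = sum(!truth_pos & pred_pos), tn = sum(!truth_pos & !pred_pos))
}

# mean CV informedness of one configuration; degenerate folds skipped
cv_informedness <- function(x, y, cfg, fold_id) {
  js <- c()
  for (f in unique(fold_id)) {
    tr <- fold_id != f; te <- !tr
    if (length(unique(y[tr])) < 2 || sum(y[te] == "pos") == 0 ||
        sum(y[te] == "neg") == 0) {
      warning("skipping degenerate cross-validation fold", call. = FALSE)
      next
    }
    m <- fit_svm(x[tr, , drop = FALSE], y[tr], cfg)
    pred <- stats::predict(m, x[te, , drop = FALSE])
    cc <- confusion_counts(y[te] == "pos", pred == "pos")
    js <- c(js, informedness(cc["tp"], cc["fn"], cc["fp"], cc["tn"]))
  }
  if (length(js) == 0) stop("all cross-validation folds degenerate", call. = FALSE)
  mean(js)
}

sample_config <- function(kernels) {
  kernel <- sample(kernels, 1)
  list(kernel = kernel,
       cost = 10^stats::runif(1, -3, 3),
       gamma = 10^stats::runif(1, -4, 1),
       degree = if (kernel == "polynomial") sample(2:4, 1) else 3L)
}

#' Hyper-parameter search maximizing cross-validated informedness
#'
#' Random search over kernel type (linear, radial, polynomial),
#' regularization cost on a log scale in \[1e-3, 1e3\], kernel width
#' `gamma` in \[1e-4, 10\] and polynomial degree 2-4. Each candidate is
#' scored by its mean informedness over stratified cross-validation
#' folds; the best configuration visited within the budget is returned.
#' The search trajectory is deterministic under a fixed seed.
#'
#' @param x Training feature matrix (rows already restricted to the
#'   class's selected voxels).
#' @param y Binary labels: logical, or factor with levels
#'   `c("neg", "pos")`.
#' @param budget Number of configurations to evaluate (>= 1).
#' @param folds Cross-validation folds (default 10; reduced with a
#'   warning when a class has fewer members).
#' @param seed Optional integer seed.
#' @param kernels Kernel types to search over.
#' @return A list: `best` (configuration + `cv_informedness`) and
#'   `trace` (data frame of all evaluations).
#' @export
tune_hyperparameters <- function(x, y, budget = 50, folds = 10, seed = NULL,
                                 kernels = c("linear", "radial", "polynomial")) {
  if (budget < 1) stop("`budget` must be >= 1", call. = FALSE)
  if (is.logical(y)) y <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  y <- factor(y, levels = c("neg", "pos"))
  counts <- table(y)
  if (any(counts < 2)) stop("both classes need >= 2 training members", call. = FALSE)
  if (folds > min(counts)) {
    folds <- max(2L, as.integer(min(counts)))
    warning(sprintf("reducing folds to %d (smallest class size)", folds),
            call. = FALSE)
  }
  x <- as.matrix(x)
  with_seed(seed, {
    fold_id <- make_folds(y, folds)
    trace <- vector("list", budget)
    best <- NULL
    for (b in seq_len(budget)) {
      cfg <- sample_config(kernels)
      j <- cv_informedness(x, y, cfg, fold_id)
      trace[[b]] <- data.frame(iter = b, kernel = cfg$kernel, cost = cfg$cost,
                               gamma = cfg$gamma, degree = cfg$degree,
                               cv_informedness = j)
      if (is.null(best) || j > best$cv_informedness + 1e-12) {
        best <- cfg; best$cv_informedness <- j
      }
    }
    list(best = best, trace = do.call(rbind, trace))
  })
}

#' Train one-against-all SVMs on per-class voxel sets
#'
#' For each survival profile: labels are binarized (profile vs rest),
#' the training columns are restricted to that profile's selected
#' voxels, hyper-parameters are tuned by [tune_hyperparameters()], and
#' the classifier is refit on all training rows with the optimal
#' configuration.
#'
#' @param x_train Training feature matrix (subjects x all voxels).
#' @param labels Profile label per training subject.
#' @param rankings List of [class_aware_ranking()] results covering all
#'   profiles present in `labels`.
#' @param budget,folds,seed Passed to [tune_hyperparameters()].
#' @return A list of `ova_model` objects (one per profile), each with
#'   `class_id`, `feature_set`, `kernel`, `cost`, `gamma`, `degree`,
#'   `cv_informedness` and the fitted classifier.
#' @export
train_ova <- function(x_train, labels, rankings, budget = 50, folds = 10,
                      seed = NULL) {
  x_train <- if (inherits(x_train, "feature_matrix")) x_train$values else as.matrix(x_train)
  class_ids <- sort(unique(labels))
  rank_ids <- vapply(rankings, function(r) r$class_id, class_ids[1])
  if (!all(class_ids %in% rank_ids))
    stop("`rankings` must cover every class present in `labels`", call. = FALSE)
  models <- list()
  for (i in seq_along(class_ids)) {
    cid <- class_ids[i]
    rk <- rankings[[which(rank_ids == cid)[1]]]
    xs <- x_train[, rk$selected, drop = FALSE]
    y <- factor(ifelse(labels == cid, "pos", "neg"), levels = c("neg", "pos"))
    tuned <- tune_hyperparameters(xs, y, budget = budget, folds = folds,
                                  seed = if (is.null(seed)) NULL else seed + i)
    fit <- fit_svm(xs, y, tuned$best)
    models[[i]] <- structure(
      list(class_id = cid, feature_set = rk$selected,
           kernel = tuned$best$kernel, cost = tuned$best$cost,
           gamma = tuned$best$gamma, degree = tuned$best$degree,
           cv_informedness = tuned$best$cv_informedness, fit = fit),
      class = "ova_model")
  }
  models
}

#' @export
print.ova_model <- function(x, ...) {
  cat(sprintf("ova_model: class %s vs rest, %s kernel, cost %.3g, CV J = %.3f\n",
              x$class_id, x$kernel, x$cost, x$cv_informedness))
  invisible(x)
}

#' Evaluate one-against-all models on a holdout set
#'
#' Per profile: binary confusion counts at the SVM's decision
#' threshold, error rate `(FP+FN)/n`, informedness, and the c-statistic
#' (AUROC of the continuous decision values, tied scores midranked).
#' Profiles absent from the test set get `NA` metrics and are flagged.
#'
#' @param models List from [train_ova()].
#' @param x_test Holdout feature matrix (all voxels; rows must be
#'   disjoint from training rows).
#' @param labels_test Profile label per holdout subject.
#' @return An `eval_report` data frame: one row per profile with
#'   confusion counts, `error_rate`, `informedness`, `c_statistic` and
#'   `flagged`.
#' @export
evaluate_holdout <- function(models, x_test, labels_test) {
  x_test <- if (inherits(x_test, "feature_matrix")) x_test$values else as.matrix(x_test)
  rows <- lapply(models, function(m) {
    xs <- x_test[, m$feature_set, drop = FALSE]
    out <- decision_values(m$fit, xs)
    truth <- labels_test == m$class_id
    if (sum(truth) == 0 || sum(!truth) == 0) {
      return(data.frame(class_id = m$class_id, tp = NA, fn = NA, fp = NA,
                        tn = NA, error_rate = NA, informedness = NA,
                        c_statistic = NA, flagged = TRUE))
    }
    cc <- confusion_counts(truth, out$pred == "pos")
    data.frame(class_id = m$class_id,
               tp = cc["tp"], fn = cc["fn"], fp = cc["fp"], tn = cc["tn"],
               error_rate = (cc["fp"] + cc["fn"]) / length(truth),
               informedness = informedness(cc["tp"], cc["fn"], cc["fp"], cc["tn"]),
               c_statistic = auroc(out$dv, truth),
               flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("holdout evaluation (one-against-all):\n")
  for (i in seq_len(nrow(x))) {
    if (isTRUE(x$flagged[i])) {
      cat(sprintf("  class %s: undefined (class missing from test set)\n",
                  x$class_id[i]))
    } else {
      cat(sprintf("  class %s: error %.2f%%, J = %.3f, c-statistic = %.3f\n",
                  x$class_id[i], 100 * x$error_rate[i], x$informedness[i],
                  x$c_statistic[i]))
    }
  }
  invisible(x)
}

#' K-nearest-neighbour baseline with the same evaluation contract
#'
#' @param x_train,x_test Feature matrices (all voxels).
#' @param y Training profile labels.
#' @param feature_set Voxel column indices to use (nonempty).
#' @param k_neighbors Number of neighbours (< training size).
#' @param labels_test Holdout profile labels.
#' @param class_id Positive profile (defaults to the first in `y`).
#' @return A one-row `eval_report` data frame.
#' @export
baseline_knn <- function(x_train, y, feature_set, k_neighbors, x_test,
                         labels_test, class_id = sort(unique(y))[1]) {
  if (length(feature_set) == 0) stop("`feature_set` is empty", call. = FALSE)
  x_train <- if (inherits(x_train, "feature_matrix")) x_train$values else as.matrix(x_train)
  x_test <- if (inherits(x_test, "feature_matrix")) x_test$values else as.matrix(x_test)
  if (k_neighbors >= nrow(x_train))
    stop("`k_neighbors` must be below the training size", call. = FALSE)
  ytr <- factor(ifelse(y == class_id, "pos", "neg"), levels = c("neg", "pos"))
  pred <- class::knn(x_train[, feature_set, drop = FALSE],
                     x_test[, feature_set, drop = FALSE],
                     ytr, k = k_neighbors, prob = TRUE)
  vote <- attr(pred, "prob")
  dv <- ifelse(pred == "pos", vote, 1 - vote)  # fraction of neighbours voting pos
  truth <- labels_test == class_id
  cc <- confusion_counts(truth, pred == "pos")
  out <- data.frame(class_id = class_id,
                    tp = cc["tp"], fn = cc["fn"], fp = cc["fp"], tn = cc["tn"],
                    error_rate = (cc["fp"] + cc["fn"]) / length(truth),
                    informedness = informedness(cc["tp"], cc["fn"], cc["fp"], cc["tn"]),
                    c_statistic = auroc(dv, truth), flagged = FALSE)
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}
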