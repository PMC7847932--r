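#' Cross-validation configuration
#'
#' @param n_folds folds per repeat (>= 2; 5 reproduces the study protocol).
#' @param n_repeats repeats with fresh fold assignments (the study protocol
#'   uses 200; smaller values are convenient at desk scale).
#' @param seed master seed; per-repeat and per-fit substreams derive from it.
#' @param positive_class optional class name treated as positive for
#'   sensitivity/specificity and ROC; defaults to the first class of the
#'   task.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 5L, n_repeats = 200L, seed = 1L,
                      positive_class = NULL) {
  if (!is_count(n_folds) || n_folds < 2)
    abort_validation("n_folds must be an integer >= 2")
  if (!is_count(n_repeats)) abort_validation("n_repeats must be >= 1")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 positive_class = positive_class),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Shuffles within each class, then deals members round-robin over folds, so
#' per-fold class counts differ from the ideal proportion by at most one
#' subject. Folds are disjoint and exhaustive.
#'
#' @param labels integer class codes or factor.
#' @param n_folds number of folds; every class must have at least `n_folds`
#'   members.
#' @param seed integer seed.
#' @return Integer fold assignment in `1..n_folds`, one per subject.
#' @export
stratified_folds <- function(labels, n_folds, seed = 1L) {
  labels <- as.integer(as.factor(labels))
  if (any(tabulate(labels) < n_folds))
    abort_validation("every class must have at least n_folds members")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Classification metrics from confusion counts
#'
#' `ACC = 100 (TP + TN) / total`, `SEN = 100 TP / (TP + FN)`,
#' `SPE = 100 TN / (TN + FP)`. A zero denominator yields `NA` with a
#' warning.
#'
#' @param tp,fp,tn,fn nonnegative confusion counts.
#' @return List with `acc`, `sen`, `spe`, in percent.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total == 0) abort_validation("confusion counts are all zero")
  sen <- if (tp + fn == 0) {
    warning("no positive subjects; sensitivity undefined"); NA_real_
  } else 100 * tp / (tp + fn)
  spe <- if (tn + fp == 0) {
    warning("no negative subjects; specificity undefined"); NA_real_
  } else 100 * tn / (tn + fp)
  list(acc = 100 * (tp + tn) / total, sen = sen, spe = spe)
}

#' Area under the ROC curve
#'
#' Sweeps thresholds over the distinct score values (ties grouped), builds
#' the ROC polygon from (0, 0) to (1, 1) and integrates by the trapezoid
#' rule — which makes the result equal to the Mann-Whitney concordance
#' probability with half credit for ties.
#'
#' @param scores continuous scores for the positive class.
#' @param truth binary truth, 1 (or `TRUE`) = positive.
#' @return List with `auc` and `roc`, a data frame of `fpr`/`tpr` points.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth))
    abort_validation("scores and truth must align")
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0)
    abort_validation("both classes must be present in truth")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(t == 1)[grp_end]
  fp <- cumsum(t == 0)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Repeated stratified cross-validation of one binary task
#'
#' Restricts the dataset to the two task classes and, for every repeat,
#' draws fresh stratified folds; within each fold the *entire* pipeline —
#' normalization, PCA, the per-modality sparse-response DBNs, and the ELM —
#' is fitted on the training portion only and evaluated on the held-out
#' fold. Fold metrics are averaged per repeat; the aggregate is the mean and
#' standard deviation across repeats.
#'
#' @param dataset a [labeled_dataset()].
#' @param task character pair of class names; the first is the positive
#'   class unless `cv$positive_class` overrides it.
#' @param config a [pipeline_config()].
#' @param cv a [cv_config()].
#' @return An object of class `cv_result`: `per_repeat` (data frame of
#'   repeat-level mean ACC/SEN/SPE in percent and AUC), `aggregate` (mean
#'   and sd of each metric across repeats), `roc` (pooled ROC points from
#'   the first repeat) and the configs used.
#' @export
run_task_cv <- function(dataset, task, config, cv) {
  if (length(task) != 2) abort_validation("task must name two classes")
  ds <- subset_dataset(dataset, classes = task)
  positive <- cv$positive_class %||% task[1]
  if (!positive %in% task) abort_validation("positive_class must be in task")
  pos_code <- match(positive, task) - 1L
  per_repeat <- data.frame(rep = seq_len(cv$n_repeats), acc = NA_real_,
                           sen = NA_real_, spe = NA_real_, auc = NA_real_)
  roc_points <- NULL
  for (r in seq_len(cv$n_repeats)) {
    folds <- stratified_folds(ds$labels, cv$n_folds,
                              derive_seed(cv$seed, paste0("folds_rep", r)))
    fm <- matrix(NA_real_, cv$n_folds, 4)
    rep_scores <- list()
    rep_truth <- list()
    for (f in seq_len(cv$n_folds)) {
      train <- subset_dataset(ds, rows = which(folds != f))
      test <- subset_dataset(ds, rows = which(folds == f))
      fit_cfg <- config
      fit_cfg$seed <- derive_seed(cv$seed, sprintf("fit_rep%d_fold%d", r, f))
      bundle <- tryCatch(fit_pipeline(train, fit_cfg),
                         error = function(e)
                           abort_state(sprintf("repeat %d fold %d: %s", r, f,
                                               conditionMessage(e))))
      pred <- predict_pipeline(bundle, test)
      truth_pos <- as.integer(test$labels == pos_code)
      pred_pos <- as.integer(pred$codes == pos_code)
      cm <- confusion_metrics(tp = sum(pred_pos == 1 & truth_pos == 1),
                              fp = sum(pred_pos == 1 & truth_pos == 0),
                              tn = sum(pred_pos == 0 & truth_pos == 0),
                              fn = sum(pred_pos == 0 & truth_pos == 1))
      sc <- pred$scores[, positive]
      fm[f, ] <- c(cm$acc, cm$sen, cm$spe,
                   roc_auc(sc, truth_pos)$auc)
      rep_scores[[f]] <- sc
      rep_truth[[f]] <- truth_pos
    }
    per_repeat[r, c("acc", "sen", "spe", "auc")] <-
      colMeans(fm, na.rm = TRUE)
    if (r == 1)
      roc_points <- roc_auc(unlist(rep_scores), unlist(rep_truth))$roc
  }
  agg <- list(mean = colMeans(per_repeat[, -1]),
              sd = apply(per_repeat[, -1], 2L, stats::sd))
  structure(list(task = task, positive_class = positive,
                 per_repeat = per_repeat, aggregate = agg, roc = roc_points,
                 cv = cv, config_variant = config$variant),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s vs %s (positive: %s), %d x %d-fold CV [%s]\n",
              x$task[1], x$task[2], x$positive_class, x$cv$n_repeats,
              x$cv$n_folds, x$config_variant))
  m <- x$aggregate$mean
  s <- x$aggregate$sd
  cat(sprintf("  ACC %.2f +/- %.2f  SEN %.2f +/- %.2f  SPE %.2f +/- %.2f  AUC %.3f +/- %.3f\n",
              m["acc"], s["acc"], m["sen"], s["sen"], m["spe"], s["spe"],
              m["auc"], s["auc"]))
  invisible(x)
}

#' Run several tasks under several pipeline variants
#'
#' Variants: `full` (PCA, one sparse-response DBN per modality, ELM),
#' `no_sparsity` (identical but with the sparsity weight forced to 0), and
#' `pca_elm` (PCA scores fed straight to the ELM).
#'
#' @param dataset a [labeled_dataset()].
#' @param tasks list of class-name pairs.
#' @param variants character subset of `c("full", "no_sparsity", "pca_elm")`.
#' @param config base [pipeline_config()].
#' @param cv a [cv_config()].
#' @return A long data frame with columns `task`, `variant`, `metric`,
#'   `mean`, `sd`, plus attribute `"results"` holding every `cv_result`.
#' @export
run_experiment_suite <- function(dataset, tasks, variants, config, cv) {
  known <- c("full", "no_sparsity", "pca_elm")
  if (length(variants) == 0 || !all(variants %in% known))
    abort_validation(sprintf("variants must be a nonempty subset of: %s",
                             paste(known, collapse = ", ")))
  rows <- list()
  results <- list()
  for (v in variants) {
    cfg <- config
    cfg$variant <- v
    for (ti in seq_along(tasks)) {
      task <- tasks[[ti]]
      res <- run_task_cv(dataset, task, cfg, cv)
      key <- paste(paste(task, collapse = "_vs_"), v, sep = ".")
      results[[key]] <- res
      for (metric in c("acc", "sen", "spe", "auc"))
        rows[[length(rows) + 1L]] <-
          data.frame(task = paste(task, collapse = " vs "), variant = v,
                     metric = toupper(metric),
                     mean = unname(res$aggregate$mean[metric]),
                     sd = unname(res$aggregate$sd[metric]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}
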