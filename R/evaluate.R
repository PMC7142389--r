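# one coarse-to-fine selection + SVM fit on a training cohort; returns
# retained original-column indices and the fitted SVM (or NULL on an empty
# surviving set)
fit_fold <- function(train, screening_cfg, rfe_cfg) {
  sres <- withCallingHandlers(
    screen(train, screening_cfg),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!length(sres$selected_cols)) return(NULL)
  selection <- select_features(train, sres, rfe_cfg)
  svm <- fit_linear_svm(selection$cohort$X, train$y, rfe_cfg$C)
  list(cols = selection$cols, svm = svm)
}

#' Leave-one-out evaluation of the coarse-to-fine pipeline
#'
#' Runs N+M leave-one-out folds of the full pipeline (t-test screen,
#' SVM-RFE, linear SVM) and evaluates the pooled predictions with the
#' proportion-based metrics of [metrics_from_proportions()] plus the
#' Mann-Whitney AUC of the pooled decision scores.
#'
#' Two protocols are provided. In `"nested"` mode (the default, leakage-free)
#' screening and RFE are re-run on each training fold, so no selection
#' statistic ever sees the held-out subject. In `"pooled"` mode feature
#' selection is computed once on all subjects and only the SVM is refit per
#' fold — the common but optimistic shortcut in older neuroimaging studies,
#' provided for comparison; the mode is recorded in the result.
#'
#' A fold whose training screen leaves no surviving voxel is recorded as a
#' fold failure: the held-out subject gets the training majority-class
#' prediction (ties to `-1`) with decision score 0, and a warning is issued.
#'
#' @param cohort a [to_matrix()] cohort (>= 2 subjects per class).
#' @param screening_cfg a [screening_config()].
#' @param rfe_cfg an [rfe_config()].
#' @param mode `"nested"` or `"pooled"`.
#' @return an `evaluation_result`: `folds` (data.frame `subject`, `truth`,
#'   `predicted`, `score`, `n_features`, `failed`), `confusion`
#'   (`N`, `M`, `N1`, `M1`, `TP`, `TN`, `FN`, `FP`), `metrics`
#'   (`metric_set` plus `AUC`), `roc`, `mode`, `configs`.
#' @export
loo_evaluate <- function(cohort, screening_cfg = screening_config(),
                         rfe_cfg = rfe_config(),
                         mode = c("nested", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort_matrix"))
  n <- nrow(cohort$X)
  if (sum(cohort$y == 1) < 2 || sum(cohort$y == -1) < 2)
    stop("need >= 2 subjects per class", call. = FALSE)

  pooled_fit <- NULL
  if (mode == "pooled") {
    pooled_fit <- fit_fold(cohort, screening_cfg, rfe_cfg)
    if (is.null(pooled_fit))
      stop("screening left no surviving voxels on the full cohort",
           call. = FALSE)
  }

  pred <- numeric(n); score <- numeric(n)
  nfeat <- integer(n); failed <- logical(n)
  for (s in seq_len(n)) {
    train <- subset_rows(cohort, setdiff(seq_len(n), s))
    if (mode == "nested") {
      fold <- fit_fold(train, screening_cfg, rfe_cfg)
    } else {
      # selection fixed from the pooled stage; refit only the SVM
      fold <- list(cols = pooled_fit$cols,
                   svm = fit_linear_svm(train$X[, pooled_fit$cols,
                                                drop = FALSE],
                                        train$y, rfe_cfg$C))
    }
    if (is.null(fold)) {
      failed[s] <- TRUE
      maj <- sum(train$y == 1) - sum(train$y == -1)
      pred[s] <- if (maj > 0) 1 else -1
      score[s] <- 0
      nfeat[s] <- 0L
    } else {
      score[s] <- predict(fold$svm,
                          cohort$X[s, fold$cols, drop = FALSE], "score")
      pred[s] <- if (score[s] >= 0) 1 else -1
      nfeat[s] <- length(fold$cols)
    }
  }
  if (any(failed))
    warning(sum(failed), " fold(s) had an empty surviving set; ",
            "majority-class prediction used", call. = FALSE)

  N <- sum(cohort$y == 1); M <- sum(cohort$y == -1)
  N1 <- sum(pred == 1 & cohort$y == 1)
  M1 <- sum(pred == -1 & cohort$y == -1)
  metrics <- compute_metrics(N, M, N1, M1)
  ra <- roc_auc(score, cohort$y)
  metrics$AUC <- ra$auc
  structure(list(
    folds = data.frame(subject = seq_len(n), truth = cohort$y,
                       predicted = pred, score = score,
                       n_features = nfeat, failed = failed),
    confusion = list(N = N, M = M, N1 = N1, M1 = M1,
                     TP = N1 / N, TN = M1 / M,
                     FN = (N - N1) / N, FP = (M - M1) / M),
    metrics = metrics, roc = ra$roc, mode = mode,
    configs = list(screening = screening_cfg, rfe = rfe_cfg)),
    class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<evaluation_result> %d-fold LOO, %s selection\n",
              nrow(x$folds), x$mode))
  cat(sprintf(
    "  ACC %.4f  SN %.4f  SP %.4f  GM %.4f  DM %.4f  F2M %.4f  AUC %.4f\n",
    m$ACC, m$SN, m$SP, m$GM, m$DM, m$F2M, m$AUC))
  if (any(x$folds$failed))
    cat(sprintf("  %d fold failure(s)\n", sum(x$folds$failed)))
  invisible(x)
}

#' Write an evaluation result to disk
#'
#' Metrics/config to JSON, per-fold records and ROC points to TSV.
#'
#' @param eres an [loo_evaluate()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(eres, dir) {
  stopifnot(inherits(eres, "evaluation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(mode = eres$mode, metrics = unclass(eres$metrics),
         confusion = eres$confusion,
         configs = lapply(eres$configs, unclass)),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.table(eres$folds, file.path(dir, "folds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(eres$roc, file.path(dir, "roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
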