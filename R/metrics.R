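#' Classification metrics from proportion-based confusion entries
#'
#' The confusion entries here are per-class *proportions*, not counts: with
#' `N` positives (`N1` correct) and `M` negatives (`M1` correct),
#' `TP = N1/N`, `FN = (N-N1)/N`, `TN = M1/M`, `FP = (M-M1)/M`, so that
#' `TP + FN = 1` and `TN + FP = 1`. On these entries the six metrics are
#' \describe{
#'   \item{ACC}{`(TP + TN) / (TP + FN + TN + FP)` — equals `(TP+TN)/2`.}
#'   \item{SN}{`TP / (TP + FN)` — equals `TP`.}
#'   \item{SP}{`TN / (TN + FP)` — equals `TN`.}
#'   \item{GM}{`sqrt(TP*TN / ((TP+FN)*(TN+FP)))` — equals `sqrt(SN*SP)`.}
#'   \item{DM}{Dice measure `2 / ((TP+FN)/TP + (TP+FP)/TP)`.}
#'   \item{F2M}{F2 measure `5 / (4*(TP+FN)/TP + (TP+FP)/TP)`.}
#' }
#' `TP = 0` gives `DM = F2M = 0` by continuity.
#'
#' @param TP,TN proportion of positives / negatives correctly classified,
#'   in `[0, 1]`.
#' @return a `metric_set`: named list `ACC`, `SN`, `SP`, `GM`, `DM`, `F2M`.
#' @export
metrics_from_proportions <- function(TP, TN) {
  stopifnot(is.finite(TP), is.finite(TN), TP >= 0, TP <= 1, TN >= 0, TN <= 1)
  FN <- 1 - TP
  FP <- 1 - TN
  acc <- (TP + TN) / (TP + FN + TN + FP)
  sn <- TP / (TP + FN)
  sp <- TN / (TN + FP)
  gm <- sqrt(TP * TN / ((TP + FN) * (TN + FP)))
  if (TP == 0) {
    dm <- 0
    f2m <- 0
  } else {
    dm <- 2 / ((TP + FN) / TP + (TP + FP) / TP)
    f2m <- 5 / (4 * (TP + FN) / TP + (TP + FP) / TP)
  }
  structure(list(ACC = acc, SN = sn, SP = sp, GM = gm, DM = dm, F2M = f2m),
            class = "metric_set")
}

#' Classification metrics from per-class counts
#'
#' Converts counts to the proportion-based confusion entries and evaluates
#' the six metrics of [metrics_from_proportions()].
#'
#' @param N,M number of positive / negative samples (>= 1).
#' @param N1,M1 correctly classified positives / negatives
#'   (`0 <= N1 <= N`, `0 <= M1 <= M`).
#' @return a `metric_set`.
#' @export
compute_metrics <- function(N, M, N1, M1) {
  if (N < 1 || M < 1)
    stop("'N' and 'M' must be >= 1", call. = FALSE)
  if (N1 < 0 || N1 > N || M1 < 0 || M1 > M)
    stop("need 0 <= N1 <= N and 0 <= M1 <= M", call. = FALSE)
  metrics_from_proportions(N1 / N, M1 / M)
}

#' @export
print.metric_set <- function(x, digits = 4, ...) {
  v <- unlist(x)
  cat(paste(sprintf("%s = %.*f", names(v), digits, v), collapse = ", "),
      "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a random positive scores
#' above a random negative, with ties counted 1/2; it is computed from
#' midranks, so it is invariant under strictly monotone transformations of
#' the scores. ROC points are obtained by sweeping the decision threshold
#' over the distinct score values.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param labels `+1`/`-1`, both classes present.
#' @return list with `auc` and `roc` (data.frame `threshold`, `fpr`, `tpr`;
#'   first row (Inf) at (0,0), last row (-Inf) at (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  pos <- labels == 1
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  roc <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, 0),
    tpr = vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, 0))
  list(auc = auc, roc = roc)
}
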