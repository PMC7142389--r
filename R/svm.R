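#' Fit a linear soft-margin SVM
#'
#' Thin wrapper around a LIBSVM linear C-classification fit (via
#' \pkg{e1071}) exposing the quantities the RFE ranking needs: the primal
#' weight vector `w`, the bias `b`, and the per-sample dual coefficients
#' `alpha` (nonzero exactly on the support vectors). The weight vector
#' satisfies the KKT identity `w = sum_i alpha_i y_i x_i` up to solver
#' tolerance, and decisions are `D(x) = w'x + b` with `sign(D)` the
#' predicted label (`+1`/`-1`). No feature scaling is applied.
#'
#' @param X numeric matrix, samples x features.
#' @param y labels, `+1`/`-1`, both classes present.
#' @param C soft-margin penalty (> 0); default 1.
#' @return an object of class `linear_svm`: list with `weights`, `bias`,
#'   `alpha` (length `nrow(X)`, >= 0), `C`, `support` (row indices of the
#'   support vectors).
#' @export
fit_linear_svm <- function(X, y, C = 1) {
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1)))
    stop("'y' must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("'y' contains a single class", call. = FALSE)
  if (length(y) != nrow(X))
    stop("'y' must have one label per row of 'X'", call. = FALSE)
  if (!is.finite(C) || C <= 0)
    stop("'C' must be > 0", call. = FALSE)
  yf <- factor(y, levels = c(1, -1))
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  # LIBSVM orients its decision values by order of appearance in the data,
  # not by factor level; normalise so positive decisions mean class +1
  dv <- attr(stats::predict(fit, X[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (strsplit(colnames(dv), "/")[[1]][1] == "1") 1 else -1
  w <- flip * drop(t(fit$coefs) %*% fit$SV)
  b <- flip * -fit$rho
  alpha <- numeric(nrow(X))
  alpha[fit$index] <- flip * drop(fit$coefs) * y[fit$index]
  structure(list(weights = w, bias = b, alpha = alpha, C = C,
                 support = fit$index),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d features, %d support vectors, C = %g\n",
              length(x$weights), length(x$support), x$C))
  invisible(x)
}

#' Decision values and predictions of a linear SVM
#'
#' @param object a [fit_linear_svm()] fit.
#' @param newdata samples x features matrix on the same features.
#' @param type `"score"` for decision values `w'x + b`, `"class"` for
#'   `+1`/`-1` predictions (score 0 maps to `+1`).
#' @param ... unused.
#' @export
predict.linear_svm <- function(object, newdata, type = c("score", "class"),
                               ...) {
  type <- match.arg(type)
  newdata <- matrix(as.numeric(newdata), ncol = length(object$weights))
  score <- drop(newdata %*% object$weights + object$bias)
  if (type == "score") score else ifelse(score >= 0, 1, -1)
}

#' RFE configuration
#'
#' Parameters of the recursive-feature-elimination schedule: the SVM penalty
#' `C` (default 1), the fraction of the *current* feature set eliminated per
#' round (default 5%, at least one feature), and the fraction of the initial
#' features retained at the stopping point. Retained-fraction defaults used
#' in tissue-map studies are around 0.40 for gray matter and 0.14 for white
#' matter; the general default here is 0.40.
#'
#' @param C SVM soft-margin penalty (> 0).
#' @param elim_fraction fraction of remaining features removed each round,
#'   in (0, 1).
#' @param retain_fraction fraction of the initial features retained at stop,
#'   in (0, 1].
#' @return an `rfe_config` object.
#' @export
rfe_config <- function(C = 1, elim_fraction = 0.05, retain_fraction = 0.40) {
  if (!is.finite(C) || C <= 0)
    stop("'C' must be > 0", call. = FALSE)
  if (!is.finite(elim_fraction) || elim_fraction <= 0 || elim_fraction >= 1)
    stop("'elim_fraction' must be in (0, 1)", call. = FALSE)
  if (!is.finite(retain_fraction) || retain_fraction <= 0 ||
      retain_fraction > 1)
    stop("'retain_fraction' must be in (0, 1]", call. = FALSE)
  structure(list(C = C, elim_fraction = elim_fraction,
                 retain_fraction = retain_fraction), class = "rfe_config")
}

#' SVM-weight recursive feature elimination
#'
#' Repeatedly fits a linear SVM on the current feature set, ranks features by
#' their squared weight `w_i^2`, and removes the `ceiling(elim_fraction *
#' |F|)` features with the smallest criterion (at least one per round; ties
#' broken by ascending column index). The loop stops when the feature set
#' would drop below `ceiling(retain_fraction * n)`; the final batch is
#' truncated so the retained set lands exactly on that size.
#'
#' @param X samples x features matrix (>= 1 feature).
#' @param y labels `+1`/`-1`.
#' @param config an [rfe_config()].
#' @return an `rfe_ranking`: list with `retained` (column indices at stop,
#'   ascending), `rank` (integer per feature; 1 = most important, i.e.
#'   retained features ranked by the final fit's descending `w^2`, then
#'   eliminated features in reverse order of removal), `log` (data.frame:
#'   `round`, `feature`, `criterion` for each elimination), `n_features`,
#'   `config`.
#' @export
rfe_rank <- function(X, y, config = rfe_config()) {
  X <- as.matrix(X)
  stopifnot(inherits(config, "rfe_config"))
  n <- ncol(X)
  if (n < 1L) stop("'X' has no features", call. = FALSE)
  target <- as.integer(ceiling(config$retain_fraction * n))
  current <- seq_len(n)
  rounds <- list()
  elim_order <- integer(0)   # features in order of elimination
  round_i <- 0L
  while (length(current) > target) {
    round_i <- round_i + 1L
    fit <- fit_linear_svm(X[, current, drop = FALSE], y, config$C)
    crit <- fit$weights^2
    n_rm <- min(max(1L, as.integer(ceiling(config$elim_fraction *
                                             length(current)))),
                length(current) - target)
    ord <- order(crit, current)      # ascending criterion, ties by index
    drop_pos <- ord[seq_len(n_rm)]
    rounds[[round_i]] <- data.frame(round = round_i,
                                    feature = current[drop_pos],
                                    criterion = crit[drop_pos])
    elim_order <- c(elim_order, current[drop_pos])
    current <- current[-drop_pos]
  }
  # rank retained features by the final fit's descending squared weight
  if (length(current) > 1L && length(unique(y)) > 1L) {
    final_fit <- fit_linear_svm(X[, current, drop = FALSE], y, config$C)
    ret_ord <- current[order(-final_fit$weights^2, current)]
  } else ret_ord <- current
  rank <- integer(n)
  rank[ret_ord] <- seq_along(ret_ord)
  if (length(elim_order))
    rank[rev(elim_order)] <- length(ret_ord) + seq_along(elim_order)
  structure(list(retained = sort(current), rank = rank,
                 log = if (length(rounds)) do.call(rbind, rounds)
                       else data.frame(round = integer(),
                                       feature = integer(),
                                       criterion = numeric()),
                 n_features = n, config = config),
            class = "rfe_ranking")
}

#' @export
print.rfe_ranking <- function(x, ...) {
  cat(sprintf(
    "<rfe_ranking> %d -> %d features (%d round(s), elim %g/round, C = %g)\n",
    x$n_features, length(x$retained),
    if (nrow(x$log)) max(x$log$round) else 0L,
    x$config$elim_fraction, x$config$C))
  invisible(x)
}

#' Fine feature selection on the screened voxel set
#'
#' Applies [rfe_rank()] to the columns that survived [screen()], returning
#' the cohort restricted to the retained voxels together with the ranking
#' and a provenance record of both stages' parameters. The retained count is
#' `ceiling(retain_fraction * n_surviving)`.
#'
#' @param cohort the full [to_matrix()] cohort.
#' @param screening_result a [screen()] result on this cohort.
#' @param config an [rfe_config()].
#' @return list with `cohort` (reduced `cohort_matrix`), `ranking`
#'   (`rfe_ranking` over the screened columns; feature indices refer to the
#'   screened submatrix, `cols` maps them back), `cols` (retained column
#'   indices of the original cohort), `provenance`.
#' @export
select_features <- function(cohort, screening_result,
                            config = rfe_config()) {
  stopifnot(inherits(cohort, "cohort_matrix"),
            inherits(screening_result, "screening_result"))
  sel <- screening_result$selected_cols
  if (!length(sel))
    stop("screening left no surviving voxels; relax 'alpha' or ",
         "'min_cluster'", call. = FALSE)
  ranking <- rfe_rank(cohort$X[, sel, drop = FALSE], cohort$y, config)
  cols <- sel[ranking$retained]
  prov <- list(alpha = screening_result$config$alpha,
               min_cluster = screening_result$config$min_cluster,
               connectivity = screening_result$config$connectivity,
               C = config$C, elim_fraction = config$elim_fraction,
               retain_fraction = config$retain_fraction,
               n_screened = length(sel), n_retained = length(cols))
  list(cohort = subset_cols(cohort, cols), ranking = ranking, cols = cols,
       provenance = prov)
}

#' Write an RFE ranking as TSV plus a retained-voxel mask
#'
#' @param selection a [select_features()] result.
#' @param full_cohort the cohort the selection came from.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_selection <- function(selection, full_cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sel_lin <- full_cohort$mask_linear[selection$cols]
  mask <- array(0, dim = full_cohort$dim)
  mask[sel_lin] <- 1
  write_volume(volume3d(mask, full_cohort$affine),
               file.path(dir, "retained_mask.nii.gz"))
  co <- arrayInd(sel_lin, full_cohort$dim)
  w <- voxel_to_world(co, full_cohort$affine)
  rk <- selection$ranking$rank[selection$ranking$retained]
  tab <- data.frame(x_mm = w[, 1], y_mm = w[, 2], z_mm = w[, 3], rank = rk)
  tab <- tab[order(tab$rank), ]
  utils::write.table(tab, file.path(dir, "ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(selection$provenance,
                       file.path(dir, "selection_provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
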