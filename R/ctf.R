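#' Fit a coarse-to-fine SVM on a cohort of tissue maps
#'
#' The package's central model: a three-stage discriminative analysis of
#' subjects x voxels tissue-map data. (1) *Coarse screen*: voxelwise pooled
#' two-sample t-tests, two-sided p threshold, cluster-extent filter
#' ([screen()]). (2) *Fine selection*: recursive feature elimination driven
#' by squared linear-SVM weights down to a retained fraction
#' ([select_features()]). (3) *Classifier*: a linear soft-margin SVM on the
#' retained voxels ([fit_linear_svm()]).
#'
#' @param x a `cohort_matrix` from [to_matrix()], or a list of [volume3d]
#'   (then `y` and optionally `mask` are used to build one).
#' @param y group labels `+1`/`-1` (ignored when `x` is a `cohort_matrix`).
#' @param screening a [screening_config()].
#' @param rfe an [rfe_config()].
#' @param mask optional binary mask volume when `x` is a list of volumes.
#' @return an object of class `ctf_svm`: the fitted model with components
#'   `screening` (`screening_result`), `selection` ([select_features()]
#'   result), `svm` (`linear_svm` on the retained voxels), `cohort_dim`
#'   (subjects, voxels), `grid`, `affine`, `y`, `call`.
#' @seealso [loo_evaluate()] for out-of-sample evaluation of the same
#'   pipeline; [report_regions()] for the biomarker report.
#' @examples
#' spec <- cohort_spec(grid_shape = c(12, 12, 12), n_group1 = 10,
#'                     n_group2 = 10, voxel_sd = 0.3, fwhm_mm = 2,
#'                     blobs = list(blob_spec(c(6, 6, 6), 2.5, 1.5)),
#'                     seed = 7)
#' cohort <- with(generate_cohort(spec), to_matrix(volumes, labels))
#' fit <- ctf_svm(cohort, screening = screening_config(min_cluster = 10))
#' fit
#' head(coef(fit))
#' @export
ctf_svm <- function(x, y = NULL, screening = screening_config(),
                    rfe = rfe_config(), mask = "all") {
  cl <- match.call()
  cohort <- if (inherits(x, "cohort_matrix")) x else to_matrix(x, y, mask)
  sres <- screen(cohort, screening)
  selection <- select_features(cohort, sres, rfe)
  svm <- fit_linear_svm(selection$cohort$X, cohort$y, rfe$C)
  structure(list(screening = sres, selection = selection, svm = svm,
                 cohort_dim = dim(cohort$X), grid = cohort$dim,
                 affine = cohort$affine,
                 mask_linear = cohort$mask_linear, y = cohort$y,
                 call = cl),
            class = "ctf_svm")
}

#' @export
print.ctf_svm <- function(x, ...) {
  cat("Coarse-to-fine SVM\n\nCall:\n  ")
  print(x$call)
  cat(sprintf("\n%d subjects (%d / %d), %d voxels tested\n",
              x$cohort_dim[1], sum(x$y == 1), sum(x$y == -1),
              x$cohort_dim[2]))
  cat(sprintf("  screen : %d voxels survive (alpha %g, min_cluster %d)\n",
              length(x$screening$selected_cols), x$screening$config$alpha,
              x$screening$config$min_cluster))
  cat(sprintf("  RFE    : %d voxels retained (retain %g, elim %g/round)\n",
              length(x$selection$cols),
              x$selection$provenance$retain_fraction,
              x$selection$provenance$elim_fraction))
  cat(sprintf("  SVM    : %d support vectors, C = %g\n",
              length(x$svm$support), x$svm$C))
  invisible(x)
}

#' SVM voxel weights of a coarse-to-fine fit
#'
#' @param object a [ctf_svm()] fit.
#' @param as_volume return a [volume3d] weight map (`NA` off the retained
#'   set) instead of a named vector.
#' @param ... unused.
#' @return named numeric vector (names `vx_<linear index>`), or a
#'   [volume3d].
#' @export
coef.ctf_svm <- function(object, as_volume = FALSE, ...) {
  w <- object$svm$weights
  lin <- object$mask_linear[object$selection$cols]
  if (as_volume) {
    a <- array(NA_real_, dim = object$grid)
    a[lin] <- w
    return(structure(list(data = a, affine = object$affine),
                     class = "volume3d"))
  }
  stats::setNames(w, paste0("vx_", lin))
}

#' Predict group membership for new tissue maps
#'
#' @param object a [ctf_svm()] fit.
#' @param newdata a list of [volume3d] on the training grid, a
#'   `cohort_matrix` on the same mask, or a matrix with one column per
#'   training-cohort voxel (or already restricted to the retained voxels).
#' @param type `"class"` for `+1`/`-1`, `"score"` for decision values.
#' @param ... unused.
#' @export
predict.ctf_svm <- function(object, newdata, type = c("class", "score"),
                            ...) {
  type <- match.arg(type)
  p_ret <- length(object$selection$cols)
  if (is.list(newdata) && !inherits(newdata, "cohort_matrix") &&
      inherits(newdata[[1]], "volume3d")) {
    lin <- object$mask_linear[object$selection$cols]
    Xr <- t(vapply(newdata, function(v) v$data[lin], numeric(p_ret)))
  } else {
    X <- if (inherits(newdata, "cohort_matrix")) newdata$X
         else as.matrix(newdata)
    if (ncol(X) == p_ret) {
      Xr <- X
    } else if (ncol(X) == object$cohort_dim[2]) {
      Xr <- X[, object$selection$cols, drop = FALSE]
    } else {
      stop("'newdata' has ", ncol(X), " columns; expected ",
           object$cohort_dim[2], " (full) or ", p_ret, " (retained)",
           call. = FALSE)
    }
  }
  predict(object$svm, Xr, type = if (type == "class") "class" else "score")
}

#' @export
fitted.ctf_svm <- function(object, ...) {
  predict(object$svm, object$selection$cohort$X, "score")
}

#' Summary of a coarse-to-fine SVM fit
#'
#' Reports the per-stage feature counts, the training (resubstitution)
#' metrics — an optimistic upper bound; use [loo_evaluate()] for honest
#' estimates — and the largest retained clusters.
#'
#' @param object a [ctf_svm()] fit.
#' @param ... unused.
#' @export
summary.ctf_svm <- function(object, ...) {
  score <- fitted(object)
  pred <- ifelse(score >= 0, 1, -1)
  N <- sum(object$y == 1); M <- sum(object$y == -1)
  m <- compute_metrics(N, M, sum(pred == 1 & object$y == 1),
                       sum(pred == -1 & object$y == -1))
  m$AUC <- roc_auc(score, object$y)$auc
  lin <- object$mask_linear[object$selection$cols]
  ret <- array(0, dim = object$grid)
  ret[lin] <- 1
  cl <- connected_components(ret, object$screening$config$connectivity)
  structure(list(fit = object, train_metrics = m,
                 n_clusters = length(cl),
                 cluster_sizes = sort(vapply(cl, `[[`, 0L, "size"),
                                      decreasing = TRUE)),
            class = "summary.ctf_svm")
}

#' @export
print.summary.ctf_svm <- function(x, ...) {
  print(x$fit)
  cat("\nTraining (resubstitution) metrics:\n  ")
  print(x$train_metrics)
  cat(sprintf("\nRetained voxels form %d cluster(s)", x$n_clusters))
  if (x$n_clusters)
    cat(sprintf("; sizes: %s",
                paste(utils::head(x$cluster_sizes, 8), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Plot a slice of the t-map and retained voxels
#'
#' Shows an axial slice of the screening t-map with the RFE-retained voxels
#' outlined, the usual visual check that the selected features form
#' anatomically plausible clusters.
#'
#' @param x a [ctf_svm()] fit.
#' @param slice axial (third-axis) slice index; defaults to the slice with
#'   the most retained voxels.
#' @param ... passed to [graphics::image()].
#' @export
plot.ctf_svm <- function(x, slice = NULL, ...) {
  lin <- x$mask_linear[x$selection$cols]
  co <- arrayInd(lin, x$grid)
  if (is.null(slice)) {
    tab <- tabulate(co[, 3], x$grid[3])
    slice <- which.max(tab)
  }
  tm <- x$screening$t_map$data[, , slice]
  tm[!is.finite(tm)] <- 0
  graphics::image(seq_len(x$grid[1]), seq_len(x$grid[2]), tm,
                  xlab = "i", ylab = "j",
                  main = sprintf("t-map, slice k = %d", slice),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  sel <- co[co[, 3] == slice, , drop = FALSE]
  if (nrow(sel)) graphics::points(sel[, 1], sel[, 2], pch = 0, cex = 0.6)
  invisible(x)
}
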