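#' Subjects-by-voxels cohort matrix
#'
#' Extracts the masked voxels of a list of co-registered volumes into a
#' subjects x voxels feature matrix. Column `j` holds the voxel at
#' `mask_linear[j]` (R column-major linear index into the grid), a fixed
#' deterministic linearisation so that feature rankings are reproducible.
#'
#' @param volumes a list of [volume3d] sharing grid shape and affine.
#' @param labels numeric vector of group labels, `+1` / `-1`, one per volume.
#' @param mask a binary [volume3d] (or 3D array) on the same grid, or `"all"`
#'   (default) to take every voxel.
#' @return an object of class `cohort_matrix`: list with `X` (n x p matrix),
#'   `y` (labels), `mask_linear` (linear indices of the columns),
#'   `mask_coords` (p x 3 voxel indices), `dim` (grid shape), `affine`.
#' @export
to_matrix <- function(volumes, labels, mask = "all") {
  if (!length(volumes)) stop("'volumes' is empty", call. = FALSE)
  if (length(labels) != length(volumes))
    stop("'labels' must have one entry per volume", call. = FALSE)
  if (!all(labels %in% c(-1, 1)))
    stop("'labels' must be +1 or -1", call. = FALSE)
  ref <- volumes[[1]]
  stopifnot(inherits(ref, "volume3d"))
  d <- dim(ref$data)
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!inherits(v, "volume3d") || !identical(dim(v$data), d))
      stop("subject ", i, ": grid shape mismatch", call. = FALSE)
    if (max(abs(v$affine - ref$affine)) > 1e-6)
      stop("subject ", i, ": affine mismatch", call. = FALSE)
  }
  if (identical(mask, "all")) {
    keep <- seq_len(prod(d))
  } else {
    mdat <- if (inherits(mask, "volume3d")) mask$data else mask
    if (!identical(dim(mdat), d))
      stop("mask grid shape mismatch", call. = FALSE)
    keep <- which(mdat != 0)
  }
  X <- matrix(0, nrow = length(volumes), ncol = length(keep))
  for (i in seq_along(volumes)) X[i, ] <- volumes[[i]]$data[keep]
  structure(list(X = X, y = as.numeric(labels), mask_linear = keep,
                 mask_coords = arrayInd(keep, d), dim = d,
                 affine = ref$affine),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d subjects (%d / %d) x %d voxels, grid %s\n",
              nrow(x$X), sum(x$y == 1), sum(x$y == -1), ncol(x$X),
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$X)

# restrict a cohort matrix to a subset of its columns
subset_cols <- function(cohort, cols) {
  structure(list(X = cohort$X[, cols, drop = FALSE], y = cohort$y,
                 mask_linear = cohort$mask_linear[cols],
                 mask_coords = cohort$mask_coords[cols, , drop = FALSE],
                 dim = cohort$dim, affine = cohort$affine),
            class = "cohort_matrix")
}

# restrict a cohort matrix to a subset of its rows (subjects)
subset_rows <- function(cohort, rows) {
  structure(list(X = cohort$X[rows, , drop = FALSE], y = cohort$y[rows],
                 mask_linear = cohort$mask_linear,
                 mask_coords = cohort$mask_coords,
                 dim = cohort$dim, affine = cohort$affine),
            class = "cohort_matrix")
}

#' Scatter a feature vector back into a volume
#'
#' Inverse of the masking in [to_matrix()]: places `values[j]` at the grid
#' position of column `j` and `fill` elsewhere.
#'
#' @param values numeric vector, one value per cohort column.
#' @param cohort a `cohort_matrix`.
#' @param fill value for voxels outside the mask (default `NA`).
#' @return a [volume3d].
#' @export
unmask <- function(values, cohort, fill = NA_real_) {
  stopifnot(inherits(cohort, "cohort_matrix"),
            length(values) == ncol(cohort$X))
  a <- array(fill, dim = cohort$dim)
  a[cohort$mask_linear] <- values
  # bypass the finite-data check: NA fill and Inf t-values are legitimate here
  structure(list(data = a, affine = cohort$affine), class = "volume3d")
}

#' Write a cohort to disk
#'
#' Writes one NIfTI per subject plus a phenotype table
#' (`subject_id`, `path`, `group`) as TSV.
#'
#' @param volumes list of [volume3d].
#' @param labels `+1`/`-1` per subject.
#' @param dir output directory (created if needed).
#' @param gzip write `.nii.gz` (default) or plain `.nii`.
#' @return path of the phenotype TSV, invisibly.
#' @export
write_cohort <- function(volumes, labels, dir, gzip = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  ids <- sprintf("sub-%03d", seq_along(volumes))
  paths <- file.path(dir, paste0(ids, ext))
  for (i in seq_along(volumes)) write_volume(volumes[[i]], paths[i])
  tsv <- file.path(dir, "phenotype.tsv")
  utils::write.table(
    data.frame(subject_id = ids, path = basename(paths), group = labels),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param tsv path to a phenotype TSV with columns `subject_id`, `path`,
#'   `group`; volume paths are resolved relative to the TSV's directory.
#' @return list with `volumes`, `labels`, `subject_id`.
#' @export
read_cohort <- function(tsv) {
  ph <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "group")
  if (!all(need %in% names(ph)))
    stop("phenotype table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  base <- dirname(tsv)
  vols <- lapply(ph$path, function(p) {
    read_volume(if (file.exists(p)) p else file.path(base, p))
  })
  list(volumes = vols, labels = as.numeric(ph$group),
       subject_id = ph$subject_id)
}
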