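#' Cluster biomarker report with atlas labels
#'
#' Turns a retained-voxel mask into the standard cluster-table biomarker
#' report: connected components of the mask (clusters below `min_cluster`
#' voxels dropped), each with its size, its peak — the member voxel with
#' maximum `|t|`, ties broken by lowest linear index — in world (MNI-style)
#' millimetre coordinates, and, when an atlas is supplied, the majority
#' atlas label plus the full per-label voxel histogram. Clusters are sorted
#' by descending size (ties by minimum linear index).
#'
#' @param retained_mask binary [volume3d] of selected voxels.
#' @param t_map [volume3d] of screening t values on the same grid.
#' @param atlas optional integer-labelled [volume3d] on the same grid and
#'   affine; `NULL` labels every cluster `"unassigned"`.
#' @param min_cluster minimum reported cluster size (default 50).
#' @param connectivity 6, 18 or 26.
#' @param p_threshold screening p threshold echoed into the table
#'   (default 0.05).
#' @return a `region_report`: data.frame with columns `cluster_id`,
#'   `majority_label`, `size`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`,
#'   `peak_t`, `p_threshold`; attribute `label_histogram` is a list (one
#'   per row) of per-label voxel counts.
#' @export
report_regions <- function(retained_mask, t_map, atlas = NULL,
                           min_cluster = 50L, connectivity = 26L,
                           p_threshold = 0.05) {
  stopifnot(inherits(retained_mask, "volume3d"), inherits(t_map, "volume3d"))
  d <- dim(retained_mask$data)
  if (!identical(d, dim(t_map$data)))
    stop("t_map grid mismatch", call. = FALSE)
  if (!is.null(atlas)) {
    stopifnot(inherits(atlas, "volume3d"))
    if (!identical(d, dim(atlas$data)) ||
        max(abs(atlas$affine - retained_mask$affine)) > 1e-6)
      stop("atlas grid/affine mismatch", call. = FALSE)
  }
  cl <- connected_components(retained_mask, connectivity)
  cl <- Filter(function(x) x$size >= min_cluster, cl)
  empty <- data.frame(cluster_id = integer(), majority_label = character(),
                      size = integer(), peak_x_mm = numeric(),
                      peak_y_mm = numeric(), peak_z_mm = numeric(),
                      peak_t = numeric(), p_threshold = numeric())
  if (!length(cl)) {
    attr(empty, "label_histogram") <- list()
    class(empty) <- c("region_report", "data.frame")
    return(empty)
  }
  rows <- vector("list", length(cl))
  hists <- vector("list", length(cl))
  for (i in seq_along(cl)) {
    idx <- cl[[i]]$indices
    tv <- abs(t_map$data[idx])
    tv[is.na(tv)] <- -Inf
    peak <- idx[which.max(tv)]   # which.max takes the first (lowest) tie
    w <- voxel_to_world(arrayInd(peak, d), retained_mask$affine)
    if (is.null(atlas)) {
      maj <- "unassigned"
      hists[[i]] <- integer(0)
    } else {
      labs <- atlas$data[idx]
      h <- sort(table(labs), decreasing = TRUE)
      # majority; ties by smallest label value
      top <- names(h)[h == max(h)]
      maj <- top[order(as.numeric(top))][1]
      hists[[i]] <- stats::setNames(as.integer(h), names(h))
    }
    rows[[i]] <- data.frame(cluster_id = i, majority_label = as.character(maj),
                            size = cl[[i]]$size, peak_x_mm = w[1],
                            peak_y_mm = w[2], peak_z_mm = w[3],
                            peak_t = t_map$data[peak],
                            p_threshold = p_threshold)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$size, vapply(cl, function(x) x$indices[1], 0))
  out <- out[ord, , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "label_histogram") <- hists[ord]
  class(out) <- c("region_report", "data.frame")
  out
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf("Region report: %d cluster(s) at extent threshold\n", nrow(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Write a region report and its cluster label map
#'
#' TSV table mirroring the usual biomarker-table columns plus a NIfTI label
#' map in which each reported cluster's voxels carry its `cluster_id`.
#'
#' @param report a [report_regions()] result.
#' @param retained_mask the mask the report was computed from.
#' @param dir output directory.
#' @param connectivity connectivity used for the report.
#' @return `dir`, invisibly.
#' @export
write_regions <- function(report, retained_mask, dir, connectivity = 26L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(report), file.path(dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- connected_components(retained_mask, connectivity)
  cl <- Filter(function(x) x$size >= min(c(report$size, Inf)), cl)
  lab <- array(0L, dim = dim(retained_mask$data))
  # re-derive the same ordering as report_regions
  if (length(cl)) {
    ord <- order(-vapply(cl, `[[`, 0L, "size"),
                 vapply(cl, function(x) x$indices[1], 0))
    for (i in seq_along(ord)) lab[cl[[ord[i]]]$indices] <- i
  }
  write_volume(volume3d(lab, retained_mask$affine),
               file.path(dir, "cluster_labels.nii.gz"))
  invisible(dir)
}
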