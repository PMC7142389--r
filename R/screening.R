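#' Screening configuration
#'
#' Parameters for the coarse univariate screen: a two-sided p-value threshold
#' on the voxelwise pooled two-sample t-test and a minimum connected cluster
#' extent. Defaults follow common practice in VBM group studies: p < 0.05
#' uncorrected with a 50-voxel cluster-extent filter.
#'
#' @param alpha two-sided p threshold, in (0, 1).
#' @param min_cluster minimum cluster voxel count (>= 1).
#' @param connectivity 3D neighbourhood: 6 (faces), 18 (+edges) or
#'   26 (+corners).
#' @param bonferroni apply a Bonferroni correction to `alpha` across tested
#'   voxels (off by default: the screen is an uncorrected filter, the
#'   downstream classifier is what is validated).
#' @return a `screening_config` object.
#' @export
screening_config <- function(alpha = 0.05, min_cluster = 50L,
                             connectivity = 26L, bonferroni = FALSE) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (!is.finite(min_cluster) || min_cluster < 1)
    stop("'min_cluster' must be >= 1", call. = FALSE)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  structure(list(alpha = alpha, min_cluster = as.integer(min_cluster),
                 connectivity = as.integer(connectivity),
                 bonferroni = isTRUE(bonferroni)),
            class = "screening_config")
}

#' Voxelwise pooled two-sample t-test
#'
#' For every cohort column computes the pooled-variance two-sample t
#' statistic
#' `T = (xbar1 - xbar2) / sqrt(((N1-1)S1^2 + (N2-1)S2^2)/(N1+N2-2) * (1/N1 + 1/N2))`
#' and its two-sided p-value on `N1 + N2 - 2` degrees of freedom. The larger
#' `|T|`, the more discriminative the voxel. Voxels with zero pooled variance
#' are degenerate: `T = 0, p = 1` when the group means agree, `T = +/-Inf,
#' p = 0` otherwise; they are flagged.
#'
#' @param cohort a [to_matrix()] cohort (labels `+1`/`-1`, >= 2 subjects per
#'   group).
#' @return list with `t`, `p` and logical `degenerate`, one entry per column.
#' @export
ttest_voxelwise <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  g1 <- cohort$y == 1
  g2 <- cohort$y == -1
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  X1 <- cohort$X[g1, , drop = FALSE]
  X2 <- cohort$X[g2, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- colSums((X1 - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((X2 - rep(m2, each = n2))^2) / (n2 - 1)
  df <- n1 + n2 - 2
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(pooled * (1 / n1 + 1 / n2))
  degenerate <- se == 0
  tt <- ifelse(degenerate,
               ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
               (m1 - m2) / se)
  pp <- ifelse(is.infinite(tt), 0, 2 * stats::pt(-abs(tt), df))
  list(t = tt, p = pp, degenerate = degenerate)
}

# neighbour offsets (as n x 3 integer matrix) for a 3D connectivity
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

#' 3D connected components of a binary mask
#'
#' Labels the nonzero voxels of a 3D mask into maximal connected sets under
#' a 6-, 18- or 26-neighbourhood, by breadth-first search with vectorised
#' frontier expansion. Clusters are ordered by their minimum linear voxel
#' index, which makes the output deterministic.
#'
#' @param mask a [volume3d] or 3D array; nonzero entries are foreground.
#' @param connectivity 6, 18 or 26.
#' @return list of clusters, each a list with `indices` (linear voxel
#'   indices, sorted) and `size`. Empty mask gives `list()`.
#' @export
connected_components <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("'connectivity' must be 6, 18 or 26", call. = FALSE)
  m <- if (inherits(mask, "volume3d")) mask$data else mask
  d <- dim(m)
  stopifnot(length(d) == 3L)
  fg <- which(m != 0)
  if (!length(fg)) return(list())
  # precompute neighbour linear indices for every foreground voxel
  co <- arrayInd(fg, d)
  off <- connectivity_offsets(connectivity)
  nn <- nrow(off)
  nbr <- matrix(NA_integer_, nrow = length(fg), ncol = nn)
  for (q in seq_len(nn)) {
    i <- co[, 1] + off[q, 1]; j <- co[, 2] + off[q, 2]; k <- co[, 3] + off[q, 3]
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
    lin <- i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
    lin[!ok] <- NA_integer_
    nbr[, q] <- lin
  }
  # map grid linear index -> position in fg (0 = background)
  pos <- integer(prod(d))
  pos[fg] <- seq_along(fg)
  visited <- logical(length(fg))
  out <- list()
  for (s in seq_along(fg)) {
    if (visited[s]) next
    visited[s] <- TRUE
    members <- s
    frontier <- s
    while (length(frontier)) {
      cand <- nbr[frontier, , drop = FALSE]
      cand <- cand[!is.na(cand)]
      cand <- unique(pos[cand])
      cand <- cand[cand != 0L]
      cand <- cand[!visited[cand]]
      if (!length(cand)) break
      visited[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    idx <- sort(fg[members])
    out[[length(out) + 1L]] <- list(indices = idx, size = length(idx))
  }
  # seeds are scanned in ascending linear order, so clusters already come
  # out ordered by minimum linear index
  out
}

#' Coarse screen: t-threshold plus cluster-extent filter
#'
#' Runs [ttest_voxelwise()], thresholds the two-sided p-map at
#' `config$alpha`, and keeps only connected clusters of supra-threshold
#' voxels with at least `config$min_cluster` members. Tightening `alpha`
#' shrinks the surviving set monotonically: a stricter-alpha cluster is a
#' subset of a looser-alpha cluster, so the looser cluster also passes the
#' extent filter.
#'
#' @param cohort a [to_matrix()] cohort.
#' @param config a [screening_config()].
#' @return a `screening_result`: `t_map`, `p_map` ([volume3d], `NA` outside
#'   the cohort mask), `surviving` (binary [volume3d]), `clusters`
#'   (surviving clusters as in [connected_components()]), `selected_cols`
#'   (cohort column indices of surviving voxels), `n_tested`, `config`.
#'   Warns (and returns an empty selection) if nothing survives.
#' @export
screen <- function(cohort, config = screening_config()) {
  stopifnot(inherits(cohort, "cohort_matrix"),
            inherits(config, "screening_config"))
  tw <- ttest_voxelwise(cohort)
  alpha <- config$alpha
  if (config$bonferroni) alpha <- alpha / ncol(cohort$X)
  sig <- tw$p < alpha
  sig_vol <- array(FALSE, dim = cohort$dim)
  sig_vol[cohort$mask_linear[sig]] <- TRUE
  cl <- connected_components(sig_vol, config$connectivity)
  cl <- Filter(function(x) x$size >= config$min_cluster, cl)
  surv <- array(0, dim = cohort$dim)
  for (x in cl) surv[x$indices] <- 1
  sel <- which(surv[cohort$mask_linear] != 0)
  if (!length(sel))
    warning("no voxel survives screening (alpha = ", config$alpha,
            ", min_cluster = ", config$min_cluster, ")", call. = FALSE)
  structure(list(t_map = unmask(tw$t, cohort),
                 p_map = unmask(tw$p, cohort),
                 degenerate = tw$degenerate,
                 surviving = structure(list(data = surv,
                                            affine = cohort$affine),
                                       class = "volume3d"),
                 clusters = cl,
                 selected_cols = sel,
                 n_tested = ncol(cohort$X),
                 config = config),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf(
    "<screening_result> %d/%d voxels survive (alpha %g, min_cluster %d, conn %d), %d cluster(s)\n",
    length(x$selected_cols), x$n_tested, x$config$alpha,
    x$config$min_cluster, x$config$connectivity, length(x$clusters)))
  invisible(x)
}

#' Write screening maps and cluster table
#'
#' Writes the t-map, p-map and surviving mask as NIfTI and the cluster table
#' (id, size, peak |T|, peak world coordinates) as TSV.
#'
#' @param sres a [screen()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_screening <- function(sres, dir) {
  stopifnot(inherits(sres, "screening_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tm <- sres$t_map; tm$data[!is.finite(tm$data)] <- 0
  pm <- sres$p_map; pm$data[!is.finite(pm$data)] <- 1
  write_volume(volume3d(tm$data, tm$affine), file.path(dir, "t_map.nii.gz"))
  write_volume(volume3d(pm$data, pm$affine), file.path(dir, "p_map.nii.gz"))
  write_volume(sres$surviving, file.path(dir, "surviving_mask.nii.gz"))
  tab <- cluster_table(sres$clusters, sres$t_map)
  utils::write.table(tab, file.path(dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# summarise clusters: peak = max |t| voxel, ties by lowest linear index
cluster_table <- function(clusters, t_map) {
  if (!length(clusters))
    return(data.frame(cluster_id = integer(), size = integer(),
                      peak_t = numeric(), x_mm = numeric(), y_mm = numeric(),
                      z_mm = numeric()))
  d <- dim(t_map$data)
  rows <- lapply(seq_along(clusters), function(i) {
    idx <- clusters[[i]]$indices
    tv <- abs(t_map$data[idx])
    tv[!is.finite(tv)] <- Inf
    peak <- idx[which.max(tv)]
    w <- voxel_to_world(arrayInd(peak, d), t_map$affine)
    data.frame(cluster_id = i, size = clusters[[i]]$size,
               peak_t = t_map$data[peak], x_mm = w[1], y_mm = w[2],
               z_mm = w[3])
  })
  do.call(rbind, rows)
}
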