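#' Specify a spherical effect blob
#'
#' A blob is the ground-truth unit of the synthetic cohort: a sphere of grid
#' voxels `{v : ||v - center||_2 <= radius}` whose intensities are shifted by
#' `effect` in group 1 (before smoothing), emulating a localized group
#' difference in a tissue map.
#'
#' @param center voxel index triple (1-based, inside the grid).
#' @param radius Euclidean radius in voxels (> 0).
#' @param effect signed mean shift added to group-1 subjects inside the blob
#'   (tissue-intensity units).
#' @return a `blob_spec` object.
#' @export
blob_spec <- function(center, radius, effect) {
  if (length(center) != 3L || any(!is.finite(center)))
    stop("blob 'center' must be a voxel index triple", call. = FALSE)
  if (!is.finite(radius) || radius <= 0)
    stop("blob 'radius' must be > 0", call. = FALSE)
  if (!is.finite(effect))
    stop("blob 'effect' must be finite", call. = FALSE)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 effect = as.numeric(effect)), class = "blob_spec")
}

#' Specify a synthetic two-group cohort
#'
#' Defines the generating model for [generate_cohort()]: per-subject volumes
#' `baseline + subject offset + voxel noise (+ blob effects in group 1)`,
#' Gaussian-smoothed at `fwhm_mm`. Defaults mirror a typical structural-MRI
#' group study: 34 + 34 subjects, 1 mm voxels, 6 mm FWHM smoothing, on a
#' 32^3 grid sized for desk-scale runs.
#'
#' @param grid_shape integer triple of grid dimensions.
#' @param n_group1,n_group2 subject counts (>= 2 each; the pooled t-test
#'   needs at least one degree of freedom).
#' @param baseline mean tissue intensity (unit-free).
#' @param subject_sd s.d. of the per-subject global offset (>= 0).
#' @param voxel_sd s.d. of i.i.d. voxel noise before smoothing (>= 0).
#' @param blobs list of [blob_spec()] applied to group 1.
#' @param fwhm_mm smoothing kernel FWHM in mm (>= 0).
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param seed integer RNG seed; identical spec (incl. seed) gives
#'   bit-identical cohorts.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(grid_shape = c(32L, 32L, 32L),
                        n_group1 = 34L, n_group2 = 34L,
                        baseline = 0.5, subject_sd = 0.01, voxel_sd = 0.5,
                        blobs = list(), fwhm_mm = 6, voxel_size_mm = 1,
                        seed = 1L) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid '", field, "': ", msg, call. = FALSE)
  chk(length(grid_shape) == 3L && all(grid_shape >= 1), "grid_shape",
      "must be a triple of positive integers")
  chk(n_group1 >= 2, "n_group1", "need >= 2 subjects per group")
  chk(n_group2 >= 2, "n_group2", "need >= 2 subjects per group")
  chk(is.finite(baseline), "baseline", "must be finite")
  chk(is.finite(subject_sd) && subject_sd >= 0, "subject_sd", "must be >= 0")
  chk(is.finite(voxel_sd) && voxel_sd >= 0, "voxel_sd", "must be >= 0")
  chk(is.finite(fwhm_mm) && fwhm_mm >= 0, "fwhm_mm", "must be >= 0")
  chk(is.finite(voxel_size_mm) && voxel_size_mm > 0, "voxel_size_mm",
      "must be > 0")
  if (inherits(blobs, "blob_spec")) blobs <- list(blobs)
  for (b in blobs) {
    if (!inherits(b, "blob_spec")) stop("'blobs' must be blob_spec objects",
                                        call. = FALSE)
    chk(all(b$center >= 1 & b$center <= grid_shape), "blobs",
        "blob center outside the grid")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 n_group1 = as.integer(n_group1),
                 n_group2 = as.integer(n_group2),
                 baseline = baseline, subject_sd = subject_sd,
                 voxel_sd = voxel_sd, blobs = blobs, fwhm_mm = fwhm_mm,
                 voxel_size_mm = voxel_size_mm, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> grid %s, %d + %d subjects, fwhm %g mm, %d blob(s), seed %d\n",
    paste(x$grid_shape, collapse = "x"), x$n_group1, x$n_group2,
    x$fwhm_mm, length(x$blobs), x$seed))
  invisible(x)
}

# linear indices of voxels within Euclidean 'radius' of 'center'
blob_voxels <- function(center, radius, grid_shape) {
  lo <- pmax(1, floor(center - radius))
  hi <- pmin(grid_shape, ceiling(center + radius))
  g <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  as.integer(g$i + (g$j - 1) * grid_shape[1] +
               (g$k - 1) * grid_shape[1] * grid_shape[2])
}

#' Generate a synthetic two-group cohort
#'
#' Draws `n_group1 + n_group2` volumes from the model in [cohort_spec()]:
#' each subject's volume is `baseline + offset_s + eps_sv` with
#' `offset_s ~ N(0, subject_sd^2)` and `eps_sv ~ N(0, voxel_sd^2)`; group-1
#' subjects additionally receive each blob's `effect` on its voxel set. The
#' blob effects are added *before* smoothing, so planted regions have the
#' smooth boundaries of real VBM effects; every volume is then smoothed with
#' [gaussian_smooth()] at `fwhm_mm`. Identical spec (including seed) gives
#' bit-identical output; the caller's RNG state is preserved.
#'
#' @param spec a [cohort_spec()].
#' @return list with `volumes` (list of [volume3d], group 1 first), `labels`
#'   (`+1` for group 1, `-1` for group 2), and `truth` (a `ground_truth`:
#'   `effect_mask` binary [volume3d] and `blob_voxels`, a list of per-blob
#'   linear voxel indices).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  d <- spec$grid_shape
  nvox <- prod(d)
  aff <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  n <- spec$n_group1 + spec$n_group2
  labels <- c(rep(1, spec$n_group1), rep(-1, spec$n_group2))

  bvox <- lapply(spec$blobs, function(b) blob_voxels(b$center, b$radius, d))
  effect <- array(0, dim = d)
  for (i in seq_along(spec$blobs))
    effect[bvox[[i]]] <- effect[bvox[[i]]] + spec$blobs[[i]]$effect
  mask <- array(0, dim = d)
  mask[unique(unlist(bvox))] <- 1

  offsets <- stats::rnorm(n, 0, spec$subject_sd)
  volumes <- vector("list", n)
  for (s in seq_len(n)) {
    a <- array(spec$baseline + offsets[s] +
                 stats::rnorm(nvox, 0, spec$voxel_sd), dim = d)
    if (labels[s] == 1) a <- a + effect
    volumes[[s]] <- gaussian_smooth(volume3d(a, aff), spec$fwhm_mm)
  }
  truth <- structure(list(effect_mask = volume3d(mask, aff),
                          blob_voxels = bvox), class = "ground_truth")
  list(volumes = volumes, labels = labels, truth = truth)
}

#' Generate a synthetic integer-labelled atlas
#'
#' Partitions the grid into `n_regions` contiguous boxes by recursive
#' bisection along the longest axis (region counts split floor/ceil with
#' voxel counts proportionally), then applies a seeded random permutation to
#' the label values so that labels are not spatially ordered. Every voxel
#' carries exactly one label in `1..n_regions`; deterministic under `seed`.
#'
#' @param grid_shape integer triple.
#' @param n_regions number of regions (>= 1, <= number of voxels).
#' @param seed integer seed for the label permutation; `NULL` leaves labels
#'   in spatial order.
#' @return a [volume3d] of integer labels (identity affine scaled to 1 mm).
#' @export
make_synthetic_atlas <- function(grid_shape, n_regions, seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  nvox <- prod(grid_shape)
  if (n_regions < 1 || n_regions > nvox)
    stop("'n_regions' must be between 1 and the voxel count", call. = FALSE)
  lab <- array(0L, dim = grid_shape)
  # recursion over (box, number of regions, first label)
  fill <- function(lo, hi, k, first) {
    if (k == 1L) {
      lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <<- first
      return(invisible())
    }
    ext <- hi - lo + 1L
    ax <- which.max(ext)
    k1 <- k %/% 2L; k2 <- k - k1
    # split the axis proportionally to the region counts, keeping enough
    # voxels on each side for its share of regions
    other <- prod(ext[-ax])
    lo_len <- as.integer(ceiling(k1 / other))
    hi_len <- ext[ax] - as.integer(ceiling(k2 / other))
    cutlen <- min(max(as.integer(round(ext[ax] * k1 / k)), lo_len), hi_len)
    cut <- lo[ax] - 1L + max(cutlen, 1L)
    hi1 <- hi; hi1[ax] <- cut
    lo2 <- lo; lo2[ax] <- cut + 1L
    fill(lo, hi1, k1, first)
    fill(lo2, hi, k2, first + k1)
  }
  fill(c(1L, 1L, 1L), grid_shape, as.integer(n_regions), 1L)
  if (any(tabulate(lab, n_regions) == 0L))
    stop("cannot split this grid into ", n_regions, " nonempty regions",
         call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
    perm <- sample.int(n_regions)
    lab <- array(perm[lab], dim = grid_shape)
  }
  structure(list(data = lab, affine = diag(4)), class = "volume3d")
}

#' Write ground truth and spec to disk
#'
#' Serialises a [generate_cohort()] result's ground-truth mask as NIfTI and
#' the generating [cohort_spec()] as JSON.
#'
#' @param truth a `ground_truth` object.
#' @param spec the generating [cohort_spec()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(truth$effect_mask, file.path(dir, "effect_mask.nii.gz"))
  sp <- unclass(spec)
  sp$blobs <- lapply(sp$blobs, unclass)
  jsonlite::write_json(sp, file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
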