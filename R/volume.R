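#' 3D scalar volume with a voxel-to-world affine
#'
#' A `volume3d` is the package's basic image container: a 3D numeric array
#' plus a 4x4 affine matrix mapping voxel indices to world (MNI-style)
#' millimetre coordinates, following the NIfTI convention (the affine acts on
#' 0-based indices; R-side accessors take the usual 1-based indices and
#' convert internally).
#'
#' @param data a 3D numeric array of finite values.
#' @param affine a 4x4 invertible matrix; last row `(0,0,0,1)`. Defaults to
#'   the identity (1 mm isotropic voxels at the origin).
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, affine = diag(4)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("'data' must be finite", call. = FALSE)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible", call. = FALSE)
  structure(list(data = data, affine = affine), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d, voxel size %s mm\n",
              d[1], d[2], d[3],
              paste(signif(voxel_sizes(x$affine), 4), collapse = " x ")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
as.array.volume3d <- function(x, ...) x$data

# per-axis voxel edge lengths (mm) from the affine
voxel_sizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI file (`.nii` or `.nii.gz`) into a [volume3d], taking the
#' sform affine when present, otherwise the qform.
#'
#' @param path path to a NIfTI-1 file.
#' @return a [volume3d].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  a <- as.array(img)
  a <- array(as.double(a), dim = dim(a))  # drop RNifti bookkeeping attrs
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("'", path, "' is not a 3D volume", call. = FALSE)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))[1:4, 1:4]
  volume3d(a, aff)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [volume3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel/world coordinate conversion
#'
#' Applies the NIfTI affine to map between R's 1-based voxel indices and
#' world millimetre coordinates: `world = A %*% (i-1, j-1, k-1, 1)`.
#'
#' @param idx integer voxel index triple (1-based), or an n x 3 matrix.
#' @param affine the 4x4 voxel-to-world matrix.
#' @return coordinate triple (or n x 3 matrix) in mm.
#' @export
voxel_to_world <- function(idx, affine) {
  m <- rbind(t(matrix(as.numeric(idx), ncol = 3)) - 1, 1)
  out <- t(affine %*% m)[, 1:3, drop = FALSE]
  if (length(idx) == 3L && is.null(dim(idx))) drop(out) else out
}

#' @rdname voxel_to_world
#' @param mm world coordinate triple (mm), or an n x 3 matrix.
#' @export
world_to_voxel <- function(mm, affine) {
  m <- rbind(t(matrix(as.numeric(mm), ncol = 3)), 1)
  out <- t(solve(affine) %*% m)[, 1:3, drop = FALSE] + 1
  if (length(mm) == 3L && is.null(dim(mm))) drop(out) else out
}

#' Convert a smoothing kernel FWHM to a Gaussian sigma
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, the standard relation between the
#' full width at half maximum and the standard deviation of a Gaussian.
#'
#' @param fwhm full width at half maximum (any length unit).
#' @return sigma in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# reflect an out-of-range 1-based index back into 1..n
# (scipy-style "reflect": d c b a | a b c d | d c b a)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j))
}

# convolve along the first axis of a 3D array with kernel k (odd length),
# reflect boundary; operates on the d1 x (d2*d3) unfolding
conv_axis1 <- function(a, k) {
  d <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  m <- matrix(a, nrow = d[1])
  pad_idx <- reflect_index(seq.int(1L - r, d[1] + r), d[1])
  mp <- m[pad_idx, , drop = FALSE]
  out <- matrix(0, nrow = d[1], ncol = ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[seq_len(d[1]) + (j - 1L), , drop = FALSE]
  array(out, dim = d)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution at a given FWHM in millimetres. The sigma
#' in voxels is computed per axis from the affine's voxel sizes, so
#' anisotropic voxels simply get per-axis sigmas. The kernel is truncated at
#' 4 sigma and renormalised to unit sum; boundaries are handled by
#' reflection. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param vol a [volume3d].
#' @param fwhm_mm kernel full width at half maximum, in mm (>= 0).
#' @return the smoothed [volume3d] (same grid and affine).
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "volume3d"))
  if (length(fwhm_mm) != 1L || !is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("'fwhm_mm' must be a single non-negative number", call. = FALSE)
  if (fwhm_mm == 0) return(vol)
  sig_vox <- fwhm_to_sigma(fwhm_mm) / voxel_sizes(vol$affine)
  a <- vol$data
  for (ax in 1:3) {
    s <- sig_vox[ax]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- stats::dnorm(seq.int(-r, r), sd = s)
    k <- k / sum(k)
    perm <- switch(ax, `1` = 1:3, `2` = c(2L, 1L, 3L), `3` = c(3L, 2L, 1L))
    a <- aperm(conv_axis1(aperm(a, perm), k), order(perm))
  }
  volume3d(a, vol$affine)
}
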