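# Joint image/mask augmentation: intensity normalization, random flips,
# random crop (with zero padding) and a random rigid affine with b-spline
# image interpolation.

#' Augmentation parameters
#'
#' The four-transform pipeline applied to every training pair, in order:
#' normalization of the maximal intensity to 1, random flip along any axis
#' (each axis independently with probability 0.5), random crop to
#' `crop_size` (zero-padded if the input is smaller), and a random rigid
#' affine with rotations up to `max_rotation` degrees about each axis and
#' translations up to `max_translation` voxels. Images are resampled with
#' cubic b-spline interpolation, masks with nearest neighbor (so they stay
#' binary); voxels mapped from outside the field of view are zero.
#'
#' @param crop_size integer length-3 (default 160^3).
#' @param max_rotation maximal rotation per axis, degrees (default 15).
#' @param max_translation maximal translation per axis, voxels (default 20).
#' @param image_interpolation `"bspline"` (default) or `"nearest"`.
#' @param mask_interpolation fixed to `"nearest"`.
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(crop_size = c(160, 160, 160), max_rotation = 15,
                           max_translation = 20,
                           image_interpolation = c("bspline", "nearest"),
                           mask_interpolation = "nearest") {
  crop_size <- as.integer(crop_size)
  if (length(crop_size) != 3L || any(crop_size < 1L))
    stop("crop_size must be 3 positive integers")
  if (max_rotation < 0 || max_translation < 0)
    stop("rotation/translation bounds must be non-negative")
  if (!identical(mask_interpolation, "nearest"))
    stop("mask interpolation is fixed to nearest neighbor")
  structure(list(crop_size = crop_size, max_rotation = max_rotation,
                 max_translation = max_translation,
                 image_interpolation = match.arg(image_interpolation),
                 mask_interpolation = "nearest"),
            class = "augment_params")
}

#' Normalize the maximal voxel intensity to 1
#'
#' Divides by the maximum, preserving relative intensities; idempotent on
#' already-normalized volumes.
#'
#' @param v a volume (or 3D array).
#' @return A [volume()] with maximum exactly 1.
#' @export
normalize_intensity <- function(v) {
  spacing <- if (inherits(v, "chiasm_volume")) v$spacing else c(1, 1, 1)
  arr <- as_volume_array(v)
  mx <- max(arr)
  if (mx <= 0) stop("volume maximum must be positive")
  volume(arr / mx, spacing)
}

#' Random flip of an image/mask pair along any axis
#'
#' Each of the three axes is flipped independently with probability 0.5;
#' image and mask always receive the same flips.
#'
#' @param v a volume (or 3D array).
#' @param m a binary mask of the same shape.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return List with elements `volume` and `mask`.
#' @export
random_flip <- function(v, m, seed = NULL) {
  arr <- as_volume_array(v)
  msk <- as_mask_array(m)
  if (!identical(dim(arr), dim(msk))) stop("shape mismatch")
  draw <- function() stats::runif(3) < 0.5
  flips <- if (is.null(seed)) draw() else with_seed(seed, draw())
  d <- dim(arr)
  ix <- if (flips[1]) rev(seq_len(d[1])) else seq_len(d[1])
  iy <- if (flips[2]) rev(seq_len(d[2])) else seq_len(d[2])
  iz <- if (flips[3]) rev(seq_len(d[3])) else seq_len(d[3])
  list(volume = volume(arr[ix, iy, iz, drop = FALSE]),
       mask = binary_mask(msk[ix, iy, iz, drop = FALSE]))
}

pad_to <- function(arr, size, fill = 0) {
  d <- dim(arr)
  if (all(d >= size)) return(arr)
  nd <- pmax(d, size)
  out <- array(fill, nd)
  off <- floor((nd - d) / 2)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- arr
  out
}

#' Random crop of an image/mask pair
#'
#' Crops both grids with one shared random offset; inputs smaller than the
#' crop are first zero-padded symmetrically.
#'
#' @param v a volume (or 3D array).
#' @param m a binary mask of the same shape.
#' @param crop_size integer length-3.
#' @param seed optional seed.
#' @return List with elements `volume` and `mask` of shape `crop_size`.
#' @export
random_crop <- function(v, m, crop_size, seed = NULL) {
  arr <- as_volume_array(v)
  msk <- as_mask_array(m)
  if (!identical(dim(arr), dim(msk))) stop("shape mismatch")
  crop_size <- as.integer(crop_size)
  arr <- pad_to(arr, crop_size)
  msk <- pad_to(msk, crop_size, fill = 0L)
  d <- dim(arr)
  draw <- function() vapply(1:3, function(a) {
    if (d[a] == crop_size[a]) 0L else sample.int(d[a] - crop_size[a] + 1L, 1L) - 1L
  }, integer(1))
  off <- if (is.null(seed)) draw() else with_seed(seed, draw())
  sl <- lapply(1:3, function(a) off[a] + seq_len(crop_size[a]))
  list(volume = volume(arr[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]),
       mask = binary_mask(msk[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]))
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Resample `arr` so that content is rotated by R about the grid center and
# translated by `t` voxels: out(x) = in(R^T (x - c - t) + c).
affine_resample <- function(arr, rot, trans, interpolation) {
  d <- dim(arr)
  ctr <- (d - 1) / 2  # 0-based center
  M <- t(rot)
  o <- as.numeric(ctr - M %*% (ctr + trans))
  out <- .affine_resample_cpp(as.numeric(arr), as.integer(d), M, o, interpolation)
  array(out, d)
}

#' Random rigid affine transform of an image/mask pair
#'
#' Draws one rotation (each Euler angle uniform within the bound) and one
#' translation (each component uniform within the bound) and applies the
#' identical transform to image and mask. The image is resampled with cubic
#' b-spline interpolation (recursive prefilter, so the identity transform
#' reproduces the input to floating tolerance); the mask with nearest
#' neighbor and re-binarization. Out-of-field voxels are zero.
#'
#' @param v a volume (or 3D array).
#' @param m a binary mask of the same shape.
#' @param params an [augment_params()].
#' @param seed optional seed.
#' @return List with elements `volume` and `mask`, plus the drawn `angles`
#'   (degrees) and `translation` (voxels) as attributes.
#' @export
random_affine <- function(v, m, params = augment_params(), seed = NULL) {
  arr <- as_volume_array(v)
  msk <- as_mask_array(m)
  if (!identical(dim(arr), dim(msk))) stop("shape mismatch")
  draw <- function() list(
    angles = stats::runif(3, -params$max_rotation, params$max_rotation),
    trans = stats::runif(3, -params$max_translation, params$max_translation))
  dr <- if (is.null(seed)) draw() else with_seed(seed, draw())
  rot <- rotation_matrix(dr$angles)
  img <- affine_resample(arr, rot, dr$trans, params$image_interpolation)
  mo <- affine_resample(msk * 1.0, rot, dr$trans, "nearest")
  out <- list(volume = volume(img),
              mask = binary_mask(array(as.integer(mo > 0.5), dim(mo))))
  attr(out, "angles") <- dr$angles
  attr(out, "translation") <- dr$trans
  out
}

#' Full augmentation pipeline
#'
#' Applies, in order: [normalize_intensity()], [random_flip()],
#' [random_crop()] and [random_affine()]. The whole pipeline is driven by a
#' single seed: identical `(pair, seed)` always produces an identical
#' output pair.
#'
#' @param v a volume (or 3D array).
#' @param m a binary mask of the same shape.
#' @param params an [augment_params()].
#' @param seed integer seed for the stochastic transforms.
#' @return List with elements `volume` and `mask`.
#' @export
augment <- function(v, m, params = augment_params(), seed = 1L) {
  with_seed(seed, {
    v <- normalize_intensity(v)
    fl <- random_flip(v, m)
    cr <- random_crop(fl$volume, fl$mask, params$crop_size)
    if (params$max_rotation == 0 && params$max_translation == 0)
      return(list(volume = cr$volume, mask = cr$mask))
    af <- random_affine(cr$volume, cr$mask, params)
    list(volume = af$volume, mask = af$mask)
  })
}
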