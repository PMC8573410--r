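# Volume / binary-mask data model, NIfTI I/O, and 3D grid primitives.

#' Construct a 3D intensity volume
#'
#' A volume is a 3D grid of finite real intensities with per-axis voxel
#' spacing in mm. The axis convention is fixed: axis 1 runs left-right,
#' axis 2 posterior-anterior, axis 3 inferior-superior, so axial slices are
#' indexed along the third axis.
#'
#' @param data 3D numeric array of finite intensities.
#' @param spacing numeric length-3, voxel size in mm per axis (all > 0).
#' @return An object of class `chiasm_volume` with elements `data` and
#'   `spacing`.
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("expected 3D volume")
  if (any(dim(data) < 1L)) stop("all dimensions must be positive")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values")
  structure(list(data = data, spacing = spacing), class = "chiasm_volume")
}

#' Construct a binary mask
#'
#' A mask lives on the same lattice as the volume it annotates and contains
#' only the values 0 and 1.
#'
#' @param data 3D array with values in \{0, 1\} (logical arrays are coerced).
#' @return An object of class `chiasm_mask`.
#' @export
binary_mask <- function(data) {
  data <- as.array(data)
  if (is.logical(data)) data[] <- as.integer(data)
  if (length(dim(data)) != 3L) stop("expected 3D mask")
  if (!all(data %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  storage.mode(data) <- "integer"
  structure(list(data = data), class = "chiasm_mask")
}

#' @export
print.chiasm_volume <- function(x, ...) {
  cat(sprintf("<chiasm_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.chiasm_mask <- function(x, ...) {
  cat(sprintf("<chiasm_mask> %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

as_mask_array <- function(m) {
  if (inherits(m, "chiasm_mask")) return(m$data)
  binary_mask(m)$data
}

as_volume_array <- function(v) {
  if (inherits(v, "chiasm_volume")) return(v$data)
  volume(v)$data
}

reorient_canonical <- function(img) {
  ori <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (!is.null(ori) && !identical(ori, "RAS")) {
    RNifti::orientation(img) <- "RAS"
    message(sprintf("reoriented volume from %s to RAS", ori))
  }
  img
}

#' Read a volume from a NIfTI-1 file
#'
#' Volumes are reoriented on load to the canonical axis order (left-right,
#' posterior-anterior, inferior-superior); any applied permutation is
#' reported via a message. Only 3D images are accepted.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return A [volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D volume")
  img <- reorient_canonical(img)
  volume(array(as.numeric(img), dim(img)), spacing = RNifti::pixdim(img)[1:3])
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v a [volume()].
#' @param path destination `.nii` or `.nii.gz` file.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "chiasm_volume"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Files holding two distinct values other than \{0, 1\} (e.g. \{0, 255\})
#' are normalized to \{0, 1\} with a warning; more than two distinct values
#' is an error.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D volume")
  img <- reorient_canonical(img)
  arr <- array(as.numeric(img), dim(img))
  vals <- sort(unique(as.vector(arr)))
  if (length(vals) > 2L) stop("mask file has more than two distinct values")
  if (!all(vals %in% c(0, 1))) {
    warning(sprintf("mask values {%s} normalized to {0,1}",
                    paste(format(vals), collapse = ", ")))
    arr[] <- as.integer(arr == max(vals))
  }
  binary_mask(arr)
}

#' Write a binary mask to a NIfTI-1 file (unsigned 8-bit, values \{0, 1\})
#'
#' @param m a [binary_mask()].
#' @param path destination file.
#' @param spacing voxel spacing recorded in the header (mm).
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(m, "chiasm_mask"))
  img <- RNifti::asNifti(m$data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`, ranging from 0 (disjoint) to 1
#' (identical). When exactly one mask is empty the value is 0; when both are
#' empty the coefficient is undefined and an error is raised.
#'
#' @param a,b binary masks (or 0/1 arrays) of identical shape.
#' @return A number in \[0, 1\].
#' @export
dsc <- function(a, b) {
  a <- as_mask_array(a)
  b <- as_mask_array(b)
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a)
  nb <- sum(b)
  if (na == 0L && nb == 0L) stop("DSC undefined for two empty masks")
  2 * sum(a & b) / (na + nb)
}

#' Largest connected component of a mask
#'
#' Components are defined under 6, 18 or 26 neighborhood connectivity
#' (default 26, the common neuroimaging cluster convention). Ties in size
#' are broken deterministically by keeping the component that contains the
#' smallest linear voxel index (row-major over the canonical axes).
#'
#' @param m a nonempty binary mask.
#' @param connectivity 6, 18 or 26.
#' @return A [binary_mask()] containing exactly one component.
#' @export
largest_component <- function(m, connectivity = 26) {
  arr <- as_mask_array(m)
  if (sum(arr) == 0L) stop("mask is empty")
  lab <- .cc_label_cpp(as.integer(arr), dim(arr), as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which.max(sizes)  # first max = component seeded earliest
  out <- array(as.integer(lab == keep), dim(arr))
  binary_mask(out)
}

structuring_offsets <- function(element = c("cross6", "cube26")) {
  element <- match.arg(element)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  if (element == "cross6") offs[man <= 1, , drop = FALSE] else offs
}

#' Dilate a mask by one voxel
#'
#' The default element `cross6` adds the six face neighbors ("one voxel in
#' each direction"); `cube26` adds the full 3x3x3 neighborhood. The grid
#' boundary is clipped.
#'
#' @param m a binary mask.
#' @param element `"cross6"` or `"cube26"`.
#' @return The dilated [binary_mask()]; always a superset of the input.
#' @export
dilate_mask <- function(m, element = c("cross6", "cube26")) {
  arr <- as_mask_array(m)
  offs <- structuring_offsets(element)
  idx <- which(arr == 1L)
  if (length(idx) == 0L) return(binary_mask(arr))
  d <- dim(arr)
  co <- arrayInd(idx, d)
  out <- arr
  for (i in seq_len(nrow(offs))) {
    sh <- cbind(co[, 1] + offs[i, 1], co[, 2] + offs[i, 2], co[, 3] + offs[i, 3])
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    if (any(ok)) out[sh[ok, , drop = FALSE]] <- 1L
  }
  binary_mask(out)
}

# Erosion under the same elements; voxels whose neighborhood leaves the grid
# are removed (background outside the grid).
erode_mask <- function(m, element = c("cross6", "cube26")) {
  arr <- as_mask_array(m)
  offs <- structuring_offsets(element)
  d <- dim(arr)
  keep <- array(TRUE, d)
  for (i in seq_len(nrow(offs))) {
    sh <- array(0L, d)
    src <- list(seq_len(d[1]) + offs[i, 1], seq_len(d[2]) + offs[i, 2],
                seq_len(d[3]) + offs[i, 3])
    ok <- lapply(seq_len(3), function(a) src[[a]] >= 1 & src[[a]] <= d[a])
    sh[ok[[1]], ok[[2]], ok[[3]]] <-
      arr[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    keep <- keep & (sh == 1L)
  }
  binary_mask(array(as.integer(keep & arr == 1L), d))
}

#' Linear-interpolation percentile
#'
#' The estimator interpolates linearly between order statistics at index
#' `(n - 1) * q / 100`; `q = 0` and `q = 100` return the minimum and
#' maximum.
#'
#' @param values nonempty numeric vector.
#' @param q percentage in \[0, 100\].
#' @return The q-th percentile.
#' @export
pctile <- function(values, q) {
  if (length(values) == 0L) stop("empty input")
  if (q < 0 || q > 100) stop("q must be in [0, 100]")
  unname(stats::quantile(values, probs = q / 100, type = 7, names = FALSE))
}

#' Binarize a volume to an intensity band
#'
#' Voxels with `lo <= intensity <= hi` (inclusive at both ends) are set to
#' 1, all others to 0.
#'
#' @param v a volume.
#' @param lo,hi band limits with `lo <= hi`.
#' @return A [binary_mask()].
#' @export
binarize_band <- function(v, lo, hi) {
  if (lo > hi) stop("lo must not exceed hi")
  arr <- as_volume_array(v)
  binary_mask(array(as.integer(arr >= lo & arr <= hi), dim(arr)))
}
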