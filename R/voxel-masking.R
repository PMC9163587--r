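#' Binary mask volume on a metric voxel grid
#'
#' Wraps a 3-D logical/0-1 array with its voxel size in mm so that
#' morphological operations can use metric (mm-radius) structuring
#' elements on isotropic or anisotropic grids.
#'
#' @param data 3-D array with values in `{0, 1}` (or logical).
#' @param voxel_size voxel edge lengths in mm, length 1 (isotropic) or
#'   3, all `> 0`.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, voxel_size = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-D array")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  v <- as.logical(data)
  if (anyNA(v) || !all(data %in% c(0, 1, TRUE, FALSE)))
    stop("mask values must be 0/1")
  structure(list(data = array(v, dim(data)), voxel_size = voxel_size),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s voxels (%s mm), %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

#' Metric spherical structuring element
#'
#' Integer voxel offsets whose Euclidean metric length (offset times
#' voxel size) is at most `radius_mm`. With `radius_mm = 0` only the
#' origin remains; at 1 mm isotropic voxels a 1 mm radius gives the
#' centre plus its 6 face neighbours, and a 2 mm radius gives 33
#' offsets.
#'
#' @param radius_mm sphere radius in mm, `>= 0`.
#' @param voxel_size voxel edge lengths in mm (length 1 or 3, `> 0`).
#' @return Integer matrix with one offset per row, columns x/y/z.
#' @export
make_sphere_element <- function(radius_mm, voxel_size = c(1, 1, 1)) {
  stopifnot(radius_mm >= 0)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be positive, length 1 or 3")
  r <- floor(radius_mm / voxel_size)
  g <- expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3])
  d2 <- (g$x * voxel_size[1])^2 + (g$y * voxel_size[2])^2 +
    (g$z * voxel_size[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

## Apply a structuring element by shifting a padded copy of the array;
## `op` is "and" (erosion) or "or" (dilation). Outside the volume is
## background, which makes erosion conservative at the edges.
apply_element <- function(arr, elem, op) {
  d <- dim(arr)
  m <- apply(abs(elem), 2, max)
  pd <- d + 2L * m
  pad <- array(FALSE, pd)
  core <- list(m[1] + seq_len(d[1]), m[2] + seq_len(d[2]),
               m[3] + seq_len(d[3]))
  pad[core[[1]], core[[2]], core[[3]]] <- arr
  acc <- NULL
  for (k in seq_len(nrow(elem))) {
    o <- elem[k, ]
    sh <- pad[core[[1]] + o[1], core[[2]] + o[2], core[[3]] + o[3]]
    acc <- if (is.null(acc)) sh
           else if (op == "and") acc & sh else acc | sh
  }
  array(acc, d)
}

#' Binary erosion and dilation with a metric sphere
#'
#' `erode_mask()` keeps a voxel only if the whole spherical element
#' centred on it lies in the foreground (voxels beyond the volume
#' count as background); `dilate_mask()` marks every voxel reached by
#' the element from some foreground voxel, clipped to the volume.
#' A radius of 0 mm is the identity.
#'
#' @param mask a [mask_volume()].
#' @param radius_mm sphere radius in mm, `>= 0`.
#' @return A [mask_volume()] on the same grid.
#' @export
erode_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "mask_volume"))
  elem <- make_sphere_element(radius_mm, mask$voxel_size)
  mask_volume(apply_element(mask$data, elem, "and"), mask$voxel_size)
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, radius_mm) {
  stopifnot(inherits(mask, "mask_volume"))
  elem <- make_sphere_element(radius_mm, mask$voxel_size)
  mask_volume(apply_element(mask$data, elem, "or"), mask$voxel_size)
}

#' Exclude crossing-fibre and low-anisotropy voxels
#'
#' Retains voxels whose diffusion metrics indicate a single coherent
#' fibre population: fractional anisotropy at least `fa_min` and ODF
#' peak quotient at most `pq_max` (closed acceptance region, so
#' boundary voxels are kept). The operation is idempotent.
#'
#' @param samples voxel table with `fa` and `pq` columns.
#' @param fa_min minimum fractional anisotropy (default 0.6).
#' @param pq_max maximum peak quotient (default 0.3).
#' @return The retained rows of `samples`.
#' @export
crossing_fibre_filter <- function(samples, fa_min = 0.6, pq_max = 0.3) {
  if (!all(c("fa", "pq") %in% names(samples)))
    stop("voxel table must contain 'fa' and 'pq' columns")
  if (anyNA(samples$fa) || anyNA(samples$pq))
    stop("'fa'/'pq' must not contain missing values")
  out <- samples[samples$fa >= fa_min & samples$pq <= pq_max, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normal-appearing white matter mask
#'
#' Removes the lesion mask, dilated by `dilation_mm` to absorb
#' segmentation and alignment slack, from the white-matter mask.
#'
#' @param wm_mask,lesion_mask [mask_volume()]s on the same grid.
#' @param dilation_mm lesion dilation radius in mm (default 1).
#' @return A [mask_volume()]: `wm_mask` minus the dilated lesions.
#' @export
build_nawm_mask <- function(wm_mask, lesion_mask, dilation_mm = 1) {
  stopifnot(inherits(wm_mask, "mask_volume"),
            inherits(lesion_mask, "mask_volume"))
  if (!identical(dim(wm_mask$data), dim(lesion_mask$data)) ||
      !isTRUE(all.equal(wm_mask$voxel_size, lesion_mask$voxel_size)))
    stop("white-matter and lesion masks must share grid and voxel size")
  les <- dilate_mask(lesion_mask, dilation_mm)
  mask_volume(wm_mask$data & !les$data, wm_mask$voxel_size)
}

#' Lesion load of a region of interest
#'
#' Fraction of the ROI volume occupied by lesions:
#' `|roi intersect lesion| / |roi|`.
#'
#' @param roi_mask,lesion_mask [mask_volume()]s on the same grid;
#'   the ROI must be non-empty.
#' @return A fraction in \[0, 1\].
#' @export
lesion_load <- function(roi_mask, lesion_mask) {
  stopifnot(inherits(roi_mask, "mask_volume"),
            inherits(lesion_mask, "mask_volume"))
  if (!identical(dim(roi_mask$data), dim(lesion_mask$data)))
    stop("ROI and lesion masks must share the grid")
  n_roi <- sum(roi_mask$data)
  if (n_roi == 0L) stop("lesion load is undefined for an empty ROI")
  sum(roi_mask$data & lesion_mask$data) / n_roi
}

#' Read / write mask volumes as NIfTI
#'
#' Thin wrappers over RNifti. Reading thresholds the image at
#' `threshold` to obtain a binary mask and takes the voxel size from
#' the NIfTI `pixdim`.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param threshold binarization threshold (default 0.5).
#' @return `read_mask_volume()` returns a [mask_volume()];
#'   `write_mask_volume()` returns `path` invisibly.
#' @export
read_mask_volume <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  mask_volume(array(as.array(img) > threshold, dim(img)[1:3]), vs)
}

#' @param mask a [mask_volume()].
#' @rdname read_mask_volume
#' @export
write_mask_volume <- function(mask, path) {
  stopifnot(inherits(mask, "mask_volume"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim(mask$data)))
  RNifti::pixdim(img) <- mask$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
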