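# Voxel containers: CT volumes, binary structure masks and the labeled spine.
# Axis convention throughout: array index 1 = x (right -> left), index 2 = y
# (anterior -> posterior, larger y is more dorsal), index 3 = z (inferior ->
# superior). Voxel i along an axis with spacing s spans ((i-1)*s, i*s] mm, so
# a treatment beam entering from the posterior surface travels towards
# decreasing y.

#' CT volume
#'
#' A 3-D array of CT numbers (HU) with voxel spacing in mm.
#'
#' @param data 3-D numeric array of HU values, indexed `[x, y, z]`.
#' @param spacing Positive voxel spacing `c(x, y, z)` in mm.
#' @param origin Physical coordinate of the first voxel corner (mm).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_domain("`data` must be a 3-D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_domain("`spacing` must be three positive numbers (mm)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' Binary structure mask
#'
#' A voxel mask on the same grid as its companion CT.
#'
#' @param mask 3-D logical (or 0/1) array.
#' @param spacing Voxel spacing `c(x, y, z)` in mm.
#' @param origin Physical coordinate of the first voxel corner (mm).
#' @return An object of class `structure_volume`.
#' @export
structure_volume <- function(mask, spacing, origin = c(0, 0, 0)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop_domain("`mask` must be a 3-D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_domain("`spacing` must be three positive numbers (mm)")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_volume")
}

#' Labeled spine
#'
#' Integer vertebra label map (0 = background, N = vertebral level) together
#' with the spinal canal and body (external) masks, all on one grid.
#'
#' @param labels 3-D integer array with values in 0..26.
#' @param canal,body 3-D logical arrays.
#' @param spacing Voxel spacing `c(x, y, z)` in mm.
#' @param origin Physical coordinate of the first voxel corner (mm).
#' @return An object of class `labeled_spine`.
#' @export
labeled_spine <- function(labels, canal, body, spacing, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop_domain("`labels` must be a 3-D array")
  if (!all(labels %in% 0:26))
    stop_domain("`labels` values must lie in 0..26")
  if (!identical(dim(labels), dim(canal)) || !identical(dim(labels), dim(body)))
    stop_domain("labels, canal and body must share one grid")
  storage.mode(labels) <- "integer"
  storage.mode(canal) <- "logical"
  storage.mode(body) <- "logical"
  if (any(canal & !body))
    stop_domain("the canal mask must lie inside the body mask")
  structure(list(labels = labels, canal = canal, body = body,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "labeled_spine")
}

vol_dim <- function(x) {
  dim(if (inherits(x, "ct_volume")) x$data
      else if (inherits(x, "structure_volume")) x$mask
      else x$labels)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(vol_dim(a), vol_dim(b)) ||
      !isTRUE(all.equal(a$spacing, b$spacing)))
    stop_domain(what, " are not on the same grid (dim/spacing mismatch)")
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers around the RNifti reader/writer that preserve voxel spacing.
#' Structure masks are stored as 0/1 integer volumes.
#'
#' @param x A [ct_volume()] or [structure_volume()].
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `read_ct_volume()` returns a `ct_volume`; `read_structure_volume()`
#'   a `structure_volume`; the writers return `path` invisibly.
#' @export
write_volume <- function(x, path) {
  dat <- if (inherits(x, "ct_volume")) x$data
         else if (inherits(x, "structure_volume")) x$mask * 1L
         else stop_domain("`x` must be a ct_volume or structure_volume")
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' @rdname write_volume
#' @export
read_structure_volume <- function(path) {
  img <- RNifti::readNifti(path)
  structure_volume(array(as.vector(img) != 0, dim = dim(img)),
                   spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' Structure volume in milliliters
#'
#' Voxel count times voxel volume.
#'
#' @param mask A [structure_volume()].
#' @return Volume in ml.
#' @examples
#' v <- structure_volume(array(TRUE, c(10, 10, 10)), spacing = c(1, 1, 1))
#' structure_volume_ml(v)   # 1 ml
#' @export
structure_volume_ml <- function(mask) {
  stopifnot(inherits(mask, "structure_volume"))
  sum(mask$mask) * prod(mask$spacing) / 1000
}
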