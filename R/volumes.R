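# Voxel-grid containers. Conventions: 0-based voxel indices, voxel-centred,
# world mapping through a NIfTI-style 4x4 affine; voxel i covers the
# half-open interval [i - 0.5, i + 0.5) in voxel space.

#' Voxel grid with world affine
#'
#' @param shape Integer triple of voxel counts per axis.
#' @param voxel_size Voxel edge lengths, mm (scalar or triple).
#' @param origin World coordinates of voxel (0, 0, 0)'s centre, mm.
#' @return A `vox_grid` object: `shape` and 4x4 `affine`.
#' @export
vox_grid <- function(shape, voxel_size = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  vs <- rep_len(voxel_size, 3)
  stopifnot(all(vs > 0))
  affine <- diag(4)
  diag(affine)[1:3] <- vs
  affine[1:3, 4] <- origin
  structure(list(shape = shape, affine = affine), class = "vox_grid")
}

grid_from <- function(x) {
  if (inherits(x, "vox_grid")) return(x)
  if (!is.null(attr(x, "affine"))) {
    return(structure(list(shape = dim(x)[1:3], affine = attr(x, "affine")),
                     class = "vox_grid"))
  }
  stop("cannot derive a voxel grid from this object", call. = FALSE)
}

world_to_voxel <- function(points, grid) {
  inv <- solve(grid$affine)
  p <- cbind(points, 1) %*% t(inv)
  p[, 1:3, drop = FALSE]
}

voxel_to_world <- function(idx, grid) {
  p <- cbind(idx, 1) %*% t(grid$affine)
  p[, 1:3, drop = FALSE]
}

#' Scalar volume (one value per voxel)
#'
#' @param data 3D numeric array.
#' @param kind One of `"FA"`, `"RD"`, `"AD"`, `"TR"`, `"TDI"`, `"APM"`,
#'   `"CURV"` or `"custom"`.
#' @param affine 4x4 voxel-to-world affine (default: identity spacing).
#' @param valid Logical array marking voxels where the value is defined
#'   (default: everywhere). For APM/CURV maps, voxels with zero track
#'   density are invalid.
#' @return A `scalar_volume` object.
#' @export
scalar_volume <- function(data, kind = "custom", affine = NULL, valid = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (is.null(affine)) affine <- diag(4)
  if (is.null(valid)) valid <- array(TRUE, dim = dim(data))
  stopifnot(all(dim(valid) == dim(data)))
  structure(list(data = data, kind = kind, affine = affine, valid = valid),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  rng <- range(x$data[x$valid], na.rm = TRUE)
  cat("<scalar volume>", x$kind, paste(dim(x$data), collapse = "x"),
      " range", format(rng[1], digits = 4), "..", format(rng[2], digits = 4),
      " (", sum(!x$valid), "invalid voxels )\n")
  invisible(x)
}

#' Diffusion-tensor volume
#'
#' Stores the six unique elements of the symmetric diffusion tensor per
#' voxel in lower-triangular order (dxx, dxy, dyy, dxz, dyz, dzz), the
#' order used by NIfTI tensor volumes.
#'
#' @param data 4D array, last dimension of size 6.
#' @param affine 4x4 voxel-to-world affine.
#' @return A `tensor_volume` object.
#' @export
tensor_volume <- function(data, affine = NULL) {
  stopifnot(length(dim(data)) == 4, dim(data)[4] == 6)
  if (!all(is.finite(data))) stop("tensor volume must be finite", call. = FALSE)
  if (is.null(affine)) affine <- diag(4)
  structure(list(data = data, affine = affine), class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat("<tensor volume>", paste(dim(x$data)[1:3], collapse = "x"),
      "voxels, 6 tensor components\n")
  invisible(x)
}

#' Region-of-interest mask
#'
#' @param data Logical (or 0/1) 3D array on the target grid.
#' @param label ROI label, e.g. `"ipsilateral_cc"`, `"contralateral_cc"`.
#' @return An `roi_mask` object.
#' @export
roi_mask <- function(data, label = "custom") {
  stopifnot(length(dim(data)) == 3)
  structure(list(data = array(as.logical(data), dim = dim(data)),
                 label = label), class = "roi_mask")
}

#' Mean of a scalar map over an ROI
#'
#' Arithmetic mean over all mask voxels. By default this is the
#' whole-ROI mean: zero-valued voxels count, and voxels where the map is
#' invalid (e.g. APM/CURV where no track passes) contribute 0. Set
#' `valid_only = TRUE` to average over valid in-mask voxels only.
#'
#' @param volume A [scalar_volume()] (or bare 3D array).
#' @param mask An [roi_mask()] (or logical array) of the same shape.
#' @param valid_only Restrict to valid voxels (default `FALSE`).
#' @return Scalar mean.
#' @export
roi_mean <- function(volume, mask, valid_only = FALSE) {
  if (!inherits(volume, "scalar_volume")) volume <- scalar_volume(volume)
  m <- if (inherits(mask, "roi_mask")) mask$data else array(as.logical(mask), dim = dim(mask))
  if (!all(dim(m) == dim(volume$data))) {
    stop("ROI mask shape does not match the volume", call. = FALSE)
  }
  if (!any(m)) stop("ROI mask is empty", call. = FALSE)
  vals <- volume$data
  vals[!volume$valid] <- 0
  if (valid_only) {
    sel <- m & volume$valid
    if (!any(sel)) stop("no valid voxels inside the ROI", call. = FALSE)
    return(mean(vals[sel]))
  }
  mean(vals[m])
}
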