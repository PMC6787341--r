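# Diffusion-tensor scalar metrics: eigen-decomposition of the 3x3
# symmetric tensor and the standard DTI scalars (FA, RD, AD, trace).

tensor_from_six <- function(six) {
  matrix(c(six[1], six[2], six[4],
           six[2], six[3], six[5],
           six[4], six[5], six[6]), 3, 3)
}

#' Eigenvalues of a symmetric diffusion tensor
#'
#' @param tensor 3x3 symmetric matrix, or length-6 vector in
#'   lower-triangular order (dxx, dxy, dyy, dxz, dyz, dzz).
#' @return Numeric triple of real eigenvalues, descending.
#' @export
tensor_eigenvalues <- function(tensor) {
  if (is.numeric(tensor) && length(tensor) == 6) tensor <- tensor_from_six(tensor)
  stopifnot(is.matrix(tensor), all(dim(tensor) == c(3, 3)))
  if (!all(is.finite(tensor))) stop("tensor must be finite", call. = FALSE)
  if (max(abs(tensor - t(tensor))) > 1e-8 * max(1, max(abs(tensor)))) {
    stop("tensor must be symmetric", call. = FALSE)
  }
  eigen((tensor + t(tensor)) / 2, symmetric = TRUE, only.values = TRUE)$values
}

#' DTI scalar metrics from eigenvalues
#'
#' Trace TR = l1 + l2 + l3; axial diffusivity AD = l1; radial
#' diffusivity RD = (l2 + l3) / 2; fractional anisotropy
#' FA = sqrt(3/2) * sqrt(sum((li - lbar)^2)) / sqrt(sum(li^2)),
#' defined as 0 when all eigenvalues are 0. Negative eigenvalues are not
#' clamped; `valid` flags voxels whose tensor is positive semi-definite.
#'
#' @param ev Eigenvalue triple (descending), or a tensor accepted by
#'   [tensor_eigenvalues()].
#' @return Tibble with columns `FA`, `RD`, `AD`, `TR`, `valid`.
#' @examples
#' tensor_scalars(c(2, 1, 1) * 1e-3)  # FA = 1/sqrt(6)
#' @export
tensor_scalars <- function(ev) {
  if (is.matrix(ev) || length(ev) == 6) ev <- tensor_eigenvalues(ev)
  stopifnot(length(ev) == 3)
  ss <- sum(ev^2)
  fa <- if (ss == 0) 0 else sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / sqrt(ss)
  tibble::tibble(FA = fa, RD = (ev[2] + ev[3]) / 2, AD = ev[1], TR = sum(ev),
                 valid = all(ev >= -1e-15 * max(abs(ev), 1)))
}

#' Voxelwise DTI scalar maps from a tensor volume
#'
#' Eigen-decomposes every voxel's tensor and assembles FA, RD, AD and
#' trace maps. Voxels with negative eigenvalues (non-positive-semi-
#' definite tensors) keep their computed values but are flagged invalid.
#'
#' @param volume A [tensor_volume()].
#' @return Named list of [scalar_volume()]s: `FA`, `RD`, `AD`, `TR`.
#' @export
tensor_scalar_maps <- function(volume) {
  stopifnot(inherits(volume, "tensor_volume"))
  shp <- dim(volume$data)[1:3]
  n <- prod(shp)
  six <- matrix(volume$data, nrow = n, ncol = 6)
  out <- matrix(NA_real_, n, 4)
  ok <- logical(n)
  for (i in seq_len(n)) {
    ev <- tensor_eigenvalues(six[i, ])
    ss <- sum(ev^2)
    out[i, 1] <- if (ss == 0) 0 else
      sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / sqrt(ss)
    out[i, 2] <- (ev[2] + ev[3]) / 2
    out[i, 3] <- ev[1]
    out[i, 4] <- sum(ev)
    ok[i] <- all(ev >= -1e-15 * max(abs(ev), 1))
  }
  valid <- array(ok, dim = shp)
  kinds <- c("FA", "RD", "AD", "TR")
  maps <- lapply(seq_along(kinds), function(k) {
    scalar_volume(array(out[, k], dim = shp), kind = kinds[k],
                  affine = volume$affine, valid = valid)
  })
  names(maps) <- kinds
  maps
}

#' ROI summary table for a set of scalar maps
#'
#' @param maps Named list of [scalar_volume()]s (e.g. from
#'   [tensor_scalar_maps()] or [track_weighted_maps()]).
#' @param rois Named list of [roi_mask()]s (names used as labels).
#' @param valid_only Passed to [roi_mean()].
#' @return Tidy tibble: `roi`, `metric`, `mean`.
#' @export
roi_summary <- function(maps, rois, valid_only = FALSE) {
  purrr::map_dfr(names(rois), function(rn) {
    purrr::map_dfr(names(maps), function(mn) {
      tibble::tibble(roi = rn, metric = mn,
                     mean = roi_mean(maps[[mn]], rois[[rn]],
                                     valid_only = valid_only))
    })
  })
}
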