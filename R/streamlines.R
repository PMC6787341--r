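# Streamline geometry and track-weighted imaging. A streamline is an
# ordered n x 3 matrix of world-mm points; a tractogram is a list of
# streamlines. Track-weighted maps accumulate per-streamline scalars
# (count, total length, mean curvature) into every voxel the streamline
# intersects.

as_streamline <- function(s) {
  s <- as.matrix(s)
  stopifnot(ncol(s) == 3)
  if (!all(is.finite(s))) stop("streamline coordinates must be finite", call. = FALSE)
  s
}

#' Streamline length
#'
#' Sum of Euclidean distances between consecutive points, mm.
#'
#' @param s Streamline: n x 3 matrix of world coordinates, n >= 2.
#' @return Length in mm.
#' @export
streamline_length <- function(s) {
  s <- as_streamline(s)
  if (nrow(s) < 2) stop("streamline needs >= 2 points", call. = FALSE)
  d <- diff(s)
  sum(sqrt(rowSums(d * d)))
}

#' Mean curvature of a streamline
#'
#' Discrete curvature by the Menger construction: for each interior
#' point, the curvature of the consecutive-point triple is the inverse
#' circumradius, kappa = 4 * Area / (|ab| * |bc| * |ca|); the streamline
#' summary is the mean over interior points. Collinear triples have
#' curvature 0 exactly.
#'
#' @param s Streamline: n x 3 matrix, n >= 3.
#' @return Mean curvature, 1/mm.
#' @export
streamline_mean_curvature <- function(s) {
  s <- as_streamline(s)
  n <- nrow(s)
  if (n < 3) stop("curvature needs >= 3 points", call. = FALSE)
  a <- s[1:(n - 2), , drop = FALSE]
  b <- s[2:(n - 1), , drop = FALSE]
  c_ <- s[3:n, , drop = FALSE]
  ab <- b - a
  bc <- c_ - b
  ca <- a - c_
  cross <- cbind(ab[, 2] * bc[, 3] - ab[, 3] * bc[, 2],
                 ab[, 3] * bc[, 1] - ab[, 1] * bc[, 3],
                 ab[, 1] * bc[, 2] - ab[, 2] * bc[, 1])
  area2 <- sqrt(rowSums(cross * cross))          # 2 * triangle area
  lens <- sqrt(rowSums(ab * ab)) * sqrt(rowSums(bc * bc)) *
    sqrt(rowSums(ca * ca))
  kappa <- ifelse(lens > 0, 2 * area2 / lens, 0)
  mean(kappa)
}

# Exact voxel traversal of one segment in continuous voxel coordinates:
# collect the parameters where the segment crosses any half-integer
# boundary plane, then read off the voxel of each sub-interval midpoint.
segment_voxels <- function(p0, p1) {
  ts <- c(0, 1)
  for (a in 1:3) {
    lo <- min(p0[a], p1[a])
    hi <- max(p0[a], p1[a])
    k0 <- ceiling(lo + 0.5)
    k1 <- floor(hi + 0.5)
    if (k1 >= k0) {
      bounds <- (k0:k1) - 0.5
      ts <- c(ts, (bounds - p0[a]) / (p1[a] - p0[a]))
    }
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  mids <- (ts[-length(ts)] + ts[-1]) / 2
  vox <- floor(outer(mids, p1 - p0) + rep(p0 + 0.5, each = length(mids)))
  vox
}

#' Voxels intersected by a streamline
#'
#' Exact geometric rasterization: for every polyline segment the
#' half-integer boundary-plane crossings are enumerated, so the result
#' is the exact set of voxels (voxel-centred, half-open
#' `[i - 0.5, i + 0.5)` intervals in voxel space) the polyline passes
#' through. Each voxel appears once regardless of how often the
#' streamline re-enters it; voxels outside the grid are dropped.
#'
#' @param s Streamline: n x 3 matrix of world coordinates.
#' @param grid A [vox_grid()] (or object with an affine).
#' @return Integer matrix (m x 3) of unique 0-based voxel indices;
#'   zero rows when the streamline lies entirely outside the grid.
#' @export
rasterize_streamline <- function(s, grid) {
  s <- as_streamline(s)
  grid <- grid_from(grid)
  v <- world_to_voxel(s, grid)
  n <- nrow(v)
  pieces <- vector("list", max(1, n - 1))
  if (n == 1) {
    pieces[[1]] <- matrix(floor(v[1, ] + 0.5), 1, 3)
  } else {
    for (i in seq_len(n - 1)) {
      p0 <- v[i, ]
      p1 <- v[i + 1, ]
      pieces[[i]] <- if (all(p0 == p1)) matrix(floor(p0 + 0.5), 1, 3) else
        segment_voxels(p0, p1)
    }
  }
  vox <- do.call(rbind, pieces)
  vox <- unique(vox)
  shp <- grid$shape
  keep <- vox[, 1] >= 0 & vox[, 1] < shp[1] &
          vox[, 2] >= 0 & vox[, 2] < shp[2] &
          vox[, 3] >= 0 & vox[, 3] < shp[3]
  out <- vox[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Track-weighted maps from a tractogram
#'
#' Builds the three track-weighted images on a reference grid:
#' the track density image TDI(v) — the number of streamlines passing
#' through voxel v; the average pathlength map APM(v) — the mean total
#' length of those streamlines; and the mean curvature map CURV(v) —
#' the mean of their per-track mean curvatures (track-level averaging).
#' APM and CURV are flagged invalid where no track passes; two-point
#' streamlines contribute to TDI/APM but carry no curvature.
#'
#' @param tractogram List of streamlines (n x 3 world-mm matrices).
#' @param grid A [vox_grid()].
#' @return Named list of [scalar_volume()]s: `TDI`, `APM`, `CURV`.
#' @export
track_weighted_maps <- function(tractogram, grid) {
  grid <- grid_from(grid)
  if (length(tractogram) < 1) stop("empty tractogram", call. = FALSE)
  shp <- grid$shape
  n_vox <- prod(shp)
  tdi <- numeric(n_vox)
  len_sum <- numeric(n_vox)
  curv_sum <- numeric(n_vox)
  curv_n <- numeric(n_vox)
  for (s in tractogram) {
    vox <- rasterize_streamline(s, grid)
    if (nrow(vox) == 0) next
    lin <- 1 + vox[, 1] + shp[1] * (vox[, 2] + shp[2] * vox[, 3])
    len <- streamline_length(s)
    tdi[lin] <- tdi[lin] + 1
    len_sum[lin] <- len_sum[lin] + len
    if (nrow(s) >= 3) {
      kap <- streamline_mean_curvature(s)
      curv_sum[lin] <- curv_sum[lin] + kap
      curv_n[lin] <- curv_n[lin] + 1
    }
  }
  hit <- tdi > 0
  apm <- ifelse(hit, len_sum / pmax(tdi, 1), NA_real_)
  curv <- ifelse(curv_n > 0, curv_sum / pmax(curv_n, 1), NA_real_)
  list(
    TDI = scalar_volume(array(tdi, dim = shp), kind = "TDI",
                        affine = grid$affine),
    APM = scalar_volume(array(apm, dim = shp), kind = "APM",
                        affine = grid$affine,
                        valid = array(hit, dim = shp)),
    CURV = scalar_volume(array(curv, dim = shp), kind = "CURV",
                         affine = grid$affine,
                         valid = array(curv_n > 0, dim = shp)))
}
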