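# Independent oracles used across the suite. Each one is a brute-force
# or closed-form route kept separate from the package implementation.

# Eigenvalues via the characteristic polynomial (cubic roots), not eigen().
charpoly_eigenvalues <- function(M) {
  c2 <- -sum(diag(M))
  c1 <- (sum(diag(M))^2 - sum(diag(M %*% M))) / 2
  c0 <- -det(M)
  r <- polyroot(c(c0, c1, c2, 1))
  sort(Re(r), decreasing = TRUE)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Exact rasterization oracle: a voxel (half-open [i-0.5, i+0.5) box in
# voxel space) is hit iff some polyline segment intersects the box,
# decided by Liang-Barsky slab clipping per voxel x segment.
box_clip_oracle <- function(streamline, grid) {
  inv <- solve(grid$affine)
  v <- cbind(streamline, 1) %*% t(inv)
  v <- v[, 1:3, drop = FALSE]
  shp <- grid$shape
  hits <- array(FALSE, dim = shp)
  segs <- nrow(v) - 1
  for (s in seq_len(max(segs, 0))) {
    p0 <- v[s, ]; p1 <- v[s + 1, ]
    d <- p1 - p0
    lo_r <- pmax(floor(pmin(p0, p1) + 0.5), 0)
    hi_r <- pmin(floor(pmax(p0, p1) + 0.5), shp - 1)
    if (any(lo_r > hi_r)) next
    for (i in lo_r[1]:hi_r[1]) for (j in lo_r[2]:hi_r[2]) for (k in lo_r[3]:hi_r[3]) {
      if (hits[i + 1, j + 1, k + 1]) next
      box_lo <- c(i, j, k) - 0.5
      box_hi <- c(i, j, k) + 0.5
      t0 <- 0; t1 <- 1; ok <- TRUE
      for (a in 1:3) {
        if (d[a] == 0) {
          if (p0[a] < box_lo[a] || p0[a] >= box_hi[a]) { ok <- FALSE; break }
        } else {
          ta <- (box_lo[a] - p0[a]) / d[a]
          tb <- (box_hi[a] - p0[a]) / d[a]
          if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
          t0 <- max(t0, ta); t1 <- min(t1, tb)
          if (t0 > t1) { ok <- FALSE; break }
        }
      }
      if (ok) hits[i + 1, j + 1, k + 1] <- TRUE
    }
  }
  idx <- which(hits, arr.ind = TRUE) - 1L
  dimnames(idx) <- NULL
  idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
}

# Dense supersampling membership oracle (step = voxel/100): voxels the
# sampled points fall into. A subset of the exact set by construction.
supersample_oracle <- function(streamline, grid, step = 0.01) {
  inv <- solve(grid$affine)
  v <- cbind(streamline, 1) %*% t(inv)
  v <- v[, 1:3, drop = FALSE]
  pts <- list()
  for (s in seq_len(nrow(v) - 1)) {
    d <- v[s + 1, ] - v[s, ]
    len <- sqrt(sum(d^2))
    n <- max(2, ceiling(len / step) + 1)
    tt <- seq(0, 1, length.out = n)
    pts[[s]] <- outer(tt, d) + rep(v[s, ], each = n)
  }
  vox <- unique(floor(do.call(rbind, pts) + 0.5))
  shp <- grid$shape
  keep <- vox[, 1] >= 0 & vox[, 1] < shp[1] &
          vox[, 2] >= 0 & vox[, 2] < shp[2] &
          vox[, 3] >= 0 & vox[, 3] < shp[3]
  vox <- vox[keep, , drop = FALSE]
  storage.mode(vox) <- "integer"
  vox[order(vox[, 1], vox[, 2], vox[, 3]), , drop = FALSE]
}

sort_vox <- function(m) m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]

# Type III ANOVA oracle via explicit projection matrices: residual sums
# of squares computed with hat matrices built from solve(), never qr.
projection_sse <- function(X, y) {
  if (ncol(X) == 0) return(sum(y^2))
  H <- X %*% solve(crossprod(X), t(X))
  r <- y - H %*% y
  sum(r^2)
}

type3_oracle <- function(obs, value = "value", factors = c("injury", "day")) {
  f1 <- factor(obs[[factors[1]]]); f2 <- factor(obs[[factors[2]]])
  contrasts(f1) <- contr.sum(nlevels(f1))
  contrasts(f2) <- contr.sum(nlevels(f2))
  X <- model.matrix(~ f1 * f2, data.frame(f1 = f1, f2 = f2))
  asg <- attr(X, "assign")
  y <- obs[[value]]
  sse_full <- projection_sse(X, y)
  df_res <- nrow(X) - ncol(X)
  out <- lapply(1:3, function(term) {
    ss <- projection_sse(X[, asg != term, drop = FALSE], y) - sse_full
    df <- sum(asg == term)
    Fv <- (ss / df) / (sse_full / df_res)
    data.frame(ss = ss, df = df, statistic = Fv,
               p.value = pf(Fv, df, df_res, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

# Small balanced mixed-design dataset builder for aov() cross-checks.
make_mixed_data <- function(n_per_group = 5, seed = 1, delta_group = 0,
                            delta_within = 0, delta_inter = 0, sd = 1) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(2 * n_per_group))
  grp <- rep(c("sham", "rmtbi"), each = n_per_group)
  first <- rnorm(2 * n_per_group, 10 + delta_group * (grp == "rmtbi"), sd)
  second <- first + delta_within + delta_inter * (grp == "rmtbi") +
    rnorm(2 * n_per_group, 0, sd)
  data.frame(
    subject_id = rep(subj, 2),
    injury = rep(grp, 2),
    injury_number = rep(c("first", "second"), each = 2 * n_per_group),
    value = c(first, second))
}
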