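# Synthetic-data generators. Every generator returns the simulated input
# alongside a ground-truth record so each downstream stage can be
# validated against known parameters.

check_prop <- function(x, nm) {
  if (!is.finite(x) || x < 0 || x >= 1) {
    stop(nm, " must lie in [0, 1)", call. = FALSE)
  }
}

#' Configuration for a simulated RPPM slide
#'
#' Describes a reverse-phase protein microarray slide: each sample is
#' printed as a 1:1 serial dilution series (step k carries relative
#' concentration 2^-k of the starting dilution) with replicate
#' depositions per spot. Expected log10 net intensity follows the true
#' 5PL evaluated at log2(abundance x 2^-k); noise is multiplicative
#' log-normal (additive Gaussian in log10). A fraction of spots can be
#' planted as intensity outliers (net multiplied by `outlier_scale`) or
#' as sub-threshold spots (SNR drawn uniformly in [0.5, 1.9], below the
#' SNR < 2 exclusion rule).
#'
#' @param n_samples Number of samples printed on the slide.
#' @param n_dilutions Serial dilution steps per sample (>= 4; default 8).
#' @param depositions_per_spot Replicate depositions (default 2).
#' @param true_5pl True [fivepl()] response. The default has asymptotes
#'   2 and 4.5 log10 AU and a Hill slope chosen so the mid-curve responds
#'   proportionally (slope log10(2) per log2 concentration).
#' @param true_abundance Per-sample relative abundances (positive). If
#'   `NULL`, drawn log-normally: log10 abundance ~ N(0, `abundance_sd10`).
#' @param abundance_sd10 SD of log10 abundance when drawing (default 0.1).
#' @param noise_sigma Log-normal noise SD in log10 units (default 0.02).
#' @param background_mean Local background fluorescence, AU (default 50).
#' @param outlier_fraction,outlier_scale Fraction of spots turned into
#'   intensity outliers, and their multiplier (defaults 0 and 10).
#' @param subthreshold_fraction Fraction of spots planted sub-threshold.
#' @param samples_per_block Samples per printing block (default 4).
#' @param seed Integer seed; same seed + config gives identical output.
#' @return A `slide_sim_config` object.
#' @export
slide_sim_config <- function(n_samples = 16, n_dilutions = 8,
                             depositions_per_spot = 2,
                             true_5pl = fivepl(A = 2, D = 4.5, C = -4,
                                               B = 4 * log10(2) / (2.5 * log(2)),
                                               G = 1),
                             true_abundance = NULL, abundance_sd10 = 0.1,
                             noise_sigma = 0.02, background_mean = 50,
                             outlier_fraction = 0, outlier_scale = 10,
                             subthreshold_fraction = 0,
                             samples_per_block = 4, seed = 1) {
  if (n_dilutions < 4) stop("n_dilutions must be >= 4", call. = FALSE)
  if (n_samples < 1 || depositions_per_spot < 1) {
    stop("n_samples and depositions_per_spot must be >= 1", call. = FALSE)
  }
  check_prop(outlier_fraction, "outlier_fraction")
  check_prop(subthreshold_fraction, "subthreshold_fraction")
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(background_mean) || background_mean <= 0) {
    stop("background_mean must be positive and finite", call. = FALSE)
  }
  if (!is.null(true_abundance)) {
    if (length(true_abundance) != n_samples || any(!is.finite(true_abundance)) ||
        any(true_abundance <= 0)) {
      stop("true_abundance must be ", n_samples, " finite positive values",
           call. = FALSE)
    }
  }
  structure(list(n_samples = n_samples, n_dilutions = n_dilutions,
                 depositions_per_spot = depositions_per_spot,
                 true_5pl = as_fivepl(true_5pl),
                 true_abundance = true_abundance,
                 abundance_sd10 = abundance_sd10,
                 noise_sigma = noise_sigma, background_mean = background_mean,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale,
                 subthreshold_fraction = subthreshold_fraction,
                 samples_per_block = samples_per_block,
                 seed = as.integer(seed)),
            class = "slide_sim_config")
}

#' Simulate an RPPM slide
#'
#' Generates one spot row per (sample, dilution step, deposition).
#' Raw fluorescence is net + background so that background correction
#' recovers the simulated net signal exactly; SNR is raw/background
#' except for planted sub-threshold spots. Planted counts follow the
#' deterministic rule `floor(fraction * n_spots)` with assignment by a
#' seeded shuffle.
#'
#' @param config A [slide_sim_config()].
#' @return A list of class `rppm_sim`: `spots` (spot-table tibble with
#'   columns `sample_id`, `block_id`, `dilution_step`, `deposition`,
#'   `raw`, `background`, `snr`) and `truth` (true 5PL, per-sample
#'   abundance tibble, per-row planted flags, config).
#' @export
simulate_rppm_slide <- function(config = slide_sim_config()) {
  stopifnot(inherits(config, "slide_sim_config"))
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(old), add = TRUE)

  n_s <- config$n_samples
  abund <- config$true_abundance
  if (is.null(abund)) {
    abund <- 10^stats::rnorm(n_s, 0, config$abundance_sd10)
  }
  sample_ids <- sprintf("S%02d", seq_len(n_s))
  block_of <- sprintf("B%02d", ((seq_len(n_s) - 1) %/% config$samples_per_block) + 1)

  grid <- tidyr::expand_grid(sample_idx = seq_len(n_s),
                             dilution_step = seq_len(config$n_dilutions) - 1L,
                             deposition = seq_len(config$depositions_per_spot))
  n_spots <- nrow(grid)
  xlog2 <- log2(abund[grid$sample_idx]) - grid$dilution_step
  mu <- eval_5pl(xlog2, config$true_5pl)
  ylog10 <- mu + stats::rnorm(n_spots, 0, config$noise_sigma)
  net <- 10^ylog10

  # planted labels: floor(fraction * n), assigned by one seeded shuffle
  shuffle <- sample.int(n_spots)
  n_out <- floor(config$outlier_fraction * n_spots)
  n_sub <- floor(config$subthreshold_fraction * n_spots)
  is_outlier <- rep(FALSE, n_spots)
  is_subthreshold <- rep(FALSE, n_spots)
  if (n_out > 0) is_outlier[shuffle[seq_len(n_out)]] <- TRUE
  if (n_sub > 0) is_subthreshold[shuffle[n_out + seq_len(n_sub)]] <- TRUE
  net[is_outlier] <- net[is_outlier] * config$outlier_scale

  background <- rep(config$background_mean, n_spots)
  raw <- net + background
  snr <- raw / background
  snr[is_subthreshold] <- stats::runif(sum(is_subthreshold), 0.5, 1.9)

  spots <- tibble::tibble(
    sample_id = sample_ids[grid$sample_idx],
    block_id = block_of[grid$sample_idx],
    dilution_step = grid$dilution_step,
    deposition = grid$deposition,
    raw = raw, background = background, snr = snr)
  truth <- list(
    true_5pl = config$true_5pl,
    abundance = tibble::tibble(sample_id = sample_ids,
                               block_id = block_of,
                               abundance = abund,
                               log10_abundance = log10(abund)),
    flags = tibble::tibble(row = seq_len(n_spots),
                           outlier = is_outlier,
                           subthreshold = is_subthreshold),
    config = config)
  structure(list(spots = spots, truth = truth), class = "rppm_sim")
}

# RNG scope helpers: generators set their own seed but must not disturb
# the caller's random stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Configuration for a simulated streamline bundle
#'
#' Analytic phantom bundles with known per-streamline length and
#' curvature: a straight line (curvature 0), a circular arc (curvature
#' 1/radius) or a circular helix (curvature r/(r^2 + c^2), with c the
#' pitch parameter, i.e. axial rise per radian).
#'
#' @param geometry `"line"`, `"circle"` or `"helix"`.
#' @param length_mm Line length (line geometry), mm.
#' @param radius_mm Circle/helix radius, mm.
#' @param arc_deg Circle arc in degrees (default 360).
#' @param pitch_mm Helix pitch parameter c (rise per radian), mm.
#' @param turns Helix turns (default 2).
#' @param n_streamlines Number of streamlines in the bundle.
#' @param step_size Sampling step along the curve, mm.
#' @param jitter_sigma SD of the rigid perpendicular offset applied to
#'   each streamline's whole centerline, mm (0 = all identical).
#' @param seed Integer seed.
#' @return A `tract_sim_config` object.
#' @export
tract_sim_config <- function(geometry = c("line", "circle", "helix"),
                             length_mm = 20, radius_mm = 10, arc_deg = 360,
                             pitch_mm = 1, turns = 2,
                             n_streamlines = 10, step_size = 0.5,
                             jitter_sigma = 0, seed = 1) {
  geometry <- match.arg(geometry)
  if (step_size <= 0) stop("step_size must be > 0", call. = FALSE)
  if (n_streamlines < 1) stop("n_streamlines must be >= 1", call. = FALSE)
  scale <- switch(geometry, line = length_mm,
                  circle = radius_mm * pi * arc_deg / 180,
                  helix = 2 * pi * turns * sqrt(radius_mm^2 + pitch_mm^2))
  if (step_size >= scale) {
    stop("step_size larger than the geometry scale", call. = FALSE)
  }
  structure(list(geometry = geometry, length_mm = length_mm,
                 radius_mm = radius_mm, arc_deg = arc_deg,
                 pitch_mm = pitch_mm, turns = turns,
                 n_streamlines = n_streamlines, step_size = step_size,
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "tract_sim_config")
}

#' Simulate an analytic streamline bundle
#'
#' Samples each streamline along the configured geometry at `step_size`
#' arc-length spacing. Jitter, when requested, is a Gaussian offset of
#' the whole centerline perpendicular to the bundle axis, which shifts
#' streamlines without changing their analytic length or curvature.
#'
#' @param config A [tract_sim_config()].
#' @return A list of class `tract_sim`: `tractogram` (list of n x 3
#'   point matrices, world mm) and `truth` (analytic `length_mm` and
#'   `curvature_per_mm` per streamline, config).
#' @export
simulate_bundle <- function(config = tract_sim_config()) {
  stopifnot(inherits(config, "tract_sim_config"))
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(old), add = TRUE)

  centerline <- switch(config$geometry,
    line = {
      s <- seq(0, config$length_mm, by = config$step_size)
      if (s[length(s)] < config$length_mm) s <- c(s, config$length_mm)
      cbind(s, 0, 0)
    },
    circle = {
      arc <- config$arc_deg * pi / 180
      dt <- config$step_size / config$radius_mm
      t <- seq(0, arc, by = dt)
      if (abs(t[length(t)] - arc) > 1e-12) t <- c(t, arc)
      config$radius_mm * cbind(cos(t), sin(t), 0)
    },
    helix = {
      total <- 2 * pi * config$turns
      dt <- config$step_size / sqrt(config$radius_mm^2 + config$pitch_mm^2)
      t <- seq(0, total, by = dt)
      if (abs(t[length(t)] - total) > 1e-12) t <- c(t, total)
      cbind(config$radius_mm * cos(t), config$radius_mm * sin(t),
            config$pitch_mm * t)
    })
  true_len <- switch(config$geometry,
    line = config$length_mm,
    circle = config$radius_mm * config$arc_deg * pi / 180,
    helix = 2 * pi * config$turns * sqrt(config$radius_mm^2 + config$pitch_mm^2))
  true_curv <- switch(config$geometry,
    line = 0,
    circle = 1 / config$radius_mm,
    helix = config$radius_mm / (config$radius_mm^2 + config$pitch_mm^2))

  streamlines <- lapply(seq_len(config$n_streamlines), function(i) {
    off <- if (config$jitter_sigma > 0) {
      # rigid offset perpendicular to the bundle's main axis (x for the
      # line, z for circle/helix): shift in the two remaining axes
      if (config$geometry == "line") {
        c(0, stats::rnorm(2, 0, config$jitter_sigma))
      } else {
        c(stats::rnorm(2, 0, config$jitter_sigma), 0)
      }
    } else c(0, 0, 0)
    sweep(centerline, 2, off, "+")
  })
  truth <- tibble::tibble(streamline = seq_len(config$n_streamlines),
                          length_mm = true_len,
                          curvature_per_mm = true_curv)
  structure(list(tractogram = streamlines,
                 truth = list(per_streamline = truth, config = config)),
            class = "tract_sim")
}

#' Configuration for a simulated diffusion-tensor volume
#'
#' Every voxel carries the same symmetric tensor R diag(eigenvalues) R',
#' with R rotating the x-axis onto `principal_direction`; optional
#' symmetric Gaussian noise is added to the unique tensor elements.
#'
#' @param grid_shape Integer triple of voxel counts.
#' @param eigenvalues Descending triple, mm^2/s
#'   (default `c(1.6, 0.4, 0.4) * 1e-3`, a coherent white-matter-like
#'   tensor).
#' @param principal_direction Unit 3-vector (normalised internally).
#' @param voxel_size Isotropic voxel edge, mm.
#' @param noise_sigma SD of additive element noise (default 0).
#' @param seed Integer seed.
#' @return A `tensor_sim_config` object.
#' @export
tensor_sim_config <- function(grid_shape = c(8, 8, 8),
                              eigenvalues = c(1.6, 0.4, 0.4) * 1e-3,
                              principal_direction = c(1, 0, 0),
                              voxel_size = 1, noise_sigma = 0, seed = 1) {
  if (length(eigenvalues) != 3 || is.unsorted(rev(eigenvalues))) {
    stop("eigenvalues must be a descending triple", call. = FALSE)
  }
  if (!all(is.finite(eigenvalues))) {
    stop("eigenvalues must be finite", call. = FALSE)
  }
  nrm <- sqrt(sum(principal_direction^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop("principal_direction must be a nonzero vector", call. = FALSE)
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 eigenvalues = eigenvalues,
                 principal_direction = principal_direction / nrm,
                 voxel_size = voxel_size,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "tensor_sim_config")
}

# rotation taking e1 onto unit vector v (completed by Gram-Schmidt)
rotation_to <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u2 <- a - sum(a * v) * v
  u2 <- u2 / sqrt(sum(u2^2))
  u3 <- c(v[2] * u2[3] - v[3] * u2[2],
          v[3] * u2[1] - v[1] * u2[3],
          v[1] * u2[2] - v[2] * u2[1])
  cbind(v, u2, u3)
}

#' Simulate a diffusion-tensor volume with known eigenstructure
#'
#' @param config A [tensor_sim_config()].
#' @return A list of class `tensor_sim`: `volume` (a `tensor_volume`,
#'   see [tensor_volume()]) and `truth` (eigenvalues plus the implied
#'   FA/RD/AD/trace, constant over the grid).
#' @export
simulate_tensor_volume <- function(config = tensor_sim_config()) {
  stopifnot(inherits(config, "tensor_sim_config"))
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(old), add = TRUE)

  R <- rotation_to(config$principal_direction)
  Tm <- R %*% diag(config$eigenvalues) %*% t(R)
  base <- c(Tm[1, 1], Tm[1, 2], Tm[2, 2], Tm[1, 3], Tm[2, 3], Tm[3, 3])
  shp <- config$grid_shape
  n_vox <- prod(shp)
  dat <- array(rep(base, each = n_vox), dim = c(shp, 6))
  if (config$noise_sigma > 0) {
    dat <- dat + array(stats::rnorm(n_vox * 6, 0, config$noise_sigma),
                       dim = c(shp, 6))
  }
  vol <- tensor_volume(dat, affine = diag(c(rep(config$voxel_size, 3), 1)))
  truth_scalars <- tensor_scalars(config$eigenvalues)
  structure(list(volume = vol,
                 truth = list(eigenvalues = config$eigenvalues,
                              scalars = truth_scalars, config = config)),
            class = "tensor_sim")
}

#' Configuration for factorial behavioural data
#'
#' A 2 (injury: sham vs RmTBI) x k (recovery day) between-subjects
#' design with specified cell means, common residual SD and per-cell
#' sample sizes (which may be unbalanced, as in cohorts of 8 sham vs
#' 10 injured animals).
#'
#' @param cell_means Data frame with columns `injury`, `day`, `mean`,
#'   one row per cell. Default: a null 2 x 5 design (all means 10).
#' @param residual_sd Common within-cell SD (> 0 unless exactly 0 is
#'   wanted for degenerate checks).
#' @param n_per_cell Single count or data frame (`injury`, `day`, `n`);
#'   every cell needs n >= 2.
#' @param seed Integer seed.
#' @return A `behavior_sim_config` object.
#' @export
behavior_sim_config <- function(cell_means = NULL, residual_sd = 1,
                                n_per_cell = 8, seed = 1) {
  if (is.null(cell_means)) {
    cell_means <- tidyr::expand_grid(
      injury = c("sham", "rmtbi"),
      day = c("D1", "D3", "D5", "D7", "D30"))
    cell_means$mean <- 10
  }
  cell_means <- tibble::as_tibble(cell_means)
  stopifnot(all(c("injury", "day", "mean") %in% names(cell_means)))
  if (is.data.frame(n_per_cell)) {
    stopifnot(all(c("injury", "day", "n") %in% names(n_per_cell)))
    cells <- dplyr::left_join(cell_means, tibble::as_tibble(n_per_cell),
                              by = c("injury", "day"))
    if (any(is.na(cells$n))) stop("n_per_cell misses cells", call. = FALSE)
  } else {
    cells <- dplyr::mutate(cell_means, n = as.integer(n_per_cell))
  }
  if (any(cells$n < 2)) stop("every cell needs n >= 2", call. = FALSE)
  if (!is.finite(residual_sd) || residual_sd < 0) {
    stop("residual_sd must be finite and >= 0", call. = FALSE)
  }
  structure(list(cells = cells, residual_sd = residual_sd,
                 seed = as.integer(seed)),
            class = "behavior_sim_config")
}

#' Simulate factorial behavioural observations
#'
#' Draws independent normal observations per cell at the configured
#' means and residual SD.
#'
#' @param config A [behavior_sim_config()].
#' @return A list of class `behavior_sim`: `obs` (long tibble:
#'   `subject_id`, `injury`, `day`, `value`) and `truth` (cell means,
#'   residual SD, standardised injury effect size per day).
#' @export
simulate_factorial_data <- function(config = behavior_sim_config()) {
  stopifnot(inherits(config, "behavior_sim_config"))
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(.restore_seed(old), add = TRUE)

  cells <- config$cells
  obs <- tidyr::uncount(cells, weights = .data$n, .remove = FALSE) |>
    dplyr::mutate(value = .data$mean +
                    stats::rnorm(dplyr::n(), 0, config$residual_sd)) |>
    dplyr::group_by(.data$injury, .data$day) |>
    dplyr::mutate(subject_id = sprintf("%s_%s_%02d", .data$injury, .data$day,
                                       dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "injury", "day", "value")
  effect <- cells |>
    dplyr::select("injury", "day", "mean") |>
    tidyr::pivot_wider(names_from = "injury", values_from = "mean")
  if (all(c("sham", "rmtbi") %in% names(effect)) && config$residual_sd > 0) {
    effect$injury_d <- (effect$rmtbi - effect$sham) / config$residual_sd
  }
  structure(list(obs = obs,
                 truth = list(cells = cells, residual_sd = config$residual_sd,
                              injury_effect = effect, config = config)),
            class = "behavior_sim")
}
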