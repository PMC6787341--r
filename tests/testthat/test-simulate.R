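test_that("slide simulation has one row per sample x step x deposition", {
  cfg <- slide_sim_config(n_samples = 4, n_dilutions = 8,
                          depositions_per_spot = 1, seed = 1)
  sim <- simulate_rppm_slide(cfg)
  expect_equal(nrow(sim$spots), 32)
  expect_equal(sum(sim$truth$flags$outlier), 0)
  expect_equal(sum(sim$truth$flags$subthreshold), 0)
  cfg2 <- slide_sim_config(n_samples = 4, depositions_per_spot = 2, seed = 1)
  expect_equal(nrow(simulate_rppm_slide(cfg2)$spots), 64)
})

test_that("noise-free spots lie exactly on the true 5PL", {
  cfg <- slide_sim_config(n_samples = 6, noise_sigma = 0, seed = 4)
  sim <- simulate_rppm_slide(cfg)
  ab <- sim$truth$abundance
  x <- log10(sim$spots$raw - sim$spots$background)
  mu <- eval_5pl(ab$log10_abundance[match(sim$spots$sample_id, ab$sample_id)] /
                   log10(2) - sim$spots$dilution_step,
                 sim$truth$true_5pl)
  expect_equal(x, mu, tolerance = 1e-12)
})

test_that("same seed and config give bit-identical slides; seeds differ otherwise", {
  cfg <- slide_sim_config(n_samples = 5, seed = 77)
  expect_identical(simulate_rppm_slide(cfg), simulate_rppm_slide(cfg))
  cfg2 <- slide_sim_config(n_samples = 5, seed = 78)
  expect_false(identical(simulate_rppm_slide(cfg)$spots,
                         simulate_rppm_slide(cfg2)$spots))
})

test_that("planted label counts follow floor(fraction x n) and planted spots break thresholds", {
  cfg <- slide_sim_config(n_samples = 10, n_dilutions = 8,
                          depositions_per_spot = 2,
                          outlier_fraction = 0.05,
                          subthreshold_fraction = 0.1, seed = 12)
  sim <- simulate_rppm_slide(cfg)
  n <- nrow(sim$spots)   # 160
  expect_equal(sum(sim$truth$flags$outlier), floor(0.05 * n))
  expect_equal(sum(sim$truth$flags$subthreshold), floor(0.1 * n))
  sub <- sim$truth$flags$subthreshold
  expect_true(all(sim$spots$snr[sub] < 2 & sim$spots$snr[sub] >= 0.5))
  expect_true(all(sim$spots$snr[!sub] >= 2))
})

test_that("slide config validation rejects impossible worlds", {
  expect_error(slide_sim_config(n_dilutions = 3), "n_dilutions")
  expect_error(slide_sim_config(outlier_fraction = 1), "outlier_fraction")
  expect_error(slide_sim_config(noise_sigma = NA), "noise_sigma")
  expect_error(slide_sim_config(n_samples = 4, true_abundance = c(1, 2)),
               "true_abundance")
  expect_error(slide_sim_config(true_abundance = c(-1, rep(1, 15))),
               "true_abundance")
})

test_that("bundle phantoms carry their analytic length and curvature truth", {
  b <- simulate_bundle(tract_sim_config(geometry = "line", length_mm = 20,
                                        n_streamlines = 2, jitter_sigma = 0))
  expect_equal(unique(b$truth$per_streamline$length_mm), 20)
  expect_equal(unique(b$truth$per_streamline$curvature_per_mm), 0)
  bc <- simulate_bundle(tract_sim_config(geometry = "circle", radius_mm = 10,
                                         n_streamlines = 1))
  expect_equal(bc$truth$per_streamline$curvature_per_mm, 0.1)
  bh <- simulate_bundle(tract_sim_config(geometry = "helix", radius_mm = 1,
                                         pitch_mm = 1, n_streamlines = 1,
                                         step_size = 0.05))
  expect_equal(bh$truth$per_streamline$curvature_per_mm, 1 / (1 + 1) * 1)
  expect_error(tract_sim_config(geometry = "line", length_mm = 5,
                                step_size = 10), "geometry scale")
})

test_that("polyline length converges to the analytic value as step size shrinks", {
  err <- sapply(c(1, 0.25), function(st) {
    b <- simulate_bundle(tract_sim_config(geometry = "circle", radius_mm = 10,
                                          step_size = st, n_streamlines = 1))
    abs(streamline_length(b$tractogram[[1]]) - 2 * pi * 10)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2] / (2 * pi * 10), 1e-3)
})

test_that("rigid jitter displaces streamlines without altering their geometry", {
  b <- simulate_bundle(tract_sim_config(geometry = "circle", radius_mm = 10,
                                        n_streamlines = 5, jitter_sigma = 1,
                                        seed = 3))
  lens <- sapply(b$tractogram, streamline_length)
  curvs <- sapply(b$tractogram, streamline_mean_curvature)
  expect_equal(lens, rep(lens[1], 5), tolerance = 1e-12)
  expect_equal(curvs, rep(0.1, 5), tolerance = 1e-10)
  # offsets actually differ between streamlines
  expect_gt(max(abs(b$tractogram[[1]][1, ] - b$tractogram[[2]][1, ])), 0)
})

test_that("tensor volume simulation plants the requested eigenstructure", {
  iso <- simulate_tensor_volume(tensor_sim_config(
    grid_shape = c(3, 3, 3), eigenvalues = c(1, 1, 1) * 1e-3))
  expect_equal(iso$truth$scalars$FA, 0)
  expect_equal(iso$truth$scalars$TR, 3e-3)
  stick <- simulate_tensor_volume(tensor_sim_config(
    grid_shape = c(2, 2, 2), eigenvalues = c(1, 0, 0)))
  expect_equal(stick$truth$scalars$FA, 1)
  cfg <- tensor_sim_config(grid_shape = c(4, 3, 2),
                           eigenvalues = c(2, 1, 1) * 1e-3,
                           principal_direction = c(1, 1, 0))
  sim <- simulate_tensor_volume(cfg)
  # every voxel's tensor reproduces the configured eigenvalues
  six <- sim$volume$data[2, 2, 1, ]
  expect_equal(tensor_eigenvalues(six), c(2, 1, 1) * 1e-3, tolerance = 1e-12)
  expect_equal(sim$truth$scalars$FA, 1 / sqrt(6), tolerance = 1e-12)
  expect_error(tensor_sim_config(eigenvalues = c(1, 2, 3) * 1e-3),
               "descending")
})

test_that("factorial simulator honours cell means, SD and unbalanced counts", {
  cm <- tidyr::expand_grid(injury = c("sham", "rmtbi"),
                           day = c("D1", "D3"))
  cm$mean <- c(10, 12, 14, 11)
  npc <- cm[, c("injury", "day")]
  npc$n <- c(8, 10, 8, 10)
  sim <- simulate_factorial_data(behavior_sim_config(cell_means = cm,
                                                     residual_sd = 0,
                                                     n_per_cell = npc,
                                                     seed = 6))
  got <- summarize_mean_sem(sim$obs, injury, day)
  merged <- dplyr::inner_join(got, cm, by = c("injury", "day"))
  expect_equal(merged$mean.x, merged$mean.y)
  expect_equal(sort(got$n), sort(npc$n))
  expect_equal(nrow(sim$obs), sum(npc$n))
  expect_error(behavior_sim_config(n_per_cell = 1), "n >= 2")
})

test_that("null factorial design yields F near 1 on average (property)", {
  Fs <- sapply(1:40, function(s) {
    sim <- simulate_factorial_data(behavior_sim_config(seed = s,
                                                       n_per_cell = 4))
    tab <- two_way_anova(sim$obs)
    tab$statistic[tab$effect == "injury"]
  })
  # E[F] = df2/(df2-2) under the null; loose band around it
  expect_gt(mean(Fs), 0.5)
  expect_lt(mean(Fs), 1.7)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(999)
  before <- .Random.seed
  invisible(simulate_rppm_slide(slide_sim_config(n_samples = 4, seed = 1)))
  invisible(simulate_bundle(tract_sim_config(n_streamlines = 2, seed = 2)))
  invisible(simulate_factorial_data(behavior_sim_config(seed = 3)))
  expect_identical(before, .Random.seed)
})
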