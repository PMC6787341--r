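true_p <- function() slide_sim_config()$true_5pl

noise_free_series <- function(n_samples = 8, abund = rep(1, n_samples),
                              seed = 5) {
  cfg <- slide_sim_config(n_samples = n_samples, noise_sigma = 0,
                          true_abundance = abund, seed = seed)
  sim <- simulate_rppm_slide(cfg)
  flt <- filter_spots(sim$spots)
  list(series = build_dilution_series(average_depositions(flt$kept)),
       truth = sim$truth)
}

test_that("master curve recovers true 5PL exactly on a noise-free slide", {
  nf <- noise_free_series()
  fit <- fit_master_curve(nf$series)
  truth <- nf$truth$true_5pl
  for (nm in c("A", "D", "C", "B", "G")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-6)
  }
  expect_true(fit$converged)
  expect_lt(max(abs(fit$residuals)), 1e-6)
})

test_that("master fit refuses insufficient data", {
  expect_error(fit_master_curve(tibble::tibble(x = c(-1, 0), y = c(3, 4))),
               ">= 8 usable points")
  # 8 points but only 2 distinct dilution steps
  expect_error(fit_master_curve(tibble::tibble(x = rep(c(-1, 0), 4),
                                               y = rnorm(8))),
               ">= 3 dilution steps")
})

test_that("FDR outlier mask flags a lone large residual and nothing on zeros", {
  r <- rep(0, 19)
  expect_equal(fdr_outlier_mask(c(r, 5)), c(rep(FALSE, 19), TRUE))
  expect_equal(fdr_outlier_mask(rep(0, 20)), rep(FALSE, 20))
  expect_error(fdr_outlier_mask(rnorm(5)), ">= 10 residuals")
})

test_that("FDR outlier mask controls the null and catches planted outliers", {
  set.seed(101)
  sigma <- 0.02  # slide noise scale, log10 units
  null_rates <- replicate(25, mean(fdr_outlier_mask(rnorm(200, 0, sigma),
                                                    q = 0.01)))
  expect_lt(mean(null_rates), 0.05)
  # a 10x intensity outlier is +1 log10 unit on top of the noise
  sens <- replicate(25, {
    r <- rnorm(200, 0, sigma)
    planted <- sample(200, 10)
    r[planted] <- r[planted] + sample(c(-1, 1), 10, replace = TRUE) * log10(10)
    mean(fdr_outlier_mask(r, q = 0.01)[planted])
  })
  expect_gte(mean(sens), 0.9)
})

test_that("refinement is a fixed point on clean data (single round)", {
  nf <- noise_free_series()
  fit <- fit_master_curve(nf$series)
  ref <- refine_master(fit)
  expect_equal(ref$n_refinement_rounds, 1L)
  expect_equal(ref$params, fit$params)
  expect_true(all(!ref$outlier))
  expect_true(ref$converged)
})

test_that("refinement pulls the master fit back toward truth after planted outliers", {
  cfg <- slide_sim_config(n_samples = 8, noise_sigma = 0.01,
                          true_abundance = rep(1, 8),
                          outlier_fraction = 0.04, outlier_scale = 10,
                          seed = 7)
  sim <- simulate_rppm_slide(cfg)
  ser <- build_dilution_series(average_depositions(filter_spots(sim$spots)$kept))
  fit0 <- fit_master_curve(ser)
  ref <- refine_master(fit0)
  truth <- sim$truth$true_5pl
  err <- function(p) sum(abs(unlist(p[c("A", "D", "C", "B", "G")]) -
                               unlist(truth[c("A", "D", "C", "B", "G")])))
  expect_gt(sum(ref$outlier), 0)
  expect_lt(err(ref$params), err(fit0$params))
  # refinement never increases kept-point RSS
  rss0 <- sum((fit0$residuals[!ref$outlier])^2)
  rss1 <- sum((ref$residuals[!ref$outlier])^2)
  expect_lte(rss1, rss0 + 1e-12)
})

test_that("local block fit shares shape parameters and spaces positions by dilution shifts", {
  nf <- noise_free_series(n_samples = 3, abund = c(1, 2, 4), seed = 9)
  master <- fit_master_curve(nf$series)
  bf <- fit_local_block(nf$series, master$params)
  truth <- nf$truth$true_5pl
  # shared parameters equal the generator truth
  for (nm in c("A", "D", "B", "G")) {
    expect_equal(bf$shared[[nm]], truth[[nm]], tolerance = 1e-6)
  }
  # doubling abundance shifts C by exactly -1 log2 unit (C_i = C - log2 a_i)
  Cs <- bf$C[order(names(bf$C))]
  expect_equal(unname(diff(Cs)), c(-1, -1), tolerance = 1e-6)
  expect_equal(unname(Cs[1]), truth$C, tolerance = 1e-6)
})

test_that("identical noise-free series yield identical per-sample positions", {
  nf <- noise_free_series(n_samples = 4, abund = rep(1, 4), seed = 2)
  master <- fit_master_curve(nf$series)
  bf <- fit_local_block(nf$series, master$params)
  expect_lt(diff(range(bf$C)), 1e-6)
  expect_error(
    fit_local_block(tibble::tibble(sample_id = "S01", x = c(0, -1),
                                   y = c(4, 3.7)), master$params),
    ">= 3 usable points")
})

test_that("quantification reproduces an exact line and flags unusable series", {
  p <- fivepl(A = 0, D = 16, C = 0, B = 0.5, G = 1)
  ser <- tibble::tibble(sample_id = "S01", x = c(-1, -2, -3), y = c(9, 8, 7))
  q <- quantify_sample(ser, p)
  expect_equal(q$linear_slope, 1)       # -1 log10 AU per dilution step
  expect_equal(q$y_intercept, 10)       # 1e10 AU at dilution step 0
  expect_equal(q$n_points_used, 3L)
  # a series whose fitted response never enters the linear band
  flat <- tibble::tibble(sample_id = "S02", x = c(-9, -10, -11),
                         y = c(0.1, 0.1, 0.1))
  q2 <- quantify_sample(flat, p)
  expect_false(q2$usable)
  expect_true(is.na(q2$y_intercept))
})

test_that("doubling true abundance raises the y-intercept by about log10(2)", {
  cfg <- slide_sim_config(n_samples = 4, noise_sigma = 0,
                          true_abundance = c(1, 2, 4, 8),
                          samples_per_block = 4, seed = 1)
  q <- tidy(quantify_slide(simulate_rppm_slide(cfg)$spots))
  d <- diff(q$y_intercept[order(q$sample_id)])
  expect_true(all(d > 0))
  # truth Hill slope gives a proportional mid-curve; band-edge
  # discretisation leaves a few percent of wiggle
  expect_true(all(abs(d - log10(2)) < 0.055))
})

test_that("noisy slide ranks abundances correctly (Spearman recovery)", {
  cfg <- slide_sim_config(n_samples = 16, noise_sigma = 0.02, seed = 42)
  sim <- simulate_rppm_slide(cfg)
  q <- tidy(quantify_slide(sim$spots))
  merged <- dplyr::inner_join(q, sim$truth$abundance, by = "sample_id")
  rho <- cor(merged$abundance, merged$y_intercept, method = "spearman")
  expect_gte(rho, 0.95)
})
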