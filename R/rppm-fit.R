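# Master / local 5PL fitting for RPPM dilution series.
#
# Fitting happens in log-log coordinates (log10 net intensity vs log2
# relative concentration). The slide-wide master fit pools every usable
# point on a common -dilution_step axis; local block fits share the
# asymptotes, Hill slope and asymmetry across samples with one free
# position per sample, initialised at the master values.

# Stable 5PL right-hand side used inside nls formulas.
fivepl_rhs <- function(x, A, D, C, B, G) {
  u <- B * (x - C)
  l <- ifelse(u > 0, u * log(2) + log1p(2^(-u)), log1p(2^u))
  D + (A - D) * exp(-G * l)
}

# Bounded least-squares 5PL fit; nls(port) with an optim fallback.
fit_5pl_core <- function(x, y, start, max_iter = 500, tol = 1e-10) {
  b <- fivepl_bounds(x, y)
  start <- lapply(start, function(v) v)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo + 1e-9), hi - 1e-9)
  for (nm in names(b$lower)) {
    start[[nm]] <- clamp(start[[nm]], b$lower[[nm]], b$upper[[nm]])
  }
  dat <- data.frame(x = x, y = y)
  # warnOnly keeps near-converged fits usable; the flag records the state
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ fivepl_rhs(x, A, D, C, B, G),
                 data = dat, start = start,
                 lower = b$lower, upper = b$upper,
                 algorithm = "port",
                 control = stats::nls.control(maxiter = max_iter, tol = tol,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    conv <- isTRUE(fit$convInfo$isConv)
    params <- list(A = cf[["A"]], D = cf[["D"]], C = cf[["C"]],
                   B = cf[["B"]], G = cf[["G"]])
  } else {
    conv <- FALSE
    params <- start
  }
  # polish (or rescue) with bounded quasi-Newton on the RSS
  obj <- function(th) {
    r <- y - fivepl_rhs(x, th[1], th[2], th[3], th[4], th[5])
    sum(r * r)
  }
  th0 <- unlist(params[c("A", "D", "C", "B", "G")])
  op <- tryCatch(
    stats::optim(th0, obj, method = "L-BFGS-B",
                 lower = b$lower[c("A", "D", "C", "B", "G")],
                 upper = b$upper[c("A", "D", "C", "B", "G")],
                 control = list(maxit = max_iter, factr = 10)),
    error = function(e) NULL)
  if (!is.null(op) && op$value <= obj(th0) + 1e-15) {
    params <- as.list(op$par)
    names(params) <- c("A", "D", "C", "B", "G")
    conv <- conv || op$convergence == 0
  }
  list(params = do.call(fivepl, params), converged = conv)
}

#' Fit the slide-wide 5PL master curve
#'
#' Pools every usable point on the slide onto a common log2-concentration
#' axis (per-sample positions collapsed by aligning on dilution step) and
#' fits a single five-parameter logistic by bounded least squares.
#'
#' @param series Dilution-series tibble from [build_dilution_series()]
#'   (columns `x`, `y`, optionally `usable`), or any data frame with
#'   `x`/`y` columns.
#' @param init Optional [fivepl()] initial values; by default the start is
#'   derived deterministically from data quantiles.
#' @param q FDR level retained with the fit for later outlier refinement.
#' @return A `master_fit` object: fields `params` ([fivepl()]),
#'   `residuals`, `outlier` mask, `n_refinement_rounds`, `converged`,
#'   and the fitted data.
#' @export
fit_master_curve <- function(series, init = NULL, q = 0.01) {
  series <- tibble::as_tibble(series)
  if ("usable" %in% names(series)) series <- series[series$usable, ]
  x <- series$x
  y <- series$y
  if (length(x) < 8 || length(unique(x)) < 3) {
    stop("master fit needs >= 8 usable points spanning >= 3 dilution steps",
         call. = FALSE)
  }
  start <- if (is.null(init)) fivepl_start(x, y) else unclass(as_fivepl(init))
  core <- fit_5pl_core(x, y, start)
  res <- y - eval_5pl(x, core$params)
  structure(list(params = core$params,
                 data = series,
                 residuals = res,
                 outlier = rep(FALSE, length(res)),
                 n_refinement_rounds = 0L,
                 q = q,
                 converged = core$converged),
            class = "master_fit")
}

#' @export
print.master_fit <- function(x, ...) {
  cat("<RPPM master curve fit> ", nrow(x$data), "points,",
      sum(x$outlier), "outliers,",
      x$n_refinement_rounds, "refinement round(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$params)
  invisible(x)
}

#' FDR residual outlier mask (ROUT-style)
#'
#' Flags outlying residuals from a robust fit: the scale is estimated as
#' the 68.27th percentile of the absolute residuals (which equals one
#' standard deviation for Gaussian residuals), each point gets a
#' two-sided t-test against that scale, and the Benjamini-Hochberg
#' step-up procedure at rate `q` decides which points are flagged.
#'
#' @param residuals Numeric residual vector (length >= 10).
#' @param q FDR level, in (0, 1). Default 0.01.
#' @param n_params Number of fitted parameters consumed by the model
#'   (default 5, the 5PL), used for the t degrees of freedom.
#' @return Logical mask, `TRUE` for flagged outliers.
#' @export
fdr_outlier_mask <- function(residuals, q = 0.01, n_params = 5) {
  n <- length(residuals)
  if (n < 10) stop("FDR outlier detection needs >= 10 residuals", call. = FALSE)
  if (!all(is.finite(residuals))) stop("residuals must be finite", call. = FALSE)
  scale <- stats::quantile(abs(residuals), 0.6827, names = FALSE)
  if (scale == 0) {
    return(residuals != 0)
  }
  df <- max(1L, n - n_params)
  tval <- abs(residuals) / scale
  p <- 2 * stats::pt(-tval, df = df)
  ord <- order(p)
  thresh <- q * seq_len(n) / n
  ok <- p[ord] <= thresh
  if (!any(ok)) return(rep(FALSE, n))
  cut <- p[ord][max(which(ok))]
  p <= cut
}

#' Refine the master curve by iterated FDR outlier exclusion
#'
#' Alternates outlier flagging (via [fdr_outlier_mask()]) and refitting on
#' the kept points until the outlier set stops changing, or for at most
#' `max_rounds` rounds. Residuals are re-evaluated against the refreshed
#' curve each round.
#'
#' @param fit A `master_fit` from [fit_master_curve()].
#' @param thresholds A [filter_thresholds()] (its `fdr_q` is used).
#' @param max_rounds Maximum alternation rounds (default 5).
#' @return The refined `master_fit` with updated `params`, `outlier`
#'   mask, `n_refinement_rounds` and `converged`.
#' @export
refine_master <- function(fit, thresholds = filter_thresholds(),
                          max_rounds = 5L) {
  stopifnot(inherits(fit, "master_fit"))
  x <- fit$data$x
  y <- fit$data$y
  params <- fit$params
  mask <- fit$outlier
  rounds <- 0L
  converged <- FALSE
  for (r in seq_len(max_rounds)) {
    rounds <- r
    res <- y - eval_5pl(x, params)
    new_mask <- fdr_outlier_mask(res, q = thresholds$fdr_q)
    if (all(new_mask == mask) && r > 0L) {
      mask <- new_mask
      converged <- TRUE
      break
    }
    if (all(new_mask)) {
      stop("all points flagged as outliers; cannot refit master curve",
           call. = FALSE)
    }
    mask <- new_mask
    core <- fit_5pl_core(x[!mask], y[!mask], unclass(params))
    params <- core$params
  }
  res <- y - eval_5pl(x, params)
  structure(list(params = params, data = fit$data, residuals = res,
                 outlier = mask, n_refinement_rounds = rounds,
                 q = thresholds$fdr_q,
                 converged = converged && fit$converged),
            class = "master_fit")
}

#' Shared-parameter local block fit
#'
#' Fits one block of samples jointly: the asymptotic maximum and minimum,
#' Hill slope and asymmetry constant (`A`, `D`, `B`, `G`) are shared
#' between the samples of the block while each sample keeps its own
#' position `C_i`. The master-curve values are the initial conditions.
#' A block containing a single sample degenerates to a per-sample fit.
#'
#' @param block_series Dilution-series tibble for one block (columns
#'   `sample_id`, `x`, `y`, optionally `usable`).
#' @param master A [fivepl()] (typically the refined master-fit params).
#' @param max_iter,tol Optimiser controls.
#' @return A `block_fit` object: `block_id`, `shared` (A, D, B, G),
#'   `C` (named per-sample positions), per-sample diagnostics tibble,
#'   `converged`.
#' @export
fit_local_block <- function(block_series, master, max_iter = 500, tol = 1e-10) {
  ser <- tibble::as_tibble(block_series)
  if ("usable" %in% names(ser)) ser <- ser[ser$usable, ]
  master <- as_fivepl(master)
  counts <- table(ser$sample_id)
  if (any(counts < 3)) {
    stop("every series in the block needs >= 3 usable points", call. = FALSE)
  }
  samples <- names(counts)
  si <- match(ser$sample_id, samples)
  n_s <- length(samples)
  x <- ser$x
  y <- ser$y
  b <- fivepl_bounds(x, y)
  lower <- c(b$lower[c("A", "D", "B", "G")], rep(b$lower[["C"]], n_s))
  upper <- c(b$upper[c("A", "D", "B", "G")], rep(b$upper[["C"]], n_s))
  start <- list(A = master$A, D = master$D, B = master$B, G = master$G,
                C = rep(master$C, n_s))
  clamp <- function(v, lo, hi) pmin(pmax(v, lo + 1e-9), hi - 1e-9)
  start$A <- clamp(start$A, b$lower[["A"]], b$upper[["A"]])
  start$D <- clamp(start$D, b$lower[["D"]], b$upper[["D"]])
  start$B <- clamp(start$B, b$lower[["B"]], b$upper[["B"]])
  start$G <- clamp(start$G, b$lower[["G"]], b$upper[["G"]])
  start$C <- clamp(start$C, b$lower[["C"]], b$upper[["C"]])
  dat <- data.frame(x = x, y = y, si = si)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ fivepl_rhs(x, A, D, C[si], B, G),
                 data = dat, start = start,
                 lower = lower, upper = upper, algorithm = "port",
                 control = stats::nls.control(maxiter = max_iter, tol = tol,
                                              warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    shared <- list(A = cf[["A"]], D = cf[["D"]], B = cf[["B"]], G = cf[["G"]])
    Ci <- cf[grepl("^C", names(cf))]
    conv <- isTRUE(fit$convInfo$isConv)
  } else {
    shared <- start[c("A", "D", "B", "G")]
    Ci <- start$C
    conv <- FALSE
  }
  # quasi-Newton polish on the joint RSS (also the rescue path)
  obj <- function(th) {
    r <- y - fivepl_rhs(x, th[1], th[2], th[4 + si], th[3], th[4])
    sum(r * r)
  }
  th0 <- c(shared$A, shared$D, shared$B, shared$G, unname(Ci))
  op <- tryCatch(
    stats::optim(th0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = max_iter, factr = 10)),
    error = function(e) NULL)
  if (!is.null(op) && op$value <= obj(th0) + 1e-15) {
    shared <- list(A = op$par[1], D = op$par[2], B = op$par[3], G = op$par[4])
    Ci <- op$par[-(1:4)]
    conv <- conv || op$convergence == 0
  }
  names(Ci) <- samples
  fitted <- fivepl_rhs(x, shared$A, shared$D, Ci[si], shared$B, shared$G)
  diag <- tibble::tibble(sample_id = samples,
                         C = unname(Ci),
                         n_points = as.integer(counts),
                         rss = as.numeric(tapply((y - fitted)^2, si, sum)))
  structure(list(block_id = if ("block_id" %in% names(ser))
                   ser$block_id[[1]] else NA,
                 shared = shared, C = Ci, diagnostics = diag,
                 converged = conv),
            class = "block_fit")
}

#' @export
print.block_fit <- function(x, ...) {
  cat("<RPPM local block fit> block", format(x$block_id), "-",
      length(x$C), "sample(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  shared A =", format(x$shared$A, digits = 4),
      " D =", format(x$shared$D, digits = 4),
      " B =", format(x$shared$B, digits = 4),
      " G =", format(x$shared$G, digits = 4), "\n")
  invisible(x)
}

#' Quantify one sample from its dilution series (y-intercept readout)
#'
#' Identifies the linear portion of the fitted logistic response — the
#' observed points whose fitted value lies within the central
#' `linear_range` band of the asymptote range `|A - D|` — fits an
#' ordinary least-squares line through those points in (log2
#' concentration, log10 intensity), and extrapolates it back to zero
#' dilution (step 0). The y-intercept indexes the amount of protein.
#'
#' @param series One sample's series tibble (columns `x`, `y`).
#' @param block A `block_fit` from [fit_local_block()] containing the
#'   sample, or a plain [fivepl()] to use directly.
#' @param sample_id Sample to quantify (defaults to the series' own id).
#' @param linear_range Fractional band of the asymptote range that
#'   defines the linear portion (default `c(0.25, 0.75)`).
#' @return One-row tibble: `sample_id`, `linear_slope` (log10 AU per
#'   log2 concentration), `y_intercept` (log10 AU at dilution step 0),
#'   `n_points_used`, `usable`.
#' @export
quantify_sample <- function(series, block, sample_id = NULL,
                            linear_range = c(0.25, 0.75)) {
  ser <- tibble::as_tibble(series)
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(ser)) ser$sample_id[[1]] else NA
  }
  if (inherits(block, "block_fit")) {
    if (!sample_id %in% names(block$C)) {
      stop("sample ", sample_id, " not present in block fit", call. = FALSE)
    }
    p <- fivepl(A = block$shared$A, D = block$shared$D,
                C = unname(block$C[[sample_id]]),
                B = block$shared$B, G = block$shared$G)
  } else {
    p <- as_fivepl(block)
  }
  yhat <- eval_5pl(ser$x, p)
  lo_asym <- min(p$A, p$D)
  rng <- abs(p$A - p$D)
  sel <- yhat >= lo_asym + linear_range[1] * rng &
         yhat <= lo_asym + linear_range[2] * rng
  if (sum(sel) < 2) {
    return(tibble::tibble(sample_id = sample_id, linear_slope = NA_real_,
                          y_intercept = NA_real_,
                          n_points_used = sum(sel), usable = FALSE))
  }
  cf <- stats::coef(stats::lm(y ~ x, data = ser[sel, ]))
  tibble::tibble(sample_id = sample_id,
                 linear_slope = unname(cf[["x"]]),
                 y_intercept = unname(cf[["(Intercept)"]]),
                 n_points_used = sum(sel), usable = TRUE)
}

#' Quantify a whole RPPM slide
#'
#' End-to-end dilution-series quantification: filter spots (SNR and net
#' fluorescence), average replicate depositions, build log-log series,
#' fit the slide-wide 5PL master curve, refine it by FDR outlier
#' exclusion, fit each local block with shared shape parameters, and
#' read out every sample's linear-portion y-intercept.
#'
#' @param spots Spot table (see [filter_spots()] for required columns).
#' @param thresholds A [filter_thresholds()].
#' @param min_points Minimum usable points for a series to be fitted.
#' @param linear_range Linear-portion band, see [quantify_sample()].
#' @return An `rppm_quant` object: `quant` tibble (one row per sample),
#'   `master` (refined `master_fit`), `blocks` (list of `block_fit`),
#'   `n_excluded`, `thresholds`. `tidy()` returns the per-sample table,
#'   `glance()` the slide-level summary.
#' @examples
#' sim <- simulate_rppm_slide(slide_sim_config(n_samples = 8, seed = 1))
#' q <- quantify_slide(sim$spots)
#' generics::tidy(q)
#' @export
quantify_slide <- function(spots, thresholds = filter_thresholds(),
                           min_points = 3, linear_range = c(0.25, 0.75)) {
  flt <- filter_spots(spots, thresholds)
  avg <- average_depositions(flt$kept)
  ser <- build_dilution_series(avg, min_points = min_points)
  usable <- ser[ser$usable, ]
  master <- fit_master_curve(usable, q = thresholds$fdr_q)
  master <- refine_master(master, thresholds)
  blocks <- usable |>
    dplyr::group_by(.data$block_id) |>
    dplyr::group_split() |>
    purrr::map(fit_local_block, master = master$params)
  names(blocks) <- purrr::map_chr(blocks, ~ as.character(.x$block_id))
  quant <- purrr::map_dfr(blocks, function(bf) {
    purrr::map_dfr(names(bf$C), function(sid) {
      one <- usable[usable$sample_id == sid, ]
      dplyr::mutate(
        quantify_sample(one, bf, sample_id = sid, linear_range = linear_range),
        block_id = bf$block_id, .after = "sample_id")
    })
  })
  structure(list(quant = quant, master = master, blocks = blocks,
                 n_excluded = nrow(flt$excluded),
                 excluded = flt$excluded,
                 thresholds = thresholds),
            class = "rppm_quant")
}

#' @export
print.rppm_quant <- function(x, ...) {
  cat("<RPPM slide quantification>", nrow(x$quant), "samples,",
      length(x$blocks), "blocks,", x$n_excluded, "spots filtered out\n")
  print(x$master$params)
  invisible(x)
}
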