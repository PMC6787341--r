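#' Filtering thresholds for RPPM spot tables
#'
#' Spots indiscernible from background are excluded before any curve is
#' fitted: a spot is dropped when its signal-to-noise ratio falls below
#' `snr_min` or its background-corrected net fluorescence falls below
#' `net_min` (strict inequalities). `fdr_q` is the false-discovery rate
#' used later for residual outlier rejection on the master curve.
#'
#' @param snr_min Minimum signal-to-noise ratio (default 2).
#' @param net_min Minimum net fluorescence in AU (default 10).
#' @param fdr_q FDR level for outlier rejection (default 0.01).
#' @return A `filter_thresholds` object (named list).
#' @export
filter_thresholds <- function(snr_min = 2, net_min = 10, fdr_q = 0.01) {
  if (snr_min <= 0 || net_min <= 0) {
    stop("filter thresholds must be positive", call. = FALSE)
  }
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must lie in (0, 1)", call. = FALSE)
  structure(list(snr_min = snr_min, net_min = net_min, fdr_q = fdr_q),
            class = "filter_thresholds")
}

#' Background-corrected net fluorescence
#'
#' Subtracts the local background estimate from the raw spot fluorescence.
#' The result may be negative; such spots are removed downstream by the
#' `net_min` filter, not here.
#'
#' @param raw Raw spot fluorescence, AU (vectorised).
#' @param background Local background fluorescence, AU.
#' @return Net fluorescence, AU.
#' @examples
#' compute_net_fluorescence(100, 40)  # 60
#' @export
compute_net_fluorescence <- function(raw, background) {
  if (!all(is.finite(raw)) || !all(is.finite(background))) {
    stop("raw and background fluorescence must be finite", call. = FALSE)
  }
  raw - background
}

spot_required_cols <- c("sample_id", "block_id", "dilution_step",
                        "deposition", "raw", "background", "snr")

validate_spot_table <- function(spots) {
  missing <- setdiff(spot_required_cols, names(spots))
  if (length(missing) > 0) {
    stop("spot table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(spots)
}

#' Filter an RPPM spot table
#'
#' Computes net fluorescence per spot and partitions the table into kept
#' and excluded spots. A spot is excluded iff `snr < snr_min` OR
#' `net < net_min` (strict `<`, so spots exactly at a threshold are kept).
#' The two outputs partition the input exactly.
#'
#' @param spots A spot table with columns `sample_id`, `block_id`,
#'   `dilution_step`, `deposition`, `raw`, `background`, `snr`.
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with tibbles `kept` and `excluded`, each carrying a
#'   `net` column; `excluded` also records the `reason`.
#' @export
filter_spots <- function(spots, thresholds = filter_thresholds()) {
  spots <- tibble::as_tibble(spots)
  if (nrow(spots) == 0) {
    empty <- dplyr::mutate(spots, net = numeric(0))
    return(list(kept = empty,
                excluded = dplyr::mutate(empty, reason = character(0))))
  }
  validate_spot_table(spots)
  spots <- dplyr::mutate(spots,
                         net = compute_net_fluorescence(.data$raw, .data$background))
  bad_snr <- spots$snr < thresholds$snr_min
  bad_net <- spots$net < thresholds$net_min
  drop <- bad_snr | bad_net
  excluded <- spots[drop, , drop = FALSE]
  excluded$reason <- dplyr::case_when(
    bad_snr[drop] & bad_net[drop] ~ "snr+net",
    bad_snr[drop] ~ "snr",
    TRUE ~ "net"
  )
  list(kept = spots[!drop, , drop = FALSE], excluded = excluded)
}

#' Collapse replicate depositions
#'
#' The arrayer prints each sample/dilution twice (2 depositions per spot);
#' after filtering, surviving replicate depositions are averaged on the
#' linear net-fluorescence scale.
#'
#' @param kept A filtered spot table (with `net` column).
#' @return Tibble with one row per sample x block x dilution step:
#'   `sample_id`, `block_id`, `dilution_step`, `net`, `n_depositions`.
#' @export
average_depositions <- function(kept) {
  kept |>
    dplyr::group_by(.data$sample_id, .data$block_id, .data$dilution_step) |>
    dplyr::summarise(n_depositions = dplyr::n(),
                     net = mean(.data$net), .groups = "drop")
}

#' Build per-sample dilution series
#'
#' Converts an averaged, filtered spot table into log-log dilution series:
#' x = log2 relative concentration (`-dilution_step`, step 0 being the
#' undiluted printed sample, each further step a 1:1 dilution) and
#' y = log10 net fluorescence. Points are ordered by concentration; a
#' series is usable for fitting only with at least `min_points` points.
#'
#' @param kept Filtered spot table, typically from [average_depositions()].
#' @param min_points Minimum usable points per series (default 3).
#' @return Tibble with columns `sample_id`, `block_id`, `x`, `y`,
#'   `usable` (series-level flag).
#' @export
build_dilution_series <- function(kept, min_points = 3) {
  if (nrow(kept) == 0) {
    return(tibble::tibble(sample_id = character(), block_id = character(),
                          x = numeric(), y = numeric(), usable = logical()))
  }
  ser <- kept |>
    dplyr::filter(.data$net > 0) |>
    dplyr::mutate(x = -as.numeric(.data$dilution_step), y = log10(.data$net)) |>
    dplyr::arrange(.data$sample_id, .data$x)
  ser |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(usable = dplyr::n() >= min_points) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "block_id", "x", "y", "usable")
}
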