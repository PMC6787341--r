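# Factorial group statistics: between-subjects two-way ANOVA with
# Type III sums of squares (sum-to-zero contrasts, as in the SPSS
# default), protected Bonferroni pairwise comparisons on the pooled
# error term, a 2x2 mixed-design ANOVA, and mean +/- SEM summaries.

new_anova_table <- function(tbl, kind) {
  structure(tbl, class = c("anova_table", class(tbl)), kind = kind)
}

#' @export
print.anova_table <- function(x, ...) {
  cat("<ANOVA table:", attr(x, "kind"), ">\n")
  NextMethod()
}

ss_from_fit <- function(X, y) {
  # residual sum of squares of y on column space of X
  if (ncol(X) == 0) return(sum(y^2))
  qr_ <- qr(X)
  sum(qr.resid(qr_, y)^2)
}

#' Between-subjects two-way ANOVA (Type III)
#'
#' Decomposes a 2-factor between-subjects design into main effects and
#' interaction using Type III sums of squares with sum-to-zero
#' contrasts, which keeps main-effect tests meaningful in unbalanced
#' designs (e.g. cohorts of 8 sham vs 10 injured animals). Each effect's
#' SS is the increase in residual SS when that effect's columns are
#' removed from the full model (all other terms retained).
#'
#' @param obs Long-format data frame of observations.
#' @param value Name of the response column (default `"value"`).
#' @param factors Character pair naming the two between-subjects factor
#'   columns (default `c("injury", "day")`).
#' @return An `anova_table` tibble: `effect`, `ss`, `df`, `statistic`
#'   (F), `p.value`, with a `Residuals` row.
#' @export
two_way_anova <- function(obs, value = "value", factors = c("injury", "day")) {
  obs <- tibble::as_tibble(obs)
  stopifnot(all(c(value, factors) %in% names(obs)))
  f1 <- factor(obs[[factors[1]]])
  f2 <- factor(obs[[factors[2]]])
  y <- obs[[value]]
  stopifnot(is.numeric(y), all(is.finite(y)))
  if (nlevels(f1) < 2 || nlevels(f2) < 2) {
    stop("both factors need >= 2 levels", call. = FALSE)
  }
  counts <- table(f1, f2)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1, ]
    stop("empty cell: ", factors[1], "=", rownames(counts)[bad[1]], ", ",
         factors[2], "=", colnames(counts)[bad[2]], call. = FALSE)
  }
  contrasts(f1) <- stats::contr.sum(nlevels(f1))
  contrasts(f2) <- stats::contr.sum(nlevels(f2))
  mf <- data.frame(y = y, f1 = f1, f2 = f2)
  X <- stats::model.matrix(~ f1 * f2, mf)
  asg <- attr(X, "assign")   # 0 = intercept, 1 = f1, 2 = f2, 3 = f1:f2
  sse_full <- ss_from_fit(X, y)
  df_res <- nrow(X) - ncol(X)
  if (df_res <= 0) stop("residual degrees of freedom must be > 0", call. = FALSE)
  mse <- sse_full / df_res
  effects <- c(factors[1], factors[2],
               paste0(factors[1], ":", factors[2]))
  rows <- purrr::map_dfr(1:3, function(term) {
    keep <- asg != term
    ss <- ss_from_fit(X[, keep, drop = FALSE], y) - sse_full
    df <- sum(asg == term)
    Fv <- (ss / df) / mse
    tibble::tibble(effect = effects[term], ss = ss, df = df,
                   statistic = Fv,
                   p.value = stats::pf(Fv, df, df_res, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows,
    tibble::tibble(effect = "Residuals", ss = sse_full, df = df_res,
                   statistic = NA_real_, p.value = NA_real_))
  new_anova_table(out, kind = "two-way between-subjects (Type III)")
}

#' Bonferroni-adjusted pairwise group comparisons per time level
#'
#' Protected post-hoc comparisons following a two-way ANOVA: at each
#' level of the `time` factor the two `group` means are compared with a
#' t-statistic using the pooled ANOVA error term (mean squared error and
#' residual degrees of freedom from the full two-way model), and raw
#' p-values are Bonferroni-adjusted by the family size
#' (`adjusted = min(1, m * p)`).
#'
#' @param obs Long-format data frame.
#' @param value Response column name.
#' @param group Grouping factor (2 levels compared; default `"injury"`).
#' @param time Stratifying factor whose levels form the family
#'   (default `"day"`).
#' @param family_size Family size m for the Bonferroni correction;
#'   defaults to the number of time levels actually compared.
#' @return Tibble: `time` level, the two group means, `difference`,
#'   `statistic`, `df`, `p.value`, `adj.p.value`, `family_size`.
#' @export
bonferroni_pairwise <- function(obs, value = "value", group = "injury",
                                time = "day", family_size = NULL) {
  obs <- tibble::as_tibble(obs)
  aov_tab <- two_way_anova(obs, value = value, factors = c(group, time))
  res_row <- aov_tab[aov_tab$effect == "Residuals", ]
  mse <- res_row$ss / res_row$df
  df_res <- res_row$df
  g <- factor(obs[[group]])
  if (nlevels(g) != 2) stop("pairwise comparison needs exactly 2 groups",
                            call. = FALSE)
  lv <- levels(g)
  tlv <- unique(as.character(obs[[time]]))
  comp <- purrr::map_dfr(tlv, function(tl) {
    sub <- obs[obs[[time]] == tl, ]
    y1 <- sub[[value]][sub[[group]] == lv[1]]
    y2 <- sub[[value]][sub[[group]] == lv[2]]
    if (length(y1) == 0 || length(y2) == 0) {
      warning("time level ", tl, " has only one group; skipped")
      return(NULL)
    }
    se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
    tv <- (mean(y2) - mean(y1)) / se
    tibble::tibble(time = tl,
                   mean_1 = mean(y1), mean_2 = mean(y2),
                   difference = mean(y2) - mean(y1),
                   statistic = tv, df = df_res,
                   p.value = 2 * stats::pt(-abs(tv), df_res))
  })
  m <- if (is.null(family_size)) nrow(comp) else family_size
  comp$adj.p.value <- pmin(1, m * comp$p.value)
  comp$family_size <- m
  names(comp)[names(comp) == "mean_1"] <- paste0("mean_", lv[1])
  names(comp)[names(comp) == "mean_2"] <- paste0("mean_", lv[2])
  comp
}

#' 2x2 mixed-design ANOVA (one between, one within factor)
#'
#' Split-plot decomposition for designs where each subject is measured
#' at both levels of a within-subject factor (e.g. reflex times after a
#' first and a second injury) and belongs to one of two groups. The
#' between-group effect is tested against subjects-within-group; the
#' within effect and the interaction are tested against the
#' subject-by-within residual. With two within levels the strata reduce
#' to per-subject means and differences, which is how the sums of
#' squares are computed (Type III / unweighted means for unbalanced
#' groups). Subjects missing either measurement are dropped with a
#' warning. An effect with zero sum of squares reports F = 0.
#'
#' @param obs Long-format data frame.
#' @param value Response column name.
#' @param group Between-subjects factor column (2 levels).
#' @param within Within-subject factor column (2 levels).
#' @param subject Subject identifier column.
#' @return An `anova_table` tibble with effects `group`, `within`,
#'   `group:within` and the two error strata.
#' @export
mixed_anova_2x2 <- function(obs, value = "value", group = "injury",
                            within = "injury_number",
                            subject = "subject_id") {
  obs <- tibble::as_tibble(obs)
  stopifnot(all(c(value, group, within, subject) %in% names(obs)))
  w <- factor(obs[[within]])
  if (nlevels(w) != 2) stop("within factor must have exactly 2 levels",
                            call. = FALSE)
  wide <- obs |>
    dplyr::select(subj = dplyr::all_of(subject), grp = dplyr::all_of(group),
                  w = dplyr::all_of(within), y = dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "w", values_from = "y")
  wl <- levels(w)
  complete <- stats::complete.cases(wide[, wl])
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) missing a measurement; dropped")
    wide <- wide[complete, ]
  }
  g <- factor(wide$grp)
  if (nlevels(g) != 2) stop("between factor must have exactly 2 levels",
                            call. = FALSE)
  N <- nrow(wide)
  if (N < 4) stop("need >= 2 subjects per group", call. = FALSE)
  m_s <- (wide[[wl[1]]] + wide[[wl[2]]]) / 2
  d_s <- wide[[wl[2]]] - wide[[wl[1]]]
  contrasts(g) <- stats::contr.sum(2)
  Xg <- stats::model.matrix(~ g)

  # between stratum (subject means; x2 restores the observation scale)
  ss_group <- 2 * (ss_from_fit(Xg[, 1, drop = FALSE], m_s) - ss_from_fit(Xg, m_s))
  ss_subj <- 2 * ss_from_fit(Xg, m_s)
  # within stratum (subject differences; /2 for the observation scale)
  ss_within <- (ss_from_fit(Xg[, 2, drop = FALSE], d_s) - ss_from_fit(Xg, d_s)) / 2
  ss_inter <- (ss_from_fit(Xg[, 1, drop = FALSE], d_s) - ss_from_fit(Xg, d_s)) / 2
  ss_res_w <- ss_from_fit(Xg, d_s) / 2
  df_err <- N - 2

  safe_F <- function(ss, ms_err) {
    if (ss <= 1e-300) return(c(0, 1))
    if (ms_err <= 0) return(c(Inf, 0))
    Fv <- ss / ms_err
    c(Fv, stats::pf(Fv, 1, df_err, lower.tail = FALSE))
  }
  fg <- safe_F(ss_group, ss_subj / df_err)
  fw <- safe_F(ss_within, ss_res_w / df_err)
  fi <- safe_F(ss_inter, ss_res_w / df_err)
  out <- tibble::tibble(
    effect = c(group, "subjects(group)", within,
               paste0(group, ":", within), "Residuals(within)"),
    stratum = c("between", "between", "within", "within", "within"),
    ss = c(ss_group, ss_subj, ss_within, ss_inter, ss_res_w),
    df = c(1, df_err, 1, 1, df_err),
    statistic = c(fg[1], NA, fw[1], fi[1], NA),
    p.value = c(fg[2], NA, fw[2], fi[2], NA))
  new_anova_table(out, kind = "2x2 mixed design")
}

#' Mean +/- SEM summary per cell
#'
#' @param obs Long-format data frame.
#' @param value Response column name.
#' @param ... Grouping columns (tidy-select), e.g. `injury, day`.
#' @return Tibble with `n`, `mean`, `sem` per cell; SEM is the sample
#'   SD over sqrt(n), reported as 0 when n = 1.
#' @examples
#' df <- data.frame(g = "a", value = c(1, 2, 3))
#' summarize_mean_sem(df, g)   # mean 2, sem 1/sqrt(3)
#' @export
summarize_mean_sem <- function(obs, ..., value = "value") {
  obs |>
    tibble::as_tibble() |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sem = ifelse(dplyr::n() > 1,
                   stats::sd(.data[[value]]) / sqrt(dplyr::n()), 0),
      .groups = "drop")
}
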