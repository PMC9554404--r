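# Participant-level aggregation and cohort reporting: valid-day selection,
# participant means, the four adherence criteria, day-by-day adherence
# curves, subgroup prevalence with chi-square/Fisher tests, and the
# MVPA-vs-steps regressions.

.metric_cols <- c("wear_hours", "sleep_min", "inactive_min", "lpa_min",
                  "mvpa_min", "vpa_min", "mvpa_bout10_min", "mean_acc_mg",
                  "m2_mg", "m30_mg", "m60_mg", "steps", "mean_cadence_spm",
                  "cad100_min", "pct_zero_cadence", "peak1_cad",
                  "peak30_cad", "peak60_cad")

#' Select valid days
#'
#' A valid day has at least `min_wear_h` hours of wear and a day index of at
#' least `first_day` (recordings start the evening of discharge, so the
#' first complete days are only widely available from day 2 after the
#' intervention).
#'
#' @param days day-summary data frame with `day_index` and `wear_hours`.
#' @param min_wear_h minimum wear (h).
#' @param first_day first eligible day index.
#' @return The filtered day rows.
#' @export
select_valid_days <- function(days, min_wear_h = 12, first_day = 2) {
  days[days$wear_hours >= min_wear_h & days$day_index >= first_day, ,
       drop = FALSE]
}

#' Summarise a participant over valid days
#'
#' Arithmetic mean of every daily metric over the participant's valid days;
#' the participant is included in cohort analyses when at least 7 valid days
#' exist.
#'
#' @param valid_days valid day rows for one participant (possibly 0 rows).
#' @param meta a [participant_meta()].
#' @return One-row data frame: metadata, `n_valid_days`, metric means,
#'   `included`.
#' @export
summarize_participant <- function(valid_days, meta) {
  nv <- nrow(valid_days)
  means <- if (nv > 0)
    as.list(colMeans(valid_days[, .metric_cols, drop = FALSE]))
  else stats::setNames(as.list(rep(NA_real_, length(.metric_cols))),
                       .metric_cols)
  cbind(data.frame(participant_id = meta$participant_id,
                   age_years = meta$age_years, sex = meta$sex,
                   presentation = meta$presentation,
                   n_valid_days = nv, included = nv >= 7,
                   stringsAsFactors = FALSE),
        as.data.frame(means))
}

#' Classify the four adherence criteria
#'
#' Boundaries are inclusive: who2020 when mean MVPA >= 30 min/day; who2010
#' when mean bouted (>=10 min) MVPA >= 30 min/day; steps7500 / steps10000
#' when mean daily steps reach those totals.
#'
#' @param ps one-row participant summary from [summarize_participant()].
#' @param thresholds the `adherence` group of a [wpa_config()].
#' @return `ps` with logical columns who2020, who2010, steps7500,
#'   steps10000 appended.
#' @export
classify_adherence <- function(ps, thresholds = wpa_config()$adherence) {
  if (!ps$included) stop("adherence is defined only for included participants")
  ps$who2020 <- ps$mvpa_min >= thresholds$mvpa_min_per_day
  ps$who2010 <- ps$mvpa_bout10_min >= thresholds$mvpa_min_per_day
  ps$steps7500 <- ps$steps >= thresholds$steps_lo
  ps$steps10000 <- ps$steps >= thresholds$steps_hi
  ps
}

#' Day-by-day adherence curve
#'
#' For each day index (from `first_day`), among participants with a valid
#' day at that index, the fraction whose that-day metrics meet each
#' criterion. Days without any valid participant-day yield NA.
#'
#' @param days cohort day-summary rows (all participants).
#' @param config a [wpa_config()].
#' @return Data frame: `day_index`, `n`, `frac_who2020`, `frac_who2010`,
#'   `frac_steps7500`, `frac_steps10000`.
#' @export
daily_adherence_curve <- function(days, config = wpa_config()) {
  v <- select_valid_days(days, config$validity$min_wear_h,
                         config$validity$first_day)
  th <- config$adherence
  idx <- sort(unique(v$day_index))
  out <- lapply(idx, function(d) {
    dd <- v[v$day_index == d, ]
    data.frame(day_index = d, n = nrow(dd),
               frac_who2020 = mean(dd$mvpa_min >= th$mvpa_min_per_day),
               frac_who2010 = mean(dd$mvpa_bout10_min >= th$mvpa_min_per_day),
               frac_steps7500 = mean(dd$steps >= th$steps_lo),
               frac_steps10000 = mean(dd$steps >= th$steps_hi))
  })
  do.call(rbind, out)
}

#' Subgroup adherence prevalence with a between-group test
#'
#' Splits included participants by sex, clinical presentation, or the cohort
#' median age (below versus at/above), and reports per-group counts and
#' percentages adherent for each criterion with a two-sided Pearson
#' chi-square p-value (Fisher's exact test when any expected cell count is
#' below 5).
#'
#' @param participants included participant rows with adherence flags.
#' @param grouping "age", "sex", or "presentation".
#' @return Data frame with one row per criterion: group sizes, adherent
#'   counts, percentages and p-value.
#' @export
subgroup_prevalence <- function(participants,
                                grouping = c("age", "sex", "presentation")) {
  grouping <- match.arg(grouping)
  p <- participants[participants$included, , drop = FALSE]
  g <- switch(grouping,
              age = {
                med <- stats::median(p$age_years)
                factor(ifelse(p$age_years < med, sprintf("<%g", med),
                              sprintf(">=%g", med)))
              },
              sex = factor(p$sex),
              presentation = factor(p$presentation))
  if (nlevels(droplevels(g)) < 2) stop("empty group under this split")
  crits <- c("who2020", "who2010", "steps7500", "steps10000")
  lv <- levels(droplevels(g))
  out <- lapply(crits, function(cr) {
    tab <- table(g, factor(p[[cr]], levels = c(FALSE, TRUE)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    pval <- if (any(expected < 5))
      stats::fisher.test(tab)$p.value
    else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    data.frame(criterion = cr, grouping = grouping,
               group1 = lv[1], n1 = sum(g == lv[1]),
               adherent1 = sum(p[[cr]][g == lv[1]]),
               pct1 = 100 * mean(p[[cr]][g == lv[1]]),
               group2 = lv[2], n2 = sum(g == lv[2]),
               adherent2 = sum(p[[cr]][g == lv[2]]),
               pct2 = 100 * mean(p[[cr]][g == lv[2]]),
               p_value = pval, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Regress participant-mean MVPA on daily steps and peak-30 cadence
#'
#' Ordinary least squares of each MVPA definition (any-bout and >=10-min
#' bout) on mean daily steps and on peak-30-min cadence; reports slope,
#' intercept, Pearson r, R-squared and the predictor value at which the
#' fitted line crosses 30 min/day of MVPA (NA when the slope is not
#' positive).
#'
#' @param participants included participant rows.
#' @return Data frame with one row per response/predictor pair.
#' @export
regress_metrics <- function(participants) {
  p <- participants[participants$included, , drop = FALSE]
  if (nrow(p) < 3) stop("need at least 3 included participants")
  pairs <- expand.grid(response = c("mvpa_min", "mvpa_bout10_min"),
                       predictor = c("steps", "peak30_cad"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    y <- p[[pairs$response[k]]]; x <- p[[pairs$predictor[k]]]
    if (stats::var(x) == 0) stop("zero variance in predictor ", pairs$predictor[k])
    fit <- suppressWarnings(stats::lm(y ~ x))
    sm <- suppressWarnings(summary(fit))
    sl <- unname(stats::coef(fit)[2]); ic <- unname(stats::coef(fit)[1])
    r <- stats::cor(x, y)
    data.frame(response = pairs$response[k], predictor = pairs$predictor[k],
               slope = sl, intercept = ic, r = r, r_squared = r^2,
               se_slope = sm$coefficients[2, 2],
               se_intercept = sm$coefficients[1, 2],
               x_at_30min = if (sl > 0) (30 - ic) / sl else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# quartile convention: linear interpolation (stats::quantile type 7)
.med_iqr <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE,
                                        na.rm = TRUE)

#' Cohort report tables
#'
#' Produces the cohort outputs: per-metric medians with first and third
#' quartiles for all included participants and within each adherence
#' subgroup (table1); subgroup prevalence with tests (table2); the daily
#' adherence curve (fig2_curve); the regressions (fig3_regressions); and the
#' adherence set counts, including the 2010/2020 overlap (fig4_sets).
#' Quartiles use the linear-interpolation convention.
#'
#' @param participants participant summaries with adherence flags.
#' @param days cohort day summaries.
#' @param config a [wpa_config()].
#' @return Named list of data frames: `table1`, `table2`, `fig2_curve`,
#'   `fig3_regressions`, `fig4_sets`, `prevalence`.
#' @export
cohort_report <- function(participants, days, config = wpa_config()) {
  p <- participants[participants$included, , drop = FALSE]
  crits <- c("who2020", "who2010", "steps7500", "steps10000")
  groups <- c(list(all = rep(TRUE, nrow(p))),
              stats::setNames(lapply(crits, function(cr) p[[cr]]), crits))
  t1 <- do.call(rbind, lapply(.metric_cols, function(mc) {
    row <- data.frame(metric = mc, stringsAsFactors = FALSE)
    for (gn in names(groups)) {
      q <- .med_iqr(p[[mc]][groups[[gn]]])
      row[[paste0(gn, "_median")]] <- q[1]
      row[[paste0(gn, "_q1")]] <- q[2]
      row[[paste0(gn, "_q3")]] <- q[3]
    }
    row
  }))
  t2 <- do.call(rbind, lapply(c("age", "sex", "presentation"),
                              function(gr) subgroup_prevalence(p, gr)))
  sets <- data.frame(
    n_included = nrow(p),
    n_who2020 = sum(p$who2020), n_who2010 = sum(p$who2010),
    n_steps7500 = sum(p$steps7500), n_steps10000 = sum(p$steps10000),
    n_2010_and_2020 = sum(p$who2010 & p$who2020),
    n_2010_not_2020 = sum(p$who2010 & !p$who2020),
    n_2020_not_2010 = sum(p$who2020 & !p$who2010),
    n_none = sum(!p$who2020 & !p$who2010 & !p$steps7500 & !p$steps10000))
  prev <- data.frame(criterion = crits,
                     n = vapply(crits, function(cr) sum(p[[cr]]), integer(1)),
                     pct = vapply(crits, function(cr) 100 * mean(p[[cr]]),
                                  numeric(1)), row.names = NULL)
  list(table1 = t1, table2 = t2,
       fig2_curve = daily_adherence_curve(days, config),
       fig3_regressions = regress_metrics(p), fig4_sets = sets,
       prevalence = prev)
}

#' Write the cohort report to a directory of CSV files
#'
#' @param report list from [cohort_report()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(table1 = "table1.csv", table2 = "table2.csv",
             fig2_curve = "fig2_curve.csv",
             fig3_regressions = "fig3_regressions.csv",
             fig4_sets = "fig4_sets.csv", prevalence = "prevalence.csv")
  for (nm in names(files))
    utils::write.csv(report[[nm]], file.path(dir, files[[nm]]),
                     row.names = FALSE)
  invisible(dir)
}
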