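# Daily activity metrics on the 5-s epoch grid: intensity classification,
# class-minute accrual, >=10-min/80% MVPA bout detection, MX metrics and the
# imputed 24-h mean acceleration.

#' Classify epoch intensity
#'
#' Intensity bands on epoch ENMO: inactivity below 25 mg, light physical
#' activity in \[25, 100) mg, MVPA at or above 100 mg, with a vigorous
#' sub-band at or above the configured threshold (default 400 mg).
#'
#' @param enmo_mg numeric vector of epoch ENMO values (mg).
#' @param bands the `bands` group of a [wpa_config()].
#' @return Factor with levels inactive, light, mvpa; the vigorous sub-flag is
#'   attached as attribute `vigorous` (logical vector).
#' @export
classify_epoch_intensity <- function(enmo_mg, bands = wpa_config()$bands) {
  if (any(enmo_mg < 0)) stop("enmo_mg must be non-negative")
  cls <- cut(enmo_mg, c(-Inf, bands$inactive_max_mg, bands$mvpa_min_mg, Inf),
             labels = c("inactive", "light", "mvpa"), right = FALSE)
  attr(cls, "vigorous") <- enmo_mg >= bands$vigorous_min_mg
  cls
}

#' Accrue daily class minutes
#'
#' Default accrual mode `"epoch"`: class minutes are the count of wear epochs
#' in the class divided by 12. Alternative `"minute80"`: a minute counts as
#' MVPA when at least 80\% of its 12 epochs are at or above the MVPA
#' threshold, otherwise the minute is light when light-or-above epochs
#' outnumber inactive ones, else inactive. Non-wear epochs count toward no
#' class in either mode.
#'
#' @param enmo_mg epoch ENMO for one full day (17,280 epochs).
#' @param wear logical wear flags.
#' @param config a [wpa_config()].
#' @return List: `inactive_min`, `lpa_min`, `mvpa_min`, `vpa_min`.
#' @export
accrue_class_minutes <- function(enmo_mg, wear, config = wpa_config()) {
  if (length(enmo_mg) %% 12 != 0)
    stop("day epoch grid incomplete: need whole minutes of epochs")
  bands <- config$bands
  cls <- classify_epoch_intensity(enmo_mg, bands)
  vig <- attr(cls, "vigorous")
  if (config$accrual$mode == "epoch") {
    list(inactive_min = sum(wear & cls == "inactive") / 12,
         lpa_min = sum(wear & cls == "light") / 12,
         mvpa_min = sum(wear & cls == "mvpa") / 12,
         vpa_min = sum(wear & vig) / 12)
  } else if (config$accrual$mode == "minute80") {
    nmin <- length(enmo_mg) %/% 12
    grp <- rep(seq_len(nmin), each = 12)
    wear_n <- rowsum(as.numeric(wear), grp)[, 1]
    mvpa_n <- rowsum(as.numeric(wear & cls == "mvpa"), grp)[, 1]
    li_n <- rowsum(as.numeric(wear & cls == "light"), grp)[, 1]
    in_n <- rowsum(as.numeric(wear & cls == "inactive"), grp)[, 1]
    vig_n <- rowsum(as.numeric(wear & vig), grp)[, 1]
    is_mvpa <- wear_n > 0 & mvpa_n >= 0.8 * 12
    # below the 80% criterion, MVPA epochs still count as (at least) light
    modal <- ifelse(in_n >= li_n + mvpa_n, "inactive", "light")
    modal[wear_n == 0] <- "none"
    modal[is_mvpa] <- "mvpa"
    list(inactive_min = sum(modal == "inactive"),
         lpa_min = sum(modal == "light"),
         mvpa_min = sum(modal == "mvpa"),
         vpa_min = sum(modal == "mvpa" & vig_n >= 0.8 * 12))
  } else stop("unknown accrual mode: ", config$accrual$mode)
}

#' Detect MVPA bouts of at least 10 min under the 80 percent criterion
#'
#' Greedy left-to-right scan over one day's epochs. A candidate bout starts
#' at an above-threshold epoch and is extended rightward as long as (a) the
#' running above-threshold fraction stays at or above 0.8 and (b) no run of
#' more than 1 min of consecutive below-threshold epochs occurs. The
#' candidate is trimmed so that both ends are above threshold; it qualifies
#' if the trimmed interval spans at least 120 epochs. Non-wear epochs count
#' as below threshold.
#'
#' @param enmo_mg epoch ENMO for one day.
#' @param wear logical wear flags.
#' @param config a [wpa_config()].
#' @return List: `intervals` (two-column matrix of 1-based start/end epoch
#'   indices, inclusive) and `mvpa_bout10_min` (total bouted epochs / 12).
#' @export
detect_mvpa_bouts <- function(enmo_mg, wear = rep(TRUE, length(enmo_mg)),
                              config = wpa_config()) {
  bt <- config$bout
  above <- enmo_mg >= config$bands$mvpa_min_mg & wear
  min_len <- round(bt$min_duration_min * 60 / config$epoch$length_s)
  max_gap <- round(bt$max_gap_min * 60 / config$epoch$length_s)
  frac <- bt$criterion_fraction
  n <- length(above)
  intervals <- NULL
  i <- 1L
  while (i <= n) {
    if (!above[i]) { i <- i + 1L; next }
    n_above <- 0L; gap <- 0L; last_good <- i - 1L
    j <- i
    while (j <= n) {
      if (above[j]) {
        n_above <- n_above + 1L; gap <- 0L
        if (n_above >= frac * (j - i + 1L)) last_good <- j
        else break
      } else {
        gap <- gap + 1L
        if (gap > max_gap) break
        if (n_above < frac * (j - i + 1L)) break
      }
      j <- j + 1L
    }
    if (last_good - i + 1L >= min_len) {
      intervals <- rbind(intervals, c(i, last_good))
      i <- last_good + 1L
    } else i <- i + 1L
    # skip ahead to the next above-threshold epoch
    while (i <= n && !above[i]) i <- i + 1L
  }
  total <- if (is.null(intervals)) 0L else sum(intervals[, 2] - intervals[, 1] + 1L)
  list(intervals = intervals, mvpa_bout10_min = total / 12)
}

#' MX metrics: minimal acceleration of the most active X minutes
#'
#' The (X x 12)-th largest epoch ENMO of the day; non-wear epochs are
#' treated as 0 mg.
#'
#' @param enmo_mg epoch ENMO for one day.
#' @param wear logical wear flags.
#' @param minutes vector of X values (default 2, 30, 60).
#' @return Named numeric vector (`m2_mg`, `m30_mg`, `m60_mg` for the
#'   defaults).
#' @export
mx_metrics <- function(enmo_mg, wear = rep(TRUE, length(enmo_mg)),
                       minutes = c(2, 30, 60)) {
  x <- ifelse(wear, enmo_mg, 0)
  srt <- sort(x, decreasing = TRUE)
  out <- vapply(minutes, function(m) {
    k <- m * 12
    if (k > length(srt)) 0 else srt[k]
  }, numeric(1))
  names(out) <- sprintf("m%d_mg", minutes)
  out
}

#' Imputed 24-h mean acceleration
#'
#' Mean epoch ENMO over the full 17,280-epoch day, with non-wear epochs
#' imputed by the participant's mean ENMO at the same clock epoch across the
#' other valid days (wear epochs only); epochs with no donor are imputed as
#' 0.
#'
#' @param enmo_mg epoch ENMO for the day.
#' @param wear logical wear flags for the day.
#' @param donor_enmo,donor_wear matrices (epochs x other valid days) of the
#'   donor days' ENMO and wear flags, clock-aligned; NULL when no other
#'   valid day exists.
#' @return Mean acceleration in mg.
#' @export
mean_acceleration_24h <- function(enmo_mg, wear, donor_enmo = NULL,
                                  donor_wear = NULL) {
  x <- enmo_mg
  if (any(!wear)) {
    fill <- rep(0, sum(!wear))
    if (!is.null(donor_enmo)) {
      de <- donor_enmo[!wear, , drop = FALSE]
      dw <- donor_wear[!wear, , drop = FALSE]
      s <- rowSums(de * dw); k <- rowSums(dw)
      fill <- ifelse(k > 0, s / k, 0)
    }
    x[!wear] <- fill
  }
  mean(x)
}

#' Summarise one day's activity metrics
#'
#' Assembles the activity part of a day summary from one full
#' midnight-to-midnight day of epochs; step and cadence fields are filled by
#' [cadence_summary()] via [summarize_day()].
#'
#' @param day_es [epoch_series()] rows for one full day (17,280 epochs).
#' @param config a [wpa_config()].
#' @param donor_enmo,donor_wear see [mean_acceleration_24h()].
#' @return One-row data frame with wear_hours, sleep_min, class minutes,
#'   bouted MVPA minutes, MX metrics and mean_acc_mg.
#' @export
summarize_day_activity <- function(day_es, config = wpa_config(),
                                   donor_enmo = NULL, donor_wear = NULL) {
  acc <- accrue_class_minutes(day_es$enmo_mg, day_es$wear, config)
  bouts <- detect_mvpa_bouts(day_es$enmo_mg, day_es$wear, config)
  mx <- mx_metrics(day_es$enmo_mg, day_es$wear)
  data.frame(
    wear_hours = sum(day_es$wear) * attr(day_es, "epoch_length_s") / 3600,
    sleep_min = sum(day_es$sleep) * attr(day_es, "epoch_length_s") / 60,
    inactive_min = acc$inactive_min, lpa_min = acc$lpa_min,
    mvpa_min = acc$mvpa_min, vpa_min = acc$vpa_min,
    mvpa_bout10_min = bouts$mvpa_bout10_min,
    mean_acc_mg = mean_acceleration_24h(day_es$enmo_mg, day_es$wear,
                                        donor_enmo, donor_wear),
    m2_mg = mx[["m2_mg"]], m30_mg = mx[["m30_mg"]], m60_mg = mx[["m60_mg"]])
}
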