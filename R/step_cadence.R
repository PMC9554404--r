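# Step counting by windowed peak detection on the resampled acceleration
# magnitude, and all cadence metrics derived from per-epoch step counts.

#' Step detector parameters
#'
#' Defaults follow the open-source windowed-peak-detection lineage for wrist
#' devices: the magnitude signal is resampled to 15 Hz; candidate peaks are
#' local maxima of a centred 3-sample window with magnitude >= 1.2 g;
#' consecutive peaks must be 5-15 samples apart (i.e. a cadence of 60-180
#' steps/min at 15 Hz) with amplitudes within 0.5 g of each other; and only
#' runs of at least 4 such peaks in a region of sufficient signal variance
#' count as steps. The originally validated parameter set is study-internal,
#' so all eight values are exposed here and results are parameter-dependent.
#'
#' @param resample_hz resampling rate for the magnitude signal.
#' @param peak_window_samples centred window defining a local maximum.
#' @param magnitude_min_g minimum peak magnitude.
#' @param period_min_samples,period_max_samples allowed inter-peak spacing.
#' @param similarity_max_g maximum amplitude difference between consecutive
#'   peaks.
#' @param continuity_window,continuity_min_peaks a run must contain at least
#'   `continuity_min_peaks` valid peaks spanning `continuity_window`
#'   inter-peak intervals.
#' @param variance_min_g2 minimum local signal variance around a peak.
#' @return Named list of parameters.
#' @export
step_detector_params <- function(resample_hz = 15, peak_window_samples = 3,
                                 magnitude_min_g = 1.2,
                                 period_min_samples = 5,
                                 period_max_samples = 15,
                                 similarity_max_g = 0.5,
                                 continuity_window = 3,
                                 continuity_min_peaks = 4,
                                 variance_min_g2 = 0.001) {
  if (period_min_samples >= period_max_samples)
    stop("period_min_samples must be below period_max_samples")
  list(resample_hz = resample_hz, peak_window_samples = peak_window_samples,
       magnitude_min_g = magnitude_min_g,
       period_min_samples = period_min_samples,
       period_max_samples = period_max_samples,
       similarity_max_g = similarity_max_g,
       continuity_window = continuity_window,
       continuity_min_peaks = continuity_min_peaks,
       variance_min_g2 = variance_min_g2)
}

# linear resampling of a uniform signal onto a lower-rate grid
resample_linear <- function(x, from_hz, to_hz) {
  n <- length(x)
  t_out <- seq(0, (n - 1) / from_hz, by = 1 / to_hz)
  pos <- t_out * from_hz
  i0 <- pmin(floor(pos), n - 2)
  fr <- pos - i0
  x[i0 + 1] * (1 - fr) + x[i0 + 2] * fr
}

#' Detect step events by windowed peak detection
#'
#' Pipeline: (1) resample the magnitude `sqrt(x^2+y^2+z^2)` to
#' `resample_hz`; (2) candidate peaks are samples that are the maximum of
#' their centred `peak_window_samples` window; (3) drop candidates below
#' `magnitude_min_g`; (4-5) chain candidates whose spacing lies in
#' \[`period_min_samples`, `period_max_samples`\] and whose amplitude is
#' within `similarity_max_g` of the previous kept peak; (6) keep only chains
#' of at least `continuity_min_peaks` peaks whose local signal variance
#' reaches `variance_min_g2`. Each surviving peak is one step.
#'
#' @param rec a calibrated [raw_recording()].
#' @param params a [step_detector_params()].
#' @return POSIXct vector of step-event times.
#' @export
detect_steps <- function(rec, params = step_detector_params()) {
  rate <- rec$sample_rate_hz
  if (nrow(rec$data) < rate) stop("recording shorter than one detector window")
  mag <- sqrt(rec$data[, 1]^2 + rec$data[, 2]^2 + rec$data[, 3]^2)
  m <- resample_linear(mag, rate, params$resample_hz)
  n <- length(m)
  half <- params$peak_window_samples %/% 2
  if (n < 2 * half + 1) return(as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"))
  core <- (half + 1):(n - half)
  is_peak <- rep(TRUE, length(core))
  for (d in seq_len(half)) {
    is_peak <- is_peak & m[core] >= m[core - d] & m[core] > m[core + d]
  }
  cand <- core[is_peak & m[core] >= params$magnitude_min_g]
  if (!length(cand)) return(as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"))

  # local variance around each candidate (+/-1 s window)
  vw <- params$resample_hz
  cs <- cumsum(c(0, m)); cs2 <- cumsum(c(0, m^2))
  lo <- pmax(cand - vw, 1L); hi <- pmin(cand + vw, n)
  cnt <- hi - lo + 1
  lv <- (cs2[hi + 1] - cs2[lo]) / cnt - ((cs[hi + 1] - cs[lo]) / cnt)^2
  var_ok <- lv >= params$variance_min_g2

  # sequential chaining relative to the previous kept peak
  keep <- logical(length(cand))
  chain <- integer(0)              # indices into cand of current chain
  prev <- NA_integer_
  flush <- function() {
    if (length(chain) >= params$continuity_min_peaks)
      keep[chain] <<- TRUE
    chain <<- integer(0)
  }
  for (k in seq_along(cand)) {
    if (!var_ok[k]) next
    if (is.na(prev)) { chain <- k; prev <- k; next }
    gap <- cand[k] - cand[prev]
    if (gap > params$period_max_samples) {        # chain broken: start anew
      flush(); chain <- k; prev <- k
    } else if (gap < params$period_min_samples) {
      # too close to the previous kept peak: reject candidate
    } else if (abs(m[cand[k]] - m[cand[prev]]) > params$similarity_max_g) {
      # amplitude dissimilar: reject candidate
    } else {
      chain <- c(chain, k); prev <- k
    }
  }
  flush()
  t_steps <- (cand[keep] - 1) / params$resample_hz
  rec$start_time + t_steps
}

#' Assign step events to epochs
#'
#' Each step increments exactly one epoch's count (half-open epoch
#' intervals: an event at an epoch boundary belongs to the later epoch).
#'
#' @param step_times POSIXct step-event times from [detect_steps()].
#' @param es an [epoch_series()].
#' @return `es` with the `steps` column filled.
#' @export
steps_to_epochs <- function(step_times, es) {
  es$steps <- 0L
  if (!length(step_times)) return(es)
  epl <- attr(es, "epoch_length_s")
  ep0 <- as.numeric(es$epoch_start[1])
  idx <- floor((as.numeric(step_times) - ep0) / epl + 1e-9) + 1
  idx <- idx[idx >= 1 & idx <= nrow(es)]
  tab <- tabulate(idx, nbins = nrow(es))
  es$steps <- as.integer(tab)
  es
}

#' Per-minute cadence
#'
#' @param steps per-epoch step counts for one full day (17,280 epochs).
#' @return Numeric vector of 1,440 per-minute cadences (steps/min).
#' @export
minute_cadence <- function(steps) {
  if (length(steps) %% 12 != 0)
    stop("day epoch grid incomplete: need whole minutes of epochs")
  nmin <- length(steps) %/% 12
  .colSums(steps, 12, nmin)
}

#' Daily cadence summary
#'
#' Mean cadence divides daily steps by the fixed 1,440 minutes of the 24-h
#' cycle (not wear minutes), as does the percentage of zero-cadence minutes.
#' Peak-X cadence is the mean of the X highest minute cadences, not
#' necessarily consecutive.
#'
#' @param cad per-minute cadence vector (1,440 values).
#' @return One-row data frame: `steps`, `mean_cadence_spm`, `cad100_min`,
#'   `pct_zero_cadence`, `peak1_cad`, `peak30_cad`, `peak60_cad`.
#' @export
cadence_summary <- function(cad) {
  nmin <- length(cad)
  srt <- sort(cad, decreasing = TRUE)
  peak <- function(k) mean(srt[seq_len(min(k, nmin))])
  data.frame(steps = sum(cad),
             mean_cadence_spm = sum(cad) / nmin,
             cad100_min = sum(cad >= 100),
             pct_zero_cadence = 100 * sum(cad == 0) / nmin,
             peak1_cad = peak(1), peak30_cad = peak(30), peak60_cad = peak(60))
}
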