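# Synthetic wear generator: raw tri-axial signal with exact ground truth.
#
# Measurement model, per activity kind:
#   walk      gravity direction g0 scaled by (1 + w(t)) where w is a periodic
#             gait pulse  w = A * (0.5 + 0.5*cos(theta))^2  (equivalently a
#             DC term + fundamental + one harmonic), theta advancing at
#             cadence/60 Hz. The pulse peaks once per gait cycle (one true
#             step), has peak amplitude A (g) and time-mean 0.375*A, so the
#             expected epoch ENMO is 375*A mg: amplitude >= 0.3 g yields
#             >= 112 mg, inside the MVPA band. Axis noise SD = jitter * A.
#   sedentary gravity at a mildly tilted orientation with a slow per-epoch
#             orientation wobble, posture shifts every ~5 min, and axis noise
#             SD 25 mg (expected ENMO ~ 10 mg: inactivity band).
#   light     same structure with axis noise SD 90 mg (expected ENMO
#             ~ 40 mg: light band) and a larger wobble.
#   sleep     near-still (axis noise SD 5 mg) with posture changes every
#             15-25 min; the changes keep 60-min windows from looking like
#             non-wear while leaving 5-min z-angle variability minimal.
#   nonwear   exactly constant gravity vector plus quantisation-scale noise
#             (SD 0.3 mg).
#
# The frozen noise/wobble constants below were tuned once against the
# epoching stage (intensity bands, non-wear votes, sleep threshold) and are
# not runtime parameters.
.synth <- list(
  enmo_mean_factor = 0.375,   # time-mean of the unit gait pulse
  walk_wobble_deg = 5,        # arm-swing orientation drift per epoch
  sed_noise_g = 0.025, sed_wobble_deg = 2.0, sed_shift_min = 5,
  light_noise_g = 0.090, light_wobble_deg = 3.0,
  sleep_noise_g = 0.005, sleep_shift_min = c(15, 25),
  nonwear_noise_g = 3e-4
)

unit_vec <- function(polar_deg, azim_deg) {
  p <- polar_deg * pi / 180; a <- azim_deg * pi / 180
  c(sin(p) * cos(a), sin(p) * sin(a), cos(p))
}

#' Declare an activity block
#'
#' Building block of a synthetic schedule. Durations should be multiples of
#' the 5-s epoch length so that generated days tile the epoch grid exactly.
#'
#' @param kind one of "sleep", "sedentary", "light", "walk", "nonwear".
#' @param start POSIXct start time (UTC, interpreted as naive local time).
#' @param duration_s block duration in seconds.
#' @param cadence_spm walking cadence in steps/min (walk only; 40-160).
#' @param peak_amp_g per-step peak acceleration amplitude in g (walk only).
#' @param jitter relative noise scale in \[0, 0.5\]; for walks the axis noise
#'   SD is `jitter * peak_amp_g`.
#' @return One-row data frame; rbind rows to build a schedule.
#' @export
activity_block <- function(kind, start, duration_s, cadence_spm = NA_real_,
                           peak_amp_g = NA_real_, jitter = 0.05) {
  kind <- match.arg(kind, c("sleep", "sedentary", "light", "walk", "nonwear"))
  if (duration_s <= 0) stop("duration_s must be positive")
  if (jitter < 0 || jitter > 0.5) stop("jitter must lie in [0, 0.5]")
  if (kind == "walk") {
    if (is.na(cadence_spm) || cadence_spm < 40 || cadence_spm > 160)
      stop("walk blocks need cadence_spm in [40, 160]")
    if (is.na(peak_amp_g) || peak_amp_g <= 0)
      stop("walk blocks need a positive peak_amp_g")
  }
  data.frame(kind = kind, start = as.POSIXct(start, tz = "UTC"),
             duration_s = duration_s, cadence_spm = cadence_spm,
             peak_amp_g = peak_amp_g, jitter = jitter,
             stringsAsFactors = FALSE)
}

# per-epoch orientation path: mean-reverting wobble around a base posture
# (AR(1), so variability does not drift over long blocks) plus occasional
# posture shifts that move the base itself
orientation_path <- function(n_epochs, wobble_deg, shift_every_min = Inf,
                             shift_sd_deg = 10, epoch_s = 5) {
  base_p <- rep(stats::runif(1, 30, 60), n_epochs)
  base_a <- rep(stats::runif(1, 0, 360), n_epochs)
  if (is.finite(shift_every_min)) {
    per <- max(1L, round(shift_every_min * 60 / epoch_s))
    at <- if (per <= n_epochs) seq(per, n_epochs, by = per) else integer(0)
    if (length(at)) {
      dp <- da <- numeric(n_epochs)
      dp[at] <- stats::rnorm(length(at), 0, shift_sd_deg)
      da[at] <- stats::rnorm(length(at), 0, shift_sd_deg)
      base_p <- base_p + cumsum(dp)
      base_a <- base_a + cumsum(da)
    }
  }
  if (wobble_deg > 0) {
    wp <- as.numeric(stats::filter(stats::rnorm(n_epochs, 0, wobble_deg),
                                   0.9, method = "recursive"))
    wa <- as.numeric(stats::filter(stats::rnorm(n_epochs, 0, wobble_deg),
                                   0.9, method = "recursive"))
  } else wp <- wa <- numeric(n_epochs)
  polar <- pmin(pmax(base_p + wp, 5), 175)
  azim <- base_a + wa
  cbind(sin(polar * pi / 180) * cos(azim * pi / 180),
        sin(polar * pi / 180) * sin(azim * pi / 180),
        cos(polar * pi / 180))
}

#' Simulate one activity block
#'
#' Generates the raw tri-axial samples for a single [activity_block()] using
#' the current RNG stream, together with the block's exact ground truth.
#'
#' @param block one-row block data frame from [activity_block()].
#' @param rate_hz sampling rate.
#' @return List with `data` (n x 3 matrix, g), `truth` (list: `steps`,
#'   `mvpa_s`, `wear_s`, `sleep_s`, `expected_enmo_mg`), and `peak_times_s`
#'   (step-peak times in seconds relative to block start).
#' @export
simulate_block <- function(block, rate_hz = 50) {
  kind <- block$kind
  dur <- block$duration_s
  n <- round(dur * rate_hz)
  epoch_s <- 5
  n_ep <- ceiling(n / (rate_hz * epoch_s))
  truth <- list(steps = 0L, mvpa_s = 0, wear_s = 0, sleep_s = 0,
                expected_enmo_mg = 0)
  peak_times <- numeric(0)
  if (kind == "walk") {
    A <- block$peak_amp_g
    f <- block$cadence_spm / 60
    t <- (seq_len(n) - 1) / rate_hz
    theta <- 2 * pi * f * t - pi
    w <- A * (0.5 + 0.5 * cos(theta))^2
    # arm-swing: the gravity direction drifts across epochs; the magnitude
    # (and hence ENMO and step peaks) is unaffected
    ori <- orientation_path(n_ep, .synth$walk_wobble_deg)
    m <- ori[rep(seq_len(n_ep), each = rate_hz * epoch_s)[seq_len(n)], ,
             drop = FALSE] * (1 + w)
    sd_n <- block$jitter * A
    if (sd_n > 0) m <- m + stats::rnorm(3 * n, 0, sd_n)
    k <- 0:max(0, ceiling(dur * f))
    peak_times <- (k + 0.5) / f
    peak_times <- peak_times[peak_times < dur - 1e-9]
    truth$steps <- length(peak_times)
    truth$expected_enmo_mg <- 1000 * .synth$enmo_mean_factor * A
    truth$mvpa_s <- if (truth$expected_enmo_mg >= 100) dur else 0
    truth$wear_s <- dur
  } else if (kind %in% c("sedentary", "light")) {
    wob <- if (kind == "sedentary") .synth$sed_wobble_deg else .synth$light_wobble_deg
    sd_n <- if (kind == "sedentary") .synth$sed_noise_g else .synth$light_noise_g
    ori <- orientation_path(n_ep, wob,
                            shift_every_min = if (kind == "sedentary")
                              .synth$sed_shift_min else Inf)
    m <- ori[rep(seq_len(n_ep), each = rate_hz * epoch_s)[seq_len(n)], , drop = FALSE]
    m <- m + stats::rnorm(3 * n, 0, sd_n)
    truth$wear_s <- dur
    truth$expected_enmo_mg <- 1000 * sd_n / sqrt(2 * pi)
  } else if (kind == "sleep") {
    shift_min <- stats::runif(1, .synth$sleep_shift_min[1], .synth$sleep_shift_min[2])
    ori <- orientation_path(n_ep, 0, shift_every_min = shift_min,
                            shift_sd_deg = 30)
    m <- ori[rep(seq_len(n_ep), each = rate_hz * epoch_s)[seq_len(n)], , drop = FALSE]
    m <- m + stats::rnorm(3 * n, 0, .synth$sleep_noise_g)
    truth$wear_s <- dur
    truth$sleep_s <- dur
  } else if (kind == "nonwear") {
    g0 <- unit_vec(stats::runif(1, 10, 80), stats::runif(1, 0, 360))
    m <- matrix(g0, n, 3, byrow = TRUE) +
      stats::rnorm(3 * n, 0, .synth$nonwear_noise_g)
  } else stop("unsupported block kind: ", kind)
  list(data = m, truth = truth, peak_times_s = peak_times)
}

overlap_s <- function(a1, a2, b1, b2) max(0, min(a2, b2) - max(a1, b1))

#' Generate a raw recording from a schedule, with ground truth
#'
#' The schedule must tile the recording span with no gaps or overlaps.
#' Output is deterministic given `seed`. Device miscalibration, when given,
#' is applied after ground truth is recorded, so truth always reflects the
#' true physical signal.
#'
#' @param schedule data frame of [activity_block()] rows, ordered or not.
#' @param meta optional [participant_meta()] (supplies participant id and
#'   the day-0 date for day indexing).
#' @param rate_hz sampling rate (50).
#' @param miscalibration optional list with `offset_g` and `gain` 3-vectors,
#'   passed to [apply_device_distortion()].
#' @param seed integer seed; the function uses a private RNG stream and
#'   restores the caller's RNG state on exit.
#' @return List with `recording` (a [raw_recording()]), `truth` (per-day data
#'   frame: `date`, `day_index`, `true_steps`, `true_mvpa_s`,
#'   `true_bouted_mvpa_s`, `true_wear_s`, `true_sleep_s`), and `schedule`.
#' @export
generate_recording <- function(schedule, meta = NULL, rate_hz = 50,
                               miscalibration = NULL, seed = 1) {
  schedule <- schedule[order(schedule$start), , drop = FALSE]
  st <- as.numeric(schedule$start)
  ends <- st + schedule$duration_s
  if (nrow(schedule) > 1 && any(abs(st[-1] - ends[-nrow(schedule)]) > 1e-6))
    stop("schedule must tile the span: blocks overlap or leave gaps")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  n_total <- round((ends[nrow(schedule)] - st[1]) * rate_hz)
  m <- matrix(0, n_total, 3)
  blocks <- vector("list", nrow(schedule))
  pos <- 0L
  for (b in seq_len(nrow(schedule))) {
    sim <- simulate_block(schedule[b, ], rate_hz = rate_hz)
    nb <- nrow(sim$data)
    m[pos + seq_len(nb), ] <- sim$data
    pos <- pos + nb
    blocks[[b]] <- sim
  }

  day0 <- floor(st[1] / 86400)
  dayN <- floor((ends[nrow(schedule)] - 1e-6) / 86400)
  days <- day0:dayN
  truth <- data.frame(date = as.Date(days, origin = "1970-01-01"),
                      true_steps = 0L, true_mvpa_s = 0,
                      true_bouted_mvpa_s = 0, true_wear_s = 0,
                      true_sleep_s = 0)
  for (b in seq_len(nrow(schedule))) {
    tr <- blocks[[b]]$truth
    abs_peaks <- st[b] + blocks[[b]]$peak_times_s
    for (k in seq_along(days)) {
      d1 <- days[k] * 86400; d2 <- d1 + 86400
      ov <- overlap_s(st[b], ends[b], d1, d2)
      if (ov == 0) next
      frac <- ov / schedule$duration_s[b]
      truth$true_wear_s[k] <- truth$true_wear_s[k] + tr$wear_s * frac
      truth$true_sleep_s[k] <- truth$true_sleep_s[k] + tr$sleep_s * frac
      truth$true_mvpa_s[k] <- truth$true_mvpa_s[k] + tr$mvpa_s * frac
      if (tr$mvpa_s > 0 && schedule$duration_s[b] >= 600)
        truth$true_bouted_mvpa_s[k] <- truth$true_bouted_mvpa_s[k] + ov
      if (length(abs_peaks))
        truth$true_steps[k] <- truth$true_steps[k] +
          sum(abs_peaks >= d1 & abs_peaks < d2)
    }
  }
  if (!is.null(meta))
    truth$day_index <- as.integer(truth$date - meta$pci_date)

  rec <- raw_recording(m, schedule$start[1], sample_rate_hz = rate_hz,
                       participant_id = if (is.null(meta)) "synthetic"
                                        else meta$participant_id,
                       validate = FALSE)
  if (!is.null(miscalibration))
    rec <- apply_device_distortion(rec, miscalibration$offset_g,
                                   miscalibration$gain)
  list(recording = rec, truth = truth, schedule = schedule)
}

#' Apply a per-axis gain/offset device distortion
#'
#' Models device miscalibration: `sample' = gain * sample + offset` per axis,
#' clipped to the dynamic range. [apply_calibration()] with the same
#' parameters is its exact inverse (up to clipping).
#'
#' @param rec a [raw_recording()].
#' @param offset_g 3-vector of per-axis offsets in g, each within +/-0.1 g.
#' @param gain 3-vector of per-axis gains, each in (0.9, 1.1).
#' @return The distorted `raw_recording`.
#' @export
apply_device_distortion <- function(rec, offset_g, gain) {
  if (length(offset_g) != 3 || length(gain) != 3)
    stop("offset_g and gain must be 3-vectors")
  if (any(gain <= 0.9 | gain >= 1.1)) stop("gains must lie in (0.9, 1.1)")
  if (any(abs(offset_g) > 0.1)) stop("offsets must lie within +/-0.1 g")
  d <- sweep(rec$data, 2, gain, `*`)
  d <- sweep(d, 2, offset_g, `+`)
  d[d > rec$dynamic_range_g] <- rec$dynamic_range_g
  d[d < -rec$dynamic_range_g] <- -rec$dynamic_range_g
  rec$data <- d
  rec
}
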