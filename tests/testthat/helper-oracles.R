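# Independent oracles and small fixture builders used across the test files.

# Brute-force MVPA bout oracle: enumerate, for each above-threshold start in
# scan order, the longest interval whose every prefix keeps the
# above-threshold fraction >= frac, contains no below-run longer than
# max_gap, and whose (trimmed) end is above threshold; accept it if it spans
# at least min_len epochs, then continue scanning after it. Implemented
# directly from the rule statement, independently of the package's scanner.
bout_oracle <- function(above, min_len = 120, frac = 0.8, max_gap = 12) {
  n <- length(above)
  below_run <- integer(n)
  for (j in seq_len(n)) {
    below_run[j] <- if (above[j]) 0L else (if (j == 1) 1L else below_run[j - 1] + 1L)
  }
  intervals <- NULL
  i <- 1L
  while (i <= n) {
    if (!above[i]) { i <- i + 1L; next }
    len <- seq_len(n - i + 1L)
    cs <- cumsum(above[i:n])
    prefix_ok <- cumprod(cs >= frac * len - 1e-9 & below_run[i:n] <= max_gap) == 1
    valid_end <- prefix_ok & above[i:n] & len >= min_len
    if (any(valid_end)) {
      j <- i + max(which(valid_end)) - 1L
      intervals <- rbind(intervals, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  total <- if (is.null(intervals)) 0L else sum(intervals[, 2] - intervals[, 1] + 1L)
  list(intervals = intervals, minutes = total / 12)
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# still recording visiting several orientations, optionally noisy
make_still_rec <- function(orientations, dwell_s = 30, noise_mg = 0,
                           rate_hz = 50,
                           start = as.POSIXct("2021-03-03", tz = "UTC")) {
  n <- round(dwell_s * rate_hz)
  m <- do.call(rbind, lapply(seq_len(nrow(orientations)), function(k)
    matrix(orientations[k, ], n, 3, byrow = TRUE)))
  if (noise_mg > 0)
    m <- m + stats::rnorm(length(m), 0, noise_mg / 1000)
  raw_recording(m, start, sample_rate_hz = rate_hz)
}

# eight well-spread unit orientations for calibration tests
eight_orientations <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
        c(0, 0, 1), c(0, 0, -1),
        c(1, 1, 1) / sqrt(3), c(-1, 1, -1) / sqrt(3))
}

# compact schedule builder: data frame of (kind, minutes, cadence, amp) rows
# laid out back to back from `start`
build_schedule <- function(blocks, start = as.POSIXct("2021-03-03", tz = "UTC"),
                           jitter = 0.05) {
  t <- start
  rows <- list()
  for (k in seq_len(nrow(blocks))) {
    b <- blocks[k, ]
    rows[[k]] <- activity_block(b$kind, t, b$minutes * 60,
                                cadence_spm = if ("cadence" %in% names(b)) b$cadence else NA,
                                peak_amp_g = if ("amp" %in% names(b)) b$amp else NA,
                                jitter = jitter)
    t <- t + b$minutes * 60
  }
  do.call(rbind, rows)
}

# fabricate a daily-summary row without running the raw pipeline
fake_day <- function(day_index, wear_hours = 16, mvpa_min = 0,
                     mvpa_bout10_min = 0, steps = 0, peak30_cad = 0,
                     participant_id = "P01") {
  data.frame(participant_id = participant_id, date = as.Date("2021-03-03") + day_index,
             day_index = day_index, wear_hours = wear_hours, sleep_min = 400,
             inactive_min = 600, lpa_min = 200, mvpa_min = mvpa_min,
             vpa_min = 0, mvpa_bout10_min = mvpa_bout10_min,
             mean_acc_mg = 25, m2_mg = 250, m30_mg = 120, m60_mg = 90,
             steps = steps, mean_cadence_spm = steps / 1440,
             cad100_min = 10, pct_zero_cadence = 60,
             peak1_cad = 110, peak30_cad = peak30_cad, peak60_cad = 60,
             stringsAsFactors = FALSE)
}

fake_meta <- function(id = "P01", age = 60, sex = "male", pres = "ACS")
  participant_meta(id, age, sex, pres, as.Date("2021-03-01"))
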