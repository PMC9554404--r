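# End-to-end drivers: raw recording -> epoch series -> day summaries, and
# the cohort loop that feeds the adherence report.

#' Process a raw recording into epochs and day summaries
#'
#' Runs the full chain: autocalibration, per-sample ENMO, 5-s epoch
#' aggregation on the midnight-aligned grid, non-wear detection, step
#' detection, sleep detection, and per-day summarisation (partial edge days
#' are padded with non-wear epochs so every summarised day spans the full
#' 17,280-epoch grid). The imputed 24-h mean acceleration uses the
#' participant's other valid days as clock-epoch donors.
#'
#' @param rec a [raw_recording()].
#' @param meta optional [participant_meta()] (day indexing; participant id).
#' @param config a [wpa_config()].
#' @param calibrate set FALSE to skip autocalibration.
#' @return List: `epochs` (the filled [epoch_series()]), `days` (one row per
#'   calendar day), `calibration` (the fitted model or NULL).
#' @export
process_recording <- function(rec, meta = NULL, config = wpa_config(),
                              calibrate = TRUE) {
  model <- NULL
  if (calibrate) {
    cal <- calibrate_recording(rec, config)
    rec <- cal$recording
    model <- cal$model
  }
  es <- aggregate_epochs(rec, epoch_s = config$epoch$length_s)
  es <- detect_nonwear(rec, es, config)
  steps <- detect_steps(rec, config$steps)
  es <- steps_to_epochs(steps, es)
  es <- detect_sleep_period(es, config)

  pci_date <- if (is.null(meta)) NULL else meta$pci_date
  pid <- if (is.null(meta)) rec$participant_id else meta$participant_id
  days <- summarize_days(es, pid, pci_date, config)
  list(epochs = es, days = days, calibration = model)
}

# pad one day's epochs to the full midnight-to-midnight grid (non-wear,
# zero ENMO for absent epochs), preserving clock alignment
pad_day <- function(day_es, day_start_abs, epl) {
  n_full <- 86400 %/% epl
  full <- epoch_series(
    as.POSIXct(day_start_abs, origin = "1970-01-01", tz = "UTC") +
      (seq_len(n_full) - 1) * epl,
    rep(0, n_full), rep(0, n_full),
    wear = rep(FALSE, n_full), epoch_length_s = epl)
  pos <- round((as.numeric(day_es$epoch_start) - day_start_abs) / epl) + 1L
  full$enmo_mg[pos] <- day_es$enmo_mg
  full$z_angle_deg[pos] <- day_es$z_angle_deg
  full$wear[pos] <- day_es$wear
  full$steps[pos] <- day_es$steps
  full$sleep[pos] <- day_es$sleep
  full
}

#' Summarise an epoch series into per-day metrics
#'
#' @param es a filled [epoch_series()].
#' @param participant_id id column value for the output.
#' @param pci_date optional Date (day 0) for day indexing; without it,
#'   day_index counts from 0 at the first calendar day.
#' @param config a [wpa_config()].
#' @return Data frame with one row per calendar day and all daily metrics.
#' @export
summarize_days <- function(es, participant_id = "unknown", pci_date = NULL,
                           config = wpa_config()) {
  epl <- attr(es, "epoch_length_s")
  abs_t <- as.numeric(es$epoch_start)
  day_id <- floor(abs_t / 86400)
  udays <- sort(unique(day_id))
  padded <- lapply(udays, function(d) pad_day(es[day_id == d, ], d * 86400, epl))
  wear_h <- vapply(padded, function(p) sum(p$wear) * epl / 3600, numeric(1))
  valid <- wear_h >= config$validity$min_wear_h
  enmo_m <- vapply(padded, function(p) p$enmo_mg, numeric(86400 %/% epl))
  wear_m <- vapply(padded, function(p) p$wear, logical(86400 %/% epl))

  rows <- lapply(seq_along(udays), function(k) {
    donors <- which(valid & seq_along(udays) != k)
    de <- if (length(donors)) enmo_m[, donors, drop = FALSE] else NULL
    dw <- if (length(donors)) wear_m[, donors, drop = FALSE] else NULL
    p <- padded[[k]]
    act <- summarize_day_activity(p, config, de, dw)
    cad <- cadence_summary(minute_cadence(p$steps))
    date <- as.Date(udays[k], origin = "1970-01-01")
    cbind(data.frame(participant_id = participant_id, date = date,
                     day_index = if (is.null(pci_date))
                       udays[k] - udays[1]
                     else as.integer(date - as.Date(pci_date)),
                     stringsAsFactors = FALSE),
          act, cad)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline over a synthetic cohort
#'
#' Realises each participant's raw recording in turn (recordings are
#' generated, processed and discarded one at a time to bound memory),
#' summarises valid days, classifies adherence, and compares the pipeline's
#' flags against the cohort's designed ground truth.
#'
#' @param cohort a `wpa_cohort` from [generate_cohort()].
#' @param config a [wpa_config()].
#' @param rate_hz sampling rate for the realised recordings.
#' @param verbose print one line per participant.
#' @return List: `days` (all day summaries), `participants` (summaries with
#'   flags), `report` ([cohort_report()] output), `designed` (the cohort's
#'   ground-truth table), `flag_agreement` (fraction of included
#'   participants whose four pipeline flags all equal the designed flags).
#' @export
run_cohort_pipeline <- function(cohort, config = wpa_config(), rate_hz = 50,
                                verbose = FALSE) {
  n <- length(cohort$participants)
  all_days <- vector("list", n)
  parts <- vector("list", n)
  for (i in seq_len(n)) {
    gen <- realize_recording(cohort, i, rate_hz = rate_hz)
    res <- process_recording(gen$recording, cohort$participants[[i]]$meta,
                             config)
    all_days[[i]] <- res$days
    vd <- select_valid_days(res$days, config$validity$min_wear_h,
                            config$validity$first_day)
    ps <- summarize_participant(vd, cohort$participants[[i]]$meta)
    if (ps$included) ps <- classify_adherence(ps, config$adherence)
    parts[[i]] <- ps
    if (verbose)
      message(sprintf("%s: %d valid days, %.0f steps/day, MVPA %.1f min",
                      ps$participant_id, ps$n_valid_days, ps$steps,
                      ps$mvpa_min))
    rm(gen, res); gc(FALSE)
  }
  days <- do.call(rbind, all_days)
  participants <- do.call(rbind, lapply(parts, function(p) {
    for (cr in c("who2020", "who2010", "steps7500", "steps10000"))
      if (is.null(p[[cr]])) p[[cr]] <- NA
    p
  }))
  crits <- c("who2020", "who2010", "steps7500", "steps10000")
  inc <- participants$included
  agree <- if (any(inc)) {
    d <- cohort$designed[match(participants$participant_id[inc],
                               cohort$designed$participant_id), ]
    mean(rowSums(participants[inc, crits] == d[, crits]) == 4)
  } else NA_real_
  list(days = days, participants = participants,
       report = cohort_report(participants, days, config),
       designed = cohort$designed, flag_agreement = agree)
}
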