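# Cohort-level synthetic data: archetype schedules with designed adherence.
#
# Two behavioural archetypes reproduce the mechanism that separates the two
# WHO criteria:
#   bout exercisers   one continuous 45-min brisk walk per day -> the walk is
#                     itself a >=10-min MVPA bout, so both the 2010 and 2020
#                     criteria are met;
#   accumulators      ten 4-min brisk walks spread over the day -> ~40 MVPA
#                     min/day but no block reaches 10 min, so the 2020
#                     criterion is met and the 2010 criterion is not.
# Both archetypes additionally take low-amplitude "strolls" (cadence 85
# steps/min, peak amplitude 0.24 g -> expected epoch ENMO 90 mg, light band):
# countable steps that contribute no MVPA. Stroll volume is tiered so that
# daily step totals straddle the 7,500 and 10,000 thresholds, giving the
# designed prevalence ordering P(2020) > P(>=7,500) > P(>=10,000) > P(2010).

#' Specify a synthetic cohort
#'
#' Defaults describe the reference validation cohort: 20 participants, 20\%
#' bout exercisers, 8 recorded days (day 2 to day 9 after the intervention)
#' with 16 h of wear per day (the device is off overnight), noiseless walks
#' and no device miscalibration.
#'
#' @param n_participants number of participants.
#' @param fraction_bout_exercisers fraction assigned the exerciser archetype.
#' @param n_days recorded days per participant.
#' @param pci_date Date of the intervention (day 0).
#' @param first_recorded_day day index of the first recorded midnight.
#' @param wear_start_h hour at which wear starts each day (before it: nonwear).
#' @param exerciser,accumulator,stroll archetype schedule parameters: walk
#'   durations (min), cadence ranges (steps/min), peak amplitudes (g) and
#'   stroll-volume tiers (min/day) with their fractions.
#' @param walk_jitter relative walk noise scale (0 = noiseless gait).
#' @param miscalibration optional list with `offset_mg = c(lo, hi)` and
#'   `gain = c(lo, hi)` ranges from which per-axis device distortions are
#'   drawn per participant (truth is unaffected).
#' @param seed integer cohort seed.
#' @return List of class `wpa_cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20, fraction_bout_exercisers = 0.2,
                        n_days = 8, pci_date = as.Date("2021-03-01"),
                        first_recorded_day = 2, wear_start_h = 8,
                        exerciser = list(walk_min = 45,
                                         cadence = c(110, 120), amp = 0.45,
                                         stroll_min = c(35, 35)),
                        accumulator = list(n_walks = 10, walk_min = 4,
                                           cadence = c(105, 115), amp = 0.40,
                                           stroll_tiers_min = c(low = 20, mid = 50, high = 80),
                                           tier_fractions = c(low = 0.25, mid = 0.5, high = 0.25)),
                        stroll = list(cadence = 85, amp = 0.24),
                        walk_jitter = 0, miscalibration = NULL, seed = 20) {
  if (n_participants < 1) stop("n_participants must be at least 1")
  if (fraction_bout_exercisers < 0 || fraction_bout_exercisers > 1)
    stop("fraction_bout_exercisers must lie in [0, 1]")
  if (abs(sum(accumulator$tier_fractions) - 1) > 1e-9)
    stop("tier_fractions must sum to 1")
  structure(list(n_participants = n_participants,
                 fraction_bout_exercisers = fraction_bout_exercisers,
                 n_days = n_days, pci_date = as.Date(pci_date),
                 first_recorded_day = first_recorded_day,
                 wear_start_h = wear_start_h,
                 exerciser = exerciser, accumulator = accumulator,
                 stroll = stroll, walk_jitter = walk_jitter,
                 miscalibration = miscalibration, seed = seed),
            class = "wpa_cohort_spec")
}

# One day's block schedule for a participant. Walks start at fixed minutes
# past the hour so every block sits on the 5-s epoch grid and the overnight
# nonwear block sits on the 15-min non-wear window grid.
build_day_schedule <- function(spec, archetype, tier, cadence, date) {
  d0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  jit <- spec$walk_jitter
  rows <- list(activity_block("nonwear", d0, spec$wear_start_h * 3600))
  hour_plan <- vector("list", 24 - spec$wear_start_h)
  names(hour_plan) <- as.character(spec$wear_start_h:23)
  add_walk <- function(hour, dur_min, cad, amp) {
    hour_plan[[as.character(hour)]] <<- list(dur_min = dur_min, cad = cad, amp = amp)
  }
  if (archetype == "exerciser") {
    add_walk(9, spec$exerciser$walk_min, cadence, spec$exerciser$amp)
    st_hours <- c(14, 17)
    for (k in seq_along(spec$exerciser$stroll_min))
      add_walk(st_hours[k], spec$exerciser$stroll_min[k],
               spec$stroll$cadence, spec$stroll$amp)
  } else {
    for (h in 9:(8 + spec$accumulator$n_walks))
      add_walk(h, spec$accumulator$walk_min, cadence, spec$accumulator$amp)
    tier_min <- spec$accumulator$stroll_tiers_min[[tier]]
    chunks <- c()
    left <- tier_min
    while (left > 0) { chunks <- c(chunks, min(30, left)); left <- left - min(30, left) }
    st_hours <- c(19, 20, 21)
    for (k in seq_along(chunks))
      add_walk(st_hours[k], chunks[k], spec$stroll$cadence, spec$stroll$amp)
  }
  for (h in spec$wear_start_h:23) {
    h0 <- d0 + h * 3600
    plan <- hour_plan[[as.character(h)]]
    if (is.null(plan)) {
      rows <- c(rows, list(activity_block("sedentary", h0, 1800),
                           activity_block("light", h0 + 1800, 1800)))
    } else {
      wd <- plan$dur_min * 60
      rows <- c(rows, list(
        activity_block("sedentary", h0, 600),
        activity_block("walk", h0 + 600, wd, cadence_spm = plan$cad,
                       peak_amp_g = plan$amp, jitter = jit)))
      rest <- 3600 - 600 - wd
      if (rest > 0)
        rows <- c(rows, list(activity_block("light", h0 + 600 + wd, rest)))
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic cohort with designed adherence prevalence
#'
#' Builds per-participant schedules, metadata and the designed (ground-truth)
#' adherence table. Raw recordings are not materialised here (a full cohort
#' of multi-day 50 Hz recordings would be several gigabytes); use
#' [realize_recording()] to generate one participant's recording on demand,
#' deterministically from the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @return Object of class `wpa_cohort`: list with `spec`, `participants`
#'   (per participant: `meta`, `archetype`, `tier`, `cadence`, `seed`,
#'   `schedule`, optional `miscalibration`), `designed` (per-participant
#'   ground-truth daily means and adherence flags) and `designed_prevalence`
#'   (percent adherent per criterion).
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_participants
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n_ex <- round(spec$fraction_bout_exercisers * n)
  archetype <- rep("accumulator", n)
  if (n_ex > 0) archetype[seq_len(n_ex)] <- "exerciser"
  n_acc <- n - n_ex
  tier <- rep(NA_character_, n)
  tier[archetype == "accumulator"] <-
    rep_len(rep(names(spec$accumulator$tier_fractions),
                round(spec$accumulator$tier_fractions * 4)), n_acc)
  sex <- rep("male", n); sex[seq_len(round(0.16 * n))] <- "female"
  pres <- rep("ACS", n); pres[seq_len(max(0, round(0.12 * n)))] <- "CCS"
  # shuffle demographic labels independently of archetype assignment
  sex <- sample(sex); pres <- sample(pres)
  ages <- round(stats::runif(n, 46, 76))

  dates <- spec$pci_date + spec$first_recorded_day + seq_len(spec$n_days) - 1
  participants <- vector("list", n)
  designed <- vector("list", n)
  for (i in seq_len(n)) {
    cad_rng <- if (archetype[i] == "exerciser") spec$exerciser$cadence
               else spec$accumulator$cadence
    cadence <- sample(seq(cad_rng[1], cad_rng[2]), 1)
    sched <- do.call(rbind, lapply(dates, function(d)
      build_day_schedule(spec, archetype[i], tier[i], cadence, d)))
    meta <- participant_meta(sprintf("P%02d", i), ages[i], sex[i], pres[i],
                             spec$pci_date)
    mis <- NULL
    if (!is.null(spec$miscalibration))
      mis <- list(offset_g = stats::runif(3, spec$miscalibration$offset_mg[1],
                                          spec$miscalibration$offset_mg[2]) / 1000,
                  gain = stats::runif(3, spec$miscalibration$gain[1],
                                      spec$miscalibration$gain[2]))
    participants[[i]] <- list(meta = meta, archetype = archetype[i],
                              tier = tier[i], cadence = cadence,
                              seed = (spec$seed %% 1000003L) * 1000L + i,
                              schedule = sched, miscalibration = mis)
    # designed daily truth: identical by construction across days
    if (archetype[i] == "exerciser") {
      mvpa <- spec$exerciser$walk_min
      bout <- spec$exerciser$walk_min
      steps <- spec$exerciser$walk_min * cadence +
        sum(spec$exerciser$stroll_min) * spec$stroll$cadence
    } else {
      mvpa <- spec$accumulator$n_walks * spec$accumulator$walk_min
      bout <- 0
      steps <- mvpa * cadence +
        spec$accumulator$stroll_tiers_min[[tier[i]]] * spec$stroll$cadence
    }
    designed[[i]] <- data.frame(
      participant_id = meta$participant_id, archetype = archetype[i],
      tier = tier[i], true_mvpa_min = mvpa, true_bout_min = bout,
      true_steps = steps,
      true_wear_h = 24 - spec$wear_start_h,
      who2020 = mvpa >= 30, who2010 = bout >= 30,
      steps7500 = steps >= 7500, steps10000 = steps >= 10000,
      stringsAsFactors = FALSE)
  }
  designed <- do.call(rbind, designed)
  prev <- 100 * colMeans(designed[, c("who2020", "who2010",
                                      "steps7500", "steps10000")])
  structure(list(spec = spec, participants = participants,
                 designed = designed, designed_prevalence = prev),
            class = "wpa_cohort")
}

#' Materialise one participant's raw recording
#'
#' @param cohort a `wpa_cohort` from [generate_cohort()].
#' @param i participant index.
#' @param rate_hz sampling rate.
#' @return As [generate_recording()]: list with `recording`, `truth`,
#'   `schedule`.
#' @export
realize_recording <- function(cohort, i, rate_hz = 50) {
  p <- cohort$participants[[i]]
  generate_recording(p$schedule, meta = p$meta, rate_hz = rate_hz,
                     miscalibration = p$miscalibration, seed = p$seed)
}
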