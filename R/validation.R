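# Self-contained validation studies: parameter-recovery experiments run
# against the synthetic generator's ground truth. Used by the test suite and
# by scripts/acceptance.R.

#' Step-count recovery study
#'
#' Generates 3-min walks over a cadence x amplitude grid plus still and
#' non-wear control blocks, runs the step detector, and reports detected
#' versus true counts.
#'
#' @param cadences walking cadences (steps/min).
#' @param amps per-step peak amplitudes (g).
#' @param seed integer seed.
#' @return Data frame: `cadence_spm`, `peak_amp_g`, `true_steps`,
#'   `detected_steps`, `rel_error`; control rows have `cadence_spm = NA` and
#'   zero true steps.
#' @export
step_recovery_study <- function(cadences = c(80, 100, 120),
                                amps = c(0.3, 0.5, 0.8), seed = 1) {
  grid <- expand.grid(cadence_spm = cadences, peak_amp_g = amps)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    sched <- activity_block("walk", as.POSIXct("2021-03-03 10:00:00",
                                               tz = "UTC"),
                            180, cadence_spm = grid$cadence_spm[k],
                            peak_amp_g = grid$peak_amp_g[k])
    gen <- generate_recording(sched, seed = seed * 100 + k)
    det <- length(detect_steps(gen$recording))
    tr <- gen$truth$true_steps
    data.frame(cadence_spm = grid$cadence_spm[k],
               peak_amp_g = grid$peak_amp_g[k], true_steps = tr,
               detected_steps = det, rel_error = (det - tr) / tr)
  })
  controls <- lapply(c("sedentary", "nonwear"), function(kind) {
    gen <- generate_recording(
      activity_block(kind, as.POSIXct("2021-03-03 10:00:00", tz = "UTC"),
                     1800), seed = seed)
    data.frame(cadence_spm = NA, peak_amp_g = NA, true_steps = 0L,
               detected_steps = length(detect_steps(gen$recording)),
               rel_error = NA)
  })
  do.call(rbind, c(rows, controls))
}

#' Autocalibration recovery study
#'
#' Injects a 5 x 5 grid of per-axis offsets (up to +/-50 mg) and gains
#' (0.95-1.05) into an 8-orientation still recording with 2 mg sensor noise,
#' re-estimates the calibration, and reports recovery errors.
#'
#' @param offsets_mg scalar offset levels; cell offset vector is
#'   `(o, -o, o/2)` mg.
#' @param gains scalar gain levels; cell gain vector is
#'   `(g, 1 + (1 - g)/2, 1)`.
#' @param seed integer seed.
#' @return Data frame per cell: `offset_mg`, `gain`, `max_offset_err_mg`,
#'   `max_gain_err`, `error_before_mg`, `error_after_mg`, `converged`.
#' @export
calibration_recovery_study <- function(offsets_mg = seq(-50, 50, length.out = 5),
                                       gains = seq(0.95, 1.05, length.out = 5),
                                       seed = 1) {
  ori <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1),
               c(1, 1, 1) / sqrt(3), c(-1, 1, -1) / sqrt(3))
  grid <- expand.grid(offset_mg = offsets_mg, gain = gains)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    n <- 120 * 50
    m <- ori[rep(1:8, each = n), ] + stats::rnorm(8 * n * 3, 0, 0.002)
    rec <- raw_recording(m, as.POSIXct("2021-03-03", tz = "UTC"))
    off <- c(grid$offset_mg[k], -grid$offset_mg[k], grid$offset_mg[k] / 2) / 1000
    gn <- c(grid$gain[k], 1 + (1 - grid$gain[k]) / 2, 1)
    dist <- apply_device_distortion(rec, off, gn)
    model <- estimate_calibration(find_still_points(dist))
    data.frame(offset_mg = grid$offset_mg[k], gain = grid$gain[k],
               max_offset_err_mg = max(abs(model$offset_g - off)) * 1000,
               max_gain_err = max(abs(model$gain - gn)),
               error_before_mg = model$error_before_mg,
               error_after_mg = model$error_after_mg,
               converged = model$converged)
  })
  do.call(rbind, rows)
}

#' Non-wear detection recovery study
#'
#' Embeds still (device-off) blocks of several lengths inside an active
#' recording, all boundaries on the 15-min detection grid, and reports per
#' block whether it was flagged and with what boundary error, plus any
#' spurious non-wear time outside the true blocks.
#'
#' @param block_min still-block lengths in minutes.
#' @param seed integer seed.
#' @return List with `blocks` (data frame: `block_min`, `flagged_min`,
#'   `start_err_min`, `end_err_min`) and `spurious_min` (non-wear flagged
#'   more than 15 min away from any true block).
#' @export
nonwear_recovery_study <- function(block_min = c(45, 60, 90, 180), seed = 1) {
  kinds <- c(rbind(rep("light", length(block_min)),
                   rep("nonwear", length(block_min))), "light")
  mins <- c(rbind(rep(60, length(block_min)), block_min), 60)
  t0 <- as.POSIXct("2021-03-03", tz = "UTC")
  starts <- t0 + cumsum(c(0, mins[-length(mins)])) * 60
  sched <- do.call(rbind, lapply(seq_along(kinds), function(k)
    activity_block(kinds[k], starts[k], mins[k] * 60)))
  gen <- generate_recording(sched, seed = seed)
  es <- detect_nonwear(gen$recording, aggregate_epochs(gen$recording))
  t_min <- (as.numeric(es$epoch_start) - as.numeric(t0)) / 60
  nw_idx <- which(kinds == "nonwear")
  blk_start <- (cumsum(c(0, mins[-length(mins)])))[nw_idx]
  blk_end <- blk_start + mins[nw_idx]
  rows <- lapply(seq_along(nw_idx), function(k) {
    inside <- !es$wear & t_min >= blk_start[k] & t_min < blk_end[k]
    data.frame(block_min = mins[nw_idx[k]],
               flagged_min = sum(inside) / 12,
               start_err_min = if (any(inside)) min(t_min[inside]) - blk_start[k]
                               else NA_real_,
               end_err_min = if (any(inside)) blk_end[k] - (max(t_min[inside]) + 5 / 60)
                             else NA_real_)
  })
  near_block <- rep(FALSE, nrow(es))
  for (k in seq_along(nw_idx))
    near_block <- near_block |
      (t_min >= blk_start[k] - 15 & t_min < blk_end[k] + 15)
  list(blocks = do.call(rbind, rows),
       spurious_min = sum(!es$wear & !near_block) / 12)
}
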