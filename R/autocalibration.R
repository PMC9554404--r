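# Autocalibration against local gravity: during still periods the norm of
# the measured acceleration should equal 1 g, so per-axis offsets and gains
# can be estimated by iteratively fitting still-window means toward their
# projection on the unit sphere.

#' Find still-window mean vectors
#'
#' Splits the recording into non-overlapping windows (default 10 s) and
#' returns the per-axis mean vector of every window whose three per-axis
#' sample SDs are all below `sd_threshold_mg`.
#'
#' @param rec a [raw_recording()].
#' @param window_s window length in seconds.
#' @param sd_threshold_mg per-axis SD threshold in mg.
#' @return Matrix with columns x, y, z (g); zero rows when nothing is still.
#' @export
find_still_points <- function(rec, window_s = 10, sd_threshold_mg = 13) {
  n <- nrow(rec$data)
  w <- round(window_s * rec$sample_rate_hz)
  if (n < w) stop("recording shorter than one still window")
  nw <- n %/% w
  out <- matrix(NA_real_, nw, 3)
  ok <- rep(TRUE, nw)
  for (a in 1:3) {
    st <- chunk_stats_cpp(rec$data[, a], w)
    v <- (st[, 2] - st[, 1]^2 / w) / (w - 1)
    ok <- ok & sqrt(pmax(v, 0)) * 1000 < sd_threshold_mg
    out[, a] <- st[, 1] / w
  }
  colnames(out) <- c("x", "y", "z")
  out[ok, , drop = FALSE]
}

#' Estimate per-axis offset/gain calibration from still points
#'
#' Iterative sphere fit: each still point is moved toward its projection on
#' the unit (1 g) sphere by a per-axis linear fit, weighted down-weighting
#' points far from the sphere; iterates until the mean absolute norm error
#' changes by less than `tol_mg` or `max_iter` is reached. When the still
#' points span fewer than three distinct orientations (per-axis value range
#' below `min_range_g` on any axis) the problem is ill-posed and the
#' identity model is returned with `converged = FALSE`.
#'
#' @param still matrix of still-point mean vectors (g), from
#'   [find_still_points()].
#' @param max_iter,tol_mg,min_range_g iteration and well-posedness controls.
#' @return List of class `calibration_model`: `offset_g`, `gain`,
#'   `error_before_mg`, `error_after_mg`, `n_still_points`, `converged`.
#' @export
estimate_calibration <- function(still, max_iter = 1000, tol_mg = 0.001,
                                 min_range_g = 0.3) {
  if (is.null(dim(still)) || nrow(still) < 1)
    stop("need at least one still point")
  norm_err <- function(m) mean(abs(sqrt(rowSums(m^2)) - 1)) * 1000
  err0 <- norm_err(still)
  identity_model <- structure(
    list(offset_g = c(0, 0, 0), gain = c(1, 1, 1),
         error_before_mg = err0, error_after_mg = err0,
         n_still_points = nrow(still), converged = FALSE),
    class = "calibration_model")
  rng <- apply(still, 2, function(x) diff(range(x)))
  if (any(rng < min_range_g) || nrow(still) < 3) return(identity_model)

  offset <- c(0, 0, 0); gain <- c(1, 1, 1)
  prev_err <- err0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- sweep(sweep(still, 2, offset, `-`), 2, gain, `/`)
    nrm <- sqrt(rowSums(cur^2))
    tgt <- cur / nrm
    wt <- 1 / pmax(abs(nrm - 1), 0.01)          # down-weight far points
    for (a in 1:3) {
      fit <- stats::lm.wfit(cbind(1, cur[, a]), tgt[, a], wt)
      al <- fit$coefficients[1]; be <- fit$coefficients[2]
      # new correction: al + be*(p - offset)/gain == (p - offset')/gain'
      gain[a] <- gain[a] / be
      offset[a] <- offset[a] - al * gain[a]
    }
    cur <- sweep(sweep(still, 2, offset, `-`), 2, gain, `/`)
    err <- norm_err(cur)
    if (abs(prev_err - err) < tol_mg) { converged <- TRUE; break }
    prev_err <- err
  }
  err_after <- norm_err(sweep(sweep(still, 2, offset, `-`), 2, gain, `/`))
  if (any(gain <= 0.9 | gain >= 1.1) || err_after > err0 + 1e-9)
    return(identity_model)
  structure(list(offset_g = unname(offset), gain = unname(gain),
                 error_before_mg = err0, error_after_mg = err_after,
                 n_still_points = nrow(still), converged = converged),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("calibration_model: offset (%.1f, %.1f, %.1f) mg, ",
                     "gain (%.4f, %.4f, %.4f)\n  error %.2f -> %.2f mg over %d still points%s\n"),
              x$offset_g[1] * 1000, x$offset_g[2] * 1000, x$offset_g[3] * 1000,
              x$gain[1], x$gain[2], x$gain[3],
              x$error_before_mg, x$error_after_mg, x$n_still_points,
              if (x$converged) "" else " (not converged: identity)"))
  invisible(x)
}

#' Apply a calibration model to a recording
#'
#' `sample' = (sample - offset) / gain` per axis; the exact inverse of
#' [apply_device_distortion()] with the same parameters.
#'
#' @param rec a [raw_recording()].
#' @param model a `calibration_model`.
#' @return The calibrated `raw_recording`.
#' @export
apply_calibration <- function(rec, model) {
  if (all(model$offset_g == 0) && all(model$gain == 1)) return(rec)
  for (a in 1:3)
    rec$data[, a] <- (rec$data[, a] - model$offset_g[a]) / model$gain[a]
  rec
}

#' Estimate and apply calibration in one step
#'
#' @param rec a [raw_recording()].
#' @param config a [wpa_config()] (uses the `calibration` group).
#' @return List with `recording` (calibrated) and `model`.
#' @export
calibrate_recording <- function(rec, config = wpa_config()) {
  cc <- config$calibration
  still <- find_still_points(rec, cc$window_s, cc$sd_threshold_mg)
  model <- if (nrow(still) == 0)
    structure(list(offset_g = c(0, 0, 0), gain = c(1, 1, 1),
                   error_before_mg = NA_real_, error_after_mg = NA_real_,
                   n_still_points = 0L, converged = FALSE),
              class = "calibration_model")
  else estimate_calibration(still, cc$max_iter, cc$tol_mg, cc$min_range_g)
  list(recording = apply_calibration(rec, model), model = model)
}
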