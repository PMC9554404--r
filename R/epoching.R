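# Epoching: per-sample ENMO, 5-s epoch aggregation on the midnight-aligned
# grid, non-wear detection over 60-min sliding windows, and angle-based
# detection of the nightly sleep period.

#' Per-sample ENMO in mg
#'
#' Euclidean norm minus one: `max(0, sqrt(x^2+y^2+z^2) - 1) * 1000`, negative
#' values truncated to zero.
#'
#' @param rec a calibrated [raw_recording()] (or an n x 3 matrix in g).
#' @return Numeric vector of per-sample ENMO in mg.
#' @export
compute_enmo <- function(rec) {
  m <- if (inherits(rec, "raw_recording")) rec$data else as.matrix(rec)
  pmax(sqrt(m[, 1]^2 + m[, 2]^2 + m[, 3]^2) - 1, 0) * 1000
}

# first index of the 5-s epoch grid (aligned to midnight) covered by the
# recording, plus the number of whole epochs; partial edge epochs drop.
epoch_grid <- function(rec, epoch_s = 5) {
  t0 <- as.numeric(rec$start_time)
  n <- nrow(rec$data)
  first_ep <- ceiling(t0 / epoch_s - 1e-9)          # grid cell index
  off <- round((first_ep * epoch_s - t0) * rec$sample_rate_hz)
  spp <- round(epoch_s * rec$sample_rate_hz)        # samples per epoch
  n_ep <- (n - off) %/% spp
  list(first_ep = first_ep, offset_samples = off, samples_per_epoch = spp,
       n_epochs = n_ep)
}

#' Aggregate a recording into 5-s epochs
#'
#' Epochs lie on a grid aligned to local midnight; partial epochs at the
#' recording edges are dropped. Per epoch: mean ENMO (mg) and the arm angle
#' `atan(z_mean / sqrt(x_mean^2 + y_mean^2))` in degrees.
#'
#' @param rec a calibrated [raw_recording()].
#' @param enmo optional precomputed per-sample ENMO from [compute_enmo()].
#' @param epoch_s epoch length in seconds.
#' @return An [epoch_series()] (wear all TRUE, steps 0, sleep FALSE; filled
#'   by the later stages).
#' @export
aggregate_epochs <- function(rec, enmo = NULL, epoch_s = 5) {
  g <- epoch_grid(rec, epoch_s)
  if (g$n_epochs < 1) stop("recording spans no complete epoch")
  if (is.null(enmo)) enmo <- compute_enmo(rec)
  n_used <- g$n_epochs * g$samples_per_epoch
  aligned <- g$offset_samples == 0L
  sel <- if (aligned) NULL else g$offset_samples + seq_len(n_used)
  pick <- function(x) {
    if (aligned) {
      if (length(x) == n_used) x else x[seq_len(n_used)]
    } else x[sel]
  }
  em <- .colMeans(pick(enmo), g$samples_per_epoch, g$n_epochs)
  ax <- matrix(0, g$n_epochs, 3)
  for (a in 1:3)
    ax[, a] <- .colMeans(pick(rec$data[, a]), g$samples_per_epoch, g$n_epochs)
  zang <- atan(ax[, 3] / sqrt(ax[, 1]^2 + ax[, 2]^2)) * 180 / pi
  zang[is.nan(zang)] <- 90 * sign(ax[is.nan(zang), 3])
  start <- as.POSIXct(g$first_ep * epoch_s, origin = "1970-01-01", tz = "UTC")
  epoch_series(start + (seq_len(g$n_epochs) - 1) * epoch_s, em, zang,
               epoch_length_s = epoch_s)
}

#' Detect non-wear periods
#'
#' Sliding 60-min windows advanced in 15-min steps from the recording start.
#' A window votes non-wear when, on at least `min_axes` of the three axes,
#' the per-axis sample SD is below `sd_mg` or the per-axis range is below
#' `range_mg`. An epoch is non-wear if any window covering it votes
#' non-wear.
#'
#' @param rec a [raw_recording()].
#' @param es the [epoch_series()] whose `wear` column is to be filled.
#' @param config a [wpa_config()] (uses the `nonwear` group).
#' @return `es` with the `wear` column updated.
#' @export
detect_nonwear <- function(rec, es, config = wpa_config()) {
  nw <- config$nonwear
  rate <- rec$sample_rate_hz
  chunk <- round(nw$slide_min * 60 * rate)
  per_win <- nw$window_min %/% nw$slide_min          # chunks per window
  n <- nrow(rec$data)
  n_chunks <- n %/% chunk
  if (n_chunks < per_win) return(es)                 # too short to judge
  sd_ok <- rng_ok <- matrix(FALSE, n_chunks - per_win + 1L, 3)
  for (a in 1:3) {
    st <- chunk_stats_cpp(rec$data[, a], chunk)
    for (w in seq_len(n_chunks - per_win + 1L)) {
      id <- w:(w + per_win - 1L)
      m <- per_win * chunk
      v <- (sum(st[id, 2]) - sum(st[id, 1])^2 / m) / (m - 1)
      sd_ok[w, a] <- sqrt(max(v, 0)) * 1000 < nw$sd_mg
      rng_ok[w, a] <- (max(st[id, 4]) - min(st[id, 3])) * 1000 < nw$range_mg
    }
  }
  votes <- rowSums(sd_ok | rng_ok) >= nw$min_axes
  if (!any(votes)) return(es)
  t0 <- as.numeric(rec$start_time)
  ep0 <- as.numeric(es$epoch_start)
  epl <- attr(es, "epoch_length_s")
  nonwear <- rep(FALSE, nrow(es))
  for (w in which(votes)) {
    w1 <- t0 + (w - 1L) * nw$slide_min * 60
    w2 <- w1 + nw$window_min * 60
    nonwear[ep0 >= w1 - 1e-9 & ep0 + epl <= w2 + 1e-9] <- TRUE
  }
  es$wear <- !nonwear
  es
}

#' Detect the nightly sleep period from the z-angle
#'
#' For each 5-min block the mean absolute successive difference of the epoch
#' z-angle is computed. Within each noon-to-noon night, blocks below a
#' data-driven threshold (15 x the night's 10th percentile, floored at
#' 0.1 deg and capped at 15 deg) form sustained-inactivity runs; runs
#' separated by less than 60 min are merged, and the longest merged run of
#' at least 30 min is the sleep period.
#'
#' @param es an [epoch_series()].
#' @param config a [wpa_config()] (uses the `sleep` group).
#' @return `es` with the `sleep` column set.
#' @export
detect_sleep_period <- function(es, config = wpa_config()) {
  sl <- config$sleep
  epl <- attr(es, "epoch_length_s")
  per_block <- round(sl$block_min * 60 / epl)
  ep_abs <- as.numeric(es$epoch_start)
  n <- nrow(es)
  if (n < 2 * per_block) return(es)
  # block index on an absolute 5-min grid, nights on a noon-anchored grid
  block_id <- floor(ep_abs / (sl$block_min * 60))
  dz <- c(NA, abs(diff(es$z_angle_deg)))
  bm <- c(tapply(dz, block_id, mean, na.rm = TRUE))
  bstart <- as.numeric(names(bm)) * sl$block_min * 60
  bm[is.na(bm)] <- Inf
  night_id <- floor((bstart - 43200) / 86400)
  sleep <- rep(FALSE, n)
  for (nt in unique(night_id)) {
    in_night <- night_id == nt
    vals <- bm[in_night]
    if (length(vals) < sl$min_duration_min / sl$block_min) next
    thr <- min(max(sl$threshold_mult * stats::quantile(vals[is.finite(vals)],
                                                       0.1, names = FALSE),
                   sl$threshold_floor_deg), sl$threshold_cap_deg)
    below <- vals < thr
    r <- rle(below)
    # merge below-runs separated by above-gaps shorter than merge_gap_min
    gap_blocks <- sl$merge_gap_min / sl$block_min
    if (length(r$lengths) > 2)
      for (k in 2:(length(r$values) - 1))
        if (!r$values[k] && r$lengths[k] < gap_blocks &&
            r$values[k - 1] && r$values[k + 1]) r$values[k] <- TRUE
    merged <- inverse.rle(r)
    rm <- rle(merged)
    ends <- cumsum(rm$lengths); starts <- ends - rm$lengths + 1L
    cand <- which(rm$values & rm$lengths >= sl$min_duration_min / sl$block_min)
    if (!length(cand)) next
    best <- cand[which.max(rm$lengths[cand])]
    bs <- bstart[in_night][starts[best]]
    be <- bstart[in_night][ends[best]] + sl$block_min * 60
    sleep[ep_abs >= bs & ep_abs < be] <- TRUE
  }
  es$sleep <- sleep
  es
}
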