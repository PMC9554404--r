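#' Construct a raw tri-axial recording
#'
#' A `raw_recording` holds a tri-axial wrist acceleration signal on a strict
#' uniform sampling grid. Sample times are implicit: sample `i` is at
#' `start_time + (i - 1) / sample_rate_hz`. Timestamps are timezone-naive
#' local time, represented internally as POSIXct in UTC; day boundaries are
#' local midnight.
#'
#' @param data numeric matrix with columns x, y, z in g units.
#' @param start_time POSIXct (UTC) time of the first sample.
#' @param sample_rate_hz sampling rate in Hz (nominal 50).
#' @param participant_id participant identifier.
#' @param dynamic_range_g device dynamic range in g (nominal 8); all axis
#'   values must lie within it.
#' @param validate set FALSE to skip the dynamic-range scan (used internally
#'   for signals whose range is known by construction).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, start_time, sample_rate_hz = 50,
                          participant_id = "unknown", dynamic_range_g = 8,
                          validate = TRUE) {
  data <- as.matrix(data)
  if (ncol(data) != 3L) stop("raw recording data must have 3 axis columns")
  if (nrow(data) < 1L) stop("raw recording must contain at least one sample")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  if (dynamic_range_g <= 0) stop("dynamic_range_g must be positive")
  if (validate) {
    r <- range(data)
    if (max(-r[1], r[2]) > dynamic_range_g + 1e-9)
      stop("axis values exceed the device dynamic range")
  }
  colnames(data) <- c("x", "y", "z")
  structure(
    list(participant_id = participant_id,
         start_time = as.POSIXct(start_time, tz = "UTC"),
         sample_rate_hz = sample_rate_hz,
         data = data,
         dynamic_range_g = dynamic_range_g),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("raw_recording: %s, %d samples at %g Hz (%.2f h) from %s\n",
              x$participant_id, n, x$sample_rate_hz,
              n / x$sample_rate_hz / 3600,
              format(x$start_time, "%Y-%m-%d %H:%M:%OS2")))
  invisible(x)
}

#' Sample timestamps of a recording
#'
#' @param rec a `raw_recording`.
#' @return POSIXct vector, one element per sample.
#' @export
rec_times <- function(rec) {
  rec$start_time + (seq_len(nrow(rec$data)) - 1) / rec$sample_rate_hz
}

#' Duration of a recording in seconds
#' @param rec a `raw_recording`.
#' @export
rec_duration_s <- function(rec) nrow(rec$data) / rec$sample_rate_hz

#' Participant metadata record
#'
#' @param participant_id identifier token.
#' @param age_years age at enrolment; must lie in (18, 80] (the cohort design
#'   enrols adults under 80).
#' @param sex "female" or "male".
#' @param presentation clinical presentation, "ACS" (acute) or "CCS" (chronic
#'   coronary syndrome).
#' @param pci_date Date of the index intervention; day 0 of the recording
#'   day-index scale.
#' @return An object of class `participant_meta`.
#' @export
participant_meta <- function(participant_id, age_years, sex, presentation,
                             pci_date) {
  if (!(age_years > 18 && age_years <= 80))
    stop("age_years must be in (18, 80]")
  sex <- match.arg(sex, c("female", "male"))
  presentation <- match.arg(presentation, c("ACS", "CCS"))
  structure(list(participant_id = participant_id, age_years = age_years,
                 sex = sex, presentation = presentation,
                 pci_date = as.Date(pci_date)),
            class = "participant_meta")
}

#' Read a raw recording from CSV
#'
#' Reads the documented raw CSV dialect: header `time,x,y,z`, ISO-8601
#' timestamps with fractional seconds, axis values in g. The file is mapped
#' onto a strict uniform grid at `sample_rate_hz`; gaps of up to 1 s are
#' filled by holding the last observed sample, longer gaps are an error.
#'
#' @param path file path.
#' @param meta optional [participant_meta()]; its id is attached to the
#'   recording.
#' @param sample_rate_hz nominal grid rate (default 50 Hz).
#' @param dynamic_range_g device range used for validation (default 8 g).
#' @return A [raw_recording()].
#' @export
read_raw_recording <- function(path, meta = NULL, sample_rate_hz = 50,
                               dynamic_range_g = 8) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(df))) stop("raw CSV must have columns time,x,y,z")
  tt <- as.POSIXct(df$time, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(tt)) stop("unparseable timestamps in raw CSV")
  rel <- as.numeric(tt) - as.numeric(tt[1])
  if (any(diff(rel) <= 0)) stop("non-monotone timestamps in raw CSV")
  idx <- as.integer(round(rel * sample_rate_hz)) + 1L
  if (any(diff(idx) < 1L)) stop("non-monotone timestamps after grid snapping")
  gaps <- diff(idx)
  if (any(gaps > sample_rate_hz))
    stop("gap longer than 1 s in raw CSV; refusing to impute")
  n <- idx[length(idx)]
  m <- matrix(NA_real_, n, 3L)
  m[idx, ] <- cbind(df$x, df$y, df$z)
  if (anyNA(m[, 1])) {            # hold last sample across short gaps
    filled <- cummax(ifelse(is.na(m[, 1]), 0L, seq_len(n)))
    m <- m[filled, , drop = FALSE]
  }
  raw_recording(m, tt[1], sample_rate_hz = sample_rate_hz,
                participant_id = if (is.null(meta)) "unknown" else meta$participant_id,
                dynamic_range_g = dynamic_range_g)
}

#' Write a raw recording to CSV
#'
#' Inverse of [read_raw_recording()]; axis values are written with 6 decimal
#' places, timestamps with millisecond precision.
#'
#' @param rec a `raw_recording`.
#' @param path output file path.
#' @export
write_raw_recording <- function(rec, path) {
  tt <- format(rec_times(rec), "%Y-%m-%dT%H:%M:%OS3")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time,x,y,z", con)
  writeLines(sprintf("%s,%.6f,%.6f,%.6f", tt,
                     rec$data[, 1], rec$data[, 2], rec$data[, 3]), con)
  invisible(path)
}

#' Construct an epoch series
#'
#' Per-5-s epoch features on a grid aligned to local midnight. Columns:
#' `epoch_start` (POSIXct), `enmo_mg`, `z_angle_deg`, `wear` (logical),
#' `steps` (integer), `sleep` (logical).
#'
#' @param epoch_start POSIXct vector on a 5-s grid.
#' @param enmo_mg non-negative epoch-mean ENMO in mg.
#' @param z_angle_deg epoch arm angle in degrees, in \[-90, 90\].
#' @param wear,sleep logical flags (default all wear, no sleep).
#' @param steps integer step counts (default 0).
#' @param epoch_length_s epoch length (5 s).
#' @return A data frame of class `epoch_series`.
#' @export
epoch_series <- function(epoch_start, enmo_mg, z_angle_deg,
                         wear = rep(TRUE, length(epoch_start)),
                         steps = rep(0L, length(epoch_start)),
                         sleep = rep(FALSE, length(epoch_start)),
                         epoch_length_s = 5) {
  if (any(enmo_mg < 0)) stop("enmo_mg must be non-negative")
  if (length(z_angle_deg) && (min(z_angle_deg) < -90 - 1e-9 ||
                              max(z_angle_deg) > 90 + 1e-9))
    stop("z_angle_deg must lie in [-90, 90]")
  es <- data.frame(epoch_start = as.POSIXct(epoch_start, tz = "UTC"),
                   enmo_mg = as.numeric(enmo_mg),
                   z_angle_deg = as.numeric(z_angle_deg),
                   wear = as.logical(wear),
                   steps = as.integer(steps),
                   sleep = as.logical(sleep))
  attr(es, "epoch_length_s") <- epoch_length_s
  class(es) <- c("epoch_series", "data.frame")
  es
}

#' Write an epoch series to CSV
#'
#' Header `epoch_start,enmo_mg,steps,wear,z_angle_deg,sleep`; ENMO with 6
#' decimals (round-trips to within 1e-6 mg), flags as 0/1. `sleep` is an
#' extension column beyond the minimal epoch interface; readers that do not
#' know it can ignore it.
#'
#' @param es an `epoch_series`.
#' @param path output file path.
#' @export
write_epoch_series <- function(es, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("epoch_start,enmo_mg,steps,wear,z_angle_deg,sleep", con)
  if (nrow(es))
    writeLines(sprintf("%s,%.6f,%d,%d,%.6f,%d",
                       format(es$epoch_start, "%Y-%m-%dT%H:%M:%S"),
                       es$enmo_mg, es$steps, as.integer(es$wear),
                       es$z_angle_deg, as.integer(es$sleep)), con)
  invisible(path)
}

#' Read an epoch series from CSV
#'
#' @param path file written by [write_epoch_series()].
#' @return An `epoch_series`.
#' @export
read_epoch_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_start", "enmo_mg", "steps", "wear", "z_angle_deg")
  if (!all(need %in% names(df))) stop("malformed epoch CSV header")
  if (nrow(df) == 0L)
    return(epoch_series(as.POSIXct(character(), tz = "UTC"),
                        numeric(), numeric()))
  epoch_series(as.POSIXct(df$epoch_start, tz = "UTC",
                          tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                         "%Y-%m-%d %H:%M:%OS")),
               df$enmo_mg, df$z_angle_deg,
               wear = df$wear != 0, steps = df$steps,
               sleep = if ("sleep" %in% names(df)) df$sleep != 0
                       else rep(FALSE, nrow(df)))
}

#' Split a recording at local-midnight boundaries
#'
#' Partitions a recording into per-calendar-day segments (midnight to
#' midnight). The first and last segments may be partial. Each segment
#' carries `day_date` and, when `pci_date` is given, `day_index` (the
#' intervention day being index 0) as attributes.
#'
#' @param rec a `raw_recording`.
#' @param pci_date optional Date of the intervention (day 0).
#' @return List of `raw_recording` segments whose concatenation reproduces
#'   the input sample sequence.
#' @export
slice_days <- function(rec, pci_date = NULL) {
  n <- nrow(rec$data)
  t0 <- as.numeric(rec$start_time)
  day0 <- floor(t0 / 86400)                       # UTC == naive local time
  last <- t0 + (n - 1) / rec$sample_rate_hz
  dayN <- floor(last / 86400)
  out <- vector("list", dayN - day0 + 1L)
  for (k in seq_along(out)) {
    d <- day0 + k - 1L
    # sample i is at t0 + (i-1)/rate; in-day condition on [d*86400, (d+1)*86400)
    i1 <- max(1L, as.integer(ceiling((d * 86400 - t0) * rec$sample_rate_hz - 1e-6)) + 1L)
    i2 <- min(n, as.integer(ceiling(((d + 1) * 86400 - t0) * rec$sample_rate_hz - 1e-6)))
    seg <- raw_recording(rec$data[i1:i2, , drop = FALSE],
                         rec$start_time + (i1 - 1) / rec$sample_rate_hz,
                         sample_rate_hz = rec$sample_rate_hz,
                         participant_id = rec$participant_id,
                         dynamic_range_g = rec$dynamic_range_g,
                         validate = FALSE)
    date <- as.Date(d, origin = "1970-01-01")
    attr(seg, "day_date") <- date
    if (!is.null(pci_date))
      attr(seg, "day_index") <- as.integer(date - as.Date(pci_date))
    out[[k]] <- seg
  }
  out
}
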