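#' Default processing configuration
#'
#' Returns the full set of tunable constants used by the pipeline, grouped by
#' stage. Every threshold that the processing chain applies is exposed here so
#' that sensitivity to any of them can be examined; the defaults are the
#' values the package's validation suite is run with.
#'
#' Groups:
#' \describe{
#'   \item{bands}{Intensity cut-points on 5-s epoch ENMO in mg: inactivity
#'     below 25 mg, light activity in \[25, 100), MVPA at or above 100 mg,
#'     with a vigorous sub-band at 400 mg (toolchain convention).}
#'   \item{epoch}{Epoch length in seconds (5).}
#'   \item{calibration}{Still-window geometry (10 s windows, all-axis SD
#'     below 13 mg), sphere-fit iteration control, and the minimum per-axis
#'     orientation range (0.3 g) below which the fit is declared ill-posed.}
#'   \item{nonwear}{60-min windows slid in 15-min steps; a window votes
#'     non-wear when at least 2 of 3 axes have SD < 13 mg or range < 50 mg.}
#'   \item{sleep}{Angle-based sustained-inactivity detection: 5-min blocks of
#'     mean absolute successive z-angle change, data-driven threshold
#'     (15 x the 10th percentile, floored at 0.1 deg and capped at 15 deg),
#'     runs merged across gaps < 60 min, minimum period 30 min, searched
#'     noon-to-noon.}
#'   \item{bout}{MVPA bout rule: >= 10 min with >= 80\% of 5-s epochs above
#'     the MVPA threshold, tolerating at most 1 min of consecutive
#'     below-threshold epochs inside a bout.}
#'   \item{accrual}{"epoch" (minutes = epochs/12, the default) or "minute80"
#'     (a minute counts as MVPA only when >= 80\% of its epochs qualify).}
#'   \item{steps}{Windowed peak detection parameters (see
#'     [step_detector_params()]).}
#'   \item{validity}{Valid-day rule: >= 12 h wear, days counted from index 2
#'     after the intervention (day 0).}
#'   \item{adherence}{30 min/day MVPA for both WHO criteria; step thresholds
#'     7,500 and 10,000.}
#' }
#'
#' @return A named list of configuration groups.
#' @export
wpa_config <- function() {
  list(
    bands = list(inactive_max_mg = 25, mvpa_min_mg = 100, vigorous_min_mg = 400),
    epoch = list(length_s = 5),
    calibration = list(window_s = 10, sd_threshold_mg = 13,
                       max_iter = 1000, tol_mg = 0.001, min_range_g = 0.3),
    nonwear = list(window_min = 60, slide_min = 15,
                   sd_mg = 13, range_mg = 50, min_axes = 2),
    sleep = list(block_min = 5, threshold_mult = 15,
                 threshold_floor_deg = 0.1, threshold_cap_deg = 15,
                 merge_gap_min = 60, min_duration_min = 30),
    bout = list(min_duration_min = 10, criterion_fraction = 0.8, max_gap_min = 1),
    accrual = list(mode = "epoch"),
    steps = step_detector_params(),
    validity = list(min_wear_h = 12, first_day = 2),
    adherence = list(mvpa_min_per_day = 30, steps_lo = 7500, steps_hi = 10000)
  )
}
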