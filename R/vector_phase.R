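#' Rotate (HbO, HbR) into the (CBV, COE) axes
#'
#' Cerebral blood volume and cerebral oxygen exchange indices are the 45
#' degree counterclockwise rotation of the chromophore axes:
#' `CBV = (HbO + HbR) / sqrt(2)`, `COE = (HbR - HbO) / sqrt(2)`. The
#' rotation is an isometry: `CBV^2 + COE^2 = HbO^2 + HbR^2`.
#'
#' @param hbo,hbr numeric vectors (same length).
#' @return List with `cbv` and `coe`.
#' @export
to_cbv_coe <- function(hbo, hbr) {
  stopifnot(length(hbo) == length(hbr))
  list(cbv = (hbo + hbr) / sqrt(2), coe = (hbr - hbo) / sqrt(2))
}

#' Magnitude and angle of phase-plane vectors
#'
#' `|p| = sqrt(HbO^2 + HbR^2)`; the angle is the full-quadrant angle of
#' `(HbO, HbR)` in degrees, in `(-180, 180]`. The angle at the origin is
#' undefined and returned as `NA`. Within the branch where both sides are
#' defined the identity `angle = atan(COE / CBV) + 45` holds (mod 360).
#'
#' @param hbo,hbr numeric vectors.
#' @return List with `magnitude` and `angle_deg`.
#' @export
magnitude_phase <- function(hbo, hbr) {
  stopifnot(length(hbo) == length(hbr))
  mag <- sqrt(hbo^2 + hbr^2)
  ang <- atan2(hbr, hbo) * 180 / pi
  ang[which(ang <= -180)] <- ang[which(ang <= -180)] + 360
  ang[which(mag == 0)] <- NA_real_
  list(magnitude = mag, angle_deg = ang)
}

#' Classify phase-plane points into the eight phases
#'
#' Phases 1-5 are the initial-dip phases (rising HbR or rising oxygen
#' exchange), phases 6-8 the hemodynamic-response phases. Each phase is a
#' conjunction of strict inequalities on (HbO, HbR, CBV, COE); points on
#' any boundary (ties, axes, origin) belong to no phase and classify as
#' `NA`.
#'
#' \describe{
#'   \item{1}{`0 < HbR < HbO`, `COE < 0 < CBV`}
#'   \item{2}{`0 < HbO < HbR`, `0 < COE < CBV`}
#'   \item{3}{`HbO < 0 < HbR`, `0 < CBV < COE`}
#'   \item{4}{`HbO < 0 < HbR`, `CBV < 0 < COE`}
#'   \item{5}{`HbO < HbR < 0`, `CBV < 0 < COE`}
#'   \item{6}{`HbR < HbO < 0`, `CBV < COE < 0`}
#'   \item{7}{`HbR < 0 < HbO`, `COE < CBV < 0`}
#'   \item{8}{`HbR < 0 < HbO`, `COE < 0 < CBV`}
#' }
#'
#' @param hbo,hbr numeric vectors.
#' @return Integer vector in `1:8`, `NA` for boundary points.
#' @export
classify_phase <- function(hbo, hbr) {
  stopifnot(length(hbo) == length(hbr))
  rot <- to_cbv_coe(hbo, hbr)
  cbv <- rot$cbv; coe <- rot$coe
  out <- rep(NA_integer_, length(hbo))
  set <- function(cond, ph) {
    cond[is.na(cond)] <- FALSE
    out[cond] <<- ph
  }
  set(0 < hbr & hbr < hbo & coe < 0 & 0 < cbv, 1L)
  set(0 < hbo & hbo < hbr & 0 < coe & coe < cbv, 2L)
  set(hbo < 0 & 0 < hbr & 0 < cbv & cbv < coe, 3L)
  set(hbo < 0 & 0 < hbr & cbv < 0 & 0 < coe, 4L)
  set(hbo < hbr & hbr < 0 & cbv < 0 & 0 < coe, 5L)
  set(hbr < hbo & hbo < 0 & cbv < coe & coe < 0, 6L)
  set(hbr < 0 & 0 < hbo & coe < cbv & cbv < 0, 7L)
  set(hbr < 0 & 0 < hbo & coe < 0 & 0 < cbv, 8L)
  out
}

#' Phase-plane trajectory of an (HbO, HbR) pair
#'
#' @param hbo,hbr numeric vectors.
#' @param fs sampling rate in Hz.
#' @param t0_s time of the first sample in seconds (default 0); use a
#'   negative value to include pre-onset samples with onset at time 0.
#' @return A data.frame of class `phase_trajectory` with columns `time_s`,
#'   `hbo`, `hbr`, `cbv`, `coe`, `magnitude`, `angle_deg`, `phase`.
#' @export
phase_trajectory <- function(hbo, hbr, fs, t0_s = 0) {
  stopifnot(fs > 0, length(hbo) == length(hbr))
  rot <- to_cbv_coe(hbo, hbr)
  mp <- magnitude_phase(hbo, hbr)
  out <- data.frame(time_s = t0_s + (seq_along(hbo) - 1) / fs,
                    hbo = hbo, hbr = hbr, cbv = rot$cbv, coe = rot$coe,
                    magnitude = mp$magnitude, angle_deg = mp$angle_deg,
                    phase = classify_phase(hbo, hbr))
  class(out) <- c("phase_trajectory", "data.frame")
  out
}

#' Most task-responsive channel of a training session
#'
#' The channel maximizing the difference between the maximum HbO during
#' the first trial of the training session and the maximum HbO during the
#' resting state. Ties break to the lowest channel id.
#'
#' @param record an `fnirs_record` with a `"rest"` segment.
#' @param session training session name (default `"session1"`).
#' @return Integer channel id.
#' @export
select_most_active_channel <- function(record, session = "session1") {
  stopifnot(inherits(record, "fnirs_record"))
  rest_idx <- segment_indices(record, "rest")
  sess_idx <- segment_indices(record, session)
  cfg <- record$config
  n_trial <- if (!is.null(cfg)) floor((cfg$task_s + cfg$rest_s) * record$fs)
    else length(sess_idx)
  trial1 <- sess_idx[seq_len(min(n_trial, length(sess_idx)))]
  diffs <- apply(record$hbo[trial1, , drop = FALSE], 2, max) -
    apply(record$hbo[rest_idx, , drop = FALSE], 2, max)
  unname(which.max(diffs))  # which.max takes the first (lowest id) on ties
}

#' Inner threshold radius from resting-state samples
#'
#' `r1 = max(sqrt(HbO^2 + HbR^2))` over the resting period: the largest
#' resting-state excursion in the phase plane, below which fluctuations
#' are not task-related.
#'
#' @param hbo,hbr resting-state series.
#' @return Scalar radius.
#' @export
resting_radius <- function(hbo, hbr) {
  stopifnot(length(hbo) == length(hbr), length(hbo) >= 1)
  max(sqrt(hbo^2 + hbr^2))
}

#' Outer threshold radius
#'
#' `r2 = r1 + 0.3 * (p1 + SD)` where `p1` and `SD` are the peak and the
#' standard deviation of the trial-averaged HbO trace of the most active
#' channel.
#'
#' @param r1 inner radius.
#' @param p1 peak of the averaged HbO trial.
#' @param sd standard deviation of the averaged HbO trial.
#' @return Scalar radius `>= r1` whenever `p1 + sd >= 0`.
#' @export
outer_radius <- function(r1, p1, sd) {
  r1 + 0.3 * (p1 + sd)
}

# Trial-average a channel's series over a session; returns the averaged
# single-trial trace.
average_trial <- function(record, channel, session = "session1",
                          series = "hbo") {
  cfg <- record$config
  sess_idx <- segment_indices(record, session)
  n_trial <- if (!is.null(cfg)) floor((cfg$task_s + cfg$rest_s) * record$fs)
    else stop("record carries no paradigm configuration", call. = FALSE)
  n_trials <- length(sess_idx) %/% n_trial
  x <- record[[series]][sess_idx, channel]
  rowMeans(matrix(x[seq_len(n_trial * n_trials)], n_trial, n_trials))
}

#' Calibrate the dual threshold circles
#'
#' The inner radius `r1` bounds resting-state fluctuation and is computed
#' per channel from the resting segment by default (`mode =
#' "per-channel"`); `mode = "global"` uses the most active channel's `r1`
#' for every channel. The outer radius adds 30% of (peak + SD) of the
#' most active channel's trial-averaged HbO trace over the training
#' session.
#'
#' @param record an `fnirs_record` with a `"rest"` segment.
#' @param session training session (default `"session1"`).
#' @param most_active channel id; selected with
#'   [select_most_active_channel()] when `NULL`.
#' @param mode `"per-channel"` or `"global"`.
#' @return An object of class `threshold_circles`: `r1` (named vector, one
#'   per channel), `r2`, `p1`, `sd`, `most_active`, `mode`.
#' @export
calibrate_thresholds <- function(record, session = "session1",
                                 most_active = NULL,
                                 mode = c("per-channel", "global")) {
  stopifnot(inherits(record, "fnirs_record"))
  mode <- match.arg(mode)
  rest_idx <- segment_indices(record, "rest")
  if (length(rest_idx) == 0) stop("empty resting segment", call. = FALSE)
  if (is.null(most_active))
    most_active <- select_most_active_channel(record, session)
  avg <- average_trial(record, most_active, session, "hbo")
  p1 <- max(avg)
  sdv <- sd(avg)
  r1 <- vapply(seq_len(ncol(record$hbo)), function(ch)
    resting_radius(record$hbo[rest_idx, ch], record$hbr[rest_idx, ch]),
    numeric(1))
  names(r1) <- colnames(record$hbo)
  if (mode == "global") r1[] <- r1[most_active]
  r2 <- outer_radius(r1, p1, sdv)
  structure(list(r1 = r1, r2 = r2, p1 = p1, sd = sdv,
                 most_active = as.integer(most_active), mode = mode),
            class = "threshold_circles")
}

circle_radii <- function(circles, channel) {
  r1 <- if (length(circles$r1) == 1) unname(circles$r1)
    else unname(circles$r1[channel])
  r2 <- if (length(circles$r2) == 1) unname(circles$r2)
    else unname(circles$r2[channel])
  c(r1 = r1, r2 = r2)
}

#' Detect initial dips in a single-trial phase trajectory
#'
#' Rule: a candidate dip opens at the first sample within the candidate
#' window (`0 < t <= candidate_window_s` from task onset) whose phase is
#' 3, 4 or 5 and whose magnitude lies strictly between the inner and outer
#' circles (`r1 < |p| <= r2`). A candidate is rejected as a false dip if
#' the trajectory ever exceeds the outer circle within the candidate
#' window. It is confirmed if the trajectory reaches phase 7 or 8 beyond
#' the inner circle at some time in `[confirm_after_s, confirm_end_s]`
#' (the hemodynamic-response transition). The reported detection time is
#' the candidate opening time.
#'
#' @param traj a [phase_trajectory()] whose `time_s` is relative to task
#'   onset (onset at 0; pre-onset samples allowed and ignored).
#' @param r1,r2 threshold radii (scalars), or pass `circles` + `channel`.
#' @param circles optional `threshold_circles`.
#' @param channel channel id used to look radii up in `circles`.
#' @param candidate_window_s candidate window length (default 4 s).
#' @param confirm_after_s earliest confirming transition (default 2 s).
#' @param confirm_end_s latest confirming transition (default 10 s, the
#'   task duration).
#' @return A data.frame with zero or one row: `detection_time_s`, `phase`,
#'   `confirmed`, `reason` (`""`, `"false_dip"` or `"no_hr_transition"`),
#'   `hr_time_s` (`NA` if unconfirmed).
#' @export
detect_dips <- function(traj, r1 = NULL, r2 = NULL, circles = NULL,
                        channel = NULL, candidate_window_s = 4,
                        confirm_after_s = 2, confirm_end_s = 10) {
  stopifnot(inherits(traj, "phase_trajectory"))
  if (!is.null(circles)) {
    stopifnot(inherits(circles, "threshold_circles"), !is.null(channel))
    rr <- circle_radii(circles, channel)
    r1 <- rr[["r1"]]; r2 <- rr[["r2"]]
  }
  stopifnot(is.numeric(r1), is.numeric(r2), r2 >= r1)
  empty <- data.frame(detection_time_s = numeric(0), phase = integer(0),
                      confirmed = logical(0), reason = character(0),
                      hr_time_s = numeric(0))
  t <- traj$time_s
  win <- which(t > 0 & t <= candidate_window_s)
  if (!length(win)) return(empty)
  ok <- !is.na(traj$phase[win]) & traj$phase[win] %in% 3:5 &
    traj$magnitude[win] > r1 & traj$magnitude[win] <= r2
  if (!any(ok)) return(empty)
  first <- win[which(ok)[1]]
  event <- data.frame(detection_time_s = t[first],
                      phase = traj$phase[first],
                      confirmed = FALSE, reason = "",
                      hr_time_s = NA_real_)
  if (any(traj$magnitude[win] > r2)) {
    event$reason <- "false_dip"
    return(event)
  }
  conf <- which(t >= confirm_after_s & t <= confirm_end_s &
                  !is.na(traj$phase) & traj$phase %in% c(7L, 8L) &
                  traj$magnitude > r1)
  if (length(conf)) {
    event$confirmed <- TRUE
    event$hr_time_s <- t[conf[1]]
  } else {
    event$reason <- "no_hr_transition"
  }
  event
}

#' Detect dips in every trial of a session
#'
#' Slices the (measured or predicted) HbO/HbR series of one channel into
#' trials of the session and runs [detect_dips()] on each. For predicted
#' signals pass the decision-time-aligned series (see
#' [align_to_decision_time()]); detection then uses the predicted future
#' trajectory and can fire earlier than on measured data.
#'
#' @param record an `fnirs_record` (provides paradigm and timing).
#' @param channel channel id.
#' @param circles a `threshold_circles` object.
#' @param session session to scan (default `"session2"`, the test
#'   session).
#' @param hbo,hbr optional replacement series on the record's full grid
#'   (e.g. aligned predictions); default the record's measured series.
#' @param ... passed to [detect_dips()].
#' @return A data.frame with one row per detected event and columns
#'   `channel`, `trial`, plus the [detect_dips()] columns.
#' @export
detect_dips_session <- function(record, channel, circles,
                                session = "session2", hbo = NULL,
                                hbr = NULL, ...) {
  stopifnot(inherits(record, "fnirs_record"))
  cfg <- record$config
  if (is.null(cfg)) stop("record carries no paradigm configuration",
                         call. = FALSE)
  if (is.null(hbo)) hbo <- record$hbo[, channel]
  if (is.null(hbr)) hbr <- record$hbr[, channel]
  sess_idx <- segment_indices(record, session)
  n_trial <- floor((cfg$task_s + cfg$rest_s) * record$fs)
  n_trials <- length(sess_idx) %/% n_trial
  out <- list()
  for (tr in seq_len(n_trials)) {
    idx <- sess_idx[(tr - 1) * n_trial + seq_len(n_trial)]
    traj <- phase_trajectory(hbo[idx], hbr[idx], record$fs, t0_s = 0)
    ev <- detect_dips(traj, circles = circles, channel = channel, ...)
    if (nrow(ev)) {
      ev$channel <- channel
      ev$trial <- tr
      out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out))
    return(data.frame(channel = integer(0), trial = integer(0),
                      detection_time_s = numeric(0), phase = integer(0),
                      confirmed = logical(0), reason = character(0),
                      hr_time_s = numeric(0)))
  out <- do.call(rbind, out)
  out[, c("channel", "trial", "detection_time_s", "phase", "confirmed",
          "reason", "hr_time_s")]
}

#' Truncate a detection time for reporting
#'
#' Human-readable outputs truncate detection times to two decimals.
#'
#' @param x time(s) in seconds.
#' @param digits decimals kept (default 2).
#' @return Truncated value(s).
#' @export
truncate_time <- function(x, digits = 2L) {
  trunc(x * 10^digits) / 10^digits
}
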