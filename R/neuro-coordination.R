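.check_trace <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("time", "left", "right") %in% names(trace)),
            nrow(trace) >= 2)
  if (any(trace$left <= 0) || any(trace$right <= 0))
    stop("trace intensities must be > 0", call. = FALSE)
  invisible(trace)
}

#' Normalize a bilateral fluorescence trace to F/Fmin
#'
#' Each channel is divided by its own minimum frame intensity, so the
#' minimum of every normalized channel is exactly 1. Idempotent and
#' invariant to per-channel rescaling of the raw signal.
#'
#' @param trace data.frame with columns `time`, `left`, `right`
#'   (intensities > 0).
#' @return The trace with both channels normalized.
#' @examples
#' tr <- data.frame(time = 0:2, left = c(5, 10, 20), right = c(2, 2, 2))
#' normalize_trace(tr)$left  # 1 2 4
#' @export
normalize_trace <- function(trace) {
  .check_trace(trace)
  trace$left <- trace$left / min(trace$left)
  trace$right <- trace$right / min(trace$right)
  trace
}

#' Detect calcium events by threshold crossing
#'
#' An event is an upward crossing of `threshold` (the signal moves from
#' below to at-or-above), accepted only if at least `refractory` seconds
#' have elapsed since the previous accepted event in that channel.
#' Frequencies are event count divided by the trace duration. Intended
#' for normalized (F/Fmin) traces, where the resting level is 1.
#'
#' @param trace A normalized bilateral trace (see [normalize_trace()]).
#' @param threshold Fold-change threshold (> 1).
#' @param refractory Minimum inter-event interval, seconds (>= 0).
#' @return List with `left`/`right` event-time vectors (s), `f_left`,
#'   `f_right` (events/s) and `duration_s`.
#' @export
detect_events <- function(trace, threshold = 1.5, refractory = 0.5) {
  stopifnot(is.data.frame(trace), nrow(trace) >= 2,
            threshold > 1, refractory >= 0)
  dt <- diff(trace$time)
  duration <- trace$time[nrow(trace)] - trace$time[1] + stats::median(dt)
  cross_times <- function(x) {
    up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
    t_up <- trace$time[up]
    keep <- numeric(0); last <- -Inf
    for (t in t_up) {
      if (t - last >= refractory) { keep <- c(keep, t); last <- t }
    }
    keep
  }
  ev_l <- cross_times(trace$left)
  ev_r <- cross_times(trace$right)
  list(left = ev_l, right = ev_r,
       f_left = length(ev_l) / duration,
       f_right = length(ev_r) / duration,
       duration_s = duration)
}

#' Log-transformed left/right calcium event frequency ratio
#'
#' Returns `log(f_left / f_right)` (natural log by default; base
#' configurable). Zero indicates symmetric left-right activation;
#' swapping channels negates the value. A zero frequency on either side
#' leaves the ratio undefined: `NA` is returned with a `reason`
#' attribute.
#'
#' @param events Event series from [detect_events()] (or any list with
#'   `f_left`, `f_right`).
#' @param base Logarithm base (default `exp(1)`).
#' @return Log frequency ratio (possibly `NA` with a `reason`
#'   attribute).
#' @export
lr_frequency_ratio <- function(events, base = exp(1)) {
  f_l <- events$f_left; f_r <- events$f_right
  stopifnot(is.numeric(f_l), is.numeric(f_r), f_l >= 0, f_r >= 0)
  if (f_l == 0 || f_r == 0) {
    side <- paste(c("left", "right")[c(f_l, f_r) == 0], collapse = " and ")
    return(structure(NA_real_,
                     reason = paste0("zero event frequency on ", side,
                                     " channel")))
  }
  log(f_l / f_r, base = base)
}

#' Turning and locomotion statistics of a 2-D swim trajectory
#'
#' Headings are taken from consecutive displacements (`atan2`); the
#' turning angle at each interior vertex is the signed heading change
#' wrapped to (-180, 180] degrees, left (counter-clockwise) positive.
#' The relative turning angle is the sum of signed angles over the
#' whole path; absolute statistics average magnitudes. Angular velocity
#' of a turn is its magnitude divided by the duration of the following
#' step. Zero-length steps are skipped with a note.
#'
#' @param traj data.frame with columns `time` (strictly increasing, s),
#'   `x`, `y` (mm); at least 3 rows.
#' @return List with `total_distance_mm`, `mean_velocity_mm_s`,
#'   `relative_angle_deg`, `mean_abs_angle_deg`,
#'   `mean_abs_angular_velocity_deg_s` and `n_turns`.
#' @export
turning_statistics <- function(traj) {
  stopifnot(is.data.frame(traj),
            all(c("time", "x", "y") %in% names(traj)), nrow(traj) >= 3)
  if (any(diff(traj$time) <= 0))
    stop("turning_statistics: time must be strictly increasing",
         call. = FALSE)
  repeat {
    zero <- c(FALSE, diff(traj$x) == 0 & diff(traj$y) == 0)
    if (!any(zero)) break
    message("turning_statistics: skipping ", sum(zero),
            " zero-length step(s)")
    traj <- traj[!zero, , drop = FALSE]
  }
  if (nrow(traj) < 3)
    stop("turning_statistics: fewer than 2 non-degenerate steps",
         call. = FALSE)
  dx <- diff(traj$x); dy <- diff(traj$y); dt <- diff(traj$time)
  step_len <- sqrt(dx^2 + dy^2)
  heading <- atan2(dy, dx) * 180 / pi
  dtheta <- diff(heading)
  dtheta <- dtheta %% 360
  dtheta[dtheta > 180] <- dtheta[dtheta > 180] - 360
  total_dist <- sum(step_len)
  duration <- traj$time[nrow(traj)] - traj$time[1]
  list(total_distance_mm = total_dist,
       mean_velocity_mm_s = total_dist / duration,
       relative_angle_deg = sum(dtheta),
       mean_abs_angle_deg = mean(abs(dtheta)),
       mean_abs_angular_velocity_deg_s = mean(abs(dtheta) / dt[-1]),
       n_turns = length(dtheta))
}
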