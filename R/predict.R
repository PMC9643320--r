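#' Fine output grid aligned to frame boundaries
#'
#' Builds the simulation output grid used for frame averaging: at least
#' `points_per_frame` points per frame (11 by default, i.e. 10 sub-intervals).
#'
#' @param frames A [frame_schedule()].
#' @param t_offset Injection time of the scan on the absolute clock.
#' @param points_per_frame Grid points per frame (>= 3).
#' @return Sorted numeric vector of absolute times.
#' @export
frame_grid <- function(frames, t_offset = 0, points_per_frame = 11) {
  stopifnot(inherits(frames, "frame_schedule"), points_per_frame >= 3)
  sort(unique(unlist(lapply(seq_len(nrow(frames)), function(i)
    seq(frames$start[i], frames$start[i] + frames$duration[i],
        length.out = points_per_frame) + t_offset))))
}

#' Predict the PET signal over a frame schedule
#'
#' The model PET value in each frame is the time average over
#' `[start, start + duration]` of `(1 - vB) (C_ND + C_S) + vB C_WB`, i.e.
#' the tissue signal mixed with the whole-blood signal through the blood
#' volume fraction. Averages are computed by trapezoidal quadrature on a
#' fine within-frame grid (interpolating the trajectory where needed).
#'
#' @param traj A `state_trajectory` covering all frames.
#' @param whole_blood A [sampled_curve()] of whole-blood radioactivity on the
#'   absolute clock, or a single number, or `NULL` (only allowed with
#'   `vB = 0`).
#' @param frames A [frame_schedule()] (times relative to the scan injection).
#' @param vB Blood volume fraction (default 0.05).
#' @param t_offset Injection time of the scan on the absolute clock.
#' @param points_per_frame Quadrature points per frame.
#' @return Numeric vector of frame values (Bq/cm^3), one per frame.
#' @export
predict_pet <- function(traj, whole_blood, frames, vB = 0.05, t_offset = 0,
                        points_per_frame = 11) {
  stopifnot(inherits(traj, "state_trajectory"),
            inherits(frames, "frame_schedule"))
  if (is.null(whole_blood) && vB > 0)
    stop("whole_blood is required when vB > 0")
  t0 <- min(traj$t); t1 <- max(traj$t)
  fr_start <- frames$start + t_offset
  fr_end <- fr_start + frames$duration
  if (any(fr_start < t0 - 1e-9) || any(fr_end > t1 + 1e-9))
    stop(sprintf("frames span [%.4g, %.4g] min but trajectory covers [%.4g, %.4g]",
                 min(fr_start), max(fr_end), t0, t1))
  tissue <- traj$C_ND + traj$C_S
  vapply(seq_len(nrow(frames)), function(i) {
    tf <- seq(fr_start[i], fr_end[i], length.out = points_per_frame)
    ts <- approx(traj$t, tissue, xout = tf, rule = 2)$y
    wb <- if (vB == 0) 0
      else if (is.numeric(whole_blood)) whole_blood
      else interpolate_curve(whole_blood, tf)
    v <- (1 - vB) * ts + vB * wb
    trapz_mean(tf, v)
  }, numeric(1))
}

trapz_mean <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x)) / (x[n] - x[1])
}

#' Summarize the occupancy time course after dosing
#'
#' Computes the maximum target occupancy reached at or after the dosing time,
#' the time (after dosing) at which it is first attained, and the time of the
#' first crossing of half the maximum (linear interpolation between grid
#' points).
#'
#' @param traj A `state_trajectory` extending through the post-dose period.
#' @param dose_time Dosing (infusion start) time on the absolute clock, min.
#' @return A list with `O_max_pct` (percent), `t_max` and `t_half` (minutes
#'   after `dose_time`) and `defined` (FALSE when occupancy is identically
#'   zero, in which case the times are `NA` rather than 0).
#' @export
occupancy_metrics <- function(traj, dose_time) {
  stopifnot(inherits(traj, "state_trajectory"))
  sel <- traj$t >= dose_time
  if (!any(sel)) stop("trajectory does not extend past dose_time")
  t <- traj$t[sel]; o <- traj$O[sel]
  o_max <- max(o)
  if (o_max <= 0)
    return(list(O_max_pct = 0, t_max = NA_real_, t_half = NA_real_,
                defined = FALSE))
  i_max <- which.max(o)
  t_half <- crossing_time(t, o, o_max / 2)
  list(O_max_pct = 100 * o_max, t_max = t[i_max] - dose_time,
       t_half = t_half - dose_time, defined = TRUE)
}

crossing_time <- function(t, y, level) {
  above <- y >= level
  i <- which(above)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1L])
  # linear interpolation between the bracketing grid points
  t[i - 1L] + (level - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
}
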