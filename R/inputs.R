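#' Sampled concentration curve
#'
#' A time series of concentration samples on the absolute study clock
#' (minutes, injection of the first scan at t = 0). Interpolation between
#' samples is linear; outside the sampled range the curve is held at its
#' first/last value, except that curves flagged `zero_before` (drug plasma by
#' default) are zero before their first sample.
#'
#' @param times Sample times in minutes, strictly increasing.
#' @param values Non-negative concentrations; parent fractions must lie in
#'   `[0, 1]`.
#' @param kind One of `"tracer-plasma"`, `"whole-blood"`,
#'   `"parent-fraction"`, `"drug-plasma"`.
#' @param units Unit label; defaults to `"Bq/mL"` for radioactivity curves,
#'   `"nmol/L"` for drug plasma and `"fraction"` for parent fraction.
#' @param zero_before Return 0 for queries before the first sample instead of
#'   holding the first value.
#' @return Object of class `sampled_curve`.
#' @export
sampled_curve <- function(times, values,
                          kind = c("tracer-plasma", "whole-blood",
                                   "parent-fraction", "drug-plasma"),
                          units = NULL,
                          zero_before = kind[1L] == "drug-plasma") {
  kind <- match.arg(kind)
  if (length(times) == 0L) stop("sampled_curve: empty curve")
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(values < 0)) stop("values must be non-negative")
  if (kind == "parent-fraction" && any(values > 1))
    stop("parent-fraction values must lie in [0, 1]")
  if (is.null(units))
    units <- switch(kind, `tracer-plasma` = "Bq/mL", `whole-blood` = "Bq/mL",
                    `parent-fraction` = "fraction", `drug-plasma` = "nmol/L")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind, units = units,
                 zero_before = isTRUE(zero_before)),
            class = "sampled_curve")
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("sampled_curve [%s, %s]: %d samples over %.4g-%.4g min\n",
              x$kind, x$units, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Evaluate a sampled curve at arbitrary times
#'
#' Linear interpolation between samples; constant extrapolation outside the
#' sampled range (zero before the first sample for `zero_before` curves,
#' e.g. the drug input before the infusion starts).
#'
#' @param curve A [sampled_curve()].
#' @param t Query times (minutes), any order.
#' @return Numeric vector of values at `t`.
#' @examples
#' cv <- sampled_curve(c(10, 20), c(4, 8), kind = "tracer-plasma")
#' interpolate_curve(cv, 15)  # 6
#' @export
interpolate_curve <- function(curve, t) {
  stopifnot(inherits(curve, "sampled_curve"))
  if (length(curve$times) == 1L) {
    out <- rep(curve$values, length(t))
  } else {
    out <- approx(curve$times, curve$values, xout = t, rule = 2)$y
  }
  if (curve$zero_before) out[t < curve$times[1L]] <- 0
  out
}

#' Metabolite-correct a total plasma curve
#'
#' Multiplies a total plasma radioactivity curve by the parent (unmetabolized)
#' fraction, pointwise on the union of the two time grids, yielding the
#' tracer parent plasma input C_P.
#'
#' @param total_plasma [sampled_curve()] of total plasma radioactivity.
#' @param parent_fraction [sampled_curve()] of parent fraction in `[0, 1]`.
#' @return A `sampled_curve` of kind `"tracer-plasma"` on the union grid.
#' @export
metabolite_correct <- function(total_plasma, parent_fraction) {
  stopifnot(inherits(total_plasma, "sampled_curve"),
            inherits(parent_fraction, "sampled_curve"))
  if (any(parent_fraction$values < 0) || any(parent_fraction$values > 1))
    stop("parent fraction values must lie in [0, 1]")
  tt <- sort(unique(c(total_plasma$times, parent_fraction$times)))
  sampled_curve(tt,
                interpolate_curve(total_plasma, tt) *
                  interpolate_curve(parent_fraction, tt),
                kind = "tracer-plasma", units = total_plasma$units,
                zero_before = total_plasma$zero_before)
}

#' PET frame schedule
#'
#' Frame start times and durations in minutes, relative to the scan's own
#' injection. The default is the 33-frame, 120-min dynamic schedule
#' 6 x 0.5, 3 x 1, 2 x 2, 22 x 5 min.
#'
#' @param start Frame start times (minutes). `NULL` for the default schedule.
#' @param duration Frame durations (minutes).
#' @return A data frame of class `frame_schedule` with columns `start`,
#'   `duration`, `mid`.
#' @export
frame_schedule <- function(start = NULL, duration = NULL) {
  if (is.null(start)) {
    duration <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 22))
    start <- cumsum(c(0, duration[-length(duration)]))
  }
  if (length(start) != length(duration))
    stop("start and duration must have equal length")
  if (any(duration <= 0)) stop("frame durations must be positive")
  if (is.unsorted(start, strictly = TRUE))
    stop("frame start times must be strictly increasing")
  ends <- start + duration
  overlap <- which(start[-1L] < ends[-length(ends)] - 1e-9)
  if (length(overlap))
    stop("overlapping frames at indices: ",
         paste(overlap + 1L, collapse = ", "))
  structure(data.frame(start = start, duration = duration,
                       mid = start + duration / 2),
            class = c("frame_schedule", "data.frame"))
}

#' Default arterial sampling times for the tracer input
#'
#' Every 10 s for the first 90 s, then 1.75, 2, 2.25, 2.75, 3, 4, 5, 6, 8,
#' 10, 15, 20, 25, 30, 45, 60, 75, 90, 105 and 120 min post-injection.
#'
#' @return Numeric vector of minutes (including 0).
#' @export
arterial_sample_times <- function() {
  c(0, seq(1 / 6, 1.5, by = 1 / 6),
    1.75, 2, 2.25, 2.75, 3, 4, 5, 6, 8, 10, 15, 20, 25, 30, 45, 60, 75, 90,
    105, 120)
}

#' Tracer arterial input shape for synthesis
#'
#' Parameters of the bolus impulse response used to synthesize arterial
#' input functions: a linear rise over `t_peak` minutes followed by a
#' tri-exponential decline `sum(A_i exp(-lambda_i (t - t_peak)))`. The
#' default amplitude puts the late-scan parent plasma concentration around
#' 1-2 kBq/mL, typical of an SV2A tracer study.
#'
#' @param amplitude Peak plasma concentration of the pure bolus response,
#'   Bq/mL.
#' @param fractions Relative weights of the three exponentials (normalized
#'   internally).
#' @param lambdas Decay rates of the three exponentials, 1/min.
#' @param t_peak Rise time, minutes.
#' @return A list of class `tracer_shape`.
#' @export
tracer_input_shape <- function(amplitude = 30000,
                               fractions = c(0.80, 0.15, 0.05),
                               lambdas = c(0.9, 0.09, 0.009),
                               t_peak = 1) {
  stopifnot(amplitude > 0, length(fractions) == length(lambdas),
            all(fractions > 0), all(lambdas > 0), t_peak > 0)
  structure(list(A = amplitude * fractions / sum(fractions),
                 lambdas = lambdas, t_peak = t_peak),
            class = "tracer_shape")
}

#' Evaluate the bolus impulse response and its running integral
#' @noRd
bolus_response <- function(shape, t) {
  h0 <- sum(shape$A)
  u <- t - shape$t_peak
  h <- ifelse(t <= 0, 0,
       ifelse(t < shape$t_peak, h0 * t / shape$t_peak,
              colSums(shape$A * exp(-outer(shape$lambdas, pmax(u, 0))))))
  h
}

bolus_response_integral <- function(shape, t) {
  # analytic running integral of bolus_response
  h0 <- sum(shape$A)
  tp <- shape$t_peak
  ramp <- h0 / (2 * tp) * pmin(pmax(t, 0), tp)^2
  u <- pmax(t - tp, 0)
  tail <- colSums(shape$A / shape$lambdas *
                    (1 - exp(-outer(shape$lambdas, u))))
  ramp + tail * (t > tp)
}

#' Fraction of the tracer dose given as bolus under bolus + infusion
#'
#' With the bolus magnitude equal to `Kbol` minutes of the constant infusion
#' rate and the infusion running for `duration` minutes, the bolus carries
#' `Kbol / (Kbol + duration)` of the total administered dose.
#'
#' @param Kbol Bolus-to-infusion ratio, minutes.
#' @param duration Infusion (scan) duration, minutes.
#' @return The bolus dose fraction.
#' @export
bolus_fraction <- function(Kbol, duration) {
  stopifnot(Kbol > 0, duration >= 0)
  Kbol / (Kbol + duration)
}

#' Synthesize a bolus-plus-infusion tracer plasma curve
#'
#' Models the arterial plasma concentration under the bolus + constant
#' infusion protocol: the plasma curve is the bolus impulse response plus
#' the running integral of that response scaled by `1/Kbol` (the infusion
#' component), so the curve approaches a plateau late in the scan. Use
#' `Kbol = Inf` for a pure bolus.
#'
#' @param shape A [tracer_input_shape()].
#' @param Kbol Bolus-to-infusion ratio, minutes (> 0 or `Inf`).
#' @param scan_duration Scan length, minutes.
#' @param t0 Injection time on the absolute study clock, minutes.
#' @param sample_times Sampling times relative to injection; defaults to
#'   [arterial_sample_times()] clipped to the scan.
#' @return A `sampled_curve` of kind `"tracer-plasma"` on the absolute
#'   clock, with the continuous generator attached as attribute `"fun"`
#'   (a function of absolute time) and the analytic plateau as attribute
#'   `"plateau"`.
#' @export
bolus_infusion_input <- function(shape = tracer_input_shape(), Kbol = 150,
                                 scan_duration = 120, t0 = 0,
                                 sample_times = NULL) {
  stopifnot(inherits(shape, "tracer_shape"))
  if (!is.numeric(Kbol) || length(Kbol) != 1L || Kbol <= 0)
    stop("Kbol must be a single positive number (possibly Inf)")
  if (is.null(sample_times))
    sample_times <- arterial_sample_times()
  sample_times <- sample_times[sample_times <= scan_duration]
  inf_rate <- if (is.finite(Kbol)) 1 / Kbol else 0
  fun <- function(t_abs) {
    tt <- t_abs - t0
    bolus_response(shape, tt) + inf_rate * bolus_response_integral(shape, tt)
  }
  vals <- fun(t0 + sample_times)
  out <- sampled_curve(t0 + sample_times, vals, kind = "tracer-plasma",
                       zero_before = TRUE)
  attr(out, "fun") <- fun
  attr(out, "plateau") <- inf_rate *
    (sum(shape$A / shape$lambdas) + sum(shape$A) * shape$t_peak / 2)
  out
}
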