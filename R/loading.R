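# Amplitude-shift-keying loading envelopes V_rms(t) and the
# voltage-to-shear-stress law.

new_loading_profile <- function(segments, type) {
  # segments: list of list(t0, t1, fn) with fn(t) the envelope on [t0, t1)
  t0 <- vapply(segments, `[[`, numeric(1), "t0")
  t1 <- vapply(segments, `[[`, numeric(1), "t1")
  if (any(t1 <= t0)) stop("segment durations must be > 0", call. = FALSE)
  if (length(segments) > 1 &&
      any(abs(t0[-1] - t1[-length(t1)]) > 1e-12))
    stop("segments must be contiguous and non-overlapping", call. = FALSE)
  structure(list(segments = segments, duration = t1[length(t1)], type = type),
            class = "loading_profile")
}

#' Evaluate a loading profile envelope
#'
#' @param profile A `loading_profile`.
#' @param t Time(s) in s; values outside `[0, duration]` return 0.
#'
#' @return Envelope voltage(s) in V_rms.
#' @export
profile_voltage <- function(profile, t) {
  stopifnot(inherits(profile, "loading_profile"))
  out <- numeric(length(t))
  for (seg in profile$segments) {
    inseg <- t >= seg$t0 & t < seg$t1
    if (any(inseg)) out[inseg] <- seg$fn(t[inseg])
  }
  # close the final segment on the right
  last <- profile$segments[[length(profile$segments)]]
  atend <- t == last$t1
  if (any(atend)) out[atend] <- last$fn(t[atend])
  pmax(out, 0)
}

#' @export
print.loading_profile <- function(x, ...) {
  cat(sprintf("<loading_profile> type = %s, %d segment(s), duration = %g s\n",
              x$type, length(x$segments), x$duration))
  invisible(x)
}

#' @export
plot.loading_profile <- function(x, n = 500, ...) {
  t <- seq(0, x$duration, length.out = n)
  graphics::plot(t, profile_voltage(x, t), type = "l",
                 xlab = "time (s)", ylab = "V_rms (V)", ...)
  invisible(x)
}

#' Step (on/off) loading profile
#'
#' A constant envelope held for `on_duration`, then zero for `off_duration` —
#' sudden application and sudden release of the DEP load.
#'
#' @param voltage Envelope level in V_rms (>= 0).
#' @param on_duration,off_duration Durations in s (> 0).
#'
#' @return A `loading_profile`.
#' @examples
#' make_step_profile(2, 1, 1)
#' @export
make_step_profile <- function(voltage, on_duration = 1, off_duration = 1) {
  if (!is.finite(voltage) || voltage < 0)
    stop("'voltage' must be >= 0", call. = FALSE)
  if (on_duration <= 0 || off_duration <= 0)
    stop("durations must be > 0", call. = FALSE)
  force(voltage)
  segs <- list(
    list(t0 = 0, t1 = on_duration, fn = function(t) rep(voltage, length(t))),
    list(t0 = on_duration, t1 = on_duration + off_duration,
         fn = function(t) rep(0, length(t))))
  new_loading_profile(segs, "step")
}

#' Symmetric stepwise (staircase) loading profile
#'
#' Voltage rises through `levels` and descends symmetrically, each level held
#' for `step_duration`, with a zero step at each end: for levels (0.5, 1, 2)
#' and 1 s steps the profile is 0, 0.5, 1, 2, 1, 0.5, 0 V_rms over 7 s.
#'
#' @param levels Voltage levels in V_rms, all >= 0.
#' @param step_duration Hold time per step in s.
#'
#' @return A `loading_profile`.
#' @export
make_stepwise_profile <- function(levels = c(0.5, 1, 2), step_duration = 1) {
  if (length(levels) == 0) stop("'levels' must be non-empty", call. = FALSE)
  if (any(!is.finite(levels) | levels < 0))
    stop("'levels' must all be >= 0", call. = FALSE)
  if (step_duration <= 0) stop("'step_duration' must be > 0", call. = FALSE)
  seq_levels <- c(0, levels, rev(levels[-length(levels)]), 0)
  segs <- lapply(seq_along(seq_levels), function(k) {
    v <- seq_levels[k]
    force(v)
    list(t0 = (k - 1) * step_duration, t1 = k * step_duration,
         fn = function(t) rep(v, length(t)))
  })
  new_loading_profile(segs, "stepwise")
}

#' Triangular loading profile
#'
#' Linear rise from 0 to `peak` over half the cycle, linear fall back to 0:
#' a constant-strain-rate load/unload. The 2 V_rms, 20 s default corresponds
#' to the ramp V = 0.2 t (t < 10 s), 4 - 0.2 t (10-20 s).
#'
#' @param peak Peak envelope voltage in V_rms.
#' @param cycle Full cycle duration in s.
#'
#' @return A `loading_profile`.
#' @export
make_triangular_profile <- function(peak = 2, cycle = 20) {
  if (!is.finite(peak) || peak <= 0 || !is.finite(cycle) || cycle <= 0)
    stop("'peak' and 'cycle' must be > 0", call. = FALSE)
  half <- cycle / 2
  segs <- list(
    list(t0 = 0, t1 = half, fn = function(t) peak * t / half),
    list(t0 = half, t1 = cycle, fn = function(t) peak * (2 - t / half)))
  new_loading_profile(segs, "triangular")
}

#' Sinusoidal loading profile
#'
#' Half-sine envelope `V(t) = peak * sin(pi t / half_period)` on
#' `[0, half_period]`: one variable-strain-rate load/unload cycle, truncated
#' at the first zero crossing (the envelope never goes negative). Defaults
#' correspond to V = 2 sin(pi t / 5).
#'
#' @param peak Peak envelope voltage in V_rms.
#' @param half_period Duration of one load-unload cycle in s.
#'
#' @return A `loading_profile`.
#' @export
make_sinusoidal_profile <- function(peak = 2, half_period = 5) {
  if (!is.finite(peak) || peak <= 0 || !is.finite(half_period) ||
      half_period <= 0)
    stop("'peak' and 'half_period' must be > 0", call. = FALSE)
  segs <- list(list(t0 = 0, t1 = half_period,
                    fn = function(t) peak * sin(pi * t / half_period)))
  new_loading_profile(segs, "sinusoidal")
}

#' Custom loading profile from sampled points
#'
#' Linear interpolation through `(time, vrms)` samples, e.g. loaded from a
#' CSV with columns `time_s, vrms`.
#'
#' @param time Sample times in s, strictly increasing, starting at 0.
#' @param vrms Envelope samples in V_rms, all >= 0.
#'
#' @return A `loading_profile`.
#' @export
make_custom_profile <- function(time, vrms) {
  if (length(time) < 2 || any(diff(time) <= 0))
    stop("'time' must be strictly increasing with >= 2 samples", call. = FALSE)
  if (any(vrms < 0)) stop("'vrms' must be >= 0", call. = FALSE)
  f <- stats::approxfun(time, vrms, rule = 2)
  segs <- list(list(t0 = time[1], t1 = time[length(time)], fn = f))
  new_loading_profile(segs, "custom")
}

#' Quadratic voltage-to-shear-stress law
#'
#' Membrane shear stress as a function of the applied envelope voltage:
#' `sigma(V) = p2 V^2 + p1 V + p0` (in uN/m) on its fitted domain
#' `V >= v_min`. Below `v_min` the fitted polynomial does not apply (it was
#' calibrated on 0.5-3 V_rms and has a nonzero intercept); the default
#' `"bridge"` closure replaces it with a quadratic through the origin matched
#' continuously at `v_min`, so that zero field gives zero stress. The
#' `"raw_poly"` closure evaluates the polynomial everywhere.
#'
#' @param p2,p1,p0 Polynomial coefficients in uN/m (per V^2, per V, and
#'   constant). Defaults are the fitted red-blood-cell law
#'   3.65 V^2 - 2.63 V + 0.71.
#' @param v_min Lower edge of the fitted voltage domain in V_rms.
#' @param closure `"bridge"` or `"raw_poly"` (see Details).
#'
#' @return An object of class `stress_law`.
#' @export
stress_law <- function(p2 = 3.65, p1 = -2.63, p0 = 0.71, v_min = 0.5,
                       closure = c("bridge", "raw_poly")) {
  closure <- match.arg(closure)
  stopifnot(is.finite(p2), is.finite(p1), is.finite(p0), v_min >= 0)
  structure(list(p2 = p2, p1 = p1, p0 = p0, v_min = v_min,
                 closure = closure),
            class = "stress_law")
}

#' @export
print.stress_law <- function(x, ...) {
  cat(sprintf(
    "<stress_law> sigma(V) = %g V^2 + %g V + %g uN/m (V >= %g, %s closure)\n",
    x$p2, x$p1, x$p0, x$v_min, x$closure))
  invisible(x)
}

#' Membrane shear stress from envelope voltage
#'
#' @param law A [stress_law].
#' @param voltage Envelope voltage(s) in V_rms (>= 0).
#'
#' @return Shear stress in SI units (N/m).
#' @examples
#' stress_from_voltage(stress_law(), 2) # 10.05 uN/m
#' @export
stress_from_voltage <- function(law, voltage) {
  stopifnot(inherits(law, "stress_law"))
  if (any(voltage < 0)) stop("'voltage' must be >= 0", call. = FALSE)
  poly <- function(v) law$p2 * v^2 + law$p1 * v + law$p0
  s <- if (law$closure == "raw_poly" || law$v_min == 0) {
    poly(voltage)
  } else {
    s_min <- poly(law$v_min)
    ifelse(voltage >= law$v_min, poly(voltage),
           s_min * (voltage / law$v_min)^2)
  }
  s * 1e-6
}
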