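#  signal_core: sampled-signal container, zero-phase filtering, stance
#  detection, integration and laser-speed differentiation. These primitives
#  are shared by every downstream stage, so contracts are strict.

#' Uniformly sampled signal
#'
#' Container for a uniformly sampled time series: a numeric vector (one
#' channel) or an N x 3 matrix (a 3-axis channel such as a ground reaction
#' force with columns x = anteroposterior, y = mediolateral, z = vertical).
#'
#' @param values numeric vector or N x 3 numeric matrix; all values finite.
#' @param rate sampling rate in Hz (> 0).
#' @param start_time time of the first sample in seconds.
#' @param units unit label carried along for reporting (e.g. "N", "m").
#' @return object of class `sampled_signal` with fields `values`, `rate`,
#'   `start_time`, `units`.
#' @examples
#' s <- sampled_signal(sin(seq(0, 1, by = 0.001)), rate = 1000)
#' signal_times(s)[1:3]
#' @export
sampled_signal <- function(values, rate, start_time = 0, units = "") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.numeric(values)) jm_stop("invalid_input", "signal values must be numeric")
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (n < 2) jm_stop("invalid_input", "a sampled signal needs at least 2 samples")
  if (!all(is.finite(values))) jm_stop("invalid_input", "signal values must be finite")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    jm_stop("invalid_parameter", "sampling rate must be a single positive number")
  structure(list(values = values, rate = as.numeric(rate),
                 start_time = as.numeric(start_time), units = units),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  n <- signal_length(x)
  ch <- if (is.matrix(x$values)) ncol(x$values) else 1L
  cat(sprintf("<sampled_signal> %d samples x %d channel(s) @ %g Hz, t0 = %g s%s\n",
              n, ch, x$rate, x$start_time,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @rdname sampled_signal
#' @param signal a `sampled_signal`.
#' @export
signal_length <- function(signal) {
  if (is.matrix(signal$values)) nrow(signal$values) else length(signal$values)
}

#' @rdname sampled_signal
#' @export
signal_times <- function(signal) {
  signal$start_time + (seq_len(signal_length(signal)) - 1) / signal$rate
}

#' Stance interval
#'
#' One ground contact: touchdown and toe-off expressed both as sample
#' indices (first/last sample above threshold) and as sub-sample times
#' refined by linear interpolation of the threshold crossing.
#'
#' @param touchdown_index,toeoff_index integer sample indices, toe-off after
#'   touchdown.
#' @param touchdown_time,toeoff_time refined crossing times in seconds.
#' @return object of class `stance_interval` with a `duration` field
#'   (seconds, from refined times).
#' @export
stance_interval <- function(touchdown_index, toeoff_index,
                            touchdown_time, toeoff_time) {
  if (toeoff_index <= touchdown_index)
    jm_stop("invalid_input", "toe-off must come after touchdown")
  structure(list(touchdown_index = as.integer(touchdown_index),
                 toeoff_index = as.integer(toeoff_index),
                 touchdown_time = touchdown_time, toeoff_time = toeoff_time,
                 duration = toeoff_time - touchdown_time),
            class = "stance_interval")
}

#' @export
print.stance_interval <- function(x, ...) {
  cat(sprintf("<stance> [%.4f s, %.4f s] (%.1f ms, samples %d..%d)\n",
              x$touchdown_time, x$toeoff_time, 1000 * x$duration,
              x$touchdown_index, x$toeoff_index))
  invisible(x)
}

# Odd-reflection padded forward-backward IIR pass. signal::filtfilt does no
# end-condition handling and corrupts the edges; this mirrors the usual
# MATLAB-style reflection about the end points. Pad length scales with the
# filter's time constant (~1/Wn samples).
padded_filtfilt <- function(b, a, x, wn) {
  n <- length(x)
  np <- min(n - 1L, as.integer(ceiling(12 / wn)))
  pre <- 2 * x[1] - x[(np + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filter(b, a, c(pre, x, post))
  y <- rev(signal::filter(b, a, rev(y)))
  unclass(y)[(np + 1):(np + n)]
}

#' Low-pass Butterworth filter
#'
#' Filters each channel of a signal with a recursive digital Butterworth
#' low-pass filter. By default the filter is applied forward and backward
#' (zero phase) with the stated net order, i.e. a Butterworth design of
#' order/2 run in both directions, so that kinetic and kinematic channels
#' destined for inverse dynamics share identical, lag-free filtering.
#' Typical cut-offs in this pipeline: 50 Hz for forces and marker
#' trajectories, 1 Hz for laser-gun speed.
#'
#' @param signal a [sampled_signal()].
#' @param cutoff cut-off frequency in Hz; must be below the Nyquist
#'   frequency `rate/2`.
#' @param order net filter order; must be even when `zero_phase = TRUE`.
#' @param zero_phase logical; `FALSE` gives a conventional single forward
#'   pass of the full stated order (with its phase lag).
#' @return a `sampled_signal` of identical length, rate and start time.
#' @examples
#' s <- sampled_signal(rep(2.5, 100), rate = 1000)
#' range(lowpass_filter(s, 50, 4)$values)  # DC gain is 1
#' @export
lowpass_filter <- function(signal, cutoff, order = 4, zero_phase = TRUE) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= signal$rate / 2)
    jm_stop("invalid_parameter",
            sprintf("cutoff must lie in (0, %g) Hz (below Nyquist)", signal$rate / 2))
  if (order < 1 || (zero_phase && order %% 2 != 0))
    jm_stop("invalid_parameter", "zero-phase filtering needs an even net order")
  wn <- 2 * cutoff / signal$rate
  design_order <- if (zero_phase) order / 2 else order
  bf <- signal::butter(design_order, wn, type = "low")
  run <- function(x) {
    if (zero_phase) padded_filtfilt(bf$b, bf$a, x, wn)
    else unclass(signal::filter(bf$b, bf$a, x))
  }
  v <- signal$values
  out <- if (is.matrix(v)) apply(v, 2, run) else run(v)
  sampled_signal(out, signal$rate, signal$start_time, signal$units)
}

# resultant magnitude of a 1- or 3-channel signal
resultant_magnitude <- function(values) {
  if (is.matrix(values)) sqrt(rowSums(values^2)) else abs(values)
}

#' Detect stance phases from a ground-reaction-force record
#'
#' Finds the maximal intervals where the resultant GRF magnitude exceeds a
#' threshold (20 N by convention in this pipeline). Sub-threshold dips
#' shorter than `debounce` are merged into the surrounding contact, and the
#' touchdown/toe-off times are refined to sub-sample precision by linear
#' interpolation between the bracketing samples (at 1 kHz one sample is
#' about 1% of a sprint contact).
#'
#' @param grf a [sampled_signal()] holding forces in N (vector or N x 3).
#' @param threshold contact threshold in N (> 0), default 20.
#' @param debounce minimum flight/gap duration in seconds; shorter
#'   sub-threshold dips are bridged. Default 0.005 s.
#' @return list of [stance_interval()]s in time order (empty if no contact).
#' @export
detect_stances <- function(grf, threshold = 20, debounce = 0.005) {
  stopifnot(inherits(grf, "sampled_signal"))
  if (!is.numeric(threshold) || threshold <= 0)
    jm_stop("invalid_parameter", "threshold must be positive")
  res <- resultant_magnitude(grf$values)
  above <- res > threshold
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # debounce: merge contacts separated by a sub-threshold gap < debounce
  if (nrow(runs) > 1) {
    keep <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - keep$end[nrow(keep)] - 1) / grf$rate
      if (gap < debounce) keep$end[nrow(keep)] <- runs$end[i]
      else keep <- rbind(keep, runs[i, ])
    }
    runs <- keep
  }
  t <- signal_times(grf)
  dt <- 1 / grf$rate
  # Sub-sample refinement: extrapolate the secant through the two nearest
  # above-threshold samples to the threshold level. Interpolating against
  # the below-threshold neighbour instead would bias the crossing when the
  # plate is dead (exactly zero) outside the contact. Clamped to the
  # bracketing sample interval; falls back to simple interpolation when the
  # local slope is uninformative.
  lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    td <- t[s]
    if (s > 1) {
      slope <- if (e > s) (res[s + 1] - res[s]) / dt else NA_real_
      td <- if (is.finite(slope) && slope > 0) t[s] - (res[s] - threshold) / slope
            else t[s] - dt * (res[s] - threshold) / max(res[s] - res[s - 1], threshold)
      td <- min(max(td, t[s - 1]), t[s])
    }
    to <- t[e]
    if (e < length(res)) {
      slope <- if (e > s) (res[e - 1] - res[e]) / dt else NA_real_
      to <- if (is.finite(slope) && slope > 0) t[e] + (res[e] - threshold) / slope
            else t[e] + dt * (res[e] - threshold) / max(res[e] - res[e + 1], threshold)
      to <- min(max(to, t[e]), t[e + 1])
    }
    stance_interval(s, e, td, to)
  })
}

# trapezoid integral of y sampled at uniform spacing dt
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}

#' Integrate a signal over a stance interval
#'
#' Trapezoidal time-integral of a (single-channel) signal over the samples
#' of a stance interval, e.g. to turn force into impulse.
#'
#' @param signal a [sampled_signal()] (vector-valued).
#' @param interval a [stance_interval()] within the signal's bounds.
#' @return the integral in signal-units x s.
#' @export
integrate_signal <- function(signal, interval) {
  stopifnot(inherits(signal, "sampled_signal"), inherits(interval, "stance_interval"))
  n <- signal_length(signal)
  if (interval$touchdown_index < 1 || interval$toeoff_index > n)
    jm_stop("invalid_input", "interval exceeds signal bounds")
  idx <- interval$touchdown_index:interval$toeoff_index
  if (length(idx) < 2) return(0)
  v <- if (is.matrix(signal$values)) signal$values[idx, 1] else signal$values[idx]
  trapz_uniform(v, 1 / signal$rate)
}

# trapezoid integral of one channel over the REFINED stance interval:
# the sample-span integral plus the partial edge trapezoids between the
# interpolated crossing times and the first/last above-threshold samples
integrate_refined <- function(vals, rate, start_time, interval) {
  dt <- 1 / rate
  i0 <- interval$touchdown_index; i1 <- interval$toeoff_index
  t0 <- start_time + (i0 - 1) * dt
  t1 <- start_time + (i1 - 1) * dt
  total <- trapz_uniform(vals[i0:i1], dt)
  d0 <- t0 - interval$touchdown_time
  if (d0 > 0 && i0 > 1) {
    v_td <- vals[i0] + (vals[i0 - 1] - vals[i0]) * d0 / dt
    total <- total + d0 * (v_td + vals[i0]) / 2
  }
  d1 <- interval$toeoff_time - t1
  if (d1 > 0 && i1 < length(vals)) {
    v_to <- vals[i1] + (vals[i1 + 1] - vals[i1]) * d1 / dt
    total <- total + d1 * (vals[i1] + v_to) / 2
  }
  total
}

# central-difference derivative (one-sided at the ends), uniform sampling
central_diff <- function(y, dt) {
  n <- length(y)
  if (n < 3) jm_stop("invalid_input", "need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d
}

#' Running speed from a laser-gun position trace
#'
#' Differentiates a raw laser-distance record by central differences and
#' smooths the speed with a zero-phase 4th-order Butterworth low-pass
#' filter (1 Hz cut-off by default, matching the heavy smoothing used for
#' laser speed traces).
#'
#' The reported maximum is taken over the interior of the record: one
#' filter time-constant (`1/cutoff`) is excluded at each end, where the
#' one-sided difference and the filter's end conditions make the speed
#' estimate unreliable on noisy distance data.
#'
#' @param position a [sampled_signal()] of distance in m (>= 3 samples).
#' @param cutoff speed-smoothing cut-off in Hz.
#' @param order net filter order (even).
#' @return list with `speed` (a `sampled_signal`, m/s) and `max_speed` (m/s).
#' @export
laser_speed <- function(position, cutoff = 1, order = 4) {
  stopifnot(inherits(position, "sampled_signal"))
  if (signal_length(position) < 3)
    jm_stop("invalid_input", "laser trace needs at least 3 samples")
  v <- central_diff(as.numeric(position$values), 1 / position$rate)
  sp <- lowpass_filter(sampled_signal(v, position$rate, position$start_time, "m/s"),
                       cutoff = cutoff, order = order)
  n <- signal_length(sp)
  trim <- min(ceiling(position$rate / cutoff), floor((n - 1) / 4))
  list(speed = sp, max_speed = max(sp$values[(1 + trim):(n - trim)]))
}
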