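#  grf_metrics: per-stance force descriptors, between-leg asymmetry,
#  spatiotemporal parameters, and the ideal spring-mass reference waveform.

#' Stance-averaged vertical support force (ASF)
#'
#' Time-average (trapezoidal integral divided by the span) of the
#' (filtered) vertical GRF over a stance phase, normalized by bodyweight.
#' ASF is the primary support-force descriptor for comparing legs and
#' athletes.
#'
#' @param grf_vertical [sampled_signal()] of vertical force in N (a matrix
#'   signal uses its last column, the vertical channel).
#' @param interval [stance_interval()].
#' @param bodyweight bodyweight in N from the static trial (> 0).
#' @return ASF in bodyweights (BW).
#' @export
stance_average_force <- function(grf_vertical, interval, bodyweight) {
  if (!is.numeric(bodyweight) || bodyweight <= 0)
    jm_stop("invalid_parameter", "bodyweight must be positive")
  v <- if (is.matrix(grf_vertical$values)) grf_vertical$values[, ncol(grf_vertical$values)]
       else grf_vertical$values
  integrate_refined(v, grf_vertical$rate, grf_vertical$start_time, interval) /
    interval$duration / bodyweight
}

#' Vertical and net horizontal impulse of a stance
#'
#' Trapezoidal time-integrals of the vertical and anteroposterior force
#' components over a stance, normalized by bodyweight. Braking-dominated
#' contacts give a negative net horizontal impulse.
#'
#' @param grf [sampled_signal()], N x 3 matrix (x = anteroposterior,
#'   z = vertical) or a list of per-axis signals.
#' @param interval [stance_interval()].
#' @param bodyweight bodyweight in N (> 0).
#' @return list with `vertical_impulse` and `net_horizontal_impulse`, BW s.
#' @export
impulses <- function(grf, interval, bodyweight) {
  if (!is.numeric(bodyweight) || bodyweight <= 0)
    jm_stop("invalid_parameter", "bodyweight must be positive")
  stopifnot(is.matrix(grf$values), ncol(grf$values) == 3)
  list(vertical_impulse =
         integrate_refined(grf$values[, 3], grf$rate, grf$start_time,
                           interval) / bodyweight,
       net_horizontal_impulse =
         integrate_refined(grf$values[, 1], grf$rate, grf$start_time,
                           interval) / bodyweight)
}

#' Directional between-leg asymmetry of ASF
#'
#' Signed percent difference of the take-off-leg ASF relative to the
#' non-take-off-leg ASF:
#' `100 * (asf_takeoff - asf_non_takeoff) / asf_non_takeoff`.
#' Negative values mean the non-take-off leg applies the greater support
#' force.
#'
#' @param asf_takeoff,asf_non_takeoff ASF of the two legs in BW (> 0).
#' @return asymmetry in percent.
#' @examples
#' directional_asymmetry(2.17, 2.39)  # -9.2 %
#' @export
directional_asymmetry <- function(asf_takeoff, asf_non_takeoff) {
  if (any(c(asf_takeoff, asf_non_takeoff) <= 0))
    jm_stop("invalid_parameter", "ASF values must be positive")
  100 * (asf_takeoff - asf_non_takeoff) / asf_non_takeoff
}

#' Fluctuating (absolute) between-leg asymmetry over athletes
#'
#' Mean and sample SD of the absolute directional asymmetry across a set of
#' athletes, ignoring which leg is the take-off leg.
#'
#' @param per_athlete_pairs list of length-2 numeric vectors
#'   `(asf_takeoff, asf_non_takeoff)` in BW, one per athlete.
#' @return list with `mean` and `sd` in percent (`sd` is `NA` for a single
#'   athlete).
#' @export
fluctuating_asymmetry <- function(per_athlete_pairs) {
  if (length(per_athlete_pairs) < 1)
    jm_stop("invalid_input", "need at least one athlete")
  a <- vapply(per_athlete_pairs,
              function(p) abs(directional_asymmetry(p[1], p[2])), numeric(1))
  list(mean = mean(a), sd = if (length(a) > 1) stats::sd(a) else NA_real_)
}

#' Spatiotemporal stride parameters
#'
#' Stride time is the interval between successive ipsilateral touchdowns
#' (one left and one right contact plus two aerial phases); stride
#' frequency is its reciprocal and step frequency is twice the stride
#' frequency. Contact length is the CoM horizontal displacement during
#' stance when a CoM trace is supplied, with speed x contact time as the
#' documented fallback.
#'
#' @param stance_events data.frame with columns `leg` (character),
#'   `touchdown`, `toeoff` (seconds), one row per contact, in time order.
#' @param speed running speed in m/s (used for the fallback contact length).
#' @param com_ap optional [sampled_signal()] of CoM anteroposterior
#'   position in m for measured contact lengths.
#' @return list with `stride_time`, `stride_frequency`, `step_frequency`,
#'   `contact_time`, `swing_time`, `contact_length`,
#'   `contact_length_source`; stride-based fields are `NA` when no complete
#'   ipsilateral stride exists.
#' @export
spatiotemporal <- function(stance_events, speed = NA_real_, com_ap = NULL) {
  stopifnot(is.data.frame(stance_events),
            all(c("leg", "touchdown", "toeoff") %in% names(stance_events)))
  ev <- stance_events[order(stance_events$touchdown), ]
  strides <- c()
  for (leg in unique(ev$leg)) {
    td <- ev$touchdown[ev$leg == leg]
    if (length(td) >= 2) strides <- c(strides, diff(td))
  }
  t_stride <- if (length(strides)) mean(strides) else NA_real_
  contact_time <- mean(ev$toeoff - ev$touchdown)
  if (!is.null(com_ap)) {
    tt <- signal_times(com_ap)
    disp <- vapply(seq_len(nrow(ev)), function(i) {
      x0 <- stats::approx(tt, as.numeric(com_ap$values), ev$touchdown[i])$y
      x1 <- stats::approx(tt, as.numeric(com_ap$values), ev$toeoff[i])$y
      x1 - x0
    }, numeric(1))
    contact_length <- mean(disp, na.rm = TRUE)
    cl_src <- "com_kinematics"
  } else {
    contact_length <- if (is.finite(speed)) speed * contact_time else NA_real_
    cl_src <- "speed_x_time"
  }
  list(stride_time = t_stride,
       stride_frequency = if (is.na(t_stride)) NA_real_ else 1 / t_stride,
       step_frequency = if (is.na(t_stride)) NA_real_ else 2 / t_stride,
       contact_time = contact_time,
       swing_time = if (is.na(t_stride)) NA_real_ else t_stride - contact_time,
       contact_length = contact_length,
       contact_length_source = cl_src)
}

#' Ideal spring-mass vertical GRF reference
#'
#' Half-sine vertical GRF over the contact whose stance impulse equals
#' bodyweight x step time (contact + aerial), i.e. peak
#' `BW * (pi/2) * t_step / t_contact`. Used as the idealized reference
#' waveform against which measured sprint GRF patterns are compared.
#'
#' @param contact_time,aerial_time seconds (contact > 0, aerial >= 0).
#' @param bodyweight N (> 0).
#' @param rate sampling rate of the generated waveform, Hz.
#' @return [sampled_signal()] of vertical force in N over `[0, contact_time]`.
#' @export
spring_mass_reference <- function(contact_time, aerial_time, bodyweight,
                                  rate = 1000) {
  if (contact_time <= 0 || aerial_time < 0 || bodyweight <= 0)
    jm_stop("invalid_parameter", "times and bodyweight must be positive")
  peak <- bodyweight * (pi / 2) * (contact_time + aerial_time) / contact_time
  t <- seq(0, contact_time, by = 1 / rate)
  sampled_signal(peak * sin(pi * t / contact_time), rate, 0, "N")
}
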