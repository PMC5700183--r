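#  jump_takeoff: take-off state from the initial flight vector, ballistic
#  flight time, jump distance, and the full take-off-step summary.

#' Take-off state from the initial flight-phase CoM vector
#'
#' The flight vector is the CoM displacement over the first 25 ms after the
#' last ground contact. The take-off angle is the angle of that raw
#' displacement vector. Take-off velocities are recovered from the same
#' displacement: the horizontal component is displacement / 0.025 s
#' (exact for drag-free flight), and the vertical component is
#' gravity-corrected (`v0 = dz / t + g t / 2`, the exact inversion of the
#' ballistic parabola), so that the recovered velocities propagate the true
#' flight curve.
#'
#' @param com_ap,com_vert [sampled_signal()]s of CoM anteroposterior and
#'   vertical position (m) on one time base, extending at least 25 ms past
#'   `toeoff_time`.
#' @param toeoff_time time of last contact in s.
#' @param toe_tip_ap anteroposterior position of the most anterior point of
#'   the foot or prosthesis during the take-off contact (m).
#' @param flight_window displacement window in s (default 0.025).
#' @return object of class `takeoff_state`: `com0_ap`, `com0_vert` (m),
#'   `v_ap`, `v_vert`, `v_res` (m/s), `alpha` (deg), `toe_tip_ap` (m).
#' @export
takeoff_state <- function(com_ap, com_vert, toeoff_time, toe_tip_ap,
                          flight_window = 0.025) {
  t_ap <- signal_times(com_ap); t_v <- signal_times(com_vert)
  t1 <- toeoff_time + flight_window
  if (max(t_ap) < t1 || max(t_v) < t1)
    jm_stop("invalid_input",
            "CoM trajectory must extend past toe-off by the flight window")
  at <- function(tt, x, when) stats::approx(tt, as.numeric(x$values), when)$y
  x0 <- at(t_ap, com_ap, toeoff_time); x1 <- at(t_ap, com_ap, t1)
  z0 <- at(t_v, com_vert, toeoff_time); z1 <- at(t_v, com_vert, t1)
  if (z0 <= 0) jm_stop("invalid_input", "CoM take-off height must be positive")
  dx <- x1 - x0; dz <- z1 - z0
  v_ap <- dx / flight_window
  v_vert <- dz / flight_window + GRAVITY * flight_window / 2
  structure(list(com0_ap = x0, com0_vert = z0,
                 v_ap = v_ap, v_vert = v_vert,
                 v_res = sqrt(v_ap^2 + v_vert^2),
                 alpha = atan2(dz, dx) * 180 / pi,
                 toe_tip_ap = toe_tip_ap),
            class = "takeoff_state")
}

#' @export
print.takeoff_state <- function(x, ...) {
  cat(sprintf(paste0("<takeoff_state> h %.3f m, v_ap %.2f m/s, v_vert %.2f m/s,",
                     " alpha %.2f deg\n"), x$com0_vert, x$v_ap, x$v_vert, x$alpha))
  invisible(x)
}

#' Ballistic flight time to ground intersection
#'
#' Positive root of the drag-free vertical flight equation
#' `h0 + v_vert t - g t^2 / 2 = 0` (gravity acting downward).
#'
#' @param h0 CoM take-off height in m (>= 0).
#' @param v_vert vertical take-off velocity in m/s.
#' @return flight time in s (0 when the parabola never leaves the ground).
#' @examples
#' flight_time(1.18, 3.00)  # 0.884 s
#' @export
flight_time <- function(h0, v_vert) {
  if (h0 < 0) jm_stop("invalid_parameter", "take-off height cannot be negative")
  disc <- v_vert^2 + 2 * GRAVITY * h0
  t <- (v_vert + sqrt(disc)) / GRAVITY
  max(t, 0)
}

#' Theoretical jump distance from the take-off state
#'
#' Distance from the most anterior point of the foot or prosthesis during
#' take-off contact to the intersection of the CoM flight parabola with the
#' ground; landing technique is deliberately outside the computation.
#'
#' @param state a [takeoff_state()].
#' @return jump distance in m.
#' @export
jump_distance <- function(state) {
  stopifnot(inherits(state, "takeoff_state"))
  (state$com0_ap - state$toe_tip_ap) +
    state$v_ap * flight_time(state$com0_vert, state$v_vert)
}

#' Full take-off-step summary
#'
#' Computes the scalar descriptors of one long-jump take-off step: contact
#' time, touchdown velocities, horizontal velocity loss, take-off angle and
#' height, impulses and ASF, the vertical-to-braking impulse ratio, CoM
#' works, and the theoretical jump distance.
#'
#' @param grf [sampled_signal()], N x 3 take-off-plate forces in N.
#' @param com_ap,com_vert [sampled_signal()]s of CoM position (m) covering
#'   the stance and at least 25 ms of flight.
#' @param bodyweight static-trial bodyweight in N.
#' @param mass body mass in kg (default `bodyweight / 9.81`).
#' @param toe_tip_ap most anterior foot/prosthesis point during contact (m).
#' @param max_speed optional maximum sprint speed in m/s (for the
#'   touchdown/maximum velocity ratio).
#' @param threshold stance-detection threshold in N.
#' @param detection_grf signal used for stance detection (default `grf`);
#'   pass the unfiltered record here when `grf` is low-pass filtered, since
#'   filter edge ringing dilates threshold crossings at 20 N.
#' @return list of take-off descriptors (see Details in the vignette);
#'   degenerate ratios (zero braking impulse) are reported as `NA` with
#'   `ratio_flag = "no_braking"`.
#' @export
takeoff_summary <- function(grf, com_ap, com_vert, bodyweight,
                            mass = bodyweight / GRAVITY, toe_tip_ap,
                            max_speed = NULL, threshold = 20,
                            detection_grf = grf) {
  stances <- detect_stances(detection_grf, threshold)
  if (length(stances) != 1)
    jm_stop("invalid_input", sprintf("expected one take-off stance, found %d",
                                     length(stances)))
  st <- stances[[1]]
  dt_k <- 1 / com_ap$rate
  v_ap_series <- central_diff(as.numeric(com_ap$values), dt_k)
  v_vert_series <- central_diff(as.numeric(com_vert$values), dt_k)
  tt <- signal_times(com_ap)
  v_td_ap <- stats::approx(tt, v_ap_series, st$touchdown_time)$y
  v_td_vert <- stats::approx(tt, v_vert_series, st$touchdown_time)$y
  state <- takeoff_state(com_ap, com_vert, st$toeoff_time, toe_tip_ap)
  imp <- impulses(grf, st, bodyweight)
  asf <- stance_average_force(
    sampled_signal(grf$values[, 3], grf$rate, grf$start_time), st, bodyweight)
  idx <- st$touchdown_index:st$toeoff_index
  asf_res <- mean(resultant_magnitude(grf$values[idx, , drop = FALSE])) / bodyweight
  # CoM velocity resampled onto the force time base for the work split
  tf <- signal_times(grf)
  v_on_f <- cbind(stats::approx(tt, v_ap_series, tf, rule = 2)$y, 0,
                  stats::approx(tt, v_vert_series, tf, rule = 2)$y)
  vsig <- sampled_signal(v_on_f, grf$rate, grf$start_time, "m/s")
  work <- com_work(grf, vsig, st, mass)
  coll <- collision_angle(grf, vsig, st, mass)
  braking <- imp$net_horizontal_impulse
  e_td <- com_energies(1, stats::approx(tt, as.numeric(com_vert$values),
                                        st$touchdown_time)$y,
                       v_td_ap, v_td_vert)
  list(contact_time = st$duration,
       v_td_ap = v_td_ap, v_td_vert = v_td_vert,
       v_loss_hor = state$v_ap - v_td_ap,
       takeoff_angle = state$alpha,
       takeoff_height = state$com0_vert,
       com_takeoff_offset = state$com0_ap - toe_tip_ap,
       v_toeoff_vert = state$v_vert,
       vertical_impulse = imp$vertical_impulse,
       net_horizontal_impulse = braking,
       peak_vertical_force = max(grf$values[idx, 3]) / bodyweight,
       asf = asf, asf_resultant = asf_res,
       ratio_vert_to_braking = if (braking != 0) abs(imp$vertical_impulse / braking)
                               else NA_real_,
       ratio_flag = if (braking != 0) NA_character_ else "no_braking",
       ratio_td_to_max = if (!is.null(max_speed)) 100 * v_td_ap / max_speed
                         else NA_real_,
       E_total_touchdown = e_td$E_total,
       negative_com_work = work$negative_work,
       positive_com_work = work$positive_work,
       net_com_work = work$net_work,
       ratio_com_work = work$ratio_pos_neg,
       collision_angle = coll,
       distance = jump_distance(state),
       state = state)
}
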