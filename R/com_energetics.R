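#  com_energetics: CoM mechanical energies, external-force CoM work split
#  into absorption and generation, and collision angles.

#' Centre-of-mass mechanical energies
#'
#' Potential energy `m g h`, horizontal kinetic energy `m v_hor^2 / 2`,
#' vertical kinetic energy `m v_vert^2 / 2` and their sum. With `m = 1`
#' the results are mass-specific (J/kg).
#'
#' @param mass body mass in kg (> 0).
#' @param height CoM height above the track surface in m (>= 0).
#' @param v_hor,v_vert horizontal and vertical CoM velocity in m/s.
#' @return list with `E_pot`, `E_kin_hor`, `E_kin_vert`, `E_total` (J).
#' @examples
#' com_energies(1, 0, v_hor = 9.32, v_vert = 0)$E_kin_hor  # 43.4 J/kg
#' @export
com_energies <- function(mass, height, v_hor, v_vert) {
  if (mass <= 0) jm_stop("invalid_parameter", "mass must be positive")
  if (height < 0) jm_stop("invalid_parameter", "CoM height cannot be negative")
  e <- list(E_pot = mass * GRAVITY * height,
            E_kin_hor = mass * v_hor^2 / 2,
            E_kin_vert = mass * v_vert^2 / 2)
  e$E_total <- e$E_pot + e$E_kin_hor + e$E_kin_vert
  e
}

# instantaneous mass-specific CoM power from GRF and CoM velocity.
# Default (GRF only): the integral is the rate of change of TOTAL CoM
# energy (kinetic + potential), since gravity's power is -dE_pot/dt.
# include_gravity = TRUE adds the weight vector, making the integral the
# change of kinetic energy alone.
com_power_series <- function(grf, v_com, interval, mass, include_gravity = FALSE) {
  stopifnot(is.matrix(grf$values), is.matrix(v_com$values))
  if (grf$rate != v_com$rate || abs(grf$start_time - v_com$start_time) > 1e-9)
    jm_stop("invalid_input", "GRF and CoM velocity series must share one time base")
  if (signal_length(grf) != signal_length(v_com))
    jm_stop("invalid_input", "GRF and CoM velocity series must have equal length")
  idx <- interval$touchdown_index:interval$toeoff_index
  f <- grf$values[idx, , drop = FALSE]
  if (include_gravity) f[, 3] <- f[, 3] - mass * GRAVITY
  v <- v_com$values[idx, , drop = FALSE]
  rowSums(f * v) / mass
}

#' External work performed on the centre of mass
#'
#' Mass-specific CoM power is the dot product of the ground reaction force
#' and the CoM velocity divided by body mass; with this (default)
#' convention the net CoM work over an interval equals the change of total
#' CoM energy (kinetic + potential), because gravity's power is exactly
#' `-dE_pot/dt`. Negative work (absorption) and positive work (generation)
#' are the time-integrals of the negative and positive portions of the
#' power curve.
#'
#' @param grf [sampled_signal()], N x 3 forces in N.
#' @param v_com [sampled_signal()], N x 3 CoM velocity in m/s on the same
#'   time base.
#' @param interval [stance_interval()].
#' @param mass body mass in kg.
#' @param include_gravity add the weight vector to the external force
#'   (default `FALSE`); if `TRUE` the net work equals the kinetic-energy
#'   change alone.
#' @return list with `negative_work` (<= 0), `positive_work` (>= 0),
#'   `net_work` (all J/kg) and `ratio_pos_neg`
#'   (`100 * positive / |negative|`, percent; `NA` with a flag when there is
#'   no absorption).
#' @export
com_work <- function(grf, v_com, interval, mass, include_gravity = FALSE) {
  p <- com_power_series(grf, v_com, interval, mass, include_gravity)
  dt <- 1 / grf$rate
  neg <- trapz_uniform(pmin(p, 0), dt)
  pos <- trapz_uniform(pmax(p, 0), dt)
  list(negative_work = neg, positive_work = pos, net_work = pos + neg,
       ratio_pos_neg = if (neg < 0) 100 * pos / abs(neg) else NA_real_)
}

#' Magnitude-weighted collision angle during energy absorption
#'
#' The collision angle at each sample is the deviation from
#' perpendicularity between the GRF vector and the CoM velocity vector:
#' 0 deg means the force is perpendicular to the motion (a perfectly
#' "smooth" redirection), 90 deg means the force directly opposes the
#' motion (a full collision). The per-sample angles are averaged over the
#' energy-absorption phase (samples with negative CoM power) with weights
#' `|F| |v|`.
#'
#' @inheritParams com_work
#' @param absorption_interval optional [stance_interval()] delimiting the
#'   absorption phase; all its samples are used. When `NULL`, the
#'   absorption phase is auto-detected as the stance samples with negative
#'   GRF power (gravity excluded: the collision concept concerns how the
#'   contact force redirects the CoM).
#' @param interval [stance_interval()] delimiting the stance.
#' @return weighted mean collision angle in degrees, or `NA` when there is
#'   no absorption phase.
#' @export
collision_angle <- function(grf, v_com, interval, mass,
                            absorption_interval = NULL) {
  idx <- if (is.null(absorption_interval))
    interval$touchdown_index:interval$toeoff_index
  else absorption_interval$touchdown_index:absorption_interval$toeoff_index
  f <- grf$values[idx, , drop = FALSE]
  v <- v_com$values[idx, , drop = FALSE]
  fn <- sqrt(rowSums(f^2)); vn <- sqrt(rowSums(v^2))
  ok <- fn > 0 & vn > 0
  p <- rowSums(f * v)
  sel <- if (is.null(absorption_interval)) ok & p < 0 else ok
  if (!any(sel)) return(NA_real_)
  ct <- pmin(1, pmax(-1, p[sel] / (fn[sel] * vn[sel])))
  ang <- acos(ct) * 180 / pi - 90       # deviation from perpendicular
  w <- fn[sel] * vn[sel]
  sum(w * ang) / sum(w)
}
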