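#  synthetic_data: generators for sprint and jump trials and reference
#  populations, each carrying closed-form ground truth so every pipeline
#  stage can be validated without laboratory recordings.

#' Synthetic maximum-speed sprint trial
#'
#' Generates alternating-leg stance GRFs, a laser-gun position trace and
#' ground-truth spatiotemporal parameters. Each stance is a half-sine
#' vertical force (the ideal spring-mass pattern typical of the affected
#' leg on a running-specific prosthesis) whose impulse satisfies
#' impulse-momentum over the step: when per-leg ASF values are supplied the
#' aerial time after each step follows from `t_step = ASF x t_contact`, so
#' the mean vertical force over any full stride is exactly 1 BW.
#' The `impact_peak = "two_mass"` option superimposes the early narrow
#' impact transient seen in non-amputee sprinters (approximated by a
#' Gaussian bump) and rescales the main half-sine so the stance impulse is
#' preserved. The anteroposterior channel is a braking-then-propulsion
#' full sine with zero net impulse.
#'
#' @param body_mass kg.
#' @param top_speed maximum running speed in m/s (laser ground truth).
#' @param contact_time ground contact time per step in s.
#' @param aerial_time aerial time per step in s; ignored when `asf` is
#'   given (then `aerial = contact x (ASF - 1)` per leg).
#' @param asf optional named numeric length-2 vector of per-leg
#'   stance-average vertical forces in BW (names become the leg labels,
#'   e.g. `c(takeoff = 2.17, non_takeoff = 2.39)`); each must exceed 1 BW.
#' @param impact_peak `"none"` (pure half-sine) or `"two_mass"`.
#' @param noise_sd force-plate noise SD in N.
#' @param laser_noise_sd laser distance noise SD in m.
#' @param n_steps number of steps to generate (first step uses the first
#'   leg in `asf`).
#' @param seed integer seed fixing all randomness.
#' @param rate force sampling rate in Hz; `laser_rate` laser rate in Hz.
#' @param laser_duration laser record length in s.
#' @return list with `forces` (named list of per-leg N x 3
#'   [sampled_signal()]s), `laser` (position trace), `bodyweight` (N),
#'   `body_mass`, and `truth` (per-leg ASF, events data.frame, stride and
#'   step parameters, top speed).
#' @export
make_sprint_trial <- function(body_mass = 80.1, top_speed = 10.15,
                              contact_time = 0.099, aerial_time = 0.126,
                              asf = NULL, impact_peak = c("none", "two_mass"),
                              noise_sd = 2, laser_noise_sd = 0.003,
                              n_steps = 6, seed = 1, rate = 1000,
                              laser_rate = 100, laser_duration = 12) {
  impact_peak <- match.arg(impact_peak)
  if (contact_time <= 0 || aerial_time < 0 || body_mass <= 0)
    jm_stop("invalid_parameter", "times and mass must be positive")
  set.seed(as.integer(seed))
  bw <- body_mass * GRAVITY
  if (is.null(asf)) {
    asf <- rep((contact_time + aerial_time) / contact_time, 2)
    names(asf) <- c("left", "right")
  }
  if (length(asf) != 2 || any(asf <= 1))
    jm_stop("infeasible_spec",
            "per-leg ASF must be two values > 1 BW (aerial time must be positive)")
  legs <- names(asf)
  t_step <- asf * contact_time            # per-leg step time from impulse-momentum
  lead <- 0.05
  total <- lead + sum(rep(t_step, length.out = n_steps)) + lead
  n <- ceiling(total * rate) + 1
  tgrid <- (seq_len(n) - 1) / rate
  f <- lapply(legs, function(l) matrix(0, n, 3))
  names(f) <- legs
  events <- data.frame(leg = character(0), touchdown = numeric(0),
                       toeoff = numeric(0))
  t0 <- lead
  for (k in seq_len(n_steps)) {
    leg <- legs[(k - 1) %% 2 + 1]
    peak <- asf[[leg]] * bw * pi / 2
    rel <- tgrid - t0
    inside <- rel >= 0 & rel <= contact_time
    fz <- ifelse(inside, peak * sin(pi * rel / contact_time), 0)
    if (impact_peak == "two_mass") {
      ctr <- 0.15 * contact_time; width <- 0.04 * contact_time
      bump <- ifelse(inside, 1.4 * bw * exp(-0.5 * ((rel - ctr) / width)^2), 0)
      target <- asf[[leg]] * bw * contact_time
      scale <- (target - trapz_uniform(bump, 1 / rate)) /
        trapz_uniform(fz, 1 / rate)
      fz <- scale * fz + bump
    }
    fx <- ifelse(inside, -0.3 * bw * sin(2 * pi * rel / contact_time), 0)
    f[[leg]][, 1] <- f[[leg]][, 1] + fx
    f[[leg]][, 3] <- f[[leg]][, 3] + fz
    events <- rbind(events, data.frame(leg = leg, touchdown = t0,
                                       toeoff = t0 + contact_time))
    t0 <- t0 + t_step[[leg]]
  }
  forces <- lapply(f, function(m) {
    if (noise_sd > 0) m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow(m))
    sampled_signal(m, rate, 0, "N")
  })
  # laser trace: smooth speed ramp saturating at top_speed, integrated
  tl <- (seq_len(ceiling(laser_duration * laser_rate) + 1) - 1) / laser_rate
  tau <- 2
  pos <- top_speed * tau * log(cosh(tl / tau))   # integral of top_speed*tanh(t/tau)
  if (laser_noise_sd > 0) pos <- pos + rnorm(length(pos), 0, laser_noise_sd)
  stride_time <- sum(t_step)
  list(forces = forces,
       laser = sampled_signal(pos, laser_rate, 0, "m"),
       bodyweight = bw, body_mass = body_mass,
       truth = list(asf = asf, events = events,
                    contact_time = contact_time,
                    stride_time = stride_time,
                    step_frequency = 2 / stride_time,
                    top_speed = top_speed))
}

#' Synthetic long-jump take-off trial
#'
#' Builds a take-off-step GRF record and a CoM trajectory that are exactly
#' consistent: half-sine vertical and (braking) anteroposterior forces are
#' scaled so their impulses produce precisely the requested velocity
#' changes, the stance-phase CoM path is the closed-form double integral of
#' those forces, and the post-toe-off path is the exact ballistic parabola.
#' The ground-truth jump distance follows in closed form.
#'
#' @param v_td_hor horizontal CoM velocity at touchdown, m/s.
#' @param v_loss_hor magnitude of the horizontal velocity loss over the
#'   stance, m/s (>= 0).
#' @param v_vert_toeoff vertical CoM velocity at toe-off, m/s.
#' @param v_td_vert vertical CoM velocity at touchdown, m/s (negative =
#'   descending).
#' @param contact_time stance duration in s.
#' @param takeoff_height CoM height at toe-off, m.
#' @param com_offset horizontal CoM-to-toe-tip distance at toe-off, m.
#' @param body_mass kg.
#' @param noise_sd force-plate noise SD in N.
#' @param seed integer seed.
#' @param rate force rate Hz; `kin_rate` kinematic rate Hz.
#' @return list with `grf` (N x 3 [sampled_signal()]), `com_ap`,
#'   `com_vert` ([sampled_signal()]s, time 0 = touchdown), `toe_tip_ap`,
#'   `bodyweight`, `body_mass`, and `truth` (all spec inputs plus
#'   `v_toeoff_hor`, `flight_time`, `distance`, `asf`, signed
#'   `v_loss_signed`).
#' @export
make_jump_trial <- function(v_td_hor = 9.32, v_loss_hor = 0.64,
                            v_vert_toeoff = 3.00, v_td_vert = -0.68,
                            contact_time = 0.118, takeoff_height = 1.18,
                            com_offset = 0.30, body_mass = 78.7,
                            noise_sd = 2, seed = 1, rate = 1000,
                            kin_rate = 250) {
  if (v_loss_hor < 0) jm_stop("invalid_parameter", "v_loss_hor is a magnitude (>= 0)")
  if (contact_time <= 0 || takeoff_height <= 0 || body_mass <= 0)
    jm_stop("invalid_parameter", "contact time, height and mass must be positive")
  set.seed(as.integer(seed))
  m <- body_mass; tc <- contact_time; g <- GRAVITY
  dv_z <- v_vert_toeoff - v_td_vert
  Pz <- pi * m * (dv_z + g * tc) / (2 * tc)   # vertical half-sine peak
  if (Pz <= 0) jm_stop("infeasible_spec", "requested velocity change needs negative force")
  Ax <- pi * m * v_loss_hor / (2 * tc)        # braking half-sine peak
  # stance closed forms (t relative to touchdown)
  vz <- function(t) v_td_vert - g * t + Pz * tc / (m * pi) * (1 - cos(pi * t / tc))
  zz <- function(t) v_td_vert * t - g * t^2 / 2 +
    Pz * tc / (m * pi) * (t - tc / pi * sin(pi * t / tc))
  xx <- function(t) v_td_hor * t - Ax * tc / (m * pi) * (t - tc / pi * sin(pi * t / tc))
  z0 <- takeoff_height - zz(tc)               # touchdown height
  v_to_x <- v_td_hor - v_loss_hor
  x_to <- xx(tc)
  lead <- 0.05; tail_t <- 0.15
  # force record
  nf <- ceiling((lead + tc + lead) * rate) + 1
  tf <- (seq_len(nf) - 1) / rate - lead
  inside <- tf >= 0 & tf <= tc
  fmat <- cbind(ifelse(inside, -Ax * sin(pi * tf / tc), 0), 0,
                ifelse(inside, Pz * sin(pi * tf / tc), 0))
  if (noise_sd > 0) fmat <- fmat + matrix(rnorm(length(fmat), 0, noise_sd), nf)
  # kinematics: ballistic approach, closed-form stance, exact parabola after
  nk <- ceiling((lead + tc + tail_t) * kin_rate) + 1
  tk <- (seq_len(nk) - 1) / kin_rate - lead
  com_x <- ifelse(tk < 0, v_td_hor * tk,
           ifelse(tk <= tc, xx(tk), x_to + v_to_x * (tk - tc)))
  com_z <- ifelse(tk < 0, z0 + v_td_vert * tk - g * tk^2 / 2,
           ifelse(tk <= tc, z0 + zz(tk),
                  takeoff_height + v_vert_toeoff * (tk - tc) -
                    g * (tk - tc)^2 / 2))
  tf_flight <- flight_time(takeoff_height, v_vert_toeoff)
  list(grf = sampled_signal(fmat, rate, -lead, "N"),
       com_ap = sampled_signal(com_x, kin_rate, -lead, "m"),
       com_vert = sampled_signal(com_z, kin_rate, -lead, "m"),
       toe_tip_ap = x_to - com_offset,
       bodyweight = m * g, body_mass = m,
       truth = list(v_td_hor = v_td_hor, v_td_vert = v_td_vert,
                    v_loss_hor = v_loss_hor, v_loss_signed = -v_loss_hor,
                    v_toeoff_hor = v_to_x, v_vert_toeoff = v_vert_toeoff,
                    contact_time = tc, takeoff_height = takeoff_height,
                    com_offset = com_offset,
                    asf = (2 * Pz / pi) / (m * g),
                    flight_time = tf_flight,
                    distance = com_offset + v_to_x * tf_flight))
}

#' Synthetic reference population for the velocity-loss regression
#'
#' Draws touchdown velocities and take-off angles uniformly over configured
#' ranges and generates signed horizontal velocity losses from a linear
#' model with Gaussian residuals. The default coefficients place the
#' population around a mean loss of about -1.1 m/s at 9.4 m/s / 18 deg,
#' with losses growing with approach speed and take-off angle.
#'
#' @param n population size (>= 4).
#' @param intercept,coef_v_td,coef_alpha linear-model coefficients
#'   (loss in m/s, signed negative).
#' @param noise_sd residual SD in m/s.
#' @param seed integer seed.
#' @param v_td_range,alpha_range sampling ranges for touchdown velocity
#'   (m/s) and take-off angle (deg).
#' @param source_label value for the `source_label` column.
#' @return data.frame with columns `v_td`, `alpha`, `v_loss`,
#'   `source_label`.
#' @export
make_reference_population <- function(n = 40, intercept = 1.22,
                                      coef_v_td = -0.15, coef_alpha = -0.05,
                                      noise_sd = 0.1, seed = 1,
                                      v_td_range = c(8.8, 10.8),
                                      alpha_range = c(16, 22),
                                      source_label = "synthetic_reference") {
  if (n < 4) jm_stop("invalid_input", "need n >= 4")
  set.seed(as.integer(seed))
  v_td <- runif(n, v_td_range[1], v_td_range[2])
  alpha <- runif(n, alpha_range[1], alpha_range[2])
  v_loss <- intercept + coef_v_td * v_td + coef_alpha * alpha +
    rnorm(n, 0, noise_sd)
  data.frame(v_td = v_td, alpha = alpha, v_loss = v_loss,
             source_label = source_label)
}

#' Parameter presets mirroring the study's printed per-athlete values
#'
#' `jump_presets()` returns [make_jump_trial()] argument lists for the
#' three athletes with BKA (`"P1"`, `"P2"`, `"P3"`, best jumps) and the
#' non-amputee group mean (`"nonamputee_mean"`); `sprint_presets()` returns
#' [make_sprint_trial()] argument lists with the per-leg ASF values and top
#' speeds (take-off leg = affected leg for athletes with BKA).
#'
#' @return named list of argument lists.
#' @export
jump_presets <- function() {
  list(
    P1 = list(v_td_hor = 9.32, v_loss_hor = 0.64, v_vert_toeoff = 3.00,
              v_td_vert = -0.68, contact_time = 0.118, takeoff_height = 1.18,
              com_offset = 0.30, body_mass = 78.7),
    P2 = list(v_td_hor = 8.61, v_loss_hor = 0.59, v_vert_toeoff = 3.08,
              v_td_vert = -0.52, contact_time = 0.127, takeoff_height = 1.24,
              com_offset = 0.26, body_mass = 78.7),
    P3 = list(v_td_hor = 8.22, v_loss_hor = 0.57, v_vert_toeoff = 2.55,
              v_td_vert = -0.36, contact_time = 0.147, takeoff_height = 1.18,
              com_offset = 0.39, body_mass = 78.7),
    nonamputee_mean = list(v_td_hor = 9.39, v_loss_hor = 1.09,
                           v_vert_toeoff = 3.01, v_td_vert = -0.37,
                           contact_time = 0.125, takeoff_height = 1.18,
                           com_offset = 0.29, body_mass = 80.1))
}

#' @rdname jump_presets
#' @export
sprint_presets <- function() {
  list(
    P1 = list(top_speed = 9.98, asf = c(takeoff = 2.17, non_takeoff = 2.39),
              contact_time = 0.098, body_mass = 78.7),
    P2 = list(top_speed = 9.27, asf = c(takeoff = 2.11, non_takeoff = 2.37),
              contact_time = 0.113, body_mass = 78.7),
    P3 = list(top_speed = 8.89, asf = c(takeoff = 1.82, non_takeoff = 2.34),
              contact_time = 0.113, body_mass = 78.7),
    nonamputee_mean = list(top_speed = 10.15,
                           asf = c(takeoff = 2.24, non_takeoff = 2.24),
                           contact_time = 0.099, body_mass = 80.1,
                           impact_peak = "two_mass"))
}
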