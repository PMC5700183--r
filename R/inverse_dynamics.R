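#  inverse_dynamics: cuboid-composite prosthesis inertia, joint centres,
#  bottom-up Newton-Euler link-segment pass, joint power/work, and the
#  sagittal-plane MTP work convention.
#
#  Frames: world axes x = anteroposterior, y = mediolateral, z = vertical
#  (up). Segment inertia tensors are given about the segment CoM in the
#  segment frame; R maps segment-frame vectors into the world frame.

#' Inertia tensor of a homogeneous cuboid
#'
#' Principal moments `m (a^2 + b^2) / 12` about the cuboid's CoM, with the
#' x axis along the width, y along the length and z along the thickness.
#'
#' @param width,length,thickness edge lengths in m (>= 0).
#' @param mass cuboid mass in kg (>= 0).
#' @return 3 x 3 diagonal inertia tensor in kg m^2.
#' @examples
#' cuboid_inertia(0.1, 0.1, 0.1, 1.2)  # 0.002 on the diagonal
#' @export
cuboid_inertia <- function(width, length, thickness, mass) {
  if (any(c(width, length, thickness, mass) < 0))
    jm_stop("invalid_parameter", "cuboid dimensions and mass must be non-negative")
  diag(mass / 12 * c(length^2 + thickness^2,
                     width^2 + thickness^2,
                     width^2 + length^2))
}

#' Geometric specification of a running-specific prosthesis
#'
#' The prosthesis is discretized into cuboids (the standard protocol uses
#' 9, one per measured region of the blade); the material is assumed
#' homogeneous, so the measured total mass fixes a single density and each
#' cuboid's mass follows from its volume. The prosthetic "joint" sits
#' between two named cuboids, at the point of highest curvature of the
#' blade.
#'
#' @param cuboids list of cuboid descriptions, each a list with `width`,
#'   `length`, `thickness` (m), `position` (3-vector, CoM in the prosthesis
#'   frame, m) and optional `orientation` (3 x 3 rotation, default
#'   identity).
#' @param total_mass measured prosthesis mass in kg (> 0).
#' @param joint_after index: the prosthetic joint lies between cuboid
#'   `joint_after` and cuboid `joint_after + 1`.
#' @return object of class `prosthesis_spec`.
#' @export
prosthesis_spec <- function(cuboids, total_mass, joint_after) {
  n <- length(cuboids)
  if (n < 2) jm_stop("invalid_parameter", "a prosthesis spec needs at least 2 cuboids")
  if (n != 9)
    warning("standard prosthesis discretization uses 9 cuboids; got ", n)
  if (total_mass <= 0) jm_stop("invalid_parameter", "total mass must be positive")
  if (joint_after < 1 || joint_after >= n)
    jm_stop("invalid_parameter", "joint_after must split the cuboid list in two")
  cuboids <- lapply(cuboids, function(cb) {
    if (is.null(cb$orientation)) cb$orientation <- diag(3)
    cb$volume <- cb$width * cb$length * cb$thickness
    cb
  })
  vol <- sum(vapply(cuboids, `[[`, numeric(1), "volume"))
  if (vol <= 0) jm_stop("invalid_parameter", "total cuboid volume must be positive")
  structure(list(cuboids = cuboids, total_mass = total_mass,
                 joint_after = as.integer(joint_after),
                 density = total_mass / vol),
            class = "prosthesis_spec")
}

# composite rigid body from cuboids: mass, CoM, inertia about the CoM in
# the common (prosthesis) frame, via rotation + parallel-axis transport
composite_body <- function(cuboids, masses) {
  m <- sum(masses)
  pos <- t(vapply(cuboids, function(cb) as.numeric(cb$position), numeric(3)))
  com <- colSums(pos * masses) / m
  inertia <- matrix(0, 3, 3)
  for (i in seq_along(cuboids)) {
    cb <- cuboids[[i]]
    I0 <- cb$orientation %*%
      cuboid_inertia(cb$width, cb$length, cb$thickness, masses[i]) %*%
      t(cb$orientation)
    d <- as.numeric(cb$position) - com
    inertia <- inertia + I0 +
      masses[i] * (sum(d^2) * diag(3) - outer(d, d))
  }
  list(mass = m, com = com, inertia = inertia)
}

#' Build the two rigid prosthesis bodies from a cuboid spec
#'
#' Assigns each cuboid a mass from the homogeneous density, then assembles
#' the cuboids on each side of the prosthetic joint into one rigid body
#' (mass, CoM, inertia about the CoM via the parallel-axis theorem).
#'
#' @param spec a [prosthesis_spec()].
#' @return list with `proximal` and `distal` composite bodies (each
#'   `mass`, `com`, `inertia`), plus `density` (kg/m^3) and the per-cuboid
#'   `masses`.
#' @export
build_prosthesis <- function(spec) {
  stopifnot(inherits(spec, "prosthesis_spec"))
  masses <- vapply(spec$cuboids, function(cb) cb$volume * spec$density, numeric(1))
  i <- seq_len(spec$joint_after)
  list(proximal = composite_body(spec$cuboids[i], masses[i]),
       distal = composite_body(spec$cuboids[-i], masses[-i]),
       density = spec$density, masses = masses)
}

#' Joint centres from anatomical markers
#'
#' Knee and ankle joint centres are the midpoints of the medial/lateral
#' femoral-condyle and malleolus markers; the metatarsophalangeal (MTP)
#' joint centre is the midpoint of the 1st and 5th metatarsal-head markers;
#' the prosthetic joint centre is the midpoint of the two prosthesis edge
#' markers placed at the point of highest blade curvature. The hip joint
#' centre comes from a Bell-style regression on the inter-ASIS distance
#' (0.36 d medial, 0.22 d posterior, 0.30 d inferior to the ipsilateral
#' ASIS), with the posterior direction taken from a sacrum marker when
#' present and the lab -x axis otherwise.
#'
#' @param markers named list of 3-vectors (m). Recognized labels:
#'   `knee_med`, `knee_lat`, `mal_med`, `mal_lat`, `mt1`, `mt5`,
#'   `pros_med`, `pros_lat`, `asis_l`, `asis_r`, `sacrum`.
#' @param side `"right"` or `"left"`, used for the hip regression.
#' @param hip_coefficients regression fractions of the inter-ASIS distance
#'   `(medial, posterior, inferior)`.
#' @return named list of the joint centres computable from the supplied
#'   markers (`kjc`, `ajc`, `mjc`, `prosthetic`, `hjc`).
#' @export
joint_centres <- function(markers, side = "right",
                          hip_coefficients = c(0.36, 0.22, 0.30)) {
  need <- function(labels) {
    miss <- setdiff(labels, names(markers))
    if (length(miss))
      jm_stop("missing_marker", paste("missing marker(s):", paste(miss, collapse = ", ")))
    lapply(markers[labels], as.numeric)
  }
  mid <- function(a, b) (a + b) / 2
  out <- list()
  if (all(c("knee_med", "knee_lat") %in% names(markers))) {
    m <- need(c("knee_med", "knee_lat")); out$kjc <- mid(m[[1]], m[[2]])
  }
  if (all(c("mal_med", "mal_lat") %in% names(markers))) {
    m <- need(c("mal_med", "mal_lat")); out$ajc <- mid(m[[1]], m[[2]])
  }
  if (all(c("mt1", "mt5") %in% names(markers))) {
    m <- need(c("mt1", "mt5")); out$mjc <- mid(m[[1]], m[[2]])
  }
  if (all(c("pros_med", "pros_lat") %in% names(markers))) {
    m <- need(c("pros_med", "pros_lat")); out$prosthetic <- mid(m[[1]], m[[2]])
  }
  if (all(c("asis_l", "asis_r") %in% names(markers))) {
    m <- need(c("asis_l", "asis_r"))
    al <- m[[1]]; ar <- m[[2]]
    d <- sqrt(sum((ar - al)^2))
    ml <- (ar - al) / d                      # left -> right
    post <- if ("sacrum" %in% names(markers)) {
      s <- as.numeric(markers$sacrum)
      p <- s - mid(al, ar); p <- p - sum(p * ml) * ml
      p / sqrt(sum(p^2))
    } else c(-1, 0, 0)
    inf <- c(0, 0, -1)
    asis <- if (identical(side, "right")) ar else al
    medial <- if (identical(side, "right")) -ml else ml
    out$hjc <- asis + hip_coefficients[1] * d * medial +
      hip_coefficients[2] * d * post + hip_coefficients[3] * d * inf
  }
  if (!length(out)) jm_stop("missing_marker", "no recognized marker labels supplied")
  out
}

#' Time-varying rigid-segment description for inverse dynamics
#'
#' @param name segment label.
#' @param mass segment mass in kg (>= 0).
#' @param inertia 3 x 3 inertia tensor about the segment CoM, segment frame.
#' @param com T x 3 matrix of CoM world positions (m).
#' @param prox_joint T x 3 matrix of proximal-joint world positions (m).
#' @param dist_joint T x 3 matrix of distal-joint world positions, or
#'   `NULL` for the most distal segment (ground contact via the CoP).
#' @param R 3 x 3 x T array of segment-to-world rotations, or `NULL` for a
#'   non-rotating segment.
#' @return object of class `segment_kinematics`.
#' @export
segment_kinematics <- function(name, mass, inertia, com, prox_joint,
                               dist_joint = NULL, R = NULL) {
  com <- as.matrix(com); prox_joint <- as.matrix(prox_joint)
  if (!is.null(dist_joint)) dist_joint <- as.matrix(dist_joint)
  if (mass < 0) jm_stop("invalid_parameter", "segment mass must be non-negative")
  if (!isTRUE(all.equal(inertia, t(inertia), tolerance = 1e-8)))
    jm_stop("invalid_parameter", "inertia tensor must be symmetric")
  T_ <- nrow(com)
  ok <- nrow(prox_joint) == T_ &&
    (is.null(dist_joint) || nrow(dist_joint) == T_) &&
    (is.null(R) || (length(dim(R)) == 3 && dim(R)[3] == T_))
  if (!ok) jm_stop("invalid_input", "segment trajectories must share one length")
  structure(list(name = name, mass = mass, inertia = inertia, com = com,
                 prox_joint = prox_joint, dist_joint = dist_joint, R = R),
            class = "segment_kinematics")
}

# second central difference acceleration of a T x 3 trajectory
traj_accel <- function(x, dt) {
  T_ <- nrow(x)
  a <- matrix(0, T_, 3)
  if (T_ >= 3) {
    a[2:(T_ - 1), ] <- (x[3:T_, ] - 2 * x[2:(T_ - 1), ] + x[1:(T_ - 2), ]) / dt^2
    a[1, ] <- a[2, ]; a[T_, ] <- a[T_ - 1, ]
  }
  a
}

# angular velocity and acceleration from a rotation array (world frame):
# skew(omega) = Rdot R^T by central differences
rotation_rates <- function(R, dt) {
  T_ <- dim(R)[3]
  w <- matrix(0, T_, 3)
  for (i in 2:(T_ - 1)) {
    Rd <- (R[, , i + 1] - R[, , i - 1]) / (2 * dt)
    S <- Rd %*% t(R[, , i])
    w[i, ] <- c(S[3, 2], S[1, 3], S[2, 1])
  }
  w[1, ] <- w[2, ]; w[T_, ] <- w[T_ - 1, ]
  al <- matrix(0, T_, 3)
  al[2:(T_ - 1), ] <- (w[3:T_, ] - w[1:(T_ - 2), ]) / (2 * dt)
  al[1, ] <- al[2, ]; al[T_, ] <- al[T_ - 1, ]
  list(omega = w, alpha = al)
}

#' Bottom-up Newton-Euler inverse dynamics over a segment chain
#'
#' Starting from the most distal segment (loaded by the measured GRF at the
#' centre of pressure), solves each segment's force and moment balance
#' (`F_p = m a - m g - F_d`; moment balance about the segment CoM including
#' `I alpha + omega x I omega`) and propagates the negated reactions up the
#' chain. Joint moments are reported both in the world frame and expressed
#' in the frame of the distal segment at each joint.
#'
#' @param chain list of [segment_kinematics()] ordered distal to proximal.
#' @param grf T x 3 matrix of ground forces in N (ground-on-athlete).
#' @param cop T x 3 matrix of centre-of-pressure world positions (m).
#' @param rate sampling rate in Hz.
#' @param free_moment optional T x 3 matrix of free moments at the CoP (N m).
#' @return list with one element per joint (named by segment), each holding
#'   `force` (T x 3, world, N), `moment_world` (T x 3, N m), `moment`
#'   (T x 3, distal-segment frame), and `omega_rel` (T x 3 rad/s, angular
#'   velocity of the segment relative to the next proximal segment, or to
#'   the lab for the chain's top joint).
#' @export
inverse_dynamics_pass <- function(chain, grf, cop, rate, free_moment = NULL) {
  if (!length(chain) || !all(vapply(chain, inherits, logical(1), "segment_kinematics")))
    jm_stop("invalid_input", "chain must be a list of segment_kinematics")
  grf <- as.matrix(grf); cop <- as.matrix(cop)
  T_ <- nrow(grf)
  if (nrow(cop) != T_ || any(vapply(chain, function(s) nrow(s$com), integer(1)) != T_))
    jm_stop("invalid_input", "chain, GRF and CoP must share one time base")
  dt <- 1 / rate
  g_vec <- c(0, 0, -GRAVITY)
  # per-segment derivatives
  der <- lapply(chain, function(s) {
    acc <- traj_accel(s$com, dt)
    if (is.null(s$R)) {
      list(acc = acc, omega = matrix(0, T_, 3), alpha = matrix(0, T_, 3),
           R = NULL)
    } else c(list(acc = acc, R = s$R), rotation_rates(s$R, dt))
  })
  out <- vector("list", length(chain))
  names(out) <- vapply(chain, `[[`, character(1), "name")
  F_d <- grf
  M_d <- if (is.null(free_moment)) matrix(0, T_, 3) else as.matrix(free_moment)
  p_d <- cop
  for (k in seq_along(chain)) {
    s <- chain[[k]]; d <- der[[k]]
    if (k > 1 && !is.null(s$dist_joint)) p_d <- s$dist_joint
    F_p <- matrix(0, T_, 3); M_p <- matrix(0, T_, 3); M_loc <- matrix(0, T_, 3)
    for (i in seq_len(T_)) {
      Ri <- if (is.null(s$R)) diag(3) else s$R[, , i]
      Iw <- Ri %*% s$inertia %*% t(Ri)
      Hdot <- as.numeric(Iw %*% d$alpha[i, ]) +
        cross3(d$omega[i, ], as.numeric(Iw %*% d$omega[i, ]))
      F_p[i, ] <- s$mass * d$acc[i, ] - s$mass * g_vec - F_d[i, ]
      rd <- p_d[i, ] - s$com[i, ]
      rp <- s$prox_joint[i, ] - s$com[i, ]
      M_p[i, ] <- Hdot - M_d[i, ] - cross3(rd, F_d[i, ]) - cross3(rp, F_p[i, ])
      M_loc[i, ] <- as.numeric(t(Ri) %*% M_p[i, ])
    }
    omega_rel <- if (k < length(chain)) d$omega - der[[k + 1]]$omega else d$omega
    out[[k]] <- list(force = F_p, moment_world = M_p, moment = M_loc,
                     omega_rel = omega_rel)
    F_d <- -F_p
    M_d <- -M_p
    p_d <- s$prox_joint
  }
  out
}

# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Joint power and mass-normalized joint work
#'
#' Joint power is the per-plane product of joint moment and joint angular
#' velocity summed over the three planes of motion; joint work is its
#' time-integral, split by sign into absorption (negative) and generation
#' (positive) and normalized by body mass.
#'
#' @param moment T x 3 matrix (or vector) of joint moments in N m.
#' @param omega T x 3 matrix (or vector) of joint angular velocity, rad/s.
#' @param mass body mass in kg (> 0).
#' @param rate sampling rate in Hz.
#' @return list with `power` (W, length T), `negative_work`,
#'   `positive_work`, `net_work` (J/kg).
#' @export
joint_power_and_work <- function(moment, omega, mass, rate) {
  if (mass <= 0) jm_stop("invalid_parameter", "mass must be positive")
  moment <- as.matrix(moment); omega <- as.matrix(omega)
  if (!all(dim(moment) == dim(omega)))
    jm_stop("invalid_input", "moment and angular velocity series must align")
  p <- rowSums(moment * omega)
  dt <- 1 / rate
  list(power = p,
       negative_work = trapz_uniform(pmin(p, 0), dt) / mass,
       positive_work = trapz_uniform(pmax(p, 0), dt) / mass,
       net_work = trapz_uniform(p, dt) / mass)
}

#' Sagittal-plane MTP power convention
#'
#' MTP-joint energy exchange is counted only in the sagittal plane and only
#' while the centre of pressure lies anterior to the MTP joint centre; this
#' zeroes the power series elsewhere.
#'
#' @param power_sagittal numeric vector, sagittal-plane MTP joint power (W).
#' @param cop_ap,mjc_ap anteroposterior positions of the CoP and the MTP
#'   joint centre (m), same length as `power_sagittal`.
#' @return power series with non-qualifying samples set to zero.
#' @export
mtp_work_filter <- function(power_sagittal, cop_ap, mjc_ap) {
  if (length(cop_ap) != length(power_sagittal) ||
      length(mjc_ap) != length(power_sagittal))
    jm_stop("invalid_input", "series must share one length")
  power_sagittal * (cop_ap > mjc_ap)
}

#' Below-knee joint work aggregation
#'
#' For non-amputee legs the "below knee" energy exchange is the sum of the
#' ankle and MTP joint works; for the affected leg of an athlete with BKA
#' it is the prosthetic-joint work.
#'
#' @param group `"BKA"` or `"non_amputee"`.
#' @param ankle,mtp,prosthetic joint works in J/kg (`NA` when not
#'   applicable).
#' @return below-knee work in J/kg.
#' @export
below_knee_work <- function(group, ankle = NA_real_, mtp = NA_real_,
                            prosthetic = NA_real_) {
  if (identical(group, "BKA")) prosthetic
  else sum(c(ankle, mtp), na.rm = TRUE)
}
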