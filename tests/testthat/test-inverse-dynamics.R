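test_that("cuboid inertia matches the standard formula and a Monte-Carlo mass cloud", {
  expect_equal(cuboid_inertia(0.1, 0.1, 0.1, 1.2), diag(rep(0.002, 3)))
  expect_equal(cuboid_inertia(0, 0, 0, 2), matrix(0, 3, 3))
  expect_error(cuboid_inertia(-0.1, 0.1, 0.1, 1), class = "invalid_parameter")

  # thin plate vs uniform point-cloud oracle (1e6 samples)
  plate <- list(width = 0.3, length = 0.2, thickness = 0.004,
                position = c(0, 0, 0), orientation = diag(3))
  oracle <- mc_inertia(list(plate), 0.9, n = 1e6)
  got <- cuboid_inertia(0.3, 0.2, 0.004, 0.9)
  for (a in 1:3)
    expect_lt(abs(got[a, a] - oracle$inertia[a, a]) / got[a, a], 0.005)
})

test_that("prosthesis assembly distributes mass by volume and matches the cloud oracle", {
  cube <- function(pos) list(width = 0.1, length = 0.1, thickness = 0.1,
                             position = pos)
  # non-standard discretizations are allowed but flagged
  expect_warning(
    two <- prosthesis_spec(list(cube(c(0, 0, 0)), cube(c(0, 0, 0.3))),
                           total_mass = 1.5, joint_after = 1),
    "9 cuboids")
  expect_equal(two$density, 1.5 / 0.002)
  built <- build_prosthesis(two)
  expect_equal(built$masses, c(0.75, 0.75))
  expect_equal(built$proximal$com, c(0, 0, 0))
  expect_equal(built$distal$com, c(0, 0, 0.3))
  # symmetric pair: composite CoM of the union sits at the midpoint
  all_com <- (built$proximal$mass * built$proximal$com +
                built$distal$mass * built$distal$com) / 1.5
  expect_equal(all_com, c(0, 0, 0.15))

  # arbitrary 9-cuboid blade layout vs Monte-Carlo composite (0.5%)
  set.seed(5)
  cuboids <- lapply(1:9, function(i)
    list(width = runif(1, 0.04, 0.12), length = runif(1, 0.05, 0.2),
         thickness = runif(1, 0.008, 0.03),
         position = c(runif(1, -0.05, 0.05), runif(1, -0.02, 0.02),
                      0.05 * i)))
  spec <- prosthesis_spec(cuboids, total_mass = 1.8, joint_after = 5)
  built <- build_prosthesis(spec)
  for (side in c(1, 2)) {
    idx <- if (side == 1) 1:5 else 6:9
    body <- if (side == 1) built$proximal else built$distal
    oracle <- mc_inertia(cuboids[idx], built$masses[idx], n = 8e5, seed = side)
    expect_equal(body$mass, oracle$mass, tolerance = 1e-9)
    expect_equal(body$com, oracle$com, tolerance = 0.01)
    expect_lt(max(abs(body$inertia - oracle$inertia)) /
                max(abs(body$inertia)), 0.005)
  }
  expect_error(prosthesis_spec(list(cube(c(0, 0, 0))), 1, 1),
               class = "invalid_parameter")
})

test_that("joint centres are the stated midpoints and a marker round-trip is exact", {
  jc <- joint_centres(list(knee_med = c(0, 0, 0), knee_lat = c(0.1, 0, 0),
                           mt1 = c(0.2, 0, 0), mt5 = c(0.1, 0.05, 0)))
  expect_equal(jc$kjc, c(0.05, 0, 0))
  expect_equal(jc$mjc, c(0.15, 0.025, 0))
  expect_error(joint_centres(list(knee_med = c(0, 0, 0))),
               class = "missing_marker")

  # markers generated from known centres are recovered exactly
  set.seed(9)
  truth <- list(kjc = c(0.1, 0.2, 0.5), ajc = c(0.15, 0.21, 0.1),
                mjc = c(0.3, 0.2, 0.02), prosthetic = c(0.2, 0.2, 0.2))
  half <- function(ctr, off) list(ctr + off, ctr - off)
  mk <- list()
  off <- c(0.05, 0, 0)
  mk[c("knee_med", "knee_lat")] <- half(truth$kjc, off)
  mk[c("mal_med", "mal_lat")] <- half(truth$ajc, off)
  mk[c("mt1", "mt5")] <- half(truth$mjc, c(0.04, 0.02, 0))
  mk[c("pros_med", "pros_lat")] <- half(truth$prosthetic, c(0, 0.03, 0))
  got <- joint_centres(mk)
  for (nm in names(truth)) expect_equal(got[[nm]], truth[[nm]])

  # hip regression: 0.36 d medial, 0.22 d posterior, 0.30 d inferior
  hj <- joint_centres(list(asis_l = c(0, -0.12, 1), asis_r = c(0, 0.12, 1)),
                      side = "right")
  expect_equal(hj$hjc, c(0, 0.12, 1) + 0.24 * c(-0.22, -0.36, -0.30))
})

test_that("static single-segment inverse dynamics reproduces the lever-arm moment", {
  T_ <- 11
  const <- function(p) matrix(p, T_, 3, byrow = TRUE)
  # massless foot, ankle at origin, 800 N vertical at CoP 0.1 m anterior
  foot <- segment_kinematics("foot", 0, diag(3) * 0, const(c(0.05, 0, 0)),
                             prox_joint = const(c(0, 0, 0)))
  res <- inverse_dynamics_pass(list(foot), const(c(0, 0, 800)),
                               const(c(0.1, 0, 0)), rate = 100)
  expect_equal(res$foot$moment_world[5, ], c(0, 80, 0), tolerance = 1e-10)
  expect_equal(res$foot$force[5, ], c(0, 0, -800), tolerance = 1e-10)

  # zero GRF, static posture: joint moments equal gravitational moments
  m <- 3.2
  shank <- segment_kinematics("shank", m, diag(3) * 0.05,
                              const(c(0.1, 0, 0.2)),
                              prox_joint = const(c(0, 0, 0.4)))
  res2 <- inverse_dynamics_pass(list(shank), const(c(0, 0, 0)),
                                const(c(0, 0, 0)), rate = 100)
  # weight m*g at lever arm 0.1 m anterior of the joint
  expect_equal(res2$shank$moment_world[5, ], c(0, -m * 9.81 * 0.1, 0),
               tolerance = 1e-9)
  expect_equal(res2$shank$force[5, ], c(0, 0, m * 9.81), tolerance = 1e-10)
})

test_that("recursive chain solution equals the free-body oracle on random chains", {
  for (n_seg in 2:4) {
    fx <- random_chain(n_seg, seed = 100 + n_seg)
    got <- inverse_dynamics_pass(fx$chain, fx$grf, fx$cop, fx$rate)
    oracle <- free_body_oracle(fx$chain, fx$grf, fx$cop, fx$rate)
    interior <- 3:(fx$T_ - 2)
    for (k in seq_len(n_seg)) {
      scale_f <- max(abs(oracle[[k]]$force[interior, ]))
      scale_m <- max(abs(oracle[[k]]$moment_world[interior, ]))
      expect_lt(max(abs(got[[k]]$force[interior, ] -
                          oracle[[k]]$force[interior, ])) / scale_f, 1e-6)
      expect_lt(max(abs(got[[k]]$moment_world[interior, ] -
                          oracle[[k]]$moment_world[interior, ])) / scale_m, 1e-6)
    }
  }
})

test_that("joint power is the per-plane moment-velocity product with sign-split work", {
  T_ <- 101; rate <- 100; mass <- 80
  M <- matrix(rep(c(100, 0, 0), each = T_), T_)
  w <- matrix(rep(c(2, 0, 0), each = T_), T_)
  jw <- joint_power_and_work(M, w, mass, rate)
  expect_equal(unique(jw$power), 200)
  expect_equal(jw$positive_work, 200 * 1 / 80, tolerance = 1e-9)  # 2.5 J/kg
  expect_equal(jw$negative_work, 0)

  # moment and velocity in quadrature -> zero net work over full cycles
  t <- (seq_len(T_) - 1) / rate
  Mq <- cbind(100 * sin(2 * pi * t), 0, 0)
  wq <- cbind(2 * cos(2 * pi * t), 0, 0)
  expect_equal(joint_power_and_work(Mq, wq, mass, rate)$net_work, 0,
               tolerance = 1e-9)
  zero <- joint_power_and_work(Mq, wq * 0, mass, rate)
  expect_equal(zero$power, rep(0, T_))
  expect_equal(zero$net_work, 0)
})

test_that("MTP power convention zeroes samples with the CoP behind the joint centre", {
  p <- c(1, 2, 3, 4, 5)
  expect_equal(mtp_work_filter(p, cop_ap = rep(0, 5), mjc_ap = rep(1, 5)),
               rep(0, 5))
  expect_equal(mtp_work_filter(p, cop_ap = rep(2, 5), mjc_ap = rep(1, 5)), p)
  crossing <- mtp_work_filter(p, cop_ap = c(0, 0.5, 1.5, 2, 3),
                              mjc_ap = rep(1, 5))
  expect_equal(crossing, c(0, 0, 3, 4, 5))
})

test_that("below-knee work aggregates ankle+MTP for non-amputees and prosthesis for BKA", {
  expect_equal(below_knee_work("non_amputee", ankle = -1.8, mtp = -0.37),
               -2.17)
  expect_equal(below_knee_work("BKA", prosthetic = -1.94), -1.94)
})

test_that("joint work equals the total CoM energy change on a prescribed stance motion", {
  # single rigid segment pivoting about a fixed ground contact: the ankle
  # moment is the only actuator, so its work must equal dE_total (and the
  # gravity-inclusive CoM work must equal dKE)
  rate <- 2000; T_ <- 401
  t <- (seq_len(T_) - 1) / rate
  L <- 0.9; m <- 75
  th <- pi / 2 + 0.25 * sin(2 * pi * 1.25 * t)   # lean angle, rad
  com <- cbind(L * cos(th), 0, L * sin(th))
  R <- array(0, c(3, 3, T_))
  for (i in seq_len(T_)) {   # rotation about +y by (pi/2 - th)
    a <- pi / 2 - th[i]
    R[, , i] <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                       3, 3, byrow = TRUE)
  }
  seg <- segment_kinematics("body", m, diag(3) * 1e-9, com,
                            prox_joint = matrix(0, T_, 3), R = R)
  # ground force consistent with the motion: F = m a - m g
  acc <- matrix(0, T_, 3)
  acc[2:(T_ - 1), ] <- (com[3:T_, ] - 2 * com[2:(T_ - 1), ] +
                          com[1:(T_ - 2), ]) * rate^2
  grf <- cbind(m * acc[, 1], 0, m * acc[, 3] + m * 9.81)
  res <- inverse_dynamics_pass(list(seg), grf, matrix(0, T_, 3), rate)
  # the reported moment acts on the segment from the (fixed) proximal side;
  # the actuator about the contact is its reaction propagated to the pivot
  i0 <- 3; i1 <- T_ - 2
  jw <- joint_power_and_work(res$body$moment_world[i0:i1, ],
                             res$body$omega_rel[i0:i1, ], m, rate)
  vel <- matrix(0, T_, 3)
  vel[2:(T_ - 1), ] <- (com[3:T_, ] - com[1:(T_ - 2), ]) * rate / 2
  dE <- (com[i1, 3] - com[i0, 3]) * 9.81 +
    (sum(vel[i1, ]^2) - sum(vel[i0, ]^2)) / 2
  expect_equal(jw$net_work, dE, tolerance = 0.01)

  # gravity-inclusive CoM work equals the kinetic-energy change alone
  iv <- stance_interval(i0, i1, t[i0], t[i1])
  w <- com_work(sampled_signal(grf, rate), sampled_signal(vel, rate), iv, m,
                include_gravity = TRUE)
  dKE <- (sum(vel[i1, ]^2) - sum(vel[i0, ]^2)) / 2
  expect_equal(w$net_work, dKE, tolerance = 0.01)
})
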