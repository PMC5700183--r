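# shared fixtures built in code

G <- 9.81

# half-sine force burst embedded in zeros: peak P (N), duration dur (s)
half_sine_grf <- function(peak, dur, rate = 1000, pad = 0.05, axis = 3) {
  t <- seq(0, pad + dur + pad, by = 1 / rate)
  f <- matrix(0, length(t), 3)
  inside <- t >= pad & t <= pad + dur
  f[inside, axis] <- peak * sin(pi * (t[inside] - pad) / dur)
  sampled_signal(f, rate, 0, "N")
}

# measured amplitude of a (filtered) sinusoid, interior portion only (RMS)
mid_amplitude <- function(x) {
  n <- length(x)
  mid <- x[round(n / 4):round(3 * n / 4)]
  sqrt(2 * mean(mid^2))
}

# exact magnitude of the net-order-`order` zero-phase digital Butterworth
# (bilinear design of order/2 applied twice), with frequency pre-warping
butter_zero_phase_gain <- function(f, fc, fs, order = 4) {
  w <- tan(pi * f / fs) / tan(pi * fc / fs)
  1 / (1 + w^(2 * order / 2))   # two passes of |H| = (1 + w^order)^(-1/2)
}

# random smooth rigid-segment chain for inverse-dynamics oracle tests:
# polynomial/sinusoid CoM paths, single-axis rotations, random joints
random_chain <- function(n_seg, T_ = 41, rate = 200, seed = 1) {
  set.seed(seed)
  t <- (seq_len(T_) - 1) / rate
  segs <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    f1 <- runif(1, 0.5, 2); ph <- runif(3, 0, 2 * pi); amp <- runif(3, 0.02, 0.1)
    com <- cbind(amp[1] * sin(2 * pi * f1 * t + ph[1]) + 0.1 * k,
                 amp[2] * sin(2 * pi * f1 * t + ph[2]),
                 amp[3] * sin(2 * pi * f1 * t + ph[3]) + 0.3 * k)
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    th <- runif(1, 0.5, 1.5) * sin(2 * pi * runif(1, 0.5, 1.5) * t)
    R <- array(0, c(3, 3, T_))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    for (i in seq_len(T_))
      R[, , i] <- diag(3) + sin(th[i]) * K + (1 - cos(th[i])) * (K %*% K)
    d <- runif(2, 0.05, 0.2)
    prox <- com + t(vapply(seq_len(T_), function(i)
      as.numeric(R[, , i] %*% c(0, 0, d[1])), numeric(3)))
    dist <- com - t(vapply(seq_len(T_), function(i)
      as.numeric(R[, , i] %*% c(0, 0, d[2])), numeric(3)))
    A <- matrix(rnorm(9, sd = 0.3), 3); Ib <- crossprod(A) + diag(3) * 0.05
    # segments share joints: the distal joint of segment k is the proximal
    # joint of segment k-1 (the ground-loaded segment has none)
    dist_joint <- if (k == 1) NULL else segs[[k - 1]]$prox_joint
    segs[[k]] <- segment_kinematics(paste0("seg", k), runif(1, 1, 5), Ib,
                                    com, prox, dist_joint, R)
  }
  grf <- cbind(50 * sin(2 * pi * t) + rnorm(T_, sd = 5),
               30 * cos(2 * pi * t),
               600 + 100 * sin(2 * pi * 1.3 * t))
  cop <- cbind(0.05 * sin(2 * pi * t), 0.02 * cos(2 * pi * t), 0 * t)
  list(chain = segs, grf = grf, cop = cop, rate = rate, T_ = T_, t = t)
}

# independent free-body oracle: joint load at the proximal joint of segment
# k equals the summed inertial-minus-applied loads of all segments at or
# below k (no recursion; solved per joint directly)
free_body_oracle <- function(chain, grf, cop, rate) {
  dt <- 1 / rate
  T_ <- nrow(grf)
  g_vec <- c(0, 0, -9.81)
  acc <- lapply(chain, function(s) {
    a <- matrix(0, T_, 3)
    a[2:(T_ - 1), ] <- (s$com[3:T_, ] - 2 * s$com[2:(T_ - 1), ] +
                          s$com[1:(T_ - 2), ]) / dt^2
    a[1, ] <- a[2, ]; a[T_, ] <- a[T_ - 1, ]
    a
  })
  rot <- lapply(chain, function(s) {
    w <- matrix(0, T_, 3)
    for (i in 2:(T_ - 1)) {
      Rd <- (s$R[, , i + 1] - s$R[, , i - 1]) / (2 * dt)
      S <- Rd %*% t(s$R[, , i])
      w[i, ] <- c(S[3, 2], S[1, 3], S[2, 1])
    }
    w[1, ] <- w[2, ]; w[T_, ] <- w[T_ - 1, ]
    al <- matrix(0, T_, 3)
    al[2:(T_ - 1), ] <- (w[3:T_, ] - w[1:(T_ - 2), ]) / (2 * dt)
    al[1, ] <- al[2, ]; al[T_, ] <- al[T_ - 1, ]
    list(w = w, al = al)
  })
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  lapply(seq_along(chain), function(k) {
    Fk <- matrix(0, T_, 3); Mk <- matrix(0, T_, 3)
    for (i in seq_len(T_)) {
      p_k <- chain[[k]]$prox_joint[i, ]
      Fs <- -grf[i, ]; Ms <- -xp(cop[i, ] - p_k, grf[i, ])
      for (j in seq_len(k)) {
        s <- chain[[j]]
        Rw <- s$R[, , i]
        Iw <- Rw %*% s$inertia %*% t(Rw)
        Hdot <- as.numeric(Iw %*% rot[[j]]$al[i, ]) +
          xp(rot[[j]]$w[i, ], as.numeric(Iw %*% rot[[j]]$w[i, ]))
        net <- s$mass * acc[[j]][i, ] - s$mass * g_vec
        Fs <- Fs + net
        Ms <- Ms + Hdot + xp(s$com[i, ] - p_k, net)
      }
      Fk[i, ] <- Fs; Mk[i, ] <- Ms
    }
    list(force = Fk, moment_world = Mk)
  })
}

# Monte-Carlo inertia tensor of a union of cuboids with given masses
mc_inertia <- function(cuboids, masses, n = 1e6, seed = 42) {
  set.seed(seed)
  vols <- vapply(cuboids, function(cb) cb$width * cb$length * cb$thickness,
                 numeric(1))
  n_i <- round(n * vols / sum(vols))
  pts <- NULL; wts <- NULL
  for (i in seq_along(cuboids)) {
    cb <- cuboids[[i]]
    loc <- cbind(runif(n_i[i], -cb$width / 2, cb$width / 2),
                 runif(n_i[i], -cb$length / 2, cb$length / 2),
                 runif(n_i[i], -cb$thickness / 2, cb$thickness / 2))
    orient <- if (is.null(cb$orientation)) diag(3) else cb$orientation
    pts <- rbind(pts, loc %*% t(orient) +
                   matrix(cb$position, n_i[i], 3, byrow = TRUE))
    wts <- c(wts, rep(masses[i] / n_i[i], n_i[i]))
  }
  com <- colSums(pts * wts) / sum(wts)
  d <- sweep(pts, 2, com)
  I <- matrix(0, 3, 3)
  r2 <- rowSums(d^2)
  for (a in 1:3) for (b in 1:3)
    I[a, b] <- sum(wts * ((a == b) * r2 - d[, a] * d[, b]))
  list(mass = sum(wts), com = com, inertia = I)
}
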