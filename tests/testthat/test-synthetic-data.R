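test_that("generators are deterministic under a fixed seed", {
  a <- make_sprint_trial(seed = 12)
  b <- make_sprint_trial(seed = 12)
  expect_identical(a$forces$takeoff, b$forces$takeoff)
  expect_identical(a$laser$values, b$laser$values)
  expect_false(identical(a$laser$values, make_sprint_trial(seed = 13)$laser$values))
  j1 <- make_jump_trial(seed = 8); j2 <- make_jump_trial(seed = 8)
  expect_identical(j1$grf$values, j2$grf$values)
  p1 <- make_reference_population(seed = 4); p2 <- make_reference_population(seed = 4)
  expect_identical(p1, p2)
})

test_that("sprint generator satisfies impulse-momentum: mean force over a stride is 1 BW", {
  for (args in list(list(), sprint_presets()$P1, sprint_presets()$nonamputee_mean)) {
    sp <- do.call(make_sprint_trial, c(args, list(seed = 6)))
    total <- sp$forces[[1]]$values[, 3] + sp$forces[[2]]$values[, 3]
    t <- signal_times(sp$forces[[1]])
    td1 <- sp$truth$events$touchdown[1]
    idx <- t >= td1 & t < td1 + sp$truth$stride_time
    mean_force <- mean(total[idx]) / sp$bodyweight
    expect_equal(mean_force, 1, tolerance = 0.005)
  }
})

test_that("sprint generator round-trips ASF, asymmetry and step frequency through the pipeline", {
  sp <- do.call(make_sprint_trial, c(sprint_presets()$P1, list(seed = 2)))
  asf <- events <- list()
  for (leg in names(sp$forces)) {
    sig <- sp$forces[[leg]]
    sts <- detect_stances(sig, 20)
    asf[[leg]] <- mean(vapply(sts, function(s)
      stance_average_force(sig, s, sp$bodyweight), numeric(1)))
    events[[leg]] <- data.frame(
      leg = leg, touchdown = vapply(sts, `[[`, numeric(1), "touchdown_time"),
      toeoff = vapply(sts, `[[`, numeric(1), "toeoff_time"))
  }
  expect_equal(asf$takeoff, 2.17, tolerance = 0.01)
  expect_equal(asf$non_takeoff, 2.39, tolerance = 0.01)
  expect_equal(directional_asymmetry(asf$takeoff, asf$non_takeoff), -9.2,
               tolerance = 0.01)
  st <- spatiotemporal(do.call(rbind, events), speed = sp$truth$top_speed)
  expect_equal(st$step_frequency, sp$truth$step_frequency,
               tolerance = 0.01 / st$step_frequency)
  # laser round-trip recovers the top speed
  expect_equal(laser_speed(sp$laser)$max_speed, sp$truth$top_speed,
               tolerance = 0.01)

  # a generated step-frequency target is recovered to 0.01 Hz
  tc <- 0.098; freq <- 4.34                 # step time 1/freq = tc + aerial
  sp2 <- make_sprint_trial(contact_time = tc, aerial_time = 1 / freq - tc,
                           seed = 3)
  ev <- do.call(rbind, lapply(seq_along(sp2$forces), function(i) {
    s <- detect_stances(sp2$forces[[i]], 20)
    data.frame(leg = names(sp2$forces)[i],
               touchdown = vapply(s, `[[`, numeric(1), "touchdown_time"),
               toeoff = vapply(s, `[[`, numeric(1), "toeoff_time"))
  }))
  expect_equal(spatiotemporal(ev)$step_frequency, 4.34, tolerance = 0.01 / 4.34)
})

test_that("noiseless generation is recovered to numerical precision", {
  sp <- make_sprint_trial(noise_sd = 0, laser_noise_sd = 0, seed = 1)
  sig <- sp$forces[[1]]
  # near-zero threshold: the 20 N stance definition trims the force tails
  # by construction, which is a property of the threshold, not an error
  sts <- detect_stances(sig, 0.01)
  got <- mean(vapply(sts, function(s)
    stance_average_force(sig, s, sp$bodyweight), numeric(1)))
  expect_equal(got, unname(sp$truth$asf[1]), tolerance = 1e-3)
  expect_equal(laser_speed(sp$laser)$max_speed, sp$truth$top_speed,
               tolerance = 1e-3)
})

test_that("impact-peak option preserves the stance impulse", {
  base <- make_sprint_trial(noise_sd = 0, seed = 1)
  peaky <- make_sprint_trial(noise_sd = 0, impact_peak = "two_mass", seed = 1)
  for (sp in list(base, peaky)) {
    sig <- sp$forces[[1]]
    st <- detect_stances(sig, 1)[[1]]
    imp <- impulses(sig, st, sp$bodyweight)$vertical_impulse
    expect_equal(imp, unname(sp$truth$asf[1]) * sp$truth$contact_time,
                 tolerance = 2e-3)
  }
  # the early transient is actually there
  sig <- peaky$forces[[1]]
  st <- detect_stances(sig, 1)[[1]]
  n <- st$toeoff_index - st$touchdown_index
  early <- sig$values[st$touchdown_index + seq_len(round(0.25 * n)), 3]
  expect_gt(max(diff(early) < 0), 0)  # non-monotonic rise = extra peak
})

test_that("jump generator ground truth composes Table-2-style presets", {
  j <- do.call(make_jump_trial, c(jump_presets()$P1, list(seed = 1)))
  expect_equal(j$truth$distance, 0.30 + 8.68 * flight_time(1.18, 3.00),
               tolerance = 1e-12)
  expect_equal(j$truth$distance, 7.96, tolerance = 0.02 / 7.96)
  expect_equal(j$truth$v_toeoff_hor, 9.32 - 0.64)

  # doubling body mass leaves all per-kg/normalized outputs unchanged
  j1 <- make_jump_trial(body_mass = 70, noise_sd = 0, seed = 1)
  j2 <- make_jump_trial(body_mass = 140, noise_sd = 0, seed = 1)
  s1 <- takeoff_summary(j1$grf, j1$com_ap, j1$com_vert, j1$bodyweight,
                        j1$body_mass, j1$toe_tip_ap)
  s2 <- takeoff_summary(j2$grf, j2$com_ap, j2$com_vert, j2$bodyweight,
                        j2$body_mass, j2$toe_tip_ap)
  # tolerance reflects the fixed 20 N threshold: the trimmed force tails
  # scale with 1/peak, so normalized outputs differ at O(threshold/peak)
  for (fld in c("asf", "vertical_impulse", "net_horizontal_impulse",
                "negative_com_work", "positive_com_work", "distance"))
    expect_equal(s1[[fld]], s2[[fld]], tolerance = 2e-3, info = fld)

  expect_error(make_jump_trial(v_loss_hor = -1), class = "invalid_parameter")
  expect_error(make_jump_trial(v_vert_toeoff = -50, v_td_vert = 0),
               class = "infeasible_spec")
})

test_that("reference population has the configured linear structure", {
  noiseless <- make_reference_population(n = 30, noise_sd = 0, seed = 2)
  expect_equal(fit_loss_model(noiseless)$r_squared, 1, tolerance = 1e-9)
  pop <- make_reference_population(n = 200, seed = 9)
  expect_true(all(pop$v_td >= 8.8 & pop$v_td <= 10.8))
  expect_true(all(pop$alpha >= 16 & pop$alpha <= 22))
  expect_lt(mean(pop$v_loss), 0)   # losses are signed negative
  expect_error(make_reference_population(n = 3), class = "invalid_input")
})
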