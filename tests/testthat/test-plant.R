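# Plant: configuration invariants, standard human build, MTU mechanics,
# ground contact, dynamics stepping.

test_that("standard human build matches its anthropometric contract", {
  b <- biped_fixture()
  k <- query_plant(b)
  expect_equal(k$total_mass, 74.5)
  expect_equal(length(b$model$muscles$fmax), 18L)     # 9 MTUs per leg
  expect_equal(length(b$model$bodies$parent), 7L)     # 7 segments
  expect_equal(b$ndof, 9L)                            # floating torso + 6 joints
  expect_equal(b$config$height_m, 1.80)
  # standing: all four contact points exactly at ground level
  expect_true(all(abs(k$contact_points[, 2]) < 1e-12))
  # biarticular muscles span exactly two joints, all others one
  mt <- default_mtu_table()
  spanned <- rowSums(cbind(mt$r_hip_m, mt$r_knee_m, mt$r_ankle_m) != 0)
  expect_equal(spanned[mt$name %in% c("RF", "HAM", "GAS")], rep(2, 3),
               ignore_attr = TRUE)
  expect_equal(spanned[!mt$name %in% c("RF", "HAM", "GAS")], rep(1, 6),
               ignore_attr = TRUE)
})

test_that("invalid configurations are rejected with the field named", {
  seg <- default_segment_table()
  seg$mass_kg[1] <- seg$mass_kg[1] + 1      # masses no longer sum to total
  expect_error(plant_config(segments = seg), "segments")
  expect_error(plant_config(dt_s = 0), "dt_s")
  expect_error(plant_config(total_mass_kg = -1), "total_mass_kg")
})

test_that("MTU: activation decay, isometric force, nonnegativity", {
  mtu <- mtu_defaults("SOL")
  # stimulation 0 held long: activation decays to 0
  st <- list(act = 0.9, lce = mtu$lopt)
  lmt <- mtu$lopt + mtu$lslack
  for (i in 1:3000) st <- mtu_step(mtu, st, 0, lmt, 1e-3)$state
  expect_lt(st$act, 1e-6)
  # full activation, isometric at optimal CE length, taut tendon: F ~ fmax
  st <- list(act = 1, lce = mtu$lopt)
  lmt_taut <- mtu$lopt + mtu$lslack * (1 + mtu$eps_ref)
  for (i in 1:3000) r <- {tmp <- mtu_step(mtu, st, 1, lmt_taut, 1e-3); st <- tmp$state; tmp}
  expect_lt(abs(r$force - mtu$fmax) / mtu$fmax, 0.02)
  # tendon cannot push: force >= 0 under arbitrary inputs
  set.seed(4)
  st <- list(act = 0.5, lce = mtu$lopt)
  for (i in 1:200) {
    r <- mtu_step(mtu, st, runif(1), runif(1, 0.1, 0.6), 1e-3)
    st <- r$state
    expect_gte(r$force, 0)
  }
  expect_error(mtu_step(mtu, st, NaN, lmt, 1e-3), "non-finite")
  expect_error(mtu_step(mtu, st, 0.5, lmt, 0), "dt")
})

test_that("activation stays in [0, 1] for any stimulation sequence in [0, 1]", {
  mtu <- mtu_defaults("VAS")
  set.seed(11)
  st <- list(act = 0, lce = mtu$lopt)
  for (i in 1:500) {
    st <- mtu_step(mtu, st, runif(1), mtu$lopt + mtu$lslack, 2e-3)$state
    expect_true(st$act >= 0 && st$act <= 1)
  }
})

test_that("contact: zero above ground, closed-form static law, friction saturation", {
  p <- make_puck()
  # 5 cm above ground: zero wrench
  w <- contact_wrench(p, q = c(0, 0.05), qd = c(0, 0))
  expect_equal(w$normal, 0)
  expect_equal(w$tangential, 0)
  # static penetration d, zero velocity: F_n = k * d^1.5 exactly
  d <- 0.012
  w <- contact_wrench(p, q = c(0, -d), qd = c(0, 0))
  expect_equal(w$normal, 1e4 * d^1.5)
  # sliding faster than the regularization velocity: |F_t| = mu * F_n
  w <- contact_wrench(p, q = c(0, -d), qd = c(0.5, 0))
  expect_equal(abs(w$tangential), 0.8 * w$normal)
  expect_lt(w$tangential, 0)                     # opposes motion
  # friction never exceeds the Coulomb cone at any sliding speed
  for (vx in c(0.001, 0.02, 0.049, 0.3)) {
    w <- contact_wrench(p, q = c(0, -d), qd = c(vx, 0))
    expect_lte(abs(w$tangential), 0.8 * w$normal + 1e-12)
  }
})

test_that("dynamics step: rest invariance, determinism, divergence error", {
  pend <- make_pendulum()
  s0 <- list(q = 0.7, qd = 0, t = 0)
  s1 <- step_dynamics(pend, s0, numeric(0), dt = 5e-4, contact = FALSE,
                      gravity = FALSE)
  expect_identical(s1$q, 0.7)
  expect_identical(s1$qd, 0)
  # bit-identical repetition
  a <- step_dynamics(pend, s0, numeric(0), dt = 5e-4)
  b <- step_dynamics(pend, s0, numeric(0), dt = 5e-4)
  expect_identical(a, b)
  expect_error(step_dynamics(pend, list(q = NaN, qd = 0, t = 1.5),
                             numeric(0), dt = 5e-4),
               "non-finite")
})

test_that("passive pendulum conserves energy to < 0.1% over 10 s at default dt", {
  pend <- make_pendulum()
  segs <- list(t = 0, KL = matrix(0, 1, 0), KF = matrix(0, 1, 0),
               C = matrix(0, 1, 0))
  cfg <- list(dt = 5e-4, t_max = 10, fall_y = NA_real_, record_dt = 0.01,
              q0 = 1.2, qd0 = 0, act0 = numeric(0), lce0 = numeric(0))
  r <- reflexgait:::cpp_simulate(pend$model, segs, cfg)
  E <- pendulum_energy(r$q[, 1], r$qd[, 1])
  drift <- abs(E[length(E)] - E[1]) / abs(E[1])
  expect_lt(drift, 1e-3)
})

test_that("left-right mirror symmetry of the biped dynamics", {
  b <- biped_fixture()
  # instantaneous equivariance: mirroring state and muscle forces mirrors
  # the advanced state to machine precision
  q0 <- b$q0; q0[2] <- q0[2] + 3; q0[4] <- 0.25; q0[5] <- 0.3; q0[7] <- -0.15
  qd0 <- c(0.5, -0.2, 0.1, 0.4, -0.3, 0.2, -0.1, 0.25, 0.05)
  set.seed(6)
  f <- runif(18, 0, 500)
  fm <- f[c(10:18, 1:9)]
  s1 <- step_dynamics(b, list(q = q0, qd = qd0, t = 0), f, dt = 5e-4)
  s2 <- step_dynamics(b, list(q = mirror_state(b, q0),
                              qd = mirror_state(b, qd0), t = 0), fm,
                      dt = 5e-4)
  expect_equal(s1$q, mirror_state(b, s2$q), tolerance = 1e-13)
  expect_equal(s1$qd, mirror_state(b, s2$qd), tolerance = 1e-12)
  # short-horizon trajectory symmetry under the full reflex loop (the stiff
  # muscle-contact dynamics amplify last-bit rounding differences
  # exponentially, so longer horizons only reflect that amplification)
  p <- rep(0, 71); p[63:71] <- 0.15                 # symmetric tonus only
  qg <- b$q0; qg[4] <- 0.15; qg[7] <- -0.08         # asymmetric leg pose
  e1 <- run_episode(b, p, episode_config(b, t_max = 0.1, q0 = qg))
  e2 <- run_episode(b, p, episode_config(b, t_max = 0.1,
                                         q0 = mirror_state(b, qg)))
  expect_equal(e1$q[, 4:6], e2$q[, 7:9], tolerance = 1e-7)
  expect_equal(e1$q[, 1:3], e2$q[, 1:3], tolerance = 1e-7)
})

test_that("kinematic queries expose CoM, joint angles and MTU lengths", {
  b <- biped_fixture()
  k <- query_plant(b)
  expect_equal(unname(k$joint_angles[b$dof_names == "knee_l"]), 0)
  # at the standing zero pose every MTU sits at lopt + lslack
  expect_equal(mtu_lengths(b), b$model$muscles$lref, tolerance = 1e-12)
  # hip flexion shortens the hip flexor ILI and lengthens the extensor GLU
  q <- b$q0; q[4] <- 0.3
  l <- mtu_lengths(b, q)
  expect_lt(l[2], b$model$muscles$lref[2])   # ILI
  expect_gt(l[1], b$model$muscles$lref[1])   # GLU
})
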