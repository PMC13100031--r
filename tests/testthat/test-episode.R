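# Episodes: termination rules, stability flag, gait metrics.

test_that("unactuated biped collapses; stable flag tracks t_sim = t_max", {
  b <- biped_fixture()
  ep <- run_episode(b, rep(0, 71), episode_config(b))
  expect_false(ep$stable)
  expect_lt(ep$t_sim, 50)
  expect_equal(ep$diagnostic, "fell")
  # fall detection: recorded CoM height at termination is near the threshold
  expect_lt(ep$com[nrow(ep$com), 2], 0.9)
})

test_that("a surviving episode is stable with t_sim = t_max exactly", {
  toy <- toy_fixture()
  ep <- run_episode(toy$plant, toy$p_baseline,
                    episode_config(toy$plant, t_max = 20))
  expect_true(ep$stable)
  expect_identical(ep$t_sim, 20)
  expect_equal(ep$gait, "run")               # periodic flight phases
  expect_false(is.na(ep$v_act))
})

test_that("episodes are deterministic", {
  toy <- toy_fixture()
  cfg <- episode_config(toy$plant, t_max = 3)
  e1 <- run_episode(toy$plant, toy$p_baseline, cfg)
  e2 <- run_episode(toy$plant, toy$p_baseline, cfg)
  expect_identical(e1$q, e2$q)
  expect_identical(e1$force, e2$force)
  expect_identical(e1$t_sim, e2$t_sim)
})

test_that("completed distance follows the conservative segment-selection rule", {
  # rigid translation: both directions agree
  x <- rbind(c(0, 0), c(10, 10))
  expect_equal(completed_distance(x, "maximize_v"), 10)
  expect_equal(completed_distance(x, "minimize_v"), 10)
  # stationary model
  expect_equal(completed_distance(rbind(c(0, 0), c(0, 0))), 0)
  # two segments ending at 3 m and 5 m: min distance for maximization,
  # max distance for minimization
  x <- rbind(c(0, 0), c(3, 5))
  expect_equal(completed_distance(x, "maximize_v"), 3)
  expect_equal(completed_distance(x, "minimize_v"), 5)
  expect_error(completed_distance(matrix(0, 0, 2)), "empty")
})

test_that("d_sim is invariant to a rigid global translation of the start pose", {
  toy <- toy_fixture()
  cfg1 <- episode_config(toy$plant, t_max = 3)
  q0 <- toy$plant$q0; q0[1] <- 5                   # start 5 m downstream
  cfg2 <- episode_config(toy$plant, t_max = 3, q0 = q0)
  e1 <- run_episode(toy$plant, toy$p_baseline, cfg1)
  e2 <- run_episode(toy$plant, toy$p_baseline, cfg2)
  expect_equal(completed_distance(e1), completed_distance(e2),
               tolerance = 1e-9)
})

test_that("moving-average velocity: constants, step response, brute force", {
  dt <- 0.01
  expect_equal(moving_average_velocity(rep(1.2, 300), dt),
               rep(1.2, 300))
  # unit step at t0: linear rise completing one window after the step
  n <- 400; i0 <- 200
  v <- c(rep(0, i0), rep(1, n - i0))
  out <- moving_average_velocity(v, dt, window = 1)
  k <- round(1 / dt)
  expect_equal(out[i0], 0)
  expect_equal(out[i0 + k], 1)                      # rise complete at t0 + 1 s
  ramp <- out[(i0 + 1):(i0 + k)]
  expect_equal(ramp, seq_len(k) / k)                # exactly linear
  # series shorter than the window
  expect_error(moving_average_velocity(rep(1, 50), dt, window = 1),
               "shorter")
  # exact agreement with a brute-force trailing mean
  set.seed(3)
  v <- rnorm(250)
  out <- moving_average_velocity(v, dt, window = 0.3)
  kk <- round(0.3 / dt)
  brute <- vapply(seq_along(v), function(i)
    mean(v[max(1, i - kk + 1):i]), numeric(1))
  expect_equal(out, brute, tolerance = 1e-12)
})

test_that("gait classification distinguishes walk, run and neither", {
  n <- 600
  phase <- ((seq_len(n) - 1) %% 100) / 100
  # walking: duty factor 0.6 per foot, half-cycle offset: always >= 1 down
  walk <- cbind(phase < 0.6, (phase + 0.5) %% 1 < 0.6)
  expect_equal(classify_gait(walk), "walk")
  # running: duty factor 0.3: periodic flight phases
  run <- cbind(phase < 0.3, (phase + 0.5) %% 1 < 0.3)
  expect_equal(classify_gait(run), "run")
  # single stride: too short to classify
  expect_equal(classify_gait(walk[1:120, ]), "none")
  # grounded but never single-support (hopping on both feet): none
  both <- cbind(rep(TRUE, n), rep(TRUE, n))
  expect_equal(classify_gait(both), "none")
})

test_that("stride events: square-wave forces give toe-off at falling edges", {
  dt <- 0.01
  t <- seq(0, 6, by = dt)
  fz <- ifelse((t %% 1) < 0.6, 100, 0)              # 1 s stride, 60% stance
  ev <- stride_events(fz, t, threshold = 20)
  expect_equal(diff(ev$heel_strike), rep(1, length(ev$heel_strike) - 1),
               tolerance = 0.02)
  # toe-offs at each falling edge (0.6 s into each stride)
  expect_true(all(abs((ev$toe_off %% 1) - 0.6) < 0.02))
  expect_equal(ev$stance_fraction, 0.6, tolerance = 0.02)
  expect_error(stride_events(rep(0, 100), seq(0, 0.99, 0.01)), "cycles")
})

test_that("gait-cycle curves and RMS against reference behave as defined", {
  toy <- toy_fixture()
  ep <- run_episode(toy$plant, toy$p_baseline,
                    episode_config(toy$plant, t_max = 10))
  ev <- stride_events(ep$contact_normal[, 1], ep$t)
  ang <- gait_cycle_angles(ep, "leg_s", ev$heel_strike)
  expect_equal(dim(ang), c(101L, 1L))
  expect_identical(range(attr(ang, "phase")), c(0, 100))
  # identical curves: RMS 0; constant 5 degree offset: RMS 5
  expect_equal(unname(rms_vs_reference(ang, ang)), 0)
  expect_equal(unname(rms_vs_reference(ang + 5, ang)), 5)
  expect_error(gait_cycle_angles(ep, "nope", ev$heel_strike), "unknown dof")
})
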