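# Target-speed schedules: step and ramp analytics, online runs,
# step-limit scanning.

test_that("schedules start mid-range and hold through the settle time", {
  s <- make_schedule("ramp", v_min = 0.8, v_max = 1.5)
  expect_equal(s$v_start, 0.8 + (1.5 - 0.8) / 2)
  for (kind in c("constant", "step", "ramp")) {
    sk <- make_schedule(kind, 0.8, 1.5, j = 1)
    expect_equal(schedule_value(sk, 5), sk$v_start)      # t < settle
    expect_equal(schedule_value(sk, 0), sk$v_start)
  }
})

test_that("step schedules jump by exactly j quanta at the settle time", {
  s <- make_schedule("step", v_min = 0.8, v_max = 1.2, j = 1)
  expect_equal(s$v_start, 1.0)
  expect_equal(schedule_value(s, 19.999), 1.0)
  expect_equal(schedule_value(s, 20), 1.025)
  expect_equal(schedule_value(s, 45), 1.025)
  sdn <- make_schedule("step", 0.8, 1.2, j = 25, direction = "down")
  expect_equal(schedule_value(sdn, 30), 1.0 - 25 * 0.025)
  # piecewise constant with exactly one discontinuity, at the settle time
  tt <- seq(0, 50, by = 0.01)
  v <- schedule_value(s, tt)
  jumps <- which(diff(v) != 0)
  expect_length(jumps, 1L)
  expect_equal(tt[jumps + 1L], 20)
  expect_error(make_schedule("step", 0.8, 1.2, j = 26), "j in 1..25")
  expect_error(make_schedule("step", 0.8, 1.2), "j in 1..25")
})

test_that("ramp analytics: period, extrema, slope, onset (brute force)", {
  # span 0.7 m/s at 0.05 m/s per s: period 28 s
  s <- make_schedule("ramp", v_min = 0.9, v_max = 1.6)
  expect_equal(s$T_period, 28)
  tt <- seq(20, 20 + 2 * 28, by = 1e-3)
  v <- schedule_value(s, tt)
  expect_equal(max(v), 1.6, tolerance = 1e-9)
  expect_equal(min(v), 0.9, tolerance = 1e-9)
  # starts at v_start and first increases toward v_max
  expect_equal(schedule_value(s, 20), s$v_start)
  expect_gt(schedule_value(s, 21), s$v_start)
  expect_equal(schedule_value(s, 20 + 28 / 4), 1.6)      # peak a quarter in
  # |slope| = v_a except at the extrema
  sl <- diff(v) / 1e-3
  interior <- abs(v[-1] - 1.6) > 1e-3 & abs(v[-1] - 0.9) > 1e-3
  expect_equal(range(abs(sl[interior])), c(0.05, 0.05), tolerance = 1e-6)
  # bounded everywhere
  expect_true(all(v >= 0.9 - 1e-12 & v <= 1.6 + 1e-12))
})

test_that("online runs switch parameters only at schedule update instants", {
  toy <- toy_fixture()
  p0 <- encode_params(toy$p_baseline)
  keys <- c(1L, 5L)
  m <- structure(list(beta = matrix(c(p0[keys], 0.01, 0.02, 0, 0, 0, 0),
                                    2, 4),
                      keys = keys, d_reg = 1, p_init = p0,
                      v_range = c(0, 0.2), stable_range = c(0, 0.2)),
                 class = "rg_smf")
  cfg <- episode_config(toy$plant, t_max = 12)
  s <- make_schedule("step", 0.02, 0.18, j = 2, settle = 6)
  r <- run_online(toy$plant, m, s, cfg)
  expect_equal(r$switch_t, c(0, 6))
  expect_equal(r$switch_v_tgt, schedule_value(s, c(0, 6)))
  ramp <- make_schedule("ramp", 0.02, 0.18, settle = 6)
  rr <- run_online(toy$plant, m, ramp, cfg)
  expect_true(all(rr$switch_t %in% c(0, seq(6, 12, by = 1))))
  # applied vectors before/after the settle time match the assembly rule
  expect_equal(r$switch_v_tgt[1], s$v_start)
  expect_equal(r$switch_v_tgt[2], s$v_end)
})

test_that("an online run with a constant schedule is bit-identical to the episode", {
  toy <- toy_fixture()
  p0 <- encode_params(toy$p_baseline)
  m <- structure(list(beta = matrix(c(p0[1], 0, 0, 0), 1, 4), keys = 1L,
                      d_reg = 1, p_init = p0, v_range = c(0, 0.2),
                      stable_range = c(0, 0.2)),
                 class = "rg_smf")
  cfg <- episode_config(toy$plant, t_max = 8)
  on <- run_online(toy$plant, m, make_schedule("constant", 0.05, 0.15), cfg)
  off <- run_episode(toy$plant, assemble_params(m, 0.1), cfg)
  expect_identical(on$episode$q, off$q)
  expect_identical(on$episode$force, off$force)
  expect_identical(on$episode$t_sim, off$t_sim)
})

test_that("the step-limit scan returns the largest surviving index", {
  toy <- toy_fixture()
  m <- structure(list(stable_range = c(0.5, 1.5)), class = "rg_smf")
  stub <- function(limit) function(plant, model, s, cfg)
    list(stable = s$j <= limit)
  r <- largest_stable_step(toy$plant, m, "up", runner = stub(7))
  expect_equal(r$j_star, 7L)
  expect_equal(r$delta_v, 7 * 0.025)
  expect_equal(largest_stable_step(toy$plant, m, "up",
                                   runner = stub(99))$j_star, 25L)
  expect_equal(largest_stable_step(toy$plant, m, "down",
                                   runner = stub(0))$j_star, 0L)
  m_unswept <- structure(list(stable_range = c(NA_real_, NA_real_)),
                         class = "rg_smf")
  expect_error(largest_stable_step(toy$plant, m_unswept, "up",
                                   runner = stub(1)), "stable range")
})
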