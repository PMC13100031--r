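# Speed optimization: cost arithmetic, CMA-ES behaviour, harvesting,
# dataset merging.

test_that("cost reproduces the fall-penalty/velocity-reward arithmetic", {
  # immediate fall: J_fall = 1, J_vel = 0, J = 100
  cb <- cost(fake_episode(0, 50, c(0, 0), c(0, 0)), "minimize_v")
  expect_equal(cb$J_fall, 1)
  expect_equal(cb$J_vel, 0)
  expect_equal(cb$J, 100)
  # stable stationary model, minimize: both terms vanish
  cb <- cost(fake_episode(50, 50, c(0, 0), c(0, 0)), "minimize_v")
  expect_equal(cb$J, 0)
  # stable, d_sim = 150 m over t_max = 50 s, maximize: J_vel = -3, J = -300
  cb <- cost(fake_episode(50, 50, c(0, 0), c(150, 160)), "maximize_v")
  expect_equal(cb$J_vel, -3)
  expect_equal(cb$J, -300)
  # J = 100 J_vel + 100 J_fall holds exactly on random inputs
  set.seed(5)
  for (i in 1:20) {
    ts <- runif(1, 0, 50); x1 <- rnorm(3, 5)
    ep <- fake_episode(ts, 50, c(0, 0, 0), x1)
    for (dir in c("minimize_v", "maximize_v")) {
      cb <- cost(ep, dir)
      d <- completed_distance(ep, dir)
      jv <- if (dir == "minimize_v") d / 50 else -d / 50
      expect_equal(cb$J, 100 * jv + 100 * (1 - ts / 50), tolerance = 1e-12)
      expect_true(cb$J_fall >= 0 && cb$J_fall <= 1)
    }
  }
})

test_that("CMA-ES recovers the optimum of a 5-D sphere to < 1e-6", {
  sphere <- function(x) sum((x - 3)^2)
  r <- cma_es(sphere, rep(0, 5), sigma0 = 0.5, seed = 2, max_gen = 600)
  expect_lt(r$value, 1e-6)
  expect_lt(max(abs(r$par - 3)), 1e-3)
})

test_that("CMA-ES stops via the improvement rule on a flat landscape", {
  r <- cma_es(function(x) 1, rep(0, 4), sigma0 = 0.1, seed = 1,
              max_gen = 3000, improve_window = 500)
  expect_equal(r$reason, "improvement")
  expect_equal(r$generations, 501L)
})

test_that("best-so-far cost is non-increasing along any history", {
  r <- cma_es(function(x) sum(x^2) + rnorm(1), rep(1, 3), sigma0 = 0.3,
              seed = 9, max_gen = 120, improve_window = 1e6)
  expect_true(all(diff(r$history$best) <= 0))
})

test_that("CMA-ES is reproducible given a seed", {
  f <- function(x) sum(x^2)
  r1 <- cma_es(f, rep(1, 4), sigma0 = 0.3, seed = 5, max_gen = 50,
               improve_window = 1e6)
  r2 <- cma_es(f, rep(1, 4), sigma0 = 0.3, seed = 5, max_gen = 50,
               improve_window = 1e6)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$history, r2$history)
})

test_that("speed optimization on the hopper produces a usable history", {
  toy <- toy_fixture()
  cfg <- episode_config(toy$plant, t_max = 10)
  h <- optimize_speed(toy$plant, encode_params(toy$p_baseline), "maximize_v",
                      cma = cma_config(sigma0 = 0.05, lambda = 6,
                                       max_gen = 5, seed = 3),
                      cfg = cfg, check_init = FALSE)
  expect_s3_class(h, "rg_opt_history")
  expect_equal(ncol(h$candidates), 10L)
  expect_true(all(diff(h$history$best) <= 0))
  # harvested records are all stable and sorted by speed
  ds <- harvest(h, toy$plant, cfg)
  expect_true(all(ds$stable))
  expect_lte(n_records(ds), nrow(h$candidates))
  expect_true(!is.unsorted(ds$v_act))
})

test_that("an unstable starting point triggers a warning", {
  toy <- toy_fixture()
  expect_warning(
    optimize_speed(toy$plant, rep(0, 10), "maximize_v",
                   cma = cma_config(lambda = 4, max_gen = 1, seed = 1),
                   cfg = episode_config(toy$plant, t_max = 2)),
    "stable")
})

test_that("harvesting a history whose candidates all fall yields an empty dataset", {
  toy <- toy_fixture()
  h <- structure(list(direction = "maximize_v", seed = 1,
                      candidates = matrix(0, 3, 10),
                      history = data.frame(gen = 1:3)),
                 class = "rg_opt_history")
  expect_warning(ds <- harvest(h, toy$plant,
                               episode_config(toy$plant, t_max = 2)),
                 "empty")
  expect_equal(n_records(ds), 0L)
})

test_that("omega merging selects the largest-span run per direction", {
  mk_ds <- function(v, off) reflexgait:::new_speed_dataset(
    matrix(seq_along(v) + off, length(v), 3), v,
    data.frame(seed = 1, gen = seq_along(v), direction = "x"))
  narrow <- mk_ds(c(1.0, 1.05, 1.1), 0)
  wide <- mk_ds(c(0.8, 0.95, 1.1), 10)
  fast <- mk_ds(c(1.6, 1.9), 20)
  toy <- toy_fixture()
  omega <- build_omega(list(narrow, wide), list(fast), toy$plant)
  # the wider minimization harvest wins; merged set spans both directions
  expect_equal(speed_range(omega), 1.9 - 0.8)
  expect_true(!is.unsorted(omega$v_act))
  # duplicates (identical parameter rows) are removed
  omega2 <- build_omega(list(wide, wide), list(fast), toy$plant)
  expect_equal(n_records(omega2), 5L)
  expect_error(build_omega(list(), list(), toy$plant), "empty")
})
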