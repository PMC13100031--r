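# Reflex controller: connection topology, parameter codec, stimulation law,
# delays, and consistency of the in-simulation controller with the law.

test_that("default connection matrix has the canonical topology", {
  cm <- build_connection_matrix()
  expect_s3_class(cm, "rg_connections")
  expect_equal(nrow(cm), 31L)
  expect_equal(sum(cm$relation == "homonymous"), 9L)
  expect_equal(sum(cm$relation == "antagonistic"), 22L)
  # every muscle is a target at least once, identical for both legs by design
  expect_setequal(unique(cm$target), muscle_names())
  # canonical order: by target, homonymous first, then source
  tid <- match(cm$target, muscle_names())
  expect_true(!is.unsorted(tid))
  expect_equal(n_params(cm), 71L)
})

test_that("malformed antagonist maps raise topology errors with the count", {
  expect_error(build_connection_matrix(NULL), "9 connections")
  expect_error(build_connection_matrix(rbind(c("GLU", "GLU"))), "self-pair")
  expect_error(build_connection_matrix(rbind(c("GLU", "XXX"))), "XXX")
})

test_that("parameter codec round-trips exactly and rejects wrong lengths", {
  cm <- build_connection_matrix()
  set.seed(1)
  p <- reflex_params(rnorm(31), rnorm(31), rnorm(9), cm)
  v <- encode_params(p)
  expect_length(v, 71L)
  expect_identical(names(v), param_names(cm))
  p2 <- decode_params(v, cm)
  expect_identical(p2$kL, p$kL)
  expect_identical(p2$kF, p$kF)
  expect_identical(p2$c, p$c)
  expect_error(decode_params(rnorm(70), cm), "codec")
  expect_error(reflex_params(rnorm(30), rnorm(31), rnorm(9), cm), "31")
})

test_that("stimulation law: offsets, gains, clipping", {
  cm <- build_connection_matrix()
  nm <- 9L
  h <- sensor_history(dt = 1e-3, L = matrix(0.5, 100, nm),
                      F = matrix(0.2, 100, nm), delays = rep(0.01, nm))
  # all gains zero: u = c everywhere
  p <- reflex_params(rep(0, 31), rep(0, 31), rep(0.3, 9), cm)
  expect_equal(unname(compute_stimulation(0.05, h, p)), rep(0.3, 9))
  # single length connection: u = kL * Ldel
  kL <- rep(0, 31); kL[1] <- 1     # first connection is GLU homonymous
  p <- reflex_params(kL, rep(0, 31), rep(0, 9), cm)
  u <- compute_stimulation(0.05, h, p)
  expect_equal(unname(u["GLU"]), 0.5)
  # offsets beyond the bound clip to 1
  p <- reflex_params(rep(0, 31), rep(0, 31), rep(2, 9), cm)
  expect_equal(unname(compute_stimulation(0.05, h, p)), rep(1, 9))
})

test_that("stimulation is affine in the gains before clipping (brute force)", {
  cm <- build_connection_matrix()
  nm <- 9L
  set.seed(7)
  L <- matrix(runif(200 * nm), 200, nm)
  F <- matrix(runif(200 * nm), 200, nm)
  delays <- rep(0.02, nm)
  h <- sensor_history(dt = 1e-3, L, F, delays)
  mus <- muscle_names()
  for (rep in 1:5) {
    p <- reflex_params(rnorm(31, sd = 0.1), rnorm(31, sd = 0.1),
                       runif(9, 0.1, 0.5), cm)
    t <- 0.15
    u <- compute_stimulation(t, h, p)
    # independent recomputation straight from the reflex law
    idx <- round((t - 0.02) / 1e-3) + 1L
    u_ref <- p$c
    for (k in seq_len(31)) {
      s <- match(cm$source[k], mus); tg <- match(cm$target[k], mus)
      u_ref[tg] <- u_ref[tg] + p$kL[k] * L[idx, s] + p$kF[k] * F[idx, s]
    }
    expect_equal(unname(u), pmin(pmax(u_ref, 0), 1), tolerance = 1e-12)
  }
})

test_that("a sinusoidal length signal arrives shifted by exactly the delay", {
  cm <- build_connection_matrix()
  nm <- 9L
  dt <- 1e-3; delay <- 0.02
  tgrid <- seq(0, 1, by = dt)
  L <- matrix(sin(2 * pi * 2 * tgrid), length(tgrid), nm)
  h <- sensor_history(dt, L, matrix(0, length(tgrid), nm),
                      delays = rep(delay, nm))
  kL <- rep(0, 31); kL[1] <- 1
  p <- reflex_params(kL, rep(0, 31), rep(0, 9), cm)
  for (t in c(0.1, 0.25, 0.42)) {
    u <- compute_stimulation(t, h, p)
    expect_equal(unname(u["GLU"]),
                 max(0, sin(2 * pi * 2 * (t - delay))), tolerance = 1e-9)
  }
})

test_that("normalized signals follow their definitions", {
  s <- normalize_signals(lce = 0.05, force = 4000, lopt = 0.05, fmax = 4000)
  expect_equal(s$L, 1)
  expect_equal(s$F, 1)
  expect_equal(normalize_signals(0.04, 0, 0.05, 4000)$F, 0)
})

test_that("the simulated controller reproduces the reflex law sample by sample", {
  toy <- toy_fixture()
  p <- toy$p_baseline
  ep <- run_episode(toy$plant, p, episode_config(toy$plant, t_max = 3))
  # connection order: EXT-EXT, EXT<-FLX, FLX-FLX, FLX<-EXT
  u_ext <- pmin(pmax(p$c[1] +
                       p$kL[1] * ep$L_delayed[, 1] + p$kF[1] * ep$F_delayed[, 1] +
                       p$kL[2] * ep$L_delayed[, 2] + p$kF[2] * ep$F_delayed[, 2],
                     0), 1)
  u_flx <- pmin(pmax(p$c[2] +
                       p$kL[3] * ep$L_delayed[, 2] + p$kF[3] * ep$F_delayed[, 2] +
                       p$kL[4] * ep$L_delayed[, 1] + p$kF[4] * ep$F_delayed[, 1],
                     0), 1)
  expect_equal(ep$stim[, 1], u_ext, tolerance = 1e-12)
  expect_equal(ep$stim[, 2], u_flx, tolerance = 1e-12)
})
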