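# Speed-modulation function: polynomial recovery, assembly, sweeps.

noiseless_ds <- function(coefs, keys = seq_len(nrow(coefs)), n = 30,
                         seed = 1, n_params = 71) {
  gen_param_speed_dataset(synth_dataset_spec(
    n_params = n_params, n_records = n, true_keys = keys, coefs = coefs,
    noise_rel = 0, seed = seed))
}

test_that("noiseless cubic data are recovered to < 1e-8, and degree caps hold", {
  co <- rbind(c(0.2, -0.5, 0.3, 0.05), c(1, 0.8, -0.2, 0.01),
              c(-0.4, 1.2, 0, -0.08))
  ds <- noiseless_ds(co, keys = c(2, 10, 33))
  m3 <- fit_smf(ds, c(2, 10, 33), d_reg = 3, p_init = rep(0.1, 71))
  expect_lt(max(abs(m3$beta - co)), 1e-8)
  # noiseless linear data, degree 1: exact recovery
  col <- cbind(c(0.5, -1), c(2, 0.3), 0, 0)
  dsl <- noiseless_ds(col, keys = c(1, 5))
  m1 <- fit_smf(dsl, c(1, 5), d_reg = 1, p_init = rep(0, 71))
  expect_lt(max(abs(m1$beta - col)), 1e-8)
  # beta_n = 0 for n > d_reg, recomputed per degree
  m2 <- fit_smf(ds, c(2, 10, 33), d_reg = 2, p_init = rep(0.1, 71))
  expect_true(all(m2$beta[, 4] == 0))
  m1b <- fit_smf(ds, c(2, 10, 33), d_reg = 1, p_init = rep(0.1, 71))
  expect_true(all(m1b$beta[, 3:4] == 0))
})

test_that("degenerate designs are rejected", {
  co <- rbind(c(0, 1, 0, 0))
  ds <- noiseless_ds(co, keys = 3, n = 10)
  ds$v_act[] <- 1.0
  expect_error(fit_smf(ds, 3, d_reg = 1), "degenerate")
  small <- noiseless_ds(co, keys = 3, n = 10)
  small$v_act <- small$v_act[1:3]
  small$params <- small$params[1:3, , drop = FALSE]
  expect_error(fit_smf(small, 3, d_reg = 3), "too small")
})

test_that("assembly: key polynomials, frozen non-keys, smoothness", {
  co <- rbind(c(0.2, -0.5, 0.3, 0.05), c(1, 0.8, -0.2, 0.01))
  keys <- c(7, 40)
  ds <- noiseless_ds(co, keys = keys)
  p_init <- seq(0.01, 0.71, by = 0.01)
  m <- fit_smf(ds, keys, d_reg = 3, p_init = p_init)
  # non-key entries equal p_init exactly for any target
  for (v in c(0.3, 1.0, 2.7)) {
    p <- assemble_params(m, v)
    expect_identical(p[-keys], p_init[-keys])
  }
  # at dataset speeds the key entries reproduce the records
  for (i in c(1, 12, 30)) {
    p <- assemble_params(m, ds$v_act[i])
    expect_lt(max(abs(p[keys] - ds$params[i, keys])), 1e-8)
  }
  # pass-through: editing a non-key entry of p_init propagates identically
  p_init2 <- p_init; p_init2[3] <- -9
  m2 <- fit_smf(ds, keys, d_reg = 3, p_init = p_init2)
  expect_equal(assemble_params(m2, 1)[3], -9)
  # continuity: nearby targets give O(eps) output differences
  d <- max(abs(assemble_params(m, 1) - assemble_params(m, 1 + 1e-6)))
  expect_lt(d, 1e-4)
  # extrapolation is allowed but flagged
  expect_true(attr(assemble_params(m, 99), "extrapolated"))
  expect_false(attr(assemble_params(m, 1), "extrapolated"))
})

test_that("the default sweep grid has 121 points with 0.025 spacing", {
  g <- sweep_grid()
  expect_length(g, 121L)
  expect_equal(g[1], 0.5)
  expect_equal(g[length(g)], 3.5)
  expect_equal(unique(round(diff(g), 10)), 0.025)
})

test_that("offline sweep populates stability, v_act and gait per point", {
  toy <- toy_fixture()
  cfg <- episode_config(toy$plant, t_max = 10)
  # modulation model centred on the baseline: identity-ish toy SMF
  p0 <- encode_params(toy$p_baseline)
  ds <- harvest(optimize_speed(toy$plant, p0, "maximize_v",
                               cma = cma_config(sigma0 = 0.05, lambda = 6,
                                                max_gen = 6, seed = 1),
                               cfg = cfg, check_init = FALSE),
                toy$plant, cfg)
  expect_gte(n_records(ds), 4L)
  keys <- select_keys(fit_pca(ds), 3)
  m <- fit_smf(ds, keys, d_reg = 1, p_init = p0)
  grid <- seq(min(ds$v_act), max(ds$v_act), length.out = 4)
  sw <- offline_sweep(toy$plant, m, grid, cfg)
  expect_equal(nrow(sw$points), 4L)
  st <- sw$points$stable
  expect_true(all(!is.na(sw$points$v_act[st])))
  expect_true(all(is.na(sw$points$v_act[!st])))
  expect_true(all(!is.na(sw$points$gait[st])))
  expect_identical(sw$model$stable_range, sw$stable_range)
  expect_error(offline_sweep(toy$plant, m, c(1, 0.5), cfg), "increasing")
})

test_that("monotonicity diagnostics count inversions and identity deviation", {
  mk_sweep <- function(v_tgt, v_act) structure(
    list(points = data.frame(v_tgt = v_tgt, stable = TRUE, v_act = v_act,
                             gait = "run")), class = "rg_sweep")
  # strictly increasing: no violations
  r <- monotonicity_report(mk_sweep(1:5 * 0.1, 1:5 * 0.1))
  expect_equal(r$n_violations, 0L)
  expect_equal(r$max_identity_deviation, 0)
  # one inversion: exactly one violation
  r <- monotonicity_report(mk_sweep(1:5 * 0.1, c(0.1, 0.2, 0.15, 0.4, 0.5)))
  expect_equal(r$n_violations, 1L)
  expect_equal(r$violations$v_tgt, 0.3)
  # sub-tolerance jitter between identical outcomes is not a violation
  r <- monotonicity_report(mk_sweep(1:3 * 0.1, c(0.1, 0.1 - 1e-12, 0.2)))
  expect_equal(r$n_violations, 0L)
  expect_error(monotonicity_report(mk_sweep(0.1, 0.1)), "2 stable")
})
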