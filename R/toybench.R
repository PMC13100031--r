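# Desk-scale testbed: a reduced muscle-driven hopper exercising the full
# controller/episode/optimizer machinery, and synthetic parameter-over-speed
# datasets with known ground truth for PCA/regression recovery tests.

#' Toy plant configuration
#'
#' A point-mass torso on one telescoping leg with two musculotendon units
#' (extensor, flexor) sharing the full plant/controller machinery: Hill
#' muscles, viscoelastic contact, and the delayed reflex network restricted
#' to 2 homonymous + 2 antagonistic connections + 2 offsets (10
#' parameters). The leg is inclined slightly backwards so hopping carries
#' the body forward.
#'
#' @param body_mass_kg,leg_mass_kg Masses (kg).
#' @param lean_rad Backward lean of the leg axis (rad); the inclined push
#'   carries the body forward.
#' @param gear Transmission ratio between muscle length and leg extension.
#' @param leg_range_m Soft telescoping limits `c(lo, hi)` (m).
#' @param leg_damping_Nspm Viscous damping on the telescoping coordinate.
#' @param dt_s Integrator timestep (s).
#' @param fall_height_m Fall threshold on the CoM (m).
#' @param contact Contact constants (see [plant_config()]).
#' @return Object of class `rg_toy_config`.
#' @export
toy_plant_config <- function(body_mass_kg = 65, leg_mass_kg = 5,
                             lean_rad = 0.08, gear = 0.2,
                             leg_range_m = c(0.55, 0.98),
                             leg_damping_Nspm = 10, dt_s = 5e-4,
                             fall_height_m = 0.60,
                             contact = list(k_n = 2e5, exp_n = 1.5,
                                            c_hc = 1.0, mu = 0.9,
                                            v_reg = 0.05)) {
  if (!isTRUE(body_mass_kg > 0 && leg_mass_kg > 0))
    stop("configuration error: masses must be > 0")
  if (!isTRUE(dt_s > 0)) stop("configuration error in 'dt_s': must be > 0")
  structure(list(body_mass_kg = body_mass_kg, leg_mass_kg = leg_mass_kg,
                 lean_rad = lean_rad, gear = gear, leg_range_m = leg_range_m,
                 leg_damping_Nspm = leg_damping_Nspm, dt_s = dt_s,
                 fall_height_m = fall_height_m, contact = contact),
            class = "rg_toy_config")
}

#' Toy connection matrix
#'
#' The hopper's reflex network: extensor and flexor with homonymous and
#' mutual antagonistic connections (4 connections, 10 free parameters).
#'
#' @return An `rg_connections` for muscles `EXT`, `FLX`.
#' @export
toy_connection_matrix <- function() {
  build_connection_matrix(rbind(c("EXT", "FLX")),
                          muscles = c("EXT", "FLX"), expected_total = 4L)
}

#' Baseline hopper reflex parameters
#'
#' Committed constants found once by desk-scale search. Positive force
#' feedback on the extensor rebuilds the push during stance; inhibitory
#' length feedback from the flexor — whose short optimal length makes its
#' normalized CE length a sharp leg-extension sensor — cuts the extensor
#' near full extension, so the limit cycle alternates loading and flight.
#' With the default plant this yields sustained forward hopping
#' (about 0.1 m/s), and the actual velocity increases monotonically with
#' the extensor's homonymous force gain over `[0.9, 1.7]`.
#'
#' @return An `rg_params` on the toy connection matrix.
#' @export
toy_baseline_params <- function() {
  cm <- toy_connection_matrix()
  # canonical connection order: EXT-EXT (hom), EXT<-FLX, FLX-FLX (hom),
  # FLX<-EXT
  reflex_params(kL = c(0, -3.4, 0, 0),
                kF = c(1.3, 0, 0, 0),
                c = c(3.0, 0.02), cm)
}

#' Build the toy hopper plant
#'
#' @param cfg A [toy_plant_config()].
#' @return List with `plant` (an `rg_plant`) and `p_baseline` (the
#'   committed baseline `rg_params` producing sustained hopping).
#' @export
make_toy_plant <- function(cfg = toy_plant_config()) {
  stopifnot(inherits(cfg, "rg_toy_config"))
  a <- cfg$lean_rad
  bodies <- data.frame(
    name = c("body", "leg"),
    parent = c(0L, 1L),
    jtype = c("planar_xy", "prismatic"),
    anchor_x = 0, anchor_y = 0,
    axis_x = c(0, -sin(a)), axis_y = c(0, -cos(a)),
    mass = c(cfg$body_mass_kg, cfg$leg_mass_kg),
    inertia = c(1, 0.05),
    com_x = 0, com_y = 0,
    stringsAsFactors = FALSE)
  ndof <- 3L
  damping <- c(0, 0, cfg$leg_damping_Nspm)
  lim <- matrix(NA_real_, ndof, 4)
  lim[3, ] <- c(cfg$leg_range_m[1], cfg$leg_range_m[2], 1e5, 500)
  contacts <- list(body = 2L, point = matrix(c(0, 0), 1, 2))

  g <- cfg$gear
  # l_mt = lref - marm * s; the extensor shortens as the leg extends and
  # its tendon goes slack near full extension; the flexor's short CE makes
  # L~ a sharp leg-extension sensor
  lopt <- c(0.16, 0.04); lslack <- c(0.20, 0.30)
  marm <- matrix(0, 2, ndof)
  marm[1, 3] <- g; marm[2, 3] <- -g
  lref <- c(lopt[1] + lslack[1] + g * 0.95,
            lopt[2] + lslack[2] - g * 0.93)
  muscles <- list(
    fmax = c(12000, 2000), lopt = lopt, lslack = lslack,
    vmax = c(10, 10), tau_act = c(0.01, 0.01), tau_deact = c(0.04, 0.04),
    delay_steps = as.integer(round(c(0.020, 0.020) / cfg$dt_s)),
    lref = lref, flw = c(0.56, 0.56), fv_k = c(0.25, 0.25),
    fv_ml = c(1.5, 1.5), eps_ref = c(0.08, 0.08), marm = marm)

  cm <- toy_connection_matrix()
  # canonical connection order maps directly (single leg)
  conn_tgt <- match(cm$target, c("EXT", "FLX"))
  conn_src <- match(cm$source, c("EXT", "FLX"))
  model <- rg_model(bodies, damping, lim, 9.81, contacts, cfg$contact,
                    muscles, conn_tgt, conn_src)
  plant <- new_plant(model, "hopper", cfg, cm,
                     conn_class = seq_len(nrow(cm)),
                     musc_class = 1:2,
                     dof_names = c("body_x", "body_y", "leg_s"),
                     joint_sign = c(1, 1, 1),
                     q0 = c(0, 0.90, 0.88), qd0 = c(0, 0, 0),
                     contact_groups = list(foot = 1L),
                     defaults = list(dt = cfg$dt_s,
                                     fall_y = cfg$fall_height_m,
                                     record_dt = 0.01, transient = 5))
  list(plant = plant, p_baseline = toy_baseline_params())
}

#' Synthetic parameter-over-speed dataset specification
#'
#' Describes a dataset in which a known subset of parameters follows
#' polynomial trends in speed (plus Gaussian noise) while all others stay
#' constant (plus noise) — ground truth for key-parameter and
#' speed-modulation recovery tests. Reflecting the predominantly smooth,
#' monotone parameter-speed trends of harvested optimization datasets,
#' randomly drawn trend polynomials have a dominant linear term.
#'
#' @param n_params Number of parameters (default 71).
#' @param n_records Number of records `n_v`.
#' @param true_keys Indices of the truly speed-varying parameters.
#' @param coefs Polynomial coefficient matrix (`length(true_keys) x 4`,
#'   `beta0..beta3`), or `NULL` to draw them from the seed.
#' @param degree Degree of drawn polynomials (when `coefs` is `NULL`).
#' @param speed_range Speed interval `c(lo, hi)` (m/s).
#' @param noise_rel Noise standard deviation per column, relative to the
#'   per-key signal standard deviation (non-key columns use the mean key
#'   signal sd).
#' @param base Baseline values of the non-key columns (recycled).
#' @param seed RNG seed.
#' @return Object of class `rg_synth_spec`.
#' @export
synth_dataset_spec <- function(n_params = 71, n_records = 40,
                               true_keys = 1:5, coefs = NULL, degree = 3,
                               speed_range = c(0.5, 1.5), noise_rel = 0.1,
                               base = 0.1, seed = 1) {
  if (!all(true_keys >= 1 & true_keys <= n_params))
    stop("invalid spec: true_keys outside 1..n_params")
  if (anyDuplicated(true_keys)) stop("invalid spec: duplicated true keys")
  if (n_records < degree + 2)
    stop("invalid spec: n_records must be >= degree + 2")
  if (!is.null(coefs)) {
    coefs <- as.matrix(coefs)
    if (nrow(coefs) != length(true_keys) || ncol(coefs) != 4)
      stop("invalid spec: coefs must be length(true_keys) x 4")
  }
  structure(list(n_params = n_params, n_records = n_records,
                 true_keys = as.integer(true_keys), coefs = coefs,
                 degree = degree, speed_range = speed_range,
                 noise_rel = noise_rel, base = base, seed = seed),
            class = "rg_synth_spec")
}

#' Generate a synthetic parameter-over-speed dataset
#'
#' @param spec An [synth_dataset_spec()].
#' @return An `rg_speed_dataset` with `n_records` stable records at
#'   equally spaced speeds; reproducible from the spec's seed.
#' @export
gen_param_speed_dataset <- function(spec) {
  stopifnot(inherits(spec, "rg_synth_spec"))
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)
  nk <- length(spec$true_keys)
  coefs <- spec$coefs
  if (is.null(coefs)) {
    coefs <- matrix(0, nk, 4)
    coefs[, 1] <- runif(nk, -1, 1)
    coefs[, 2] <- sample(c(-1, 1), nk, replace = TRUE) * runif(nk, 0.5, 1.5)
    if (spec$degree >= 2) coefs[, 3] <- runif(nk, -0.3, 0.3)
    if (spec$degree >= 3) coefs[, 4] <- runif(nk, -0.1, 0.1)
  }
  v <- seq(spec$speed_range[1], spec$speed_range[2],
           length.out = spec$n_records)
  X <- matrix(rep(rep_len(spec$base, spec$n_params),
                  each = spec$n_records),
              spec$n_records, spec$n_params)
  V <- outer(v, 0:3, `^`)
  signal <- V %*% t(coefs)              # n_records x nk
  sds <- apply(signal, 2, sd)
  X[, spec$true_keys] <- signal
  noise_sd <- rep(spec$noise_rel * mean(sds), spec$n_params)
  noise_sd[spec$true_keys] <- spec$noise_rel * sds
  if (spec$noise_rel > 0)
    X <- X + sweep(matrix(rnorm(length(X)), nrow(X)), 2, noise_sd, "*")
  colnames(X) <- if (spec$n_params == 71) param_names(build_connection_matrix())
                 else paste0("p", seq_len(spec$n_params))
  ds <- new_speed_dataset(X, v, data.frame(seed = spec$seed,
                                           gen = seq_along(v),
                                           direction = "synthetic"))
  attr(ds, "true_keys") <- spec$true_keys
  attr(ds, "coefs") <- coefs
  ds
}

#' Desk-scale end-to-end pipeline smoke run
#'
#' Runs the entire modulation pipeline on the toy hopper with a reduced
#' optimization budget: speed minimization/maximization from the baseline
#' (`n_seeds` CMA-ES runs each) -> harvest -> merged dataset -> PCA ->
#' key selection -> restricted optimization -> speed-modulation fit ->
#' offline sweep -> online step and ramp runs. Each stage's invariants are
#' checked; any violation is reported with the stage name.
#'
#' @param seed Base RNG seed.
#' @param n_seeds CMA-ES seeds per direction.
#' @param t_max Episode length (s) for the toy runs.
#' @param n_key Number of key parameters to select (of the hopper's 10).
#' @param d_reg Regression degree of the modulation fit.
#' @param max_gen Generation cap of the reduced optimizations.
#' @param sigma0 CMA-ES initial step size for the toy searches.
#' @param lambda CMA-ES population size.
#' @param min_omega Required minimum number of records in the merged
#'   dataset.
#' @param settle Online settle time (s).
#' @return Object of class `rg_smoke`: per-stage pass flags and messages,
#'   headline numbers (dataset size, speed ranges, sweep monotonicity,
#'   online stability) and wall times.
#' @export
pipeline_smoke <- function(seed = 1, n_seeds = 2, t_max = 20, n_key = 4,
                           d_reg = 2, max_gen = 40, sigma0 = 0.05,
                           lambda = 8, min_omega = 5, settle = 5) {
  toy <- make_toy_plant()
  plant <- toy$plant
  p0 <- encode_params(toy$p_baseline)
  cfg <- episode_config(plant, t_max = t_max)
  stages <- list()
  fails <- character(0)
  note <- function(stage, ok, msg) {
    stages[[stage]] <<- list(ok = ok, msg = msg)
    if (!ok) fails <<- c(fails, stage)
  }
  t_start <- proc.time()[3]

  # stage: baseline
  ep0 <- run_episode(plant, p0, cfg)
  note("baseline", ep0$stable,
       sprintf("baseline t_sim = %.2f s, v_act = %.3f", ep0$t_sim,
               ifelse(is.na(ep0$v_act), NA, ep0$v_act)))

  # stage: speed optimization (both directions, n_seeds each)
  run_dir <- function(direction, keys = NULL, seeds) {
    lapply(seeds, function(s)
      optimize_speed(plant, p0, direction,
                     cma = cma_config(sigma0 = sigma0, lambda = lambda,
                                      max_gen = max_gen, seed = s),
                     cfg = cfg, keys = keys, check_init = FALSE))
  }
  seeds <- seed + seq_len(n_seeds) - 1L
  h_min <- run_dir("minimize_v", seeds = seeds)
  h_max <- run_dir("maximize_v", seeds = seeds + 1000L)
  mono <- all(vapply(c(h_min, h_max), function(h)
    !is.unsorted(-h$history$best), logical(1)))
  note("optimize", mono, "best-so-far non-increasing in all runs")

  # stage: harvest + merge
  omega1 <- build_omega(h_min, h_max, plant, cfg)
  note("omega1", n_records(omega1) >= min_omega,
       sprintf("omega1: %d records, range %.3f m/s", n_records(omega1),
               speed_range(omega1)))

  # stage: PCA + key selection
  pca <- fit_pca(omega1)
  ortho <- max(abs(crossprod(pca$loadings) -
                     diag(ncol(pca$loadings)))) < 1e-10
  note("pca", ortho && abs(sum(pca$explained) - 1) < 1e-10,
       sprintf("PC1 explains %.1f%%", 100 * pca$explained[1]))
  keys <- select_keys(pca, n_key)
  note("keys", length(keys$indices) == n_key,
       paste("keys:", paste(keys$names, collapse = ", ")))

  # stage: restricted optimization -> omega2
  h2_min <- run_dir("minimize_v", keys = keys, seeds = seed + 2000L)
  h2_max <- run_dir("maximize_v", keys = keys, seeds = seed + 3000L)
  omega2 <- build_omega(h2_min, h2_max, plant, cfg)
  note("omega2", n_records(omega2) >= min_omega,
       sprintf("omega2: %d records, range %.3f m/s", n_records(omega2),
               speed_range(omega2)))

  # stage: modulation fit + offline sweep
  smf <- fit_smf(omega2, keys, d_reg = d_reg, p_init = p0)
  note("smf", all(is.finite(smf$beta)), "finite regression coefficients")
  vr <- range(omega2$v_act)
  grid <- seq(vr[1], vr[2], by = 0.025)
  sw <- offline_sweep(plant, smf, grid, cfg)
  smf <- sw$model
  note("sweep", any(sw$points$stable) && !anyNA(sw$stable_range),
       sprintf("stable v_tgt range [%.3f, %.3f] m/s", sw$stable_range[1],
               sw$stable_range[2]))
  rep_mono <- monotonicity_report(sw)
  note("monotonicity",
       rep_mono$n_violations <= 0.10 * rep_mono$n_stable,
       sprintf("%d/%d violations", rep_mono$n_violations, rep_mono$n_stable))

  # stage: online step + ramp (excluding the endpoints of the stable range)
  rng <- sw$stable_range + c(0.025, -0.025)
  ocfg <- episode_config(plant, t_max = t_max)
  st <- run_online(plant, smf,
                   make_schedule("step", rng[1], rng[2], j = 2,
                                 settle = settle), ocfg)
  rp <- run_online(plant, smf,
                   make_schedule("ramp", rng[1], rng[2], settle = settle),
                   ocfg)
  note("online", st$stable || rp$stable,
       sprintf("step %s, ramp %s",
               if (st$stable) "stable" else "fell",
               if (rp$stable) "stable" else "fell"))

  structure(list(stages = stages, failed = fails,
                 passed = length(fails) == 0,
                 omega1 = omega1, omega2 = omega2, keys = keys, smf = smf,
                 sweep = sw, monotonicity = rep_mono,
                 online = list(step = st$stable, ramp = rp$stable),
                 wall_s = proc.time()[3] - t_start),
            class = "rg_smoke")
}

#' @export
print.rg_smoke <- function(x, ...) {
  cat(sprintf("Pipeline smoke run: %s (%.1f s)\n",
              if (x$passed) "all stages passed"
              else paste("FAILED at:", paste(x$failed, collapse = ", ")),
              x$wall_s))
  for (nm in names(x$stages))
    cat(sprintf("  [%s] %-12s %s\n",
                if (x$stages[[nm]]$ok) "ok" else "FAIL", nm,
                x$stages[[nm]]$msg))
  invisible(x)
}
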