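# Speed optimization: cost function, CMA-ES driver, harvesting of stable
# intermediate solutions into parameter-over-speed datasets.

#' Cost of an episode for speed optimization
#'
#' The optimization cost is `J = 100 * J_vel + 100 * J_fall`, where
#' `J_vel = d_sim / t_max` when minimizing velocity and `-d_sim / t_max`
#' when maximizing, and `J_fall = 1 - t_sim / t_max` penalizes falling
#' before the episode ends (`0 <= J_fall <= 1`).
#'
#' @param result An `rg_episode`.
#' @param direction `"minimize_v"` or `"maximize_v"`.
#' @return Object of class `rg_cost` with components `J`, `J_vel`,
#'   `J_fall`, `direction`.
#' @export
cost <- function(result, direction = c("maximize_v", "minimize_v")) {
  direction <- match.arg(direction)
  d_sim <- completed_distance(result, direction)
  J_vel <- if (direction == "minimize_v") d_sim / result$t_max
           else -d_sim / result$t_max
  J_fall <- 1 - result$t_sim / result$t_max
  structure(list(J = 100 * J_vel + 100 * J_fall, J_vel = J_vel,
                 J_fall = J_fall, d_sim = d_sim, direction = direction),
            class = "rg_cost")
}

#' @export
print.rg_cost <- function(x, ...) {
  cat(sprintf("J = %.4f (J_vel = %.4f, J_fall = %.4f, %s)\n",
              x$J, x$J_vel, x$J_fall, x$direction))
  invisible(x)
}

#' CMA-ES optimizer configuration
#'
#' @param sigma0 Initial step size (default 0.01).
#' @param n_seeds Number of independent optimization runs with different
#'   random seeds (default 20).
#' @param improve_tol Stop when the average relative improvement of the
#'   best cost per iteration over the last `improve_window` iterations
#'   falls below this (default 1e-5).
#' @param improve_window Length of the improvement window (iterations).
#' @param max_gen Generation cap (safety net beyond the improvement rule).
#' @param lambda Population size (default `4 + floor(3 log n)`).
#' @param seed Base RNG seed; run `k` uses `seed + k - 1`.
#' @return Object of class `rg_cma_config`.
#' @export
cma_config <- function(sigma0 = 0.01, n_seeds = 20, improve_tol = 1e-5,
                       improve_window = 500, max_gen = 3000, lambda = NULL,
                       seed = 1) {
  if (!isTRUE(sigma0 > 0)) stop("sigma0 must be > 0")
  if (!isTRUE(n_seeds >= 1)) stop("n_seeds must be >= 1")
  structure(list(sigma0 = sigma0, n_seeds = n_seeds,
                 improve_tol = improve_tol, improve_window = improve_window,
                 max_gen = max_gen, lambda = lambda, seed = seed),
            class = "rg_cma_config")
}

#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Derivative-free stochastic minimizer: (mu/mu_w, lambda)-CMA-ES with
#' rank-one and rank-mu covariance updates and cumulative step-size
#' adaptation. Terminates when the average relative improvement of the
#' best-so-far cost per iteration over the trailing window drops below
#' `improve_tol`, or at the generation cap.
#'
#' @param fn Objective. Either returns a numeric cost, or (with
#'   `fn_info = TRUE`) a list with components `value` and `info`; the
#'   `info` of each generation's best candidate is kept in the history.
#' @param x0 Initial mean.
#' @param sigma0 Initial step size.
#' @param lambda Population size (default `4 + floor(3 log n)`).
#' @param seed RNG seed for reproducibility (optional).
#' @param max_gen Generation cap.
#' @param improve_tol,improve_window Improvement-based stop rule.
#' @param fn_info Whether `fn` returns `list(value, info)`.
#' @return Object of class `rg_cma`: best point/value, per-generation
#'   history (best cost of the generation, best so far, step size), the
#'   generation-best candidates (matrix), their infos, and the stop reason.
#' @export
cma_es <- function(fn, x0, sigma0 = 0.3, lambda = NULL, seed = NULL,
                   max_gen = 3000, improve_tol = 1e-5, improve_window = 500,
                   fn_info = FALSE) {
  n <- length(x0)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- as.numeric(x0)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n); C <- diag(n)
  eigen_every <- max(1L, floor(1 / (c1 + cmu) / n / 10))
  last_eigen <- 0L

  hist_gen <- integer(0); hist_f <- numeric(0); hist_best <- numeric(0)
  hist_sigma <- numeric(0)
  cand <- matrix(NA_real_, 0, n)
  infos <- list()
  best_f <- Inf; best_x <- xmean
  reason <- "max_gen"

  for (g in seq_len(max_gen)) {
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                     # N(0, C) samples
    X <- xmean + sigma * Y
    fvals <- numeric(lambda)
    ginfo <- vector("list", lambda)
    for (k in seq_len(lambda)) {
      r <- fn(X[, k])
      if (fn_info) { fvals[k] <- r$value; ginfo[[k]] <- r$info }
      else fvals[k] <- as.numeric(r)
    }
    if (all(!is.finite(fvals)))
      stop("optimization error: all objective evaluations non-finite")
    fvals[!is.finite(fvals)] <- .Machine$double.xmax
    ord <- order(fvals)
    sel <- ord[seq_len(mu)]
    ybar <- as.numeric(Y[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * ybar

    # step-size path (C^{-1/2} y = B z)
    zbar <- as.numeric(B %*% (Z[, sel, drop = FALSE] %*% w))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * zbar
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ybar
    Ysel <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * (Ysel %*% (w * t(Ysel)))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    if (g - last_eigen >= eigen_every) {
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-30))
      B <- eg$vectors
      last_eigen <- g
    }

    gb <- ord[1]
    if (fvals[gb] < best_f) { best_f <- fvals[gb]; best_x <- X[, gb] }
    hist_gen <- c(hist_gen, g)
    hist_f <- c(hist_f, fvals[gb])
    hist_best <- c(hist_best, best_f)
    hist_sigma <- c(hist_sigma, sigma)
    cand <- rbind(cand, X[, gb])
    infos[[g]] <- ginfo[[gb]]

    if (g > improve_window) {
      f0 <- hist_best[g - improve_window]
      impr <- (f0 - hist_best[g]) / improve_window / max(abs(f0), 1e-30)
      if (impr < improve_tol) { reason <- "improvement"; break }
    }
  }
  structure(list(par = best_x, value = best_f, mean = xmean,
                 generations = length(hist_gen), reason = reason,
                 history = data.frame(gen = hist_gen, f = hist_f,
                                      best = hist_best, sigma = hist_sigma),
                 candidates = cand, infos = infos),
            class = "rg_cma")
}

#' @export
print.rg_cma <- function(x, ...) {
  cat(sprintf("CMA-ES: %d generations, best cost %.6g (stop: %s)\n",
              x$generations, x$value, x$reason))
  invisible(x)
}

#' Optimize locomotion speed from an initial parameter set
#'
#' One CMA-ES run (single seed) minimizing the speed cost [cost()] over the
#' reflex parameters, starting from a parameter set producing stable gait.
#' Optionally restricted to a subset of key parameters (all other entries
#' stay fixed at their initial values).
#'
#' @param plant An `rg_plant`.
#' @param p_init Initial parameters (`rg_params` or canonical vector); a
#'   warning is given if the initial episode is not stable.
#' @param direction `"minimize_v"` or `"maximize_v"`.
#' @param cma CMA-ES configuration ([cma_config()]); a single seed
#'   (`cma$seed`) is used here — run several calls for multi-seed searches.
#' @param cfg Episode configuration.
#' @param keys Optional [select_keys()] selection (or integer indices) for
#'   a restricted optimization over the key parameters only.
#' @param check_init Whether to evaluate `p_init` first and warn when it is
#'   unstable.
#' @return Object of class `rg_opt_history`: the CMA-ES result plus the
#'   full 71-entry generation-best candidates and episode summaries.
#' @export
optimize_speed <- function(plant, p_init, direction = c("maximize_v", "minimize_v"),
                           cma = cma_config(), cfg = episode_config(plant),
                           keys = NULL, check_init = TRUE) {
  direction <- match.arg(direction)
  p0 <- as_param_vector(plant, p_init)
  if (check_init) {
    ep0 <- run_episode(plant, p0, cfg)
    if (!ep0$stable)
      warning("initial parameter set does not produce a stable episode (t_sim = ",
              signif(ep0$t_sim, 4), " s)")
  }
  prob <- if (is.null(keys)) NULL else restricted_problem(p0, keys)
  expand <- if (is.null(prob)) identity else prob$expand
  x0 <- if (is.null(prob)) p0 else prob$x0
  objective <- function(x) {
    ep <- run_episode(plant, expand(x), cfg)
    cb <- cost(ep, direction)
    list(value = cb$J,
         info = list(t_sim = ep$t_sim, stable = ep$stable,
                     v_mean = ep$v_mean, v_act = ep$v_act, gait = ep$gait))
  }
  r <- cma_es(objective, x0, sigma0 = cma$sigma0, lambda = cma$lambda,
              seed = cma$seed, max_gen = cma$max_gen,
              improve_tol = cma$improve_tol,
              improve_window = cma$improve_window, fn_info = TRUE)
  full <- t(apply(r$candidates, 1, expand))
  if (nrow(r$candidates) == 1L) full <- matrix(full, 1)
  colnames(full) <- param_names(plant$cm)
  structure(list(direction = direction, seed = cma$seed,
                 history = r$history, candidates = full,
                 infos = r$infos, par = expand(r$par), value = r$value,
                 reason = r$reason, keys = if (is.null(prob)) NULL else prob$keys),
            class = "rg_opt_history")
}

#' @export
print.rg_opt_history <- function(x, ...) {
  cat(sprintf("Speed optimization (%s, seed %s): %d generations, best J = %.4f\n",
              x$direction, format(x$seed), nrow(x$history), x$value))
  invisible(x)
}

new_speed_dataset <- function(params, v_act, provenance) {
  params <- as.matrix(params)
  ord <- order(v_act)
  params <- params[ord, , drop = FALSE]
  v_act <- v_act[ord]
  provenance <- provenance[ord, , drop = FALSE]
  dup <- duplicated(params)
  structure(list(params = params[!dup, , drop = FALSE],
                 v_act = v_act[!dup],
                 stable = rep(TRUE, sum(!dup)),
                 provenance = provenance[!dup, , drop = FALSE]),
            class = "rg_speed_dataset")
}

#' @export
print.rg_speed_dataset <- function(x, ...) {
  cat(sprintf("Speed dataset: %d stable parameter sets, v_act in [%.3f, %.3f] m/s\n",
              length(x$v_act),
              if (length(x$v_act)) min(x$v_act) else NA,
              if (length(x$v_act)) max(x$v_act) else NA))
  invisible(x)
}

#' Number of records in a speed dataset
#' @param x An `rg_speed_dataset`.
#' @return Integer count.
#' @export
n_records <- function(x) length(x$v_act)

#' Speed range of a dataset
#'
#' `v_max - v_min` over the actual velocities of the records (0 for fewer
#' than two records).
#'
#' @param x An `rg_speed_dataset`.
#' @return Speed range (m/s).
#' @export
speed_range <- function(x) {
  if (length(x$v_act) < 2) return(0)
  max(x$v_act) - min(x$v_act)
}

#' Harvest stable intermediate solutions from an optimization
#'
#' Re-evaluates each generation's best candidate deterministically and
#' keeps those that produce a stable gait for the full episode
#' (`t_sim == t_max`), recording their actual velocity.
#'
#' @param history An `rg_opt_history`.
#' @param plant The plant the history was optimized on.
#' @param cfg Episode configuration used for re-evaluation.
#' @return An `rg_speed_dataset` (possibly empty, with a warning).
#' @export
harvest <- function(history, plant, cfg = episode_config(plant)) {
  stopifnot(inherits(history, "rg_opt_history"))
  ng <- nrow(history$candidates)
  if (ng == 0) stop("empty optimization history")
  keep_p <- list(); keep_v <- numeric(0); keep_gen <- integer(0)
  for (g in seq_len(ng)) {
    ep <- run_episode(plant, history$candidates[g, ], cfg)
    if (ep$stable) {
      keep_p[[length(keep_p) + 1L]] <- history$candidates[g, ]
      keep_v <- c(keep_v, ep$v_act)
      keep_gen <- c(keep_gen, g)
    }
  }
  if (!length(keep_p)) {
    warning("no stable intermediate solutions found; empty dataset")
    return(new_speed_dataset(matrix(0, 0, ncol(history$candidates)),
                             numeric(0),
                             data.frame(seed = integer(0), gen = integer(0),
                                        direction = character(0))))
  }
  new_speed_dataset(do.call(rbind, keep_p), keep_v,
                    data.frame(seed = history$seed, gen = keep_gen,
                               direction = history$direction))
}

#' Merge per-direction optimizations into a parameter-over-speed dataset
#'
#' For each direction (speed minimization and maximization), selects the
#' optimization run whose harvested dataset spans the largest actual-speed
#' range, then concatenates the two harvests (sorted by speed, duplicates
#' removed).
#'
#' @param min_histories,max_histories Lists of `rg_opt_history` (one per
#'   seed) for the minimization/maximization direction; pre-harvested
#'   `rg_speed_dataset`s are also accepted.
#' @param plant,cfg Plant and episode configuration for harvesting.
#' @return An `rg_speed_dataset`.
#' @export
build_omega <- function(min_histories, max_histories, plant,
                        cfg = episode_config(plant)) {
  pick <- function(histories) {
    if (!length(histories)) return(NULL)
    best <- NULL; best_span <- -Inf
    for (h in histories) {
      ds <- if (inherits(h, "rg_speed_dataset")) h
            else suppressWarnings(harvest(h, plant, cfg))
      span <- if (n_records(ds) == 0) -Inf else speed_range(ds)
      if (span > best_span) { best_span <- span; best <- ds }
    }
    best
  }
  dmin <- pick(min_histories)
  dmax <- pick(max_histories)
  parts <- Filter(function(d) !is.null(d) && n_records(d) > 0, list(dmin, dmax))
  if (!length(parts))
    stop("both directions produced empty datasets")
  params <- do.call(rbind, lapply(parts, function(d) d$params))
  v_act <- unlist(lapply(parts, function(d) d$v_act))
  prov <- do.call(rbind, lapply(parts, function(d) d$provenance))
  new_speed_dataset(params, v_act, prov)
}
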