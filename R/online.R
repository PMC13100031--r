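# Online modulation: time-varying target-speed schedules (steps, ramps),
# run-time parameter switching through the SMF, and abrupt-switch
# walk-run transition experiments.

#' Target-speed schedule
#'
#' Schedules start at the mid-range speed
#' `v_start = v_min + (v_max - v_min)/2` and hold it for the settle time.
#' A step schedule then jumps to `v_end = v_start +/- j * quantum`; a ramp
#' schedule follows the triangle wave
#' `v_min + v_a * |((tau - T/4) mod T) - T/2|` with `tau = t - settle` and
#' period `T = 2 (v_max - v_min) / v_a`, so it starts at `v_start`, first
#' rises to `v_max`, then falls to `v_min`.
#'
#' @param kind `"constant"`, `"step"` or `"ramp"`.
#' @param v_min,v_max Slow/fast ends of the usable target-speed range
#'   (m/s).
#' @param j Step index in `1..25`; the step size is `j * quantum`.
#' @param direction `"up"` or `"down"` (step schedules).
#' @param quantum Step quantum (m/s), default 0.025.
#' @param v_a Ramp rate (m/s per s), default 0.05.
#' @param settle Settle time (s) at `v_start` before modulation, default 20.
#' @return Object of class `rg_schedule`.
#' @export
make_schedule <- function(kind = c("constant", "step", "ramp"),
                          v_min, v_max, j = NULL,
                          direction = c("up", "down"),
                          quantum = 0.025, v_a = 0.05, settle = 20) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (!isTRUE(v_max >= v_min)) stop("v_max must be >= v_min")
  v_start <- v_min + (v_max - v_min) / 2
  v_end <- NA_real_
  if (kind == "step") {
    if (is.null(j) || !isTRUE(j >= 1 && j <= 25 && j == round(j)))
      stop("step schedules need an integer step index j in 1..25")
    v_end <- v_start + (if (direction == "up") 1 else -1) * j * quantum
  }
  T_period <- if (v_max > v_min) 2 * (v_max - v_min) / v_a else Inf
  structure(list(kind = kind, v_min = v_min, v_max = v_max,
                 v_start = v_start, v_end = v_end, j = j,
                 direction = direction, quantum = quantum, v_a = v_a,
                 settle = settle, T_period = T_period),
            class = "rg_schedule")
}

#' @export
print.rg_schedule <- function(x, ...) {
  cat(sprintf("Schedule '%s': v_start = %.3f m/s", x$kind, x$v_start))
  if (x$kind == "step")
    cat(sprintf(", step to %.3f m/s (j = %d, %s) at %g s", x$v_end, x$j,
                x$direction, x$settle))
  if (x$kind == "ramp")
    cat(sprintf(", ramp %.3f..%.3f m/s at %.3g m/s^2-equivalent, period %.1f s",
                x$v_min, x$v_max, x$v_a, x$T_period))
  cat("\n")
  invisible(x)
}

#' Evaluate a schedule
#'
#' Target speed at time `t`: `v_start` before the settle time; afterwards
#' the step target or the triangle ramp (bounded in `[v_min, v_max]`).
#'
#' @param s An `rg_schedule`.
#' @param t Time (s); vectorized.
#' @return Target speed(s) (m/s).
#' @export
schedule_value <- function(s, t) {
  vapply(t, function(tt) {
    if (tt < s$settle || s$kind == "constant") return(s$v_start)
    if (s$kind == "step") return(s$v_end)
    tau <- tt - s$settle
    if (!is.finite(s$T_period)) return(s$v_start)
    s$v_min + s$v_a * abs(((tau - s$T_period / 4) %% s$T_period) -
                            s$T_period / 2)
  }, numeric(1))
}

#' Run an episode with online speed modulation
#'
#' The target speed is sampled-and-held on a 1 s lattice (re-evaluated at
#' the settle time and, for ramps, every second thereafter); at each
#' change the full parameter vector is replaced instantly by
#' `assemble_params(model, v_tgt)` while the plant state, muscle states
#' and sensor histories carry over unchanged. A constant schedule executes
#' the identical code path as a plain episode.
#'
#' @param plant An `rg_plant`.
#' @param model A swept `rg_smf` (stable range known) or any `rg_smf`.
#' @param s An `rg_schedule`; its speeds should lie inside the model's
#'   stable range, endpoints excluded.
#' @param cfg Episode configuration.
#' @param update_dt Target-speed update interval (s), default 1.
#' @return Object of class `rg_online`: the `rg_episode`, the applied
#'   schedule samples (`t`, `v_tgt`), torso velocity `v` and its 1 s
#'   moving average `v_bar`.
#' @export
run_online <- function(plant, model, s, cfg = episode_config(plant),
                       update_dt = 1) {
  stopifnot(inherits(model, "rg_smf"), inherits(s, "rg_schedule"))
  times <- 0
  if (s$kind == "step") {
    if (s$settle < cfg$t_max) times <- c(0, s$settle)
  } else if (s$kind == "ramp") {
    times <- unique(c(0, seq(s$settle, cfg$t_max, by = update_dt)))
    times <- times[times < cfg$t_max]
  }
  v_tgt <- schedule_value(s, times)
  keep <- c(TRUE, diff(v_tgt) != 0)     # switch only when the target changes
  times <- times[keep]; v_tgt <- v_tgt[keep]
  pmat <- t(vapply(v_tgt, function(v) assemble_params(model, v),
                   numeric(length(model$p_init))))
  if (length(v_tgt) == 1L) pmat <- matrix(pmat, 1)
  ep <- simulate_segments(plant, times, pmat, cfg)
  vx <- ep$qd[, 1]                      # torso horizontal velocity
  v_bar <- tryCatch(moving_average_velocity(vx, ep$record_dt, 1),
                    error = function(e) rep(NA_real_, length(vx)))
  structure(list(episode = ep, switch_t = times, switch_v_tgt = v_tgt,
                 t = ep$t, v_tgt = schedule_value(s, sapply(ep$t, function(tt)
                   max(times[times <= tt + 1e-9]))),
                 v = vx, v_bar = v_bar, schedule = s,
                 stable = ep$stable, fall_time = if (ep$stable) NA_real_
                 else ep$t_sim),
            class = "rg_online")
}

#' @export
print.rg_online <- function(x, ...) {
  cat(sprintf("Online run (%s schedule): %s", x$schedule$kind,
              if (x$stable) "stable" else sprintf("fell at %.2f s", x$fall_time)))
  cat(sprintf(", %d parameter switches\n", length(x$switch_t) - 1L))
  invisible(x)
}

#' Largest stable target-speed step
#'
#' Scans step schedules `j = 1..j_max` in the given direction and returns
#' the largest step index whose online run survives the full episode,
#' with the corresponding speed change `delta_v = j * quantum`.
#'
#' @param plant An `rg_plant`.
#' @param model A swept `rg_smf`.
#' @param direction `"up"` or `"down"`.
#' @param cfg Episode configuration.
#' @param j_max Largest step index to try (default 25).
#' @param runner Episode runner (injectable for testing); defaults to
#'   [run_online()].
#' @return List with `j_star` (0 if no step is stable), `delta_v` (m/s)
#'   and the per-step stability flags.
#' @export
largest_stable_step <- function(plant, model, direction = c("up", "down"),
                                cfg = episode_config(plant), j_max = 25,
                                runner = run_online) {
  direction <- match.arg(direction)
  rng <- model$stable_range
  if (anyNA(rng)) stop("model has no stable range; run offline_sweep() first")
  ok <- logical(j_max)
  for (j in seq_len(j_max)) {
    s <- make_schedule("step", rng[1], rng[2], j = j, direction = direction)
    r <- runner(plant, model, s, cfg)
    ok[j] <- isTRUE(r$stable)
  }
  j_star <- if (any(ok)) max(which(ok)) else 0L
  list(j_star = j_star, delta_v = j_star * 0.025, stable = ok)
}

#' Gait-transition plan
#'
#' An ordered sequence of full parameter sets switched abruptly at fixed
#' times (multiples of the switch interval, default every 10 s).
#'
#' @param param_sets List of 2 or 4 canonical parameter vectors (or
#'   `rg_params`).
#' @param switch_times Strictly increasing switch times (s); default
#'   `10, 20, ...` with one switch fewer than parameter sets.
#' @param labels Optional gait labels per segment (e.g.
#'   `c("walk", "run")`).
#' @return Object of class `rg_transition_plan`.
#' @export
transition_plan <- function(param_sets,
                            switch_times = 10 * seq_len(length(param_sets) - 1L),
                            labels = NULL) {
  if (!length(param_sets) >= 2) stop("need at least 2 parameter sets")
  if (length(switch_times) != length(param_sets) - 1L)
    stop("need exactly one switch time between consecutive parameter sets")
  if (is.unsorted(switch_times, strictly = TRUE))
    stop("switch times must be strictly increasing")
  if (!is.null(labels) && length(labels) != length(param_sets))
    stop("labels must match the number of parameter sets")
  structure(list(param_sets = param_sets, switch_times = switch_times,
                 labels = labels),
            class = "rg_transition_plan")
}

#' @export
print.rg_transition_plan <- function(x, ...) {
  cat(sprintf("Transition plan: %d parameter sets, switches at %s s\n",
              length(x$param_sets), paste(x$switch_times, collapse = ", ")))
  invisible(x)
}

#' Run a gait-transition episode
#'
#' Runs one episode in which the active parameter vector is replaced
#' abruptly at each switch time; all dynamic state (plant, activations,
#' sensor buffers) carries over. Gait labels are classified per segment.
#'
#' @param plant An `rg_plant`.
#' @param plan An `rg_transition_plan`.
#' @param cfg Episode configuration.
#' @return Object of class `rg_transition`: the `rg_episode`, per-segment
#'   gait labels, and (when unstable) the segment index of the fall.
#' @export
run_transition <- function(plant, plan, cfg = episode_config(plant)) {
  stopifnot(inherits(plan, "rg_transition_plan"))
  pmat <- do.call(rbind, lapply(plan$param_sets, function(p)
    as_param_vector(plant, p)))
  times <- c(0, plan$switch_times)
  ep <- simulate_segments(plant, times, pmat, cfg)
  bounds <- c(times, cfg$t_max)
  seg_gait <- character(length(plan$param_sets))
  fall_segment <- NA_integer_
  for (k in seq_along(plan$param_sets)) {
    ix <- ep$t >= bounds[k] & ep$t < bounds[k + 1]
    seg_gait[k] <- if (sum(ix) > 2)
      classify_gait(ep$contact[ix, , drop = FALSE], ep$record_dt) else "none"
    if (!ep$stable && is.na(fall_segment) &&
        ep$t_sim >= bounds[k] && ep$t_sim < bounds[k + 1])
      fall_segment <- k
  }
  structure(list(episode = ep, plan = plan, stable = ep$stable,
                 segment_gaits = seg_gait, fall_segment = fall_segment),
            class = "rg_transition")
}

#' @export
print.rg_transition <- function(x, ...) {
  cat(sprintf("Transition run: %s; segment gaits: %s\n",
              if (x$stable) "stable" else
                sprintf("fell in segment %d at %.2f s", x$fall_segment,
                        x$episode$t_sim),
              paste(x$segment_gaits, collapse = " -> ")))
  invisible(x)
}

#' Concatenated optimization problem of a transition plan
#'
#' Stacks all parameter sets of the plan into one search vector (2 x 71 or
#' 4 x 71 dimensions for the human network).
#'
#' @param plant An `rg_plant`.
#' @param plan An `rg_transition_plan`.
#' @return List with `x0`, `dim` and `expand(x)` returning a plan.
#' @export
transition_problem <- function(plant, plan) {
  pmat <- do.call(rbind, lapply(plan$param_sets, function(p)
    as_param_vector(plant, p)))
  npar <- ncol(pmat)
  nset <- nrow(pmat)
  list(x0 = as.numeric(t(pmat)), dim = npar * nset,
       expand = function(x) {
         stopifnot(length(x) == npar * nset)
         sets <- lapply(seq_len(nset), function(k)
           x[(k - 1L) * npar + seq_len(npar)])
         transition_plan(sets, plan$switch_times, plan$labels)
       })
}

#' Optimize a gait-transition plan
#'
#' CMA-ES over the concatenation of all parameter sets of the plan,
#' minimizing `J = 100 * J_fall` of the transition episode (the
#' optimization focuses on surviving the full episode, not on speed).
#' Terminates early when a surviving plan (objective 0) is found.
#'
#' @param plant An `rg_plant`.
#' @param plan Initial `rg_transition_plan`.
#' @param cma CMA-ES configuration.
#' @param cfg Episode configuration.
#' @return List: optimized `plan`, its `value`, the transition `result`,
#'   and the optimizer history.
#' @export
optimize_transition <- function(plant, plan, cma = cma_config(),
                                cfg = episode_config(plant)) {
  prob <- transition_problem(plant, plan)
  objective <- function(x) {
    r <- run_transition(plant, prob$expand(x), cfg)
    ep <- r$episode
    100 * (1 - ep$t_sim / ep$t_max)
  }
  # check the initial plan first: already surviving -> objective 0, done
  f0 <- objective(prob$x0)
  if (f0 <= 0) {
    return(list(plan = plan, value = 0,
                result = run_transition(plant, plan, cfg),
                history = NULL, evaluations = 1L))
  }
  best <- list(par = prob$x0, value = f0)
  r <- cma_es(function(x) objective(x), prob$x0, sigma0 = cma$sigma0,
              lambda = cma$lambda, seed = cma$seed, max_gen = cma$max_gen,
              improve_tol = cma$improve_tol,
              improve_window = cma$improve_window)
  if (r$value < best$value) best <- r
  plan2 <- prob$expand(best$par)
  list(plan = plan2, value = best$value,
       result = run_transition(plant, plan2, cfg), history = r$history)
}
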