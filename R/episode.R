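# Episodes: run one simulation with termination rules, compute gait metrics.

#' Episode configuration
#'
#' @param plant Optional `rg_plant`; supplies plant-specific defaults
#'   (timestep, fall threshold, recording rate, transient).
#' @param t_max Maximum simulated time (s); an episode that reaches `t_max`
#'   without falling is stable.
#' @param fall_height Fall threshold (m) on the model CoM height; the
#'   simulation stops when the CoM drops below it.
#' @param dt Integrator timestep (s).
#' @param record_dt Trajectory sampling interval (s).
#' @param transient Initial transient (s) discarded when computing the
#'   actual velocity `v_act` of stable episodes.
#' @param q0,qd0 Initial generalized coordinates/velocities (default: the
#'   plant's standard initial state).
#' @return Object of class `rg_episode_config`.
#' @export
episode_config <- function(plant = NULL, t_max = 50,
                           fall_height = if (is.null(plant)) 0.9 else plant$defaults$fall_y,
                           dt = if (is.null(plant)) 5e-4 else plant$defaults$dt,
                           record_dt = if (is.null(plant)) 0.01 else plant$defaults$record_dt,
                           transient = if (is.null(plant)) 10 else plant$defaults$transient,
                           q0 = if (is.null(plant)) NULL else plant$q0,
                           qd0 = if (is.null(plant)) NULL else plant$qd0) {
  if (!isTRUE(t_max > 0)) stop("t_max must be > 0")
  if (!is.na(fall_height) && !isTRUE(fall_height > 0))
    stop("fall threshold must be > 0")
  if (!isTRUE(dt > 0) || !isTRUE(record_dt > 0))
    stop("dt and record_dt must be > 0")
  structure(list(t_max = t_max, fall_height = fall_height, dt = dt,
                 record_dt = record_dt, transient = transient,
                 q0 = q0, qd0 = qd0),
            class = "rg_episode_config")
}

# Expand canonical parameter-vector rows into per-instance gain matrices.
expand_segments <- function(plant, times, pmat) {
  ncls <- nrow(plant$cm)
  nmcls <- length(attr(plant$cm, "muscles"))
  if (ncol(pmat) != 2L * ncls + nmcls)
    stop(sprintf("parameter rows must have %d entries", 2L * ncls + nmcls))
  list(t = times,
       KL = pmat[, plant$conn_class, drop = FALSE],
       KF = pmat[, ncls + plant$conn_class, drop = FALSE],
       C = pmat[, 2L * ncls + plant$musc_class, drop = FALSE])
}

as_param_vector <- function(plant, params) {
  if (inherits(params, "rg_params")) params <- encode_params(params)
  params <- as.numeric(params)
  if (length(params) != n_params(plant$cm))
    stop(sprintf("expected %d parameters, got %d", n_params(plant$cm),
                 length(params)))
  params
}

# Shared episode runner: `segments` is a list(times, pmat) of
# piecewise-constant parameter vectors. run_episode(), run_online() and
# run_transition() all go through here, so an online run with a constant
# schedule executes exactly the same operations as a plain episode.
simulate_segments <- function(plant, times, pmat, cfg) {
  nm <- length(plant$model$muscles$fmax)
  q0 <- if (is.null(cfg$q0)) plant$q0 else cfg$q0
  qd0 <- if (is.null(cfg$qd0)) plant$qd0 else cfg$qd0
  segs <- expand_segments(plant, times, pmat)
  ccfg <- list(dt = cfg$dt, t_max = cfg$t_max,
               fall_y = if (is.na(cfg$fall_height)) NA_real_ else cfg$fall_height,
               record_dt = cfg$record_dt, q0 = q0, qd0 = qd0,
               act0 = rep(0, nm), lce0 = rep(NA_real_, nm))
  raw <- cpp_simulate(plant$model, segs, ccfg)
  build_episode(plant, raw, cfg)
}

contact_matrix <- function(plant, raw, threshold = 20) {
  groups <- plant$contact_groups
  if (!length(groups)) return(matrix(FALSE, length(raw$t), 0))
  out <- sapply(groups, function(ix)
    rowSums(raw$contact_normal[, ix, drop = FALSE]) > threshold)
  if (is.null(dim(out))) out <- matrix(out, ncol = length(groups))
  colnames(out) <- names(groups)
  out
}

build_episode <- function(plant, raw, cfg) {
  t <- raw$t
  stable <- raw$status == 0L && isTRUE(all.equal(raw$t_sim, cfg$t_max))
  n <- length(t)
  v_mean <- if (raw$t_sim > 0)
    (raw$com[n, 1] - raw$com[1, 1]) / raw$t_sim else 0
  v_act <- NA_real_
  if (stable && cfg$transient < cfg$t_max) {
    i0 <- which.min(abs(t - cfg$transient))
    v_act <- (raw$com[n, 1] - raw$com[i0, 1]) / (t[n] - t[i0])
  }
  contact <- contact_matrix(plant, raw)
  gait <- classify_gait(contact, dt = cfg$record_dt)
  structure(list(
    t_sim = raw$t_sim, t_max = cfg$t_max, stable = stable,
    status = raw$status,
    diagnostic = c("completed", "fell", "non-finite state")[raw$status + 1L],
    gait = gait, v_mean = v_mean, v_act = v_act,
    d_sim = completed_distance(raw$seg_com_x, "maximize_v"),
    t = t, q = raw$q, qd = raw$qd, com = raw$com,
    seg_com_x = raw$seg_com_x, seg_com_y = raw$seg_com_y,
    act = raw$act, force = raw$force, lce = raw$lce, stim = raw$stim,
    contact_normal = raw$contact_normal,
    contact_tangential = raw$contact_tangential,
    L_delayed = raw$L_delayed, F_delayed = raw$F_delayed,
    contact = contact, record_dt = cfg$record_dt,
    dof_names = plant$dof_names, joint_sign = plant$joint_sign,
    contact_groups = plant$contact_groups),
    class = "rg_episode")
}

#' @export
print.rg_episode <- function(x, ...) {
  cat(sprintf("Episode: t_sim = %.3f s / t_max = %g s (%s), gait = %s\n",
              x$t_sim, x$t_max, if (x$stable) "stable" else x$diagnostic,
              x$gait))
  cat(sprintf("  mean velocity %.3f m/s", x$v_mean))
  if (!is.na(x$v_act)) cat(sprintf(", v_act %.3f m/s", x$v_act))
  cat("\n")
  invisible(x)
}

#' Run one simulation episode
#'
#' Simulates the plant under the reflex controller with a fixed parameter
#' set until the model falls (CoM below the fall threshold) or `t_max` is
#' reached. Deterministic: identical inputs give identical results. An
#' integration failure is recorded as an unstable episode with a
#' diagnostic, not an R error.
#'
#' @param plant An `rg_plant` with a reflex network.
#' @param params Parameter set (`rg_params` or canonical numeric vector).
#' @param cfg Episode configuration from [episode_config()].
#' @return Object of class `rg_episode`: termination time `t_sim`,
#'   stability flag (`t_sim == t_max`), gait label, mean and actual
#'   velocity, and full sampled trajectories.
#' @export
run_episode <- function(plant, params, cfg = episode_config(plant)) {
  v <- as_param_vector(plant, params)
  simulate_segments(plant, 0, matrix(v, 1), cfg)
}

#' Completed distance of an episode
#'
#' Horizontal displacement of the CoM of the segment that, at the end of
#' the simulation, is conservative for the optimization direction: when
#' maximizing speed, the segment with the minimal final horizontal distance
#' to the origin; when minimizing, the maximal.
#'
#' @param trajectories An `rg_episode`, or a matrix of per-segment CoM
#'   horizontal positions (time x segments).
#' @param direction `"maximize_v"` or `"minimize_v"`.
#' @return Distance (m).
#' @export
completed_distance <- function(trajectories, direction = "maximize_v") {
  direction <- match.arg(direction, c("maximize_v", "minimize_v"))
  x <- if (inherits(trajectories, "rg_episode")) trajectories$seg_com_x
       else as.matrix(trajectories)
  if (nrow(x) == 0) stop("empty trajectory")
  fin <- x[nrow(x), ]
  dist <- abs(fin)
  j <- if (direction == "maximize_v") which.min(dist) else which.max(dist)
  unname(fin[j] - x[1, j])
}

#' Trailing moving-average velocity
#'
#' Causal sliding mean over a trailing window; samples earlier than one
#' full window use the expanding mean of the available samples.
#'
#' @param v Uniformly sampled velocity series (m/s).
#' @param dt Sampling interval (s).
#' @param window Window length (s), default 1.
#' @return Numeric series of the same length.
#' @export
moving_average_velocity <- function(v, dt, window = 1) {
  n <- length(v)
  if ((n - 1) * dt < window)
    stop("series shorter than the averaging window")
  k <- max(1L, round(window / dt))
  cs <- cumsum(v)
  out <- numeric(n)
  i <- seq_len(n)
  early <- i <= k
  out[early] <- cs[early] / i[early]
  late <- which(!early)
  out[late] <- (cs[late] - cs[late - k]) / k
  out
}

run_lengths <- function(b) {
  # lengths of TRUE runs in a logical vector
  r <- rle(b)
  r$lengths[r$values]
}

#' Classify the gait of a contact sequence
#'
#' `"run"` if periodic flight phases (no foot in contact) occur, `"walk"`
#' if at least one foot is always in contact with alternating single and
#' double support, `"none"` otherwise (including fewer than `min_strides`
#' complete strides).
#'
#' @param contact Logical matrix (time x feet), TRUE = foot in contact.
#' @param dt Sampling interval (s) (kept for interface symmetry).
#' @param min_strides Minimum number of complete strides required.
#' @return One of `"walk"`, `"run"`, `"none"`.
#' @export
classify_gait <- function(contact, dt = NULL, min_strides = 4L) {
  contact <- as.matrix(contact)
  if (nrow(contact) < 2 || ncol(contact) < 1) return("none")
  lead <- contact[, 1]
  strikes <- sum(diff(lead) > 0)
  if (strikes - 1L < min_strides) return("none")
  n_in_contact <- rowSums(contact)
  flight <- n_in_contact == 0
  n_flight_phases <- length(run_lengths(flight))
  if (n_flight_phases >= min_strides) return("run")
  if (n_flight_phases > 0) return("none")
  if (ncol(contact) >= 2 && any(n_in_contact == 1) && any(n_in_contact >= 2))
    return("walk")
  "none"
}

#' Gait events from a vertical contact-force series
#'
#' Thresholds the vertical ground-reaction force of one foot with
#' hysteresis: contact begins (heel strike) when the force rises above
#' `threshold` and ends (toe-off) when it falls below
#' `release_frac * threshold`.
#'
#' @param fz Vertical contact force series (N) of one foot.
#' @param t Sample times (s).
#' @param threshold Engagement threshold (N), default 20.
#' @param release_frac Release threshold as a fraction of `threshold`.
#' @return List with `heel_strike` and `toe_off` times, `stance_fraction`
#'   (mean stance over stride duration) and `stride_times` (heel strike to
#'   heel strike).
#' @export
stride_events <- function(fz, t, threshold = 20, release_frac = 0.5) {
  stopifnot(length(fz) == length(t))
  on <- logical(length(fz))
  state <- fz[1] > threshold
  for (i in seq_along(fz)) {
    if (!state && fz[i] > threshold) state <- TRUE
    else if (state && fz[i] < release_frac * threshold) state <- FALSE
    on[i] <- state
  }
  hs <- t[which(diff(on) > 0) + 1L]
  to <- t[which(diff(on) < 0) + 1L]
  if (length(hs) < 2)
    stop("no complete gait cycles detected")
  stride_times <- diff(hs)
  # stance fraction per stride: time in contact between consecutive strikes
  stance <- vapply(seq_len(length(hs) - 1L), function(k) {
    ix <- t >= hs[k] & t < hs[k + 1L]
    mean(on[ix])
  }, numeric(1))
  list(heel_strike = hs, toe_off = to,
       stance_fraction = mean(stance), stride_times = stride_times)
}

#' Per-cycle normalized joint-angle curves
#'
#' Resamples joint-angle trajectories onto a 0-100% gait-cycle phase grid
#' (heel strike to heel strike) and averages across cycles. Angles are
#' returned in degrees (flexion positive).
#'
#' @param episode An `rg_episode`.
#' @param dofs Names of the joint coordinates to extract.
#' @param heel_strikes Cycle-start times (s), e.g. from [stride_events()].
#' @param n_phase Number of phase samples (default 101: 0, 1, ..., 100%).
#' @return Matrix `n_phase x length(dofs)` of mean angles (deg), with the
#'   phase grid (%) as `attr(, "phase")`.
#' @export
gait_cycle_angles <- function(episode, dofs, heel_strikes, n_phase = 101L) {
  if (length(heel_strikes) < 2) stop("no complete gait cycles detected")
  cols <- match(dofs, episode$dof_names)
  if (anyNA(cols)) stop("unknown dof: ", paste(dofs[is.na(cols)], collapse = ", "))
  phase <- seq(0, 100, length.out = n_phase)
  acc <- matrix(0, n_phase, length(cols))
  ncyc <- length(heel_strikes) - 1L
  for (k in seq_len(ncyc)) {
    t0 <- heel_strikes[k]; t1 <- heel_strikes[k + 1L]
    tt <- t0 + (t1 - t0) * phase / 100
    for (j in seq_along(cols)) {
      ang <- episode$q[, cols[j]] * episode$joint_sign[cols[j]]
      acc[, j] <- acc[, j] + approx(episode$t, ang, xout = tt, rule = 2)$y
    }
  }
  out <- acc / ncyc * 180 / pi
  colnames(out) <- dofs
  attr(out, "phase") <- phase
  out
}

#' RMS deviation from reference joint-angle curves
#'
#' @param sim,ref Matrices of joint-angle curves (deg) on a common phase
#'   grid (phase x joints).
#' @return Named numeric vector: per-joint RMS deviation (deg).
#' @export
rms_vs_reference <- function(sim, ref) {
  sim <- as.matrix(sim); ref <- as.matrix(ref)
  if (!all(dim(sim) == dim(ref)))
    stop("sim and ref curves must share the same phase grid and joints")
  sqrt(colMeans((sim - ref)^2))
}

#' @importFrom stats approx
NULL
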