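# Plant: planar rigid-body models (standard human biped, generic chains),
# Hill-type MTU step, contact wrench, dynamics step.

#' Plant configuration
#'
#' Anthropometrics, contact, integrator and muscle constants of the planar
#' human model. Segment inertial properties default to standard
#' anthropometric proportions scaled to the requested total mass and
#' stature; all constants can be overridden.
#'
#' @param total_mass_kg Total body mass (kg).
#' @param height_m Stature (m).
#' @param gravity_mps2 Gravitational acceleration magnitude (m/s^2).
#' @param dt_s Integrator timestep (s); fixed-step semi-implicit Euler.
#' @param contact List of ground-contact constants: `k_n` (N/m^`exp_n`
#'   normal stiffness), `exp_n` (penetration exponent), `c_hc`
#'   (Hunt-Crossley dissipation, s/m), `mu` (Coulomb friction coefficient),
#'   `v_reg` (friction regularization velocity, m/s).
#' @param segments Segment table (see [default_segment_table()]); masses
#'   must sum to `total_mass_kg`.
#' @param mtu MTU constant table (see [default_mtu_table()]).
#' @param joint_damping_Nms Viscous damping at each leg joint (N m s/rad).
#' @param joint_limits List of per-joint soft range-of-motion stops, each
#'   `c(lo, hi)` in rad, flexion positive (ankle: dorsiflexion positive).
#' @param limit_stiffness_Nm Soft joint-stop stiffness (N m/rad).
#' @param limit_damping_Nms Soft joint-stop damping (N m s/rad).
#' @return Object of class `rg_plant_config`.
#' @export
plant_config <- function(total_mass_kg = 74.5,
                         height_m = 1.80,
                         gravity_mps2 = 9.81,
                         dt_s = 5e-4,
                         contact = list(k_n = 8e4, exp_n = 1.5, c_hc = 1.0,
                                        mu = 0.9, v_reg = 0.05),
                         segments = default_segment_table(total_mass_kg, height_m),
                         mtu = default_mtu_table(),
                         joint_damping_Nms = 1.0,
                         joint_limits = list(hip = c(-0.35, 1.80),
                                             knee = c(-0.09, 2.40),
                                             ankle = c(-0.80, 0.52)),
                         limit_stiffness_Nm = 200,
                         limit_damping_Nms = 10) {
  cfg <- list(total_mass_kg = total_mass_kg, height_m = height_m,
              gravity_mps2 = gravity_mps2, dt_s = dt_s, contact = contact,
              segments = segments, mtu = mtu,
              joint_damping_Nms = joint_damping_Nms,
              joint_limits = joint_limits,
              limit_stiffness_Nm = limit_stiffness_Nm,
              limit_damping_Nms = limit_damping_Nms)
  validate_plant_config(cfg)
  structure(cfg, class = "rg_plant_config")
}

validate_plant_config <- function(cfg) {
  if (!isTRUE(cfg$total_mass_kg > 0))
    stop("configuration error in 'total_mass_kg': must be > 0")
  if (!isTRUE(cfg$height_m > 0))
    stop("configuration error in 'height_m': must be > 0")
  if (!isTRUE(cfg$dt_s > 0))
    stop("configuration error in 'dt_s': must be > 0")
  seg <- cfg$segments
  need <- c("segment", "mass_kg", "length_m", "com_m", "rgyr_m")
  if (!all(need %in% names(seg)))
    stop("configuration error in 'segments': missing columns ",
         paste(setdiff(need, names(seg)), collapse = ", "))
  if (any(seg$mass_kg <= 0) || any(seg$length_m <= 0))
    stop("configuration error in 'segments': masses and lengths must be > 0")
  msum <- seg$mass_kg[seg$segment == "torso"] +
    2 * sum(seg$mass_kg[seg$segment != "torso"])
  if (abs(msum - cfg$total_mass_kg) > 1e-9)
    stop(sprintf(
      "configuration error in 'segments': masses sum to %.12g kg, not total_mass_kg = %.12g kg",
      msum, cfg$total_mass_kg))
  for (nm in c("k_n", "exp_n", "c_hc", "mu", "v_reg"))
    if (!isTRUE(cfg$contact[[nm]] >= 0))
      stop("configuration error in 'contact$", nm, "': must be >= 0")
  mtu <- cfg$mtu
  if (!setequal(mtu$name, muscle_names()))
    stop("configuration error in 'mtu': must list exactly the 9 canonical muscles")
  for (col in c("fmax_N", "lopt_m", "lslack_m", "vmax_loptps", "tau_act_s",
                "tau_deact_s", "delay_s"))
    if (any(mtu[[col]] <= 0))
      stop("configuration error in 'mtu$", col, "': must be > 0")
  invisible(cfg)
}

#' Default segment inertial table
#'
#' Standard anthropometric proportions (mass fractions, segment lengths as
#' stature fractions, center-of-mass position and radius of gyration as
#' segment-length fractions) scaled to the requested body. One row per
#' distinct segment; femur, tibia and foot occur once per leg.
#'
#' @param total_mass_kg Total body mass (kg).
#' @param height_m Stature (m).
#' @return Data frame with columns `segment`, `mass_kg`, `length_m`,
#'   `com_m` (distance of CoM from the proximal joint), `rgyr_m` (radius of
#'   gyration about the CoM).
#' @export
default_segment_table <- function(total_mass_kg = 74.5, height_m = 1.80) {
  # torso row = head + arms + trunk; legs carry the remaining mass
  frac_mass <- c(torso = NA, femur = 0.100, tibia = 0.0465, foot = 0.0145)
  frac_mass["torso"] <- 1 - 2 * sum(frac_mass[-1])
  len <- c(torso = 0.470 * height_m, femur = 0.245 * height_m,
           tibia = 0.246 * height_m, foot = 0.152 * height_m)
  com_frac <- c(torso = 0.45, femur = 0.433, tibia = 0.433, foot = 0.50)
  rg_frac <- c(torso = 0.38, femur = 0.323, tibia = 0.302, foot = 0.475)
  data.frame(segment = names(len),
             mass_kg = unname(frac_mass * total_mass_kg),
             length_m = unname(len),
             com_m = unname(com_frac * len),
             rgyr_m = unname(rg_frac * len),
             stringsAsFactors = FALSE)
}

#' Default musculotendon constant table
#'
#' Hill-model constants and constant moment arms for the nine muscles of
#' each leg, from the usual values of the predictive gait-simulation
#' literature. Moment arms are in the flexion-positive joint convention
#' (ankle: dorsiflexion positive); a negative arm means the muscle produces
#' an extension (plantarflexion) torque. Biarticular muscles (RF, HAM, GAS)
#' span two joints; all others one.
#'
#' @return Data frame, one row per muscle in canonical order.
#' @export
default_mtu_table <- function() {
  data.frame(
    name = c("GLU", "ILI", "RF", "HAM", "BF", "VAS", "GAS", "TA", "SOL"),
    fmax_N = c(1500, 2000, 1200, 3000, 350, 6000, 1500, 800, 4000),
    lopt_m = c(0.11, 0.11, 0.08, 0.10, 0.11, 0.08, 0.05, 0.06, 0.04),
    lslack_m = c(0.13, 0.10, 0.35, 0.31, 0.10, 0.23, 0.40, 0.24, 0.26),
    vmax_loptps = c(12, 12, 12, 12, 12, 12, 12, 12, 6),
    tau_act_s = rep(0.01, 9),
    tau_deact_s = rep(0.04, 9),
    delay_s = c(0.005, 0.005, 0.010, 0.010, 0.010, 0.010, 0.020, 0.020, 0.020),
    r_hip_m = c(-0.062, 0.050, 0.049, -0.072, 0, 0, 0, 0, 0),
    r_knee_m = c(0, 0, -0.045, 0.034, 0.040, -0.042, 0.020, 0, 0),
    r_ankle_m = c(0, 0, 0, 0, 0, 0, -0.053, 0.040, -0.053),
    flw = rep(0.56, 9),
    fv_k = rep(0.25, 9),
    fv_ml = rep(1.5, 9),
    eps_ref = rep(0.04, 9),
    stringsAsFactors = FALSE)
}

# ---- generic model assembly ---------------------------------------------

jtype_code <- function(x) {
  codes <- c(floating = 0L, revolute = 1L, prismatic = 2L, planar_xy = 3L)
  out <- codes[x]
  if (any(is.na(out))) stop("unknown joint type: ", paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

ndof_of <- function(jtype) c(floating = 3L, revolute = 1L, prismatic = 1L,
                             planar_xy = 2L)[jtype]

empty_muscle_table <- function(ndof) {
  list(fmax = numeric(0), lopt = numeric(0), lslack = numeric(0),
       vmax = numeric(0), tau_act = numeric(0), tau_deact = numeric(0),
       delay_steps = integer(0), lref = numeric(0), flw = numeric(0),
       fv_k = numeric(0), fv_ml = numeric(0), eps_ref = numeric(0),
       marm = matrix(0, 0, ndof))
}

# Assemble the list consumed by the compiled core.
rg_model <- function(bodies, damping, limits, gravity, contacts = NULL,
                     contact_params = list(k_n = 0, exp_n = 1, c_hc = 0,
                                           mu = 0, v_reg = 0.05),
                     muscles = NULL, conn_tgt = integer(0),
                     conn_src = integer(0), u_min = 0, u_max = 1) {
  nb <- nrow(bodies)
  jt <- jtype_code(bodies$jtype)
  ndof <- sum(ndof_of(bodies$jtype))
  if (is.null(muscles)) muscles <- empty_muscle_table(ndof)
  if (is.null(contacts))
    contacts <- list(body = integer(0), point = matrix(0, 0, 2))
  list(
    bodies = list(
      parent = as.integer(bodies$parent) - 1L,  # R 1-based (0 = world) -> C++
      jtype = jt,
      anchor = cbind(bodies$anchor_x, bodies$anchor_y),
      axis = cbind(bodies$axis_x, bodies$axis_y),
      mass = bodies$mass,
      inertia = bodies$inertia,
      com = cbind(bodies$com_x, bodies$com_y)),
    damping = damping,
    limits = limits,
    gravity = gravity,
    contacts = list(body = as.integer(contacts$body) - 1L,
                    point = contacts$point),
    contact_params = contact_params,
    muscles = muscles,
    controller = list(conn_tgt = as.integer(conn_tgt) - 1L,
                      conn_src = as.integer(conn_src) - 1L,
                      u_min = u_min, u_max = u_max))
}

new_plant <- function(model, kind, config, cm, conn_class, musc_class,
                      dof_names, joint_sign, q0, qd0, contact_groups,
                      defaults, extra = list()) {
  structure(c(list(model = model, kind = kind, config = config, cm = cm,
                   conn_class = conn_class, musc_class = musc_class,
                   ndof = length(dof_names), dof_names = dof_names,
                   joint_sign = joint_sign, q0 = q0, qd0 = qd0,
                   contact_groups = contact_groups, defaults = defaults),
              extra),
            class = "rg_plant")
}

#' @export
print.rg_plant <- function(x, ...) {
  cat(sprintf("Planar plant '%s': %d bodies, %d DoF, %d MTUs, %d contact points\n",
              x$kind, length(x$model$bodies$parent), x$ndof,
              length(x$model$muscles$fmax), length(x$model$contacts$body)))
  if (!is.null(x$cm))
    cat(sprintf("Reflex network: %d connections, %d free parameters\n",
                nrow(x$cm), n_params(x$cm)))
  invisible(x)
}

#' Build the standard planar human model
#'
#' Seven segments (torso, and femur/tibia/foot per leg) connected by six
#' revolute joints (hip, knee, ankle per leg), actuated by 18 Hill-type
#' musculotendon units (9 per leg), with viscoelastic ground contact at the
#' heel and toe of each foot. The torso is a planar floating base anchored
#' at the hip; x points forward, y up; joint angles are zero in the
#' standing configuration, flexion positive, radians internally.
#'
#' @param config Plant configuration from [plant_config()].
#' @return Object of class `rg_plant`.
#' @export
build_standard_human <- function(config = plant_config()) {
  validate_plant_config(config)
  seg <- config$segments
  srow <- function(nm) seg[seg$segment == nm, ]
  torso <- srow("torso"); femur <- srow("femur"); tibia <- srow("tibia")
  foot <- srow("foot")
  sole_y <- -0.07                       # sole depth below the ankle (m)
  heel_x <- -0.25 * foot$length_m
  toe_x <- 0.75 * foot$length_m

  # bodies: torso (floating base at the hip), then left leg, then right leg
  bodies <- data.frame(
    name = c("torso", "femur_l", "tibia_l", "foot_l",
             "femur_r", "tibia_r", "foot_r"),
    parent = c(0L, 1L, 2L, 3L, 1L, 5L, 6L),
    jtype = c("floating", rep("revolute", 6)),
    anchor_x = 0,
    anchor_y = c(0, 0, -femur$length_m, -tibia$length_m,
                 0, -femur$length_m, -tibia$length_m),
    axis_x = 0, axis_y = 0,
    mass = c(torso$mass_kg, rep(c(femur$mass_kg, tibia$mass_kg,
                                  foot$mass_kg), 2)),
    inertia = c(torso$mass_kg * torso$rgyr_m^2,
                rep(c(femur$mass_kg * femur$rgyr_m^2,
                      tibia$mass_kg * tibia$rgyr_m^2,
                      foot$mass_kg * foot$rgyr_m^2), 2)),
    com_x = c(0, rep(c(0, 0, 0.05), 2)),
    com_y = c(torso$com_m, rep(c(-femur$com_m, -tibia$com_m, -0.04), 2)),
    stringsAsFactors = FALSE)

  dof_names <- c("torso_x", "torso_y", "torso_th",
                 "hip_l", "knee_l", "ankle_l", "hip_r", "knee_r", "ankle_r")
  # internal joint coordinates are CCW-positive; knee flexion is CW, so the
  # knee carries sign -1 between the flexion-positive interface and the core
  joint_sign <- c(1, 1, 1, 1, -1, 1, 1, -1, 1)
  ndof <- 9L

  damping <- c(0, 0, 0, rep(config$joint_damping_Nms, 6))
  lim <- matrix(NA_real_, ndof, 4)
  jl <- config$joint_limits
  flex_lims <- rbind(jl$hip, jl$knee, jl$ankle, jl$hip, jl$knee, jl$ankle)
  for (j in 1:6) {
    d <- 3 + j
    lo <- flex_lims[j, 1]; hi <- flex_lims[j, 2]
    if (joint_sign[d] < 0) { tmp <- lo; lo <- -hi; hi <- -tmp }
    lim[d, ] <- c(lo, hi, config$limit_stiffness_Nm, config$limit_damping_Nms)
  }

  contacts <- list(body = c(4L, 4L, 7L, 7L),
                   point = rbind(c(heel_x, sole_y), c(toe_x, sole_y),
                                 c(heel_x, sole_y), c(toe_x, sole_y)))
  contact_groups <- list(foot_l = c(1L, 2L), foot_r = c(3L, 4L))

  # muscles: canonical order per leg, left leg then right leg
  mt <- config$mtu
  dof_idx <- list(l = c(hip = 4L, knee = 5L, ankle = 6L),
                  r = c(hip = 7L, knee = 8L, ankle = 9L))
  nm_leg <- nrow(mt)
  marm <- matrix(0, 2 * nm_leg, ndof)
  for (leg in 1:2) {
    idx <- if (leg == 1) dof_idx$l else dof_idx$r
    for (i in seq_len(nm_leg)) {
      row <- (leg - 1) * nm_leg + i
      # convert flexion-positive arms to internal CCW convention
      marm[row, idx["hip"]] <- mt$r_hip_m[i] * joint_sign[idx["hip"]]
      marm[row, idx["knee"]] <- mt$r_knee_m[i] * joint_sign[idx["knee"]]
      marm[row, idx["ankle"]] <- mt$r_ankle_m[i] * joint_sign[idx["ankle"]]
    }
  }
  rep2 <- function(x) rep(x, 2)
  muscles <- list(
    fmax = rep2(mt$fmax_N), lopt = rep2(mt$lopt_m),
    lslack = rep2(mt$lslack_m), vmax = rep2(mt$vmax_loptps),
    tau_act = rep2(mt$tau_act_s), tau_deact = rep2(mt$tau_deact_s),
    delay_steps = as.integer(round(rep2(mt$delay_s) / config$dt_s)),
    lref = rep2(mt$lopt_m + mt$lslack_m),
    flw = rep2(mt$flw), fv_k = rep2(mt$fv_k), fv_ml = rep2(mt$fv_ml),
    eps_ref = rep2(mt$eps_ref), marm = marm)

  cm <- build_connection_matrix()
  mus9 <- muscle_names()
  tgt_class <- match(cm$target, mus9)
  src_class <- match(cm$source, mus9)
  conn_tgt <- c(tgt_class, tgt_class + nm_leg)     # left leg, right leg
  conn_src <- c(src_class, src_class + nm_leg)
  conn_class <- c(seq_len(nrow(cm)), seq_len(nrow(cm)))
  musc_class <- c(seq_len(nm_leg), seq_len(nm_leg))

  model <- rg_model(bodies, damping, lim, config$gravity_mps2, contacts,
                    config$contact, muscles, conn_tgt, conn_src)

  hip_y <- femur$length_m + tibia$length_m - sole_y
  q0 <- c(0, hip_y, 0, rep(0, 6))
  qd0 <- c(1.2, 0, rep(0, 7))          # gentle forward push at release

  new_plant(model, "biped", config, cm, conn_class, musc_class, dof_names,
            joint_sign, q0, qd0, contact_groups,
            defaults = list(dt = config$dt_s, fall_y = 0.9, record_dt = 0.01,
                            transient = 10),
            extra = list(body_names = bodies$name,
                         muscle_instances = paste0(rep(mus9, 2), "_",
                                                   rep(c("l", "r"), each = nm_leg))))
}

#' Build a generic planar kinematic chain
#'
#' Low-level constructor for arbitrary planar rigid-body trees (no muscles,
#' no contact unless given), used for reduced validation models such as a
#' passive pendulum.
#'
#' @param bodies Data frame with columns `parent` (1-based index, 0 = world),
#'   `jtype` (`"floating"`, `"revolute"`, `"prismatic"`, `"planar_xy"`),
#'   `anchor_x`, `anchor_y` (joint anchor in the parent frame), `axis_x`,
#'   `axis_y` (prismatic axis in the parent frame), `mass`, `inertia`
#'   (about the CoM), `com_x`, `com_y` (CoM in the body frame).
#' @param gravity_mps2 Gravity magnitude (m/s^2).
#' @param dt_s Integrator timestep (s).
#' @param damping Per-DoF viscous damping (recycled).
#' @param contacts Optional list(body, point) of contact points.
#' @param contact_params Contact constants (see [plant_config()]).
#' @return Object of class `rg_plant` (kind `"chain"`).
#' @export
build_planar_chain <- function(bodies, gravity_mps2 = 9.81, dt_s = 5e-4,
                               damping = 0, contacts = NULL,
                               contact_params = list(k_n = 0, exp_n = 1,
                                                     c_hc = 0, mu = 0,
                                                     v_reg = 0.05)) {
  ndof <- sum(ndof_of(bodies$jtype))
  lim <- matrix(NA_real_, ndof, 4)
  model <- rg_model(bodies, rep_len(damping, ndof), lim, gravity_mps2,
                    contacts, contact_params)
  new_plant(model, "chain", list(dt_s = dt_s), NULL, integer(0), integer(0),
            paste0("q", seq_len(ndof)), rep(1, ndof), rep(0, ndof),
            rep(0, ndof), list(),
            defaults = list(dt = dt_s, fall_y = NA_real_, record_dt = 0.01,
                            transient = 0))
}

# ---- queries -------------------------------------------------------------

#' Query plant kinematics
#'
#' Forward kinematics at a configuration: per-segment and total CoM, joint
#' angles (flexion positive at the interface), and world positions of the
#' contact points.
#'
#' @param plant An `rg_plant`.
#' @param q Generalized coordinates (defaults to the plant's initial pose).
#' @return List with `com` (per body), `total_com`, `total_mass`, `theta`
#'   (world segment orientations), `joint_angles`, `contact_points`.
#' @export
query_plant <- function(plant, q = plant$q0) {
  k <- cpp_fk(plant$model, q)
  ja <- q * plant$joint_sign
  names(ja) <- plant$dof_names
  list(com = k$com, total_com = k$total_com, total_mass = k$total_mass,
       theta = k$theta, joint_angles = ja, contact_points = k$contact_points)
}

#' MTU path lengths at a configuration
#' @param plant An `rg_plant`.
#' @param q Generalized coordinates.
#' @return Numeric vector of musculotendon path lengths (m).
#' @export
mtu_lengths <- function(plant, q = plant$q0) {
  cpp_mtu_lengths(plant$model, q)
}

# ---- single-component operations ----------------------------------------

#' Default constants of a single MTU
#'
#' @param name Muscle name (one of [muscle_names()]); constants from
#'   [default_mtu_table()].
#' @return List of Hill-model constants for [mtu_step()].
#' @export
mtu_defaults <- function(name = "SOL") {
  mt <- default_mtu_table()
  i <- match(name, mt$name)
  if (is.na(i)) stop("unknown muscle: ", name)
  list(fmax = mt$fmax_N[i], lopt = mt$lopt_m[i], lslack = mt$lslack_m[i],
       vmax = mt$vmax_loptps[i], tau_act = mt$tau_act_s[i],
       tau_deact = mt$tau_deact_s[i], flw = mt$flw[i], fv_k = mt$fv_k[i],
       fv_ml = mt$fv_ml[i], eps_ref = mt$eps_ref[i])
}

#' Advance one musculotendon unit by one timestep
#'
#' First-order activation dynamics toward the stimulation, contractile
#' element advanced by the force-velocity relation under tendon force
#' equilibrium; returns the (nonnegative) tendon force computed at the
#' incoming state.
#'
#' @param mtu List of MTU constants (see [mtu_defaults()]).
#' @param state List with `act` (activation in `[0, 1]`) and `lce` (CE
#'   length, m).
#' @param stimulation Neural stimulation in `[0, 1]`.
#' @param path_length Current MTU path length (m).
#' @param dt Timestep (s), > 0.
#' @return List with `state` (advanced) and `force` (tendon force, N).
#' @export
mtu_step <- function(mtu, state, stimulation, path_length, dt) {
  if (!isTRUE(dt > 0)) stop("dt must be > 0")
  if (!all(is.finite(c(state$act, state$lce, stimulation, path_length))))
    stop("non-finite MTU input")
  r <- cpp_mtu_step(mtu, state$act, state$lce, stimulation, path_length, dt)
  list(state = list(act = r$act, lce = r$lce), force = r$force)
}

#' Ground contact forces at a plant state
#'
#' Smooth viscoelastic normal force (zero without penetration) and
#' regularized Coulomb friction at each contact point, plus per-foot
#' aggregates.
#'
#' @param plant An `rg_plant` with contact points.
#' @param q,qd Generalized coordinates and velocities.
#' @return List with per-point `normal` and `tangential` forces (N), the
#'   generalized contact force `tau`, and per-foot sums `by_group`.
#' @export
contact_wrench <- function(plant, q, qd = rep(0, plant$ndof)) {
  w <- cpp_contact_wrench(plant$model, q, qd)
  groups <- plant$contact_groups
  by_group <- lapply(groups, function(ix)
    c(normal = sum(w$normal[ix]), tangential = sum(w$tangential[ix])))
  list(normal = w$normal, tangential = w$tangential, tau = w$tau,
       by_group = by_group)
}

#' Advance the rigid-body dynamics by one timestep
#'
#' Solves the equations of motion of the planar linkage for the given
#' muscle forces (mapped through the constant moment arms), passive joint
#' elements and ground contact, then advances state by one fixed
#' semi-implicit Euler step. Deterministic: identical inputs give
#' bit-identical outputs.
#'
#' @param plant An `rg_plant`.
#' @param state List with `q`, `qd` and simulation clock `t` (s).
#' @param muscle_forces Per-MTU tendon forces (N); finite.
#' @param dt Timestep (s).
#' @param contact,gravity,passive Logical switches for the respective force
#'   contributions.
#' @return Advanced state list (`q`, `qd`, `t`).
#' @export
step_dynamics <- function(plant, state, muscle_forces = numeric(0), dt,
                          contact = TRUE, gravity = TRUE, passive = TRUE) {
  nm <- length(plant$model$muscles$fmax)
  if (length(muscle_forces) == 0) muscle_forces <- rep(0, nm)
  if (length(muscle_forces) != nm)
    stop(sprintf("expected %d muscle forces", nm))
  if (!all(is.finite(muscle_forces)))
    stop("non-finite muscle forces")
  t0 <- if (is.null(state$t)) 0 else state$t
  r <- tryCatch(
    cpp_step_dynamics(plant$model, state$q, state$qd, muscle_forces, dt,
                      contact, gravity, passive),
    error = function(e)
      stop(sprintf("integration error at t = %.6g s: %s", t0,
                   conditionMessage(e)), call. = FALSE))
  list(q = r$q, qd = r$qd, t = t0 + dt)
}
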