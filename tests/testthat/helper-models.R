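# Shared fixtures, built in code at test time.

# single pendulum: uniform rod of mass 5 kg, length 1 m, pinned at origin
make_pendulum <- function(dt = 5e-4) {
  bodies <- data.frame(parent = 0L, jtype = "revolute", anchor_x = 0,
                       anchor_y = 0, axis_x = 0, axis_y = 0, mass = 5,
                       inertia = 5 / 12, com_x = 0, com_y = -0.5)
  build_planar_chain(bodies, dt_s = dt)
}

pendulum_energy <- function(q, qd) {
  Ieff <- 5 / 12 + 5 * 0.25
  0.5 * Ieff * qd^2 + 5 * 9.81 * (-0.5 * cos(q))
}

# flat puck with one contact point at its origin (contact-model checks)
make_puck <- function(k_n = 1e4, exp_n = 1.5, c_hc = 1.0, mu = 0.8,
                      v_reg = 0.05) {
  bodies <- data.frame(parent = 0L, jtype = "planar_xy", anchor_x = 0,
                       anchor_y = 0, axis_x = 0, axis_y = 0, mass = 2,
                       inertia = 0.1, com_x = 0, com_y = 0)
  build_planar_chain(bodies,
                     contacts = list(body = 1L, point = matrix(0, 1, 2)),
                     contact_params = list(k_n = k_n, exp_n = exp_n,
                                           c_hc = c_hc, mu = mu,
                                           v_reg = v_reg))
}

# toy hopper fixture (cheap to build; episodes cost ~0.1 s/s simulated)
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_plant()
    cache
  }
})

# minimal stand-in episode with prescribed scalars/trajectories, for
# closed-form cost and distance checks
fake_episode <- function(t_sim, t_max, seg_x0, seg_x1) {
  structure(list(t_sim = t_sim, t_max = t_max,
                 seg_com_x = rbind(seg_x0, seg_x1)),
            class = "rg_episode")
}

biped_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_standard_human()
    cache
  }
})

mirror_state <- function(plant, q) {
  # swap left and right leg joint coordinates (indices 4:6 <-> 7:9)
  q[c(1:3, 7:9, 4:6)]
}
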