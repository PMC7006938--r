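# Hand-wired brains and scripted trajectories used across the suite.

# 1-in/1-out gate copying unit `from` into unit `to` (identity table)
identity_gate <- function(from, to) {
  list(inputs = as.integer(from), outputs = as.integer(to),
       n_in = 1L, n_out = 1L, table = c(0L, 1L))
}

# gate computing an arbitrary 1-bit function of one input
fun_gate <- function(from, to, table) {
  list(inputs = as.integer(from), outputs = as.integer(to),
       n_in = 1L, n_out = 1L, table = as.integer(table))
}

# memory units 3 and 4 of the smallbrain architecture copy each other
copy_loop_brain <- function() {
  markov_brain(arch_spec("smallbrain"),
               list(identity_gate(4, 3), identity_gate(3, 4)))
}

# strictly feed-forward chain: sensor -> memory -> memory -> motor
chain_brain <- function() {
  markov_brain(arch_spec("smallbrain"),
               list(identity_gate(1, 3), identity_gate(3, 4), identity_gate(4, 5)))
}

# two self-copying, mutually disconnected memory units
disconnected_brain <- function() {
  markov_brain(arch_spec("smallbrain"),
               list(identity_gate(3, 3), identity_gate(4, 4)))
}

# minimal 4-unit architecture: 1 wall sensor, 1 memory, 2 motors
tiny_arch <- function() {
  arch_spec("custom", sensors = data.frame(kind = "wall", side = "front"),
            n_memory = 1, motor_feedback = TRUE)
}

# scripted trajectory with exactly two gate crossings separated by `spacing`
# timesteps; the first crossing completes at t = 3
crossing_pair_log <- function(world, spacing, T = 500) {
  stopifnot(3 + spacing <= T)
  xs <- rep(15, T)
  xs[2] <- 16
  xs[3:(3 + spacing - 2)] <- 17
  xs[3 + spacing - 1] <- 16
  scripted_trial_log(world, data.frame(animat = 1, t = 1:T, x = xs, y = 15))
}

# adversarial gate oscillator: re-crosses at the minimum rewarded spacing
# (refractory + 1) for the whole trial
oscillator_log <- function(world, T = 500, refractory = 100) {
  xs <- rep(15, T)
  cross_t <- seq(3, T, by = refractory + 1)
  for (i in seq_along(cross_t)) {
    tc <- cross_t[i]
    xs[tc - 1] <- 16
    if (i %% 2 == 1) {
      stop_t <- if (i < length(cross_t)) cross_t[i + 1] - 2 else T
      xs[tc:stop_t] <- 17
    }
  }
  scripted_trial_log(world, data.frame(animat = 1, t = 1:T, x = xs, y = 15))
}

# two animats meeting on one cell for exactly one timestep, no crossings
collision_log <- function(world) {
  scripted_trial_log(world, rbind(
    data.frame(animat = 1, t = 1:5, x = c(5, 6, 7, 6, 5), y = 5),
    data.frame(animat = 2, t = 1:5, x = c(9, 8, 7, 8, 9), y = 5)))
}
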