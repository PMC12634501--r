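# Shared fixtures: tiny networks and reference filters used across files.

quick_params <- function(...) ca3_params(...)

# single uncoupled neuron with fixed drive, full reset
single_neuron_state <- function(params, eta, v0 = params$v_r) {
  st <- init_network(params,
                     het_spec(eta_bar = eta, delta_eta = 0, g_bar = 0,
                              theta_bar = 0, delta_theta = 0),
                     n = 1, seed = 1)
  st$v <- v0
  st
}

# direct convolution oracle: first-order exponential filter of a spike
# train evaluated on a sampling grid (unit-area kernel, jump 1/tau at the
# spike step's end, exact exponential decay between samples)
filter_oracle <- function(spike_times, grid, tau, dt) {
  out <- numeric(length(grid))
  # reproduce the integrator's event bookkeeping: a spike in step m
  # contributes from time (m+1)*dt onward with value exp(-(t-(m+1)*dt)/tau)
  # after the jump applied at the end of step m... the simulator applies
  # decay then jump within the step, so a spike at step left edge t_s
  # contributes (1/tau)*exp(-(t - t_s - dt)/tau) for t >= t_s + dt.
  for (ts in spike_times) {
    active <- grid >= ts + dt - 1e-12
    out[active] <- out[active] + exp(-(grid[active] - ts - dt) / tau) / tau
  }
  out
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
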