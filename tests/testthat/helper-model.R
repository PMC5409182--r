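# shared fixtures; heavy objects are built once per test run on demand
med_tree <- function() build_tree()
med_passive <- function() passive_params()
med_syn <- function() synaptic_params()

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

shared_impedance_grid <- function()
  cached("grid", impedance_grid())

baseline_analytic <- function()
  cached("fs_base", fluctuation_stats(baseline_state(), med_tree(),
                                      med_passive(), med_syn()))

baseline_simulated <- function()
  cached("ss_base", {
    cell <- discretize(med_tree(), med_passive(), med_syn(), nseg = 30)
    simulated_stats(cell, baseline_state(), T_ms = 2000, dt_ms = 0.05,
                    seeds = 1:4)
  })

# exact Ornstein-Uhlenbeck sampler for measurement calibration
ou_trace <- function(n, dt_ms, mu, sigma, tau_ms, seed = 1) {
  set.seed(seed)
  a <- exp(-dt_ms / tau_ms)
  x <- numeric(n)
  x[1] <- mu
  innov <- stats::rnorm(n - 1, 0, sigma * sqrt(1 - a^2))
  for (i in 2:n) x[i] <- mu + (x[i - 1] - mu) * a + innov[i - 1]
  x
}
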