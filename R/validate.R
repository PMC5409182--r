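# Analytic-vs-simulation validation: one-variable sweeps around the mean
# presynaptic configuration, and the uniform synchrony increment that
# reconciles the analytic amplitude with the simulated one.

#' Analytic vs simulated statistics across one-variable sweeps
#'
#' Each of the four rate variables is swept (multiplicatively) around the
#' mean configuration and the synchrony over the given values, one
#' variable at a time; for every state both the analytic estimator and the
#' compartmental simulator (several seeds) are evaluated.
#'
#' @param tree,passive,syn model components.
#' @param state mean configuration (default: the common baseline).
#' @param factors multiplicative sweep factors for the rate variables.
#' @param s_values synchrony sweep values.
#' @param T_ms,dt_ms,seeds,nseg simulation settings.
#' @return A data.frame with columns `variable`, `value`, analytic
#'   `mu_ana`, `sigma_ana`, `tau_ana`, simulated `mu_sim`, `sigma_sim`,
#'   `tau_sim` and their across-seed SDs.
#' @export
validate_sweeps <- function(tree = build_tree(), passive = passive_params(),
                            syn = synaptic_params(),
                            state = baseline_state(),
                            factors = c(0.5, 1, 2),
                            s_values = c(0.05, 0.2, 0.4),
                            T_ms = 2000, dt_ms = 0.05, seeds = 1:4,
                            nseg = 30) {
  cell <- discretize(tree, passive, syn, nseg)
  eval_state <- function(variable, value, st) {
    fs <- fluctuation_stats(st, tree, passive, syn)
    ss <- simulated_stats(cell, st, T_ms, dt_ms, seeds)
    data.frame(variable = variable, value = value,
               mu_ana = fs$mu_V, sigma_ana = fs$sigma_V, tau_ana = fs$tau_V,
               mu_sim = ss$mu_V, sigma_sim = ss$sigma_V, tau_sim = ss$tau_V,
               sd_mu = ss$sd_mu, sd_sigma = ss$sd_sigma, sd_tau = ss$sd_tau)
  }
  rows <- list()
  for (v in c("nu_ep", "nu_ip", "nu_ed", "nu_id")) {
    for (fac in factors) {
      st <- state; st[[v]] <- state[[v]] * fac
      rows[[length(rows) + 1]] <- eval_state(v, st[[v]], st)
    }
  }
  for (sv in s_values) {
    st <- state; st$s <- sv
    rows[[length(rows) + 1]] <- eval_state("s", sv, st)
  }
  do.call(rbind, rows)
}

#' Synchrony increment reconciling analytic and simulated amplitudes
#'
#' Newton iteration on the synchrony argument of the analytic estimator
#' (all rates fixed) to find the uniform increment `ds` above the state's
#' synchrony at which the analytic `sigma_V` equals `sigma_target`
#' (typically the simulated value). The increment may be negative when
#' the analytic amplitude overshoots the target.
#'
#' @param sigma_target target amplitude (mV).
#' @param state reference `presynaptic_state`.
#' @param tree,passive,syn model components.
#' @param tol convergence tolerance on sigma (mV).
#' @param max_iter Newton iteration cap.
#' @return The increment `ds` (scalar).
#' @export
synchrony_correction <- function(sigma_target, state, tree = build_tree(),
                                 passive = passive_params(),
                                 syn = synaptic_params(),
                                 tol = 1e-4, max_iter = 25) {
  sigma_of <- function(s) {
    st <- state; st$s <- s
    suppressWarnings(fluctuation_stats(st, tree, passive, syn)$sigma_V)
  }
  s <- state$s
  h <- 1e-4
  for (i in seq_len(max_iter)) {
    f <- sigma_of(s) - sigma_target
    if (abs(f) < tol) break
    lo <- max(s - h, 0); hi <- min(s + h, 0.95)
    df <- (sigma_of(hi) - sigma_of(lo)) / (hi - lo)
    s_new <- min(max(s - f / df, 0), 0.95)
    if (abs(s_new - s) < 1e-8) {
      # pinned at a boundary: no interior solution, return the boundary
      s <- s_new
      break
    }
    s <- s_new
  }
  s - state$s
}
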