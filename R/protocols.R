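# The curated presynaptic stimulation protocols: a common balanced
# baseline, then unbalanced / proximal / distal / synchrony ramps, each a
# sequence of presynaptic states ordered by increasing synaptic quantity.
# Inhibition is adjusted with a 1-D root find on a common scale factor of
# the free inhibitory rates so that the analytic stationary somatic mean
# hits the balance target.

#' Solve inhibitory rates for a somatic balance target
#'
#' Scales the listed free inhibitory rates by a common factor so that the
#' analytic stationary somatic mean potential equals `target_mu` (mV),
#' within 0.01 mV. The map from inhibition to mu_V is monotonically
#' decreasing, so the root is unique when it exists.
#'
#' @param state a `presynaptic_state` providing the fixed rates and the
#'   seed values of the free inhibitory rates.
#' @param target_mu balance target (mV), strictly between the reversals.
#' @param free which inhibitory rates to scale: subset of
#'   `c("nu_ip", "nu_id")` (`nu_ip` also drives the somatic synapses).
#' @param tree,passive,syn model components.
#' @param tol_mV solver tolerance on the somatic mean (mV).
#' @param clamp if TRUE and the target is unreachable from below (zero
#'   inhibition still leaves the cell hyperpolarized relative to the
#'   target), the zero-inhibition state is returned with attribute
#'   `clamped = TRUE` instead of an error; used by the protocol builders,
#'   where the printed excitation ramp can undershoot weak-synapse cells.
#' @return The solved `presynaptic_state`.
#' @export
balance_inhibition <- function(state, target_mu, free = c("nu_ip", "nu_id"),
                               tree, passive, syn, tol_mV = 0.01,
                               clamp = FALSE) {
  stopifnot(length(free) >= 1, all(free %in% c("nu_ip", "nu_id")))
  if (target_mu <= syn$Ei || target_mu >= syn$Ee)
    stop("balance target must lie strictly between the synaptic reversals")
  seeds <- unname(unlist(state[free]))
  if (all(seeds == 0)) seeds[] <- 1  # allow scaling up from zero seeds
  mu_of <- function(scale) {
    st <- state
    for (i in seq_along(free)) st[[free[i]]] <- seeds[i] * scale
    stationary_mean_profile(st, tree, passive, syn, n_points = 2)$mu_soma
  }
  mu0 <- mu_of(0)
  if (mu0 < target_mu - tol_mV) {
    if (clamp) {
      out <- state
      for (f in free) out[[f]] <- 0
      attr(out, "clamped") <- TRUE
      return(out)
    }
    stop(sprintf(
      "target %.2f mV unreachable: even zero inhibition gives %.2f mV",
      target_mu, mu0))
  }
  if (abs(mu0 - target_mu) <= tol_mV) {
    scale <- 0
  } else {
    hi <- 1
    while (mu_of(hi) > target_mu && hi < 1e4) hi <- hi * 2
    if (mu_of(hi) > target_mu)
      stop("target unreachable within the admissible inhibition range")
    scale <- stats::uniroot(function(k) mu_of(k) - target_mu,
                            interval = c(0, hi),
                            tol = 1e-10)$root
  }
  out <- state
  for (i in seq_along(free)) out[[free[i]]] <- seeds[i] * scale
  if (abs(stationary_mean_profile(out, tree, passive, syn,
                                  n_points = 2)$mu_soma - target_mu) > tol_mV)
    stop("balance solver failed to reach the target within tolerance")
  out
}

.protocol <- function(name, states, targets = NULL) {
  structure(list(name = name, states = states, targets = targets),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("protocol '%s': %d states\n", x$name, length(x$states)))
  invisible(x)
}

#' Unbalanced activity ramp
#'
#' Excitation rises linearly over `[0.05, 0.5]` Hz in both domains while
#' inhibition is re-solved at every step for a balance target ramped
#' linearly from the baseline somatic mean to 3 mV above it (the printed
#' -55 to -52 mV window); synchrony stays at baseline. Step 0 is the
#' common baseline state.
#'
#' @param n_steps ramp resolution (states beyond the baseline).
#' @param tree,passive,syn model components.
#' @return A `protocol`.
#' @export
unbalanced_protocol <- function(n_steps = 10, tree = build_tree(),
                                passive = passive_params(),
                                syn = synaptic_params()) {
  base <- baseline_state()
  mu_b <- stationary_mean_profile(base, tree, passive, syn,
                                  n_points = 2)$mu_soma
  nu_e <- seq(0.05, 0.5, length.out = n_steps)
  targets <- seq(mu_b, mu_b + 3, length.out = n_steps + 1)[-1]
  states <- vector("list", n_steps + 1)
  states[[1]] <- base
  for (i in seq_len(n_steps)) {
    st <- base
    st$nu_ep <- st$nu_ed <- nu_e[i]
    states[[i + 1]] <- balance_inhibition(st, targets[i],
                                          c("nu_ip", "nu_id"),
                                          tree, passive, syn, clamp = TRUE)
  }
  .protocol("unbalanced", states, c(mu_b, targets))
}

#' Proximal activity ramp
#'
#' Proximal excitation rises from baseline to 1.7 Hz; proximal-dendritic
#' and somatic inhibition (one common rate, `nu_ip`) is re-solved at every
#' step to hold the somatic mean at its baseline value; distal rates and
#' synchrony stay at baseline.
#'
#' @inheritParams unbalanced_protocol
#' @return A `protocol`.
#' @export
proximal_protocol <- function(n_steps = 10, tree = build_tree(),
                              passive = passive_params(),
                              syn = synaptic_params()) {
  base <- baseline_state()
  mu_b <- stationary_mean_profile(base, tree, passive, syn,
                                  n_points = 2)$mu_soma
  nu_e <- seq(base$nu_ep, 1.7, length.out = n_steps + 1)
  states <- vector("list", n_steps + 1)
  states[[1]] <- base
  for (i in seq_len(n_steps)) {
    st <- base
    st$nu_ep <- nu_e[i + 1]
    states[[i + 1]] <- balance_inhibition(st, mu_b, "nu_ip",
                                          tree, passive, syn, clamp = TRUE)
  }
  .protocol("proximal", states, rep(mu_b, n_steps + 1))
}

#' Distal activity ramp
#'
#' Distal excitation rises from baseline to 0.7 Hz; the distal inhibitory
#' rate is re-solved to hold the somatic balance; proximal rates and
#' synchrony stay at baseline.
#'
#' @inheritParams unbalanced_protocol
#' @return A `protocol`.
#' @export
distal_protocol <- function(n_steps = 10, tree = build_tree(),
                            passive = passive_params(),
                            syn = synaptic_params()) {
  base <- baseline_state()
  mu_b <- stationary_mean_profile(base, tree, passive, syn,
                                  n_points = 2)$mu_soma
  nu_e <- seq(base$nu_ed, 0.7, length.out = n_steps + 1)
  states <- vector("list", n_steps + 1)
  states[[1]] <- base
  for (i in seq_len(n_steps)) {
    st <- base
    st$nu_ed <- nu_e[i + 1]
    states[[i + 1]] <- balance_inhibition(st, mu_b, "nu_id",
                                          tree, passive, syn, clamp = TRUE)
  }
  .protocol("distal", states, rep(mu_b, n_steps + 1))
}

#' Synchrony ramp
#'
#' All rates stay at baseline; the synchrony degree rises linearly from
#' 0.05 to 0.4. Affects only the amplitude of the fluctuations.
#'
#' @inheritParams unbalanced_protocol
#' @return A `protocol`.
#' @export
synchrony_protocol <- function(n_steps = 10, tree = build_tree(),
                               passive = passive_params(),
                               syn = synaptic_params()) {
  base <- baseline_state()
  s_seq <- seq(base$s, 0.4, length.out = n_steps + 1)
  states <- lapply(s_seq, function(si) { st <- base; st$s <- si; st })
  .protocol("synchrony", states)
}

#' Evaluate the analytic fluctuation statistics along a protocol
#'
#' @param protocol a `protocol`.
#' @param tree,passive,syn model components.
#' @param ... passed to [fluctuation_stats()].
#' @return A data.frame with one row per step: the five state variables,
#'   `mu_V`, `sigma_V`, `tau_V` (ms), `g_ratio`, and `tau_V_rel` (tau_V as
#'   a fraction of its step-0 value).
#' @export
run_protocol <- function(protocol, tree = build_tree(),
                         passive = passive_params(),
                         syn = synaptic_params(), ...) {
  rows <- lapply(seq_along(protocol$states), function(i) {
    st <- protocol$states[[i]]
    fs <- fluctuation_stats(st, tree, passive, syn, ...)
    data.frame(step = i - 1, nu_ep = st$nu_ep, nu_ip = st$nu_ip,
               nu_ed = st$nu_ed, nu_id = st$nu_id, s = st$s,
               mu_V = fs$mu_V, sigma_V = fs$sigma_V, tau_V = fs$tau_V,
               g_ratio = fs$g_ratio)
  })
  out <- do.call(rbind, rows)
  out$tau_V_rel <- out$tau_V / out$tau_V[1]
  out
}
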