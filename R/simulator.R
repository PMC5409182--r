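# Ground-truth numerical simulator: explicit branched tree, conductance
# synapses driven by synchrony-biased event trains, implicit integration.

#' Discretize the branched model into compartments
#'
#' Builds the explicit compartmental representation of the full
#' arborescence: every branch of every generation is split into `nseg`
#' compartments (soma is one lumped compartment), and each dendritic
#' compartment receives one lumped excitatory and one lumped inhibitory
#' synapse whose event rate is the compartment's (real-valued) area-scaled
#' synapse count times the per-synapse rate of its domain (Poisson superposition). The
#' soma receives the lumped somatic inhibitory population.
#'
#' @param tree a `tree_morphology`.
#' @param passive a `passive_params`.
#' @param syn a `synaptic_params`.
#' @param nseg compartments per branch.
#' @return An object of class `discretized_cell`: compartment table
#'   (`comp`), electrical vectors in SI units, and synapse bookkeeping.
#' @export
discretize <- function(tree, passive, syn, nseg = 30) {
  stopifnot(nseg >= 1)
  GL <- passive$GL * .uS_cm2; Cm <- passive$Cm * .uF_cm2
  Ri <- passive$Ri * .Ohm_cm
  # soma first (index 1 in R, parent 0 sentinel)
  A_s <- pi * (tree$dS * .um) * (tree$lS * .um)
  comp <- list(data.frame(b = 0L, j = 0L, seg = 0L, parent = 0L,
                          x_mid = 0, len = tree$lS * .um, diam = tree$dS * .um,
                          area = A_s))
  idx <- 1L
  branch_last <- new.env()  # last compartment index of branch (b,j)
  key <- function(b, j) paste(b, j)
  for (b in seq_len(tree$B)) {
    g <- tree$gen[b, ]
    h <- g$length * .um / nseg
    d <- g$diam * .um
    for (j in seq_len(g$n) - 1L) {
      parent0 <- if (b == 1L) 1L else get(key(b - 1L, j %/% 2L), branch_last)
      ids <- idx + seq_len(nseg)
      x0 <- g$x0 * .um
      comp[[length(comp) + 1L]] <- data.frame(
        b = b, j = j, seg = seq_len(nseg),
        parent = c(parent0, ids[-nseg]),
        x_mid = x0 + (seq_len(nseg) - 0.5) * h,
        len = h, diam = d, area = pi * d * h)
      assign(key(b, j), ids[nseg], branch_last)
      idx <- idx + nseg
    }
  }
  comp <- do.call(rbind, comp)
  N <- nrow(comp)
  # axial conductance to parent: half-compartment resistances in series
  # (soma is lumped: only the child's half counts towards it)
  r_half <- with(comp, (len / 2) * 4 * Ri / (pi * diam^2))
  g_ax <- numeric(N)
  for (i in 2:N) {
    p <- comp$parent[i]
    rp <- if (p == 1L) 0 else r_half[p]
    g_ax[i] <- 1 / (r_half[i] + rp)
  }
  distal <- comp$x_mid > tree$lp * .um
  distal[1] <- FALSE
  # real-valued synapse counts per compartment: the lumped shotnoise rate is
  # count * nu (Poisson superposition), so no integer rounding is needed --
  # and rounding would zero out the sparse inhibitory population on thin
  # distal compartments at the default discretization
  n_e <- ifelse(seq_len(N) == 1L,
                A_s / 1e-12 / 100 * syn$De_soma,
                comp$area / 1e-12 / 100 * syn$De_tree)
  n_i <- ifelse(seq_len(N) == 1L,
                A_s / 1e-12 / 100 * syn$Di_soma,
                comp$area / 1e-12 / 100 * syn$Di_tree)
  Qe <- ifelse(distal, syn$Qed, syn$Qep) * .nS
  Qi <- ifelse(distal, syn$Qid, syn$Qip) * .nS
  Qi[1] <- syn$QiS * .nS
  structure(list(
    comp = comp, n_comp = N, distal = distal,
    g_ax = g_ax, cap = Cm * comp$area, g_leak = GL * comp$area,
    n_e = n_e, n_i = n_i, Qe = Qe, Qi = Qi,
    tree = tree, passive = passive, syn = syn, nseg = nseg),
    class = "discretized_cell")
}

# event trains for every compartment synapse -> sorted step/comp/type/q
.build_events <- function(cell, state, T_s, dt_s, seed) {
  nstep <- round(T_s / dt_s)
  rate_e <- cell$n_e * ifelse(cell$distal, state$nu_ed, state$nu_ep)
  rate_e[1] <- cell$n_e[1] * state$nu_ep
  rate_i <- cell$n_i * ifelse(cell$distal, state$nu_id, state$nu_ip)
  rate_i[1] <- cell$n_i[1] * state$nu_ip   # somatic synapses: proximal rates
  step <- comp <- type <- q <- list()
  k <- 1L
  for (i in seq_len(cell$n_comp)) {
    if (rate_e[i] > 0) {
      tr <- synchrony_train(rate_e[i], state$s, T_s * 1e3,
                            seed = .substream_seed(seed, 2L * i))
      if (length(tr)) {
        step[[k]] <- pmin(floor(tr / (dt_s * 1e3)), nstep - 1L)
        comp[[k]] <- rep(i - 1L, length(tr))
        type[[k]] <- rep(0L, length(tr))
        q[[k]] <- rep(cell$Qe[i], length(tr)); k <- k + 1L
      }
    }
    if (rate_i[i] > 0) {
      tr <- synchrony_train(rate_i[i], state$s, T_s * 1e3,
                            seed = .substream_seed(seed, 2L * i + 1L))
      if (length(tr)) {
        step[[k]] <- pmin(floor(tr / (dt_s * 1e3)), nstep - 1L)
        comp[[k]] <- rep(i - 1L, length(tr))
        type[[k]] <- rep(1L, length(tr))
        q[[k]] <- rep(cell$Qi[i], length(tr)); k <- k + 1L
      }
    }
  }
  if (k == 1L)
    return(list(step = integer(0), comp = integer(0), type = integer(0),
                q = numeric(0)))
  step <- unlist(step); o <- order(step)
  list(step = as.integer(step[o]), comp = as.integer(unlist(comp)[o]),
       type = as.integer(unlist(type)[o]), q = unlist(q)[o])
}

#' Simulate the discretized cell
#'
#' Integrates the passive branched cable with conductance synapses using
#' an unconditionally stable implicit scheme (backward Euler with a direct
#' tree solve each step); synaptic conductances decay exponentially and
#' jump by the quantal at each presynaptic event. Deterministic given
#' `seed`; event trains use one substream per compartment synapse.
#'
#' @param cell a `discretized_cell`.
#' @param state a `presynaptic_state`, or NULL for no synaptic input.
#' @param T_ms simulated duration (ms).
#' @param dt_ms time step (ms).
#' @param seed master seed (integer).
#' @param I_amp_nA,I_freq_Hz optional somatic sine-current injection
#'   (amplitude nA, frequency Hz), used for impedance cross-checks.
#' @param probes_x optional path distances (um) at which dendritic voltage
#'   is recorded (nearest compartment).
#' @param mean_background optional `presynaptic_state` whose *mean*
#'   synaptic conductances are applied as a static (noise-free) background
#'   on every compartment -- the quiescent high-conductance membrane used
#'   for single-event kernel cross-checks.
#' @param events optional data.frame with columns `time_ms`, `x_um`
#'   (0 targets the soma), `type` ("e"/"i") and `q_nS` for deterministic
#'   event injection (used with `state = NULL`).
#' @return A list of class `sim_result`: `t_ms`, `v_soma` (mV), optional
#'   `v_probe` (mV matrix), `seed`, and the call parameters.
#' @export
simulate_cell <- function(cell, state, T_ms = 2000, dt_ms = 0.05, seed = 1,
                          I_amp_nA = 0, I_freq_Hz = 0, probes_x = NULL,
                          mean_background = NULL, events = NULL) {
  stopifnot(inherits(cell, "discretized_cell"), T_ms > 0, dt_ms > 0)
  T_s <- T_ms * 1e-3; dt_s <- dt_ms * 1e-3
  nstep <- round(T_s / dt_s)
  ev <- if (is.null(state))
    list(step = integer(0), comp = integer(0), type = integer(0),
         q = numeric(0))
  else .build_events(cell, state, T_s, dt_s, seed)
  if (!is.null(events) && nrow(events)) {
    comp_of <- function(x) if (x <= 0) 1L else
      which.min(abs(cell$comp$x_mid[-1] - x * .um)) + 1L
    ad <- list(step = pmin(floor(events$time_ms / dt_ms), nstep - 1L),
               comp = vapply(events$x_um, comp_of, integer(1)) - 1L,
               type = ifelse(events$type == "e", 0L, 1L),
               q = events$q_nS * .nS)
    ev <- lapply(stats::setNames(names(ev), names(ev)), function(nm)
      c(ev[[nm]], ad[[nm]]))
    o <- order(ev$step)
    ev <- list(step = as.integer(ev$step[o]), comp = as.integer(ev$comp[o]),
               type = as.integer(ev$type[o]), q = ev$q[o])
  }
  bg_ge <- bg_gi <- numeric(cell$n_comp)
  if (!is.null(mean_background)) {
    dens <- .mean_area_densities(mean_background, cell$syn)   # S/m^2
    bg_ge <- ifelse(cell$distal, dens$ge_d, dens$ge_p) * cell$comp$area
    bg_gi <- ifelse(cell$distal, dens$gi_d, dens$gi_p) * cell$comp$area
    bg_ge[1] <- 0
    bg_gi[1] <- cell$n_i[1] * mean_background$nu_ip *
      (cell$syn$QiS * .nS) * (cell$syn$tau_i * .ms)
  }
  probes <- if (is.null(probes_x)) integer(0) else
    vapply(probes_x, function(x)
      which.min(abs(cell$comp$x_mid - x * .um))[1] - 1L, integer(1))
  res <- sim_tree_cpp(
    parent = as.integer(cell$comp$parent - 1L), g_ax = cell$g_ax,
    cap = cell$cap, gl = cell$g_leak,
    EL = cell$passive$EL * .mV, Ee = cell$syn$Ee * .mV,
    Ei = cell$syn$Ei * .mV,
    dt = dt_s, nstep = nstep,
    tau_e = cell$syn$tau_e * .ms, tau_i = cell$syn$tau_i * .ms,
    ev_step = ev$step, ev_comp = ev$comp, ev_type = ev$type, ev_q = ev$q,
    I_amp = I_amp_nA * 1e-9, I_freq = I_freq_Hz,
    bg_ge = bg_ge, bg_gi = bg_gi,
    probes = probes)
  structure(list(t_ms = seq(0, nstep) * dt_ms,
                 v_soma = res$v_soma / .mV,
                 v_probe = if (length(probes)) res$v_probe / .mV else NULL,
                 seed = seed, T_ms = T_ms, dt_ms = dt_ms, state = state),
            class = "sim_result")
}

# autocorrelation by FFT (biased estimator, lags 0..nlag)
.acf_fft <- function(x, nlag) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(nlag + 1)] / m
  ac / ac[1]
}

#' Measure fluctuation statistics from a voltage trace
#'
#' Time mean and SD after discarding the initial transient, plus the
#' global autocorrelation time: the integral of the empirical normalized
#' autocorrelation function from zero lag up to its first crossing of
#' `exp(-3)` (matching the analytic `PSD(0) / (2 sigma^2)` definition
#' while ignoring the noisy ACF tail).
#'
#' @param trace voltage trace (mV).
#' @param dt_ms sampling step (ms).
#' @param t_discard_ms initial transient to drop (ms).
#' @param max_lag_ms longest lag entering the ACF integral (ms).
#' @return A list: `mu_V`, `sigma_V` (mV), `tau_V` (ms), and `short_trace`
#'   flag (TRUE when the usable trace is shorter than 10 tau_V).
#' @export
measure_stats <- function(trace, dt_ms, t_discard_ms = 200,
                          max_lag_ms = 500) {
  keep <- seq_along(trace) * dt_ms > t_discard_ms
  x <- trace[keep]
  mu <- mean(x); sd_ <- stats::sd(x)
  if (sd_ == 0)
    return(list(mu_V = mu, sigma_V = 0, tau_V = NA_real_,
                short_trace = FALSE))
  nlag <- min(round(max_lag_ms / dt_ms), length(x) - 1)
  rho <- .acf_fft(x, nlag)
  cross <- which(rho < exp(-3))[1]
  upto <- if (is.na(cross)) nlag + 1 else cross
  tau <- dt_ms * (sum(rho[1:upto]) - rho[1] / 2)
  list(mu_V = mu, sigma_V = sd_, tau_V = tau,
       short_trace = length(x) * dt_ms < 10 * tau)
}

#' Simulated fluctuation statistics over several seeds
#'
#' Convenience wrapper: runs [simulate_cell()] for each seed, measures the
#' somatic statistics and returns their across-seed mean and SD.
#'
#' @inheritParams simulate_cell
#' @param seeds integer vector of master seeds.
#' @param t_discard_ms transient dropped before measuring.
#' @return A list with `mu_V`, `sigma_V`, `tau_V` (across-seed means),
#'   their `sd_` counterparts, and the per-seed table `per_seed`.
#' @export
simulated_stats <- function(cell, state, T_ms = 2000, dt_ms = 0.05,
                            seeds = 1:4, t_discard_ms = 200) {
  per <- lapply(seeds, function(sd0) {
    r <- simulate_cell(cell, state, T_ms, dt_ms, seed = sd0)
    m <- measure_stats(r$v_soma, dt_ms, t_discard_ms)
    data.frame(seed = sd0, mu_V = m$mu_V, sigma_V = m$sigma_V,
               tau_V = m$tau_V)
  })
  per <- do.call(rbind, per)
  list(mu_V = mean(per$mu_V), sigma_V = mean(per$sigma_V),
       tau_V = mean(per$tau_V),
       sd_mu = stats::sd(per$mu_V), sd_sigma = stats::sd(per$sigma_V),
       sd_tau = stats::sd(per$tau_V), per_seed = per)
}
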