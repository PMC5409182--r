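# Firing-response functions nu_out = F(mu_V, sigma_V, tau_V): a
# phenomenological-threshold template in which an effective spike threshold
# depends (affinely) on the fluctuation properties, the four
# characterization measures built on it, the composed transfer function,
# and synthetic heterogeneous populations standing in for in vitro
# characterizations.

#' Parameters of a phenomenological-threshold firing response
#'
#' The default template is
#' `nu_out = 1/(2 tau_V) * erfc((Vthre_eff - mu_V) / (sqrt(2) sigma_V))`
#' with an effective threshold affine in the fluctuation properties:
#' `Vthre_eff = V0 + a_mu (mu_V - mu_a) + a_sigma (sigma_V - sigma_a) +
#' a_tau (tau_VN - tau_a)`, where `tau_VN` is the autocorrelation time
#' normalized by the cell's resting membrane time constant. The anchors
#' `(mu_a, sigma_a, tau_a)` centre the sensitivities on the physiological
#' fluctuation range. Any parametric alternative can be substituted by
#' supplying an object with an `evaluate(stats)` closure.
#'
#' @param V0 base threshold (mV).
#' @param a_mu sensitivity of the threshold to `mu_V` (dimensionless,
#'   `< 1` so the rate stays monotone increasing in `mu_V`).
#' @param a_sigma threshold sensitivity to `sigma_V` (dimensionless).
#' @param a_tau threshold sensitivity to the normalized autocorrelation
#'   time (mV per unit `tau_VN`).
#' @param anchors list with `mu` (mV), `sigma` (mV), `tau` (dimensionless).
#' @param id optional identifier.
#' @return An object of class `firing_response_params`.
#' @export
firing_response_params <- function(V0 = -48, a_mu = 0, a_sigma = 0,
                                   a_tau = 0,
                                   anchors = list(mu = -60, sigma = 4,
                                                  tau = 0.5),
                                   id = NULL) {
  if (a_mu >= 1) stop("a_mu must be below 1 for excitability monotonicity")
  structure(list(V0 = V0, a_mu = a_mu, a_sigma = a_sigma, a_tau = a_tau,
                 anchors = anchors, id = id),
            class = "firing_response_params")
}

.v_thre_eff <- function(p, mu, sigma, tauN) {
  p$V0 + p$a_mu * (mu - p$anchors$mu) + p$a_sigma * (sigma - p$anchors$sigma) +
    p$a_tau * (tauN - p$anchors$tau)
}

#' Evaluate a firing-response function
#'
#' Deterministic, smooth, non-negative output rate; monotone increasing in
#' `mu_V`. Far below threshold (10 standard deviations or more) the rate
#' is suppressed below 1e-5 Hz.
#'
#' @param params a `firing_response_params`.
#' @param stats a `fluctuation_stats` (or any list with `mu_V`, `sigma_V`,
#'   `tau_V` in mV/ms and `tau_m0` in ms).
#' @return Output rate nu_out (Hz).
#' @export
firing_rate <- function(params, stats) {
  stopifnot(stats$sigma_V > 0, stats$tau_V > 0)
  tauN <- stats$tau_V / stats$tau_m0
  vth <- .v_thre_eff(params, stats$mu_V, stats$sigma_V, tauN)
  # erfc((vth-mu)/(sqrt2 sigma)) = 2 pnorm((mu-vth)/sigma)
  (1 / (stats$tau_V * .ms)) * stats::pnorm((stats$mu_V - vth) / stats$sigma_V)
}

#' Characterize a firing response over a fluctuation domain
#'
#' The four measures of a cell's biophysical specificity: the excitability
#' (mean effective threshold over the domain D, lower = more excitable)
#' and the mean sensitivities of the output rate to `mu_V`, `sigma_V` and
#' the normalized `tau_VN`. Sensitivities are estimated independently of
#' the excitability: the partial derivatives are averaged after the base
#' threshold is rescaled to a common reference level, so two cells
#' differing only in `V0` report identical sensitivities.
#'
#' @param params a `firing_response_params`.
#' @param domain list of ranges: `mu` (mV), `sigma` (mV), `tau` (tau_VN
#'   bounds); defaults to the range the stimulation protocols produce.
#' @param n_grid grid points per dimension.
#' @param tau_m0 resting membrane time constant (ms) used to map `tau_VN`
#'   back to `tau_V` in the rate prefactor.
#' @param V0_ref common reference threshold for the sensitivity estimates.
#' @return A list of class `response_characterization`: `excitability`
#'   (mV), `sens_mu` (Hz/mV), `sens_sigma` (Hz/mV), `sens_tau` (Hz per
#'   unit tau_VN).
#' @export
characterize_response <- function(params,
                                  domain = list(mu = c(-70, -50),
                                                sigma = c(1, 7),
                                                tau = c(0.1, 1)),
                                  n_grid = 8, tau_m0 = 32.3,
                                  V0_ref = -52) {
  if (any(vapply(domain, function(r) diff(range(r)) <= 0, logical(1))))
    stop("degenerate characterization domain")
  gr <- expand.grid(mu = seq(domain$mu[1], domain$mu[2], length.out = n_grid),
                    sigma = seq(domain$sigma[1], domain$sigma[2],
                                length.out = n_grid),
                    tau = seq(domain$tau[1], domain$tau[2],
                              length.out = n_grid))
  excit <- mean(.v_thre_eff(params, gr$mu, gr$sigma, gr$tau))
  pref <- params; pref$V0 <- V0_ref
  vth <- .v_thre_eff(pref, gr$mu, gr$sigma, gr$tau)
  u <- (gr$mu - vth) / gr$sigma
  tau_s <- gr$tau * tau_m0 * .ms
  phi <- stats::dnorm(u)
  nu <- stats::pnorm(u) / tau_s
  d_mu <- phi * (1 - pref$a_mu) / gr$sigma / tau_s
  d_sigma <- phi * (-pref$a_sigma - u) / gr$sigma / tau_s
  d_tau <- -nu / gr$tau + phi * (-pref$a_tau / gr$sigma) / tau_s
  structure(list(excitability = excit,
                 sens_mu = mean(d_mu), sens_sigma = mean(d_sigma),
                 sens_tau = mean(d_tau), domain = domain),
            class = "response_characterization")
}

#' Composed cellular transfer function
#'
#' `F = F_nu o F_D`: the analytic dendritic-integration step mapping a
#' presynaptic state to somatic fluctuations, composed with the cell's
#' firing-response function.
#'
#' @param tree,passive,syn the cellular model.
#' @param params a `firing_response_params`.
#' @return A function of a `presynaptic_state` returning nu_out (Hz).
#' @export
transfer_function <- function(tree, passive, syn, params) {
  function(state)
    firing_rate(params, fluctuation_stats(state, tree, passive, syn))
}

#' Synthesize a heterogeneous population of firing responses
#'
#' Stand-in for an in vitro characterized population: excitabilities (base
#' thresholds) are drawn from a normal distribution, the sensitivity
#' coefficients independently and uniformly within configured ranges, and
#' each cell is paired with a somatic input resistance drawn log-uniformly
#' over the configured span (which then sets its morphology through the
#' size map).
#'
#' @param n number of cells.
#' @param seed integer seed (reproducibility contract: same seed, same
#'   population).
#' @param config list of ranges: `V0_mean`, `V0_sd` (mV), `a_mu`,
#'   `a_sigma` (dimensionless ranges), `a_tau` (mV per unit tau_VN range),
#'   `R_in` (MOhm range for the log-uniform input-resistance draw).
#' @return A list of `firing_response_params`, each with an `R_in`
#'   attribute (MOhm).
#' @export
synthesize_population <- function(n = 30, seed = 1,
                                  config = list(V0_mean = -48, V0_sd = 4,
                                                a_mu = c(0, 0.5),
                                                a_sigma = c(-0.5, 0.5),
                                                a_tau = c(-4, 4),
                                                R_in = c(280, 850))) {
  set.seed(seed)
  V0 <- stats::rnorm(n, config$V0_mean, config$V0_sd)
  a_mu <- stats::runif(n, config$a_mu[1], config$a_mu[2])
  a_sigma <- stats::runif(n, config$a_sigma[1], config$a_sigma[2])
  a_tau <- stats::runif(n, config$a_tau[1], config$a_tau[2])
  R_in <- exp(stats::runif(n, log(config$R_in[1]), log(config$R_in[2])))
  lapply(seq_len(n), function(k) {
    p <- firing_response_params(V0 = V0[k], a_mu = a_mu[k],
                                a_sigma = a_sigma[k], a_tau = a_tau[k],
                                id = k)
    attr(p, "R_in") <- R_in[k]
    p
  })
}

#' Population couplings to the stimulation protocols
#'
#' For every cell: its morphology from the input-resistance/size map, its
#' quantals rescaled for constant somatic efficacy, the four protocols
#' re-balanced on its own model, the baseline response `nu_bsl` and the
#' mean response change `delta_nu` per protocol (mean over the scanned
#' range). Cells whose baseline response falls outside
#' `[exclude_below, exclude_above]` Hz -- the output range over which the
#' firing-response characterizations are valid and the cell remains in the
#' fluctuation-driven regime -- are flagged and excluded from the
#' correlation summaries. Pearson
#' correlations relate the log10 responses (the proximal one as the ratio
#' `delta_nu_prox / nu_bsl`, linear scale, since it can be negative) to
#' the four characterization measures.
#'
#' @param population from [synthesize_population()].
#' @param tree,passive,syn reference (medium) model components.
#' @param n_steps protocol resolution per cell.
#' @param exclude_below,exclude_above baseline-rate exclusion bounds (Hz).
#' @return A list of class `population_couplings`: `per_cell` data.frame,
#'   `correlations` data.frame (protocol x measure: Pearson r and p), and
#'   `excluded` (cell ids).
#' @export
population_couplings <- function(population, tree = build_tree(),
                                 passive = passive_params(),
                                 syn = synaptic_params(), n_steps = 4,
                                 exclude_below = 1e-2, exclude_above = 10) {
  if (length(population) < 2)
    stop("population couplings need at least two cells")
  R_ref <- input_resistance(tree, passive)
  per <- lapply(population, function(p) {
    R_in <- attr(p, "R_in")
    tr_k <- size_comodulation(resistance_to_size(R_in, passive, tree), tree)
    syn_k <- rescale_quantals(syn, R_in, R_ref)
    char <- characterize_response(p)
    tabs <- list(
      ubl = run_protocol(unbalanced_protocol(n_steps, tr_k, passive, syn_k),
                         tr_k, passive, syn_k),
      prox = run_protocol(proximal_protocol(n_steps, tr_k, passive, syn_k),
                          tr_k, passive, syn_k),
      dist = run_protocol(distal_protocol(n_steps, tr_k, passive, syn_k),
                          tr_k, passive, syn_k),
      synch = run_protocol(synchrony_protocol(n_steps, tr_k, passive, syn_k),
                           tr_k, passive, syn_k))
    tau_m0 <- passive$Cm * .uF_cm2 / (passive$GL * .uS_cm2) / .ms
    nu_of <- function(row)
      firing_rate(p, list(mu_V = row$mu_V, sigma_V = row$sigma_V,
                          tau_V = row$tau_V, tau_m0 = tau_m0))
    nu_tab <- lapply(tabs, function(tb)
      vapply(seq_len(nrow(tb)), function(i) nu_of(tb[i, ]), numeric(1)))
    nu_bsl <- nu_tab$ubl[1]
    data.frame(id = p$id, R_in = R_in, nu_bsl = nu_bsl,
               dnu_ubl = mean(nu_tab$ubl[-1]) - nu_bsl,
               dnu_prox = mean(nu_tab$prox[-1]) - nu_bsl,
               dnu_dist = mean(nu_tab$dist[-1]) - nu_bsl,
               dnu_synch = mean(nu_tab$synch[-1]) - nu_bsl,
               excitability = char$excitability, sens_mu = char$sens_mu,
               sens_sigma = char$sens_sigma, sens_tau = char$sens_tau)
  })
  per <- do.call(rbind, per)
  excluded <- per$id[per$nu_bsl < exclude_below |
                       per$nu_bsl > exclude_above]
  keep <- per[!(per$id %in% excluded), ]
  if (nrow(keep) < 3)
    stop("all (or nearly all) cells excluded: population too weakly excitable")
  measures <- c("excitability", "sens_mu", "sens_sigma", "sens_tau")
  resp <- list(bsl = log10(keep$nu_bsl),
               ubl = log10(pmax(keep$dnu_ubl, 1e-12)),
               prox = keep$dnu_prox / keep$nu_bsl,
               dist = log10(pmax(keep$dnu_dist, 1e-12)),
               synch = log10(pmax(keep$dnu_synch, 1e-12)))
  cors <- do.call(rbind, lapply(names(resp), function(rn)
    do.call(rbind, lapply(measures, function(m) {
      ct <- stats::cor.test(resp[[rn]], keep[[m]])
      data.frame(response = rn, measure = m, r = unname(ct$estimate),
                 p = ct$p.value)
    }))))
  structure(list(per_cell = per, correlations = cors, excluded = excluded),
            class = "population_couplings")
}
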