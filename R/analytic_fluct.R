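# The analytic estimator: presynaptic state -> somatic fluctuation
# statistics (mu_V, sigma_V, tau_V) and input-conductance ratio.
#
# Five steps: (1) activity-dependent reduction of the tree to a piecewise
# equivalent cable whose membrane carries the mean synaptic conductances;
# (2) stationary mean profile mu_V(x) under those mean conductances;
# (3) linearization around mu_V(x) with frozen driving force, so a synaptic
# event becomes a current transient Q e^(-t/tau) (E_rev - mu_V(x));
# (4) the somatic effect of one event at distance x in a branch of
# generation b is 1/2^(b-1) of the response to 2^(b-1) synchronous image
# events, i.e. exactly the reduced-cable transfer impedance applied to the
# single-event current; (5) shotnoise (Campbell) synthesis of the membrane
# potential power spectral density, with the synchrony entering through the
# multiplicity moments E[m], E[m^2].

#' Activity-dependent reduction to the equivalent cable
#'
#' Collapses the symmetric arborescence onto its equivalent piecewise
#' cable, with the membrane conductance of each domain augmented by the
#' mean synaptic conductance densities of `state` (the high-conductance
#' correction). With `state = NULL` this is the classical resting
#' reduction and the cable's input resistance equals the full model's.
#'
#' @param tree a `tree_morphology`.
#' @param passive a `passive_params`.
#' @param syn a `synaptic_params` (may be NULL with `state = NULL`).
#' @param state a `presynaptic_state`, or NULL for rest.
#' @return An object of class `equivalent_cylinder`: the segment table
#'   (`segments`, with effective space constants `lambda` in um and
#'   effective membrane times `tau_eff` in ms), per-domain electrotonic
#'   lengths `L_prox`, `L_dist`, and the lumped somatic load `soma`
#'   (RM MOhm, CM nF, mean somatic inhibition Gi nS).
#' @export
reduce_to_cylinder <- function(tree, passive, syn = NULL, state = NULL) {
  cab <- .cable_segments(tree, passive, syn, state)
  el <- cab$segs$len / cab$segs$lambda
  segments <- data.frame(
    x0 = cab$segs$x0 / .um, x1 = cab$segs$x1 / .um,
    generation = cab$segs$b, domain = ifelse(cab$segs$distal, "distal",
                                             "proximal"),
    lambda = cab$segs$lambda / .um, tau_eff = cab$segs$tau_eff / .ms,
    electrotonic = el)
  structure(list(
    segments = segments,
    L_prox = sum(el[!cab$segs$distal]),
    L_dist = sum(el[cab$segs$distal]),
    soma = list(RM = 1 / cab$soma$GL / 1e6, CM = cab$soma$C * 1e9,
                Gi = cab$soma$GI / .nS),
    cab = cab), class = "equivalent_cylinder")
}

#' Stationary mean membrane-potential profile
#'
#' Solves the stationary piecewise cable equation with uniform per-domain
#' mean conductances, lumped-soma boundary at `x = 0` and sealed distal
#' ends. With any synaptic input present the profile lies strictly between
#' the inhibitory and excitatory reversals; with none it is flat at `EL`.
#'
#' @inheritParams reduce_to_cylinder
#' @param n_points number of output grid points along `[0, lt]`.
#' @return A list: `x` (um), `mu` (mV), `mu_soma` (mV) and `fun` (a
#'   function of x in um returning mV).
#' @export
stationary_mean_profile <- function(state, tree, passive, syn,
                                    n_points = 101) {
  cab <- .cable_segments(tree, passive, syn, state)
  sp <- .stationary_profile(cab)
  x <- seq(0, tree$lt, length.out = n_points)
  list(x = x, mu = sp$mu(x * .um) / .mV, mu_soma = sp$mu_soma / .mV,
       fun = function(x_um) sp$mu(x_um * .um) / .mV)
}

# single-event synaptic current spectrum: FT of Q e^(-t/tau) H(t) (E - mu)
.event_current_ft <- function(Q_S, tau_s, drive_V, omega) {
  Q_S * drive_V * tau_s / (1 + 1i * omega * tau_s)
}

#' Somatic kernel of a single synaptic event
#'
#' The voltage transient at the soma caused by one synaptic conductance
#' event at path distance `x`, under the frozen-driving-force
#' linearization: the event current `Q e^(-t/tau) (E_rev - mu_V(x))` is
#' propagated through the activity-dependent equivalent cable via its
#' transfer impedance (the synchronous-image construction across the
#' `2^(b-1)` branches of generation b is exact on the reduced cable).
#' `x = 0` with `syn_type = "i"` gives the somatic-synapse kernel.
#'
#' @param cylinder an `equivalent_cylinder` built with the same `state`.
#' @param x path distance of the synapse from the soma (um).
#' @param syn_type `"e"` or `"i"`.
#' @param f frequency grid (Hz) on which the Fourier transform is returned.
#' @return An object of class `psp_kernel` with `x`, `generation`,
#'   `syn_type`, `f`, `ft` (complex, mV/Hz i.e. mV.s), `drive` (mV) and a
#'   closure `time_course(t_ms)` evaluating the kernel in mV.
#' @export
psp_kernel <- function(cylinder, x, syn_type = c("e", "i"),
                       f = .default_freqs()) {
  syn_type <- match.arg(syn_type)
  cab <- cylinder$cab
  if (is.null(cab$state))
    stop("psp_kernel needs a cylinder reduced under a presynaptic state")
  syn <- cab$syn
  if (x < 0 || x * .um > cab$lt + 1e-12)
    stop("synapse position outside [0, lt]")
  sp <- .stationary_profile(cab)
  omega <- 2 * pi * f
  ts <- .transfer_setup(cab, omega)
  somatic <- x <= 0
  if (somatic) {
    mu_x <- sp$mu_soma
    Q <- syn$QiS * .nS; tau <- syn$tau_i * .ms; Erev <- cab$Ei
    gen <- 0L
    if (syn_type == "e")
      stop("the soma carries inhibitory synapses only")
  } else {
    k <- min(max(findInterval(x * .um, cab$segs$x0, rightmost.closed = TRUE),
                 1), nrow(cab$segs))
    distal <- cab$segs$distal[k]
    gen <- cab$segs$b[k]
    mu_x <- sp$mu(x * .um)
    if (syn_type == "e") {
      Q <- (if (distal) syn$Qed else syn$Qep) * .nS
      tau <- syn$tau_e * .ms; Erev <- cab$Ee
    } else {
      Q <- (if (distal) syn$Qid else syn$Qip) * .nS
      tau <- syn$tau_i * .ms; Erev <- cab$Ei
    }
  }
  Zt <- .transfer_impedance(ts, if (somatic) 0 else x * .um)
  ft_V <- Zt * .event_current_ft(Q, tau, Erev - mu_x, omega)  # V.s
  kern <- structure(list(
    x = x, generation = gen, syn_type = syn_type, f = f,
    ft = ft_V / .mV, drive = (Erev - mu_x) / .mV,
    Q_nS = Q / .nS, tau_ms = tau / .ms), class = "psp_kernel")
  kern$time_course <- function(t_ms, f_max = 2000, n_f = 4000) {
    ff <- seq(0, f_max, length.out = n_f)
    Zt2 <- .transfer_impedance(.transfer_setup(cab, 2 * pi * ff),
                               if (somatic) 0 else x * .um)
    K <- Zt2 * .event_current_ft(Q, tau, Erev - mu_x, 2 * pi * ff)
    df <- ff[2] - ff[1]
    t_s <- t_ms * .ms
    # causal real kernel: v(t) = 2 Int_0^inf Re(K(f) e^{2 pi i f t}) df
    v <- vapply(t_s, function(tt)
      2 * sum(Re(K * exp(2i * pi * ff * tt))) * df, numeric(1))
    v / .mV
  }
  kern
}

.default_freqs <- function(n = 241)
  c(0, 10^seq(-2, 4, length.out = n - 1))

# shotnoise PSD of the somatic voltage (two-sided, V^2/Hz) on a frequency
# grid, plus the pieces needed downstream
.psd_soma <- function(cab, f, nodes_per_seg = 16) {
  omega <- 2 * pi * f
  sp <- .stationary_profile(cab)
  ts <- .transfer_setup(cab, omega)
  syn <- cab$syn; state <- cab$state
  mm <- multiplicity_moments(state$s)
  rate_fac <- mm$Em2 / mm$Em     # generator rate x E[m^2] = nu * Em2/Em
  psd <- rep(0, length(f))
  De <- syn$De_tree * .per_100um2
  Di <- syn$Di_tree * .per_100um2
  for (k in seq_len(nrow(cab$segs))) {
    s <- cab$segs[k, ]
    gl <- pracma::gaussLegendre(nodes_per_seg, s$x0, s$x1)
    perim <- s$n * pi * s$d                       # aggregated perimeter, m
    if (s$distal) {
      nu_e <- state$nu_ed; nu_i <- state$nu_id
      Qe <- syn$Qed * .nS; Qi <- syn$Qid * .nS
    } else {
      nu_e <- state$nu_ep; nu_i <- state$nu_ip
      Qe <- syn$Qep * .nS; Qi <- syn$Qip * .nS
    }
    for (j in seq_len(nodes_per_seg)) {
      x <- gl$x[j]; w <- gl$w[j]
      Zt2 <- Mod(.transfer_impedance(ts, x))^2
      mu_x <- sp$mu(x)
      Ie2 <- Mod(.event_current_ft(Qe, syn$tau_e * .ms, cab$Ee - mu_x,
                                   omega))^2
      Ii2 <- Mod(.event_current_ft(Qi, syn$tau_i * .ms, cab$Ei - mu_x,
                                   omega))^2
      psd <- psd + w * perim * rate_fac * Zt2 *
        (De * nu_e * Ie2 + Di * nu_i * Ii2)
    }
  }
  # somatic inhibitory population at x = 0
  if (cab$soma$Ni > 0 && state$nu_ip > 0) {
    Ii2 <- Mod(.event_current_ft(syn$QiS * .nS, syn$tau_i * .ms,
                                 cab$Ei - sp$mu_soma, omega))^2
    psd <- psd + cab$soma$Ni * state$nu_ip * rate_fac * Mod(ts$Zin)^2 * Ii2
  }
  list(f = f, psd = psd, mu_soma = sp$mu_soma)
}

# integrate a two-sided PSD: sigma^2 = 2 Int_0^fmax + analytic f^-4 tail
.integrate_psd <- function(f, psd) {
  var_grid <- 2 * pracma::trapz(f, psd)
  fmax <- f[length(f)]
  var_tail <- 2 * psd[length(psd)] * fmax / 3
  var_grid + var_tail
}

#' Somatic input-conductance ratio
#'
#' Ratio of the DC somatic input conductance under the mean synaptic
#' bombardment of `state` (dendritic load included, as measured in
#' intracellular studies) to its resting value. Equals 1 for zero input
#' and grows with the total synaptic conductance.
#'
#' @inheritParams stationary_mean_profile
#' @return Dimensionless ratio (scalar >= 1).
#' @export
conductance_ratio <- function(state, tree, passive, syn) {
  G_rest <- 1 / Re(model_input_impedance(tree, passive, 0))
  G_load <- 1 / Re(model_input_impedance(tree, passive, 0, syn, state))
  G_load / G_rest
}

#' Analytic somatic fluctuation statistics
#'
#' The full estimator: mean `mu_V` from the stationary profile, variance
#' from the shotnoise power spectral density of all synaptic populations
#' (positions integrated with Gauss-Legendre quadrature, synchrony entering
#' through the multiplicity moments), and the global autocorrelation time
#' `tau_V = PSD(0) / (2 sigma_V^2)`. Deterministic: no sampling anywhere.
#'
#' @inheritParams stationary_mean_profile
#' @param f frequency grid (Hz) for the PSD; defaults to 240 log-spaced
#'   points over `[1e-2, 1e4]` plus DC, with an analytic `f^-4` tail beyond.
#' @param nodes_per_seg Gauss-Legendre nodes per cable segment.
#' @param keep_psd if TRUE the PSD grid is attached to the result.
#' @return An object of class `fluctuation_stats`: `mu_V` (mV), `sigma_V`
#'   (mV), `tau_V` (ms), `g_ratio` (dimensionless), `tau_m0` (ms, resting
#'   membrane time constant `Cm/GL`, the normalization reference).
#' @examples
#' \donttest{
#' fluctuation_stats(baseline_state(), build_tree(), passive_params(),
#'                   synaptic_params())
#' }
#' @export
fluctuation_stats <- function(state, tree, passive, syn,
                              f = .default_freqs(), nodes_per_seg = 16,
                              keep_psd = FALSE) {
  stopifnot(inherits(state, "presynaptic_state"))
  cab <- .cable_segments(tree, passive, syn, state)
  no_input <- all(c(state$nu_ep, state$nu_ip, state$nu_ed, state$nu_id) == 0)
  if (no_input) {
    out <- list(mu_V = passive$EL, sigma_V = 0, tau_V = NA_real_,
                g_ratio = 1, tau_m0 = passive$Cm * .uF_cm2 /
                  (passive$GL * .uS_cm2) / .ms)
    if (keep_psd) out$psd <- data.frame(f = f, psd = 0 * f)
    return(structure(out, class = "fluctuation_stats"))
  }
  ps <- .psd_soma(cab, f, nodes_per_seg)
  sigma2 <- .integrate_psd(f, ps$psd)
  tau_V <- ps$psd[1] / (2 * sigma2)    # f[1] = 0
  out <- list(mu_V = ps$mu_soma / .mV,
              sigma_V = sqrt(sigma2) / .mV,
              tau_V = tau_V / .ms,
              g_ratio = conductance_ratio(state, tree, passive, syn),
              tau_m0 = passive$Cm * .uF_cm2 / (passive$GL * .uS_cm2) / .ms)
  if (keep_psd) out$psd <- data.frame(f = f, psd = ps$psd / .mV^2)
  structure(out, class = "fluctuation_stats")
}

#' @export
print.fluctuation_stats <- function(x, ...) {
  cat(sprintf(
    "somatic fluctuations: mu_V = %.2f mV, sigma_V = %.2f mV, tau_V = %.1f ms, g_tot/g_L = %.2f\n",
    x$mu_V, x$sigma_V, x$tau_V, x$g_ratio))
  invisible(x)
}
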