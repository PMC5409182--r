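# Parameter containers. User-facing units follow the conventions of the
# experimental literature (um, mV, nS, ms, Hz, uS/cm^2, Ohm.cm, uF/cm^2);
# the cable engine converts to SI once, in .cable_segments().

#' Passive membrane parameters
#'
#' Container for the passive electrical properties of the membrane and
#' cytoplasm. Defaults are the calibrated values for layer V pyramidal
#' cells, with the leak density chosen so that the resting membrane time
#' constant `Cm/GL` equals the ~32 ms measured in vitro and the resting
#' somatic input resistance falls in the observed few-hundred-megaohm range.
#'
#' @param GL leak conductance density (uS/cm^2), > 0.
#' @param Ri axial (intracellular) resistivity (Ohm.cm), > 0.
#' @param Cm specific membrane capacitance (uF/cm^2), > 0.
#' @param EL leak reversal potential (mV).
#' @return An object of class `passive_params`.
#' @examples
#' pas <- passive_params()
#' pas$Cm / pas$GL * 1e3 # resting membrane time constant, ms
#' @export
passive_params <- function(GL = 32.5, Ri = 30, Cm = 1.05, EL = -65) {
  stopifnot(is.numeric(GL), is.numeric(Ri), is.numeric(Cm), is.numeric(EL))
  if (GL <= 0 || Ri <= 0 || Cm <= 0)
    stop("passive parameters GL, Ri, Cm must all be positive")
  structure(list(GL = GL, Ri = Ri, Cm = Cm, EL = EL),
            class = "passive_params")
}

#' Synaptic parameters
#'
#' Reversal potentials, quantal conductances, decay times and areal synapse
#' densities for conductance-based AMPA-like (excitatory) and GABAa-like
#' (inhibitory) synapses. Distal quantals default to 1.5x the proximal ones,
#' reflecting the higher efficacy of distal synapses; the soma carries
#' inhibitory synapses only, with proximal-type properties.
#'
#' @param Ee,Ei excitatory / inhibitory reversal potentials (mV), `Ee > Ei`.
#' @param Qep,Qip proximal excitatory / inhibitory quantal conductances (nS).
#' @param Qed,Qid distal quantal conductances (nS).
#' @param QiS somatic inhibitory quantal conductance (nS).
#' @param tau_e,tau_i synaptic decay time constants (ms).
#' @param De_tree,Di_tree dendritic synapse densities (synapses per 100 um^2).
#' @param De_soma,Di_soma somatic synapse densities (synapses per 100 um^2).
#' @return An object of class `synaptic_params`.
#' @export
synaptic_params <- function(Ee = 0, Ei = -80,
                            Qep = 0.7, Qip = 1.0,
                            Qed = 1.05, Qid = 1.5,
                            QiS = 1.0,
                            tau_e = 5, tau_i = 5,
                            De_tree = 30, Di_tree = 6,
                            De_soma = 0, Di_soma = 20) {
  if (Ee <= Ei) stop("excitatory reversal must exceed inhibitory reversal")
  if (any(c(Qep, Qip, Qed, Qid, QiS) < 0))
    stop("quantal conductances must be non-negative")
  if (tau_e <= 0 || tau_i <= 0) stop("synaptic decay times must be positive")
  if (any(c(De_tree, Di_tree, De_soma, Di_soma) < 0))
    stop("synapse densities must be non-negative")
  if (De_soma != 0)
    warning("somatic excitatory synapses are not part of the standard model")
  structure(list(Ee = Ee, Ei = Ei, Qep = Qep, Qip = Qip, Qed = Qed,
                 Qid = Qid, QiS = QiS, tau_e = tau_e, tau_i = tau_i,
                 De_tree = De_tree, Di_tree = Di_tree,
                 De_soma = De_soma, Di_soma = Di_soma),
            class = "synaptic_params")
}

#' Presynaptic state: rates and synchrony
#'
#' The five input variables of the model: stationary per-synapse release
#' rates in the proximal and distal domains (excitatory and inhibitory),
#' plus a global synchrony degree `s` biasing the event generation towards
#' coincident events (pairs, triples, quadruples).
#'
#' @param nu_ep,nu_ip proximal excitatory / inhibitory rates (Hz).
#' @param nu_ed,nu_id distal excitatory / inhibitory rates (Hz).
#' @param s synchrony degree, in `[0, 1)`; values above 0.4 trigger a
#'   warning as the four-event truncation of the coincidence model becomes
#'   questionable there.
#' @return An object of class `presynaptic_state`.
#' @export
presynaptic_state <- function(nu_ep = 0.2, nu_ip = 1.2,
                              nu_ed = 0.2, nu_id = 1.2, s = 0.05) {
  rates <- c(nu_ep, nu_ip, nu_ed, nu_id)
  if (any(rates < 0)) stop("presynaptic rates must be non-negative")
  if (s < 0 || s >= 1) stop("synchrony s must lie in [0, 1)")
  if (s > 0.4)
    warning("synchrony s > 0.4: the four-event coincidence truncation is ",
            "only calibrated for s <= 0.4")
  structure(list(nu_ep = nu_ep, nu_ip = nu_ip, nu_ed = nu_ed,
                 nu_id = nu_id, s = s),
            class = "presynaptic_state")
}

#' Common baseline presynaptic configuration
#'
#' Sparse balanced proximal plus distal activity with a low degree of
#' synchrony: excitation at 0.2 Hz and inhibition at 1.2 Hz in both domains,
#' `s = 0.05`. All stimulation protocols start from this state.
#'
#' @return A `presynaptic_state`.
#' @export
baseline_state <- function() presynaptic_state()

#' @export
print.presynaptic_state <- function(x, ...) {
  cat(sprintf(
    "presynaptic state: nu_ep=%.3g nu_ip=%.3g nu_ed=%.3g nu_id=%.3g Hz, s=%.3g\n",
    x$nu_ep, x$nu_ip, x$nu_ed, x$nu_id, x$s))
  invisible(x)
}

# unit conversions to SI -----------------------------------------------------

.um <- 1e-6           # um -> m
.mV <- 1e-3           # mV -> V
.nS <- 1e-9           # nS -> S
.ms <- 1e-3           # ms -> s
.uS_cm2 <- 1e-2       # uS/cm^2 -> S/m^2
.uF_cm2 <- 1e-2       # uF/cm^2 -> F/m^2
.Ohm_cm <- 1e-2       # Ohm.cm -> Ohm.m
.per_100um2 <- 1e10   # synapses/(100 um^2) -> synapses/m^2
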