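# Presynaptic activity model: synchrony-biased compound Poisson event
# trains, their multiplicity algebra, mean conductance fields, and the
# per-cell quantal rescaling rule.

#' Multiplicity moments of the synchrony-biased event model
#'
#' For synchrony degree `s`, a generator event is duplicated into a
#' coincidence of multiplicity m with probabilities `1-s` (single), `s-s^2`
#' (double), `s^2-s^3` (triple) and `s^3` (quadruple). Hence
#' `E[m] = 1 + s + s^2 + s^3` and `E[m^2] = 1 + 3s + 5s^2 + 7s^3`. The
#' generator rate `nu / E[m]` conserves the total event rate at `nu`.
#'
#' @param s synchrony degree in `[0, 1)`.
#' @return A list with `Em`, `Em2` and the multiplicity probabilities
#'   `probs` (length 4).
#' @export
multiplicity_moments <- function(s) {
  stopifnot(s >= 0, s < 1)
  list(Em = 1 + s + s^2 + s^3,
       Em2 = 1 + 3 * s + 5 * s^2 + 7 * s^3,
       probs = c(1 - s, s - s^2, s^2 - s^3, s^3))
}

#' Generate a synchrony-biased compound Poisson event train
#'
#' A homogeneous Poisson backbone of rate `nu / (1 + s + s^2 + s^3)` is
#' drawn, and each backbone event is independently duplicated to
#' multiplicity 1-4 with probabilities `1-s`, `s-s^2`, `s^2-s^3`, `s^3`;
#' duplicates share the exact timestamp (coincidences carry multiplicity).
#' The expected total event rate equals `nu` for every `s`.
#'
#' @param nu stationary event rate (Hz).
#' @param s synchrony degree in `[0, 1)`.
#' @param T_ms train duration (ms).
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of event times (ms), sorted, duplicates allowed;
#'   class `event_train` with attribute `multiplicities` (per backbone
#'   event) and `T_ms`.
#' @export
synchrony_train <- function(nu, s, T_ms, seed = NULL) {
  stopifnot(nu >= 0, T_ms > 0)
  if (s < 0 || s >= 1) stop("synchrony s must lie in [0, 1)")
  if (s > 0.4)
    warning("synchrony s > 0.4 lies outside the calibrated range of the ",
            "four-event coincidence model")
  if (!is.null(seed)) set.seed(seed)
  mm <- multiplicity_moments(s)
  n_gen <- stats::rpois(1, nu / mm$Em * T_ms / 1000)
  if (n_gen == 0) {
    out <- numeric(0)
    attr(out, "multiplicities") <- integer(0)
  } else {
    t_gen <- sort(stats::runif(n_gen, 0, T_ms))
    m <- sample.int(4, n_gen, replace = TRUE, prob = mm$probs)
    out <- rep(t_gen, m)
    attr(out, "multiplicities") <- m
  }
  attr(out, "T_ms") <- T_ms
  class(out) <- "event_train"
  out
}

#' Mean synaptic conductance fields under a presynaptic state
#'
#' Campbell's theorem gives the stationary mean conductance of one synapse
#' as `nu * Q * tau` (independent of the synchrony, which conserves the
#' event rate). Multiplying by the areal synapse densities yields the mean
#' areal conductance densities, piecewise constant over the proximal and
#' distal domains; dividing the per-branch linear density by the local
#' perimeter recovers the same areal values on every generation.
#'
#' @param state a `presynaptic_state`.
#' @param tree a `tree_morphology`.
#' @param syn a `synaptic_params`.
#' @return A list with `areal` (data.frame: domain, ge, gi in uS/cm^2),
#'   `soma_Gi` (mean somatic inhibitory conductance, nS), and `linear`, a
#'   function of path position x (um) returning the aggregated linear
#'   densities ge and gi (nS/um, summed over the branches at x).
#' @export
mean_conductance_densities <- function(state, tree, syn) {
  stopifnot(inherits(state, "presynaptic_state"),
            inherits(tree, "tree_morphology"),
            inherits(syn, "synaptic_params"))
  d <- .mean_area_densities(state, syn)        # S/m^2
  cab <- .cable_segments(tree, passive_params(), syn, state)
  areal <- data.frame(
    domain = c("proximal", "distal"),
    ge = c(d$ge_p, d$ge_d) / .uS_cm2,
    gi = c(d$gi_p, d$gi_d) / .uS_cm2)
  linear <- function(x) {
    k <- pmin(pmax(findInterval(x * .um, cab$segs$x0,
                                rightmost.closed = TRUE), 1),
              nrow(cab$segs))
    perim <- cab$segs$n[k] * pi * cab$segs$d[k]          # m
    distal <- cab$segs$distal[k]
    ge <- ifelse(distal, d$ge_d, d$ge_p) * perim         # S/m
    gi <- ifelse(distal, d$gi_d, d$gi_p) * perim
    data.frame(x = x, ge = ge * 1e9 * 1e-6, gi = gi * 1e9 * 1e-6)  # nS/um
  }
  list(areal = areal, soma_Gi = cab$soma$GI / .nS, linear = linear)
}

#' Rescale quantal conductances by somatic input resistance
#'
#' Synaptic weights are scaled by `R_in_reference / R_in_cell`, so that the
#' product of quantal conductance and somatic input resistance -- the mean
#' synaptic efficacy seen at the soma -- is the same for all cell sizes.
#'
#' @param syn a `synaptic_params`.
#' @param R_in_cell the cell's somatic input resistance (MOhm).
#' @param R_in_reference the reference (medium-model) input resistance
#'   (MOhm).
#' @return A `synaptic_params` with all quantals multiplied by
#'   `R_in_reference / R_in_cell`.
#' @export
rescale_quantals <- function(syn, R_in_cell, R_in_reference) {
  stopifnot(R_in_cell > 0, R_in_reference > 0)
  k <- R_in_reference / R_in_cell
  syn$Qep <- syn$Qep * k; syn$Qip <- syn$Qip * k
  syn$Qed <- syn$Qed * k; syn$Qid <- syn$Qid * k
  syn$QiS <- syn$QiS * k
  syn
}

#' Export event trains as a two-column spike file
#'
#' @param trains a list of `event_train` objects (one per synapse).
#' @param path output path; columns `synapse_id`, `time_ms`.
#' @return `path`, invisibly.
#' @export
write_spike_file <- function(trains, path) {
  tab <- do.call(rbind, lapply(seq_along(trains), function(j)
    if (length(trains[[j]]))
      data.frame(synapse_id = j, time_ms = as.numeric(trains[[j]]))))
  if (is.null(tab)) tab <- data.frame(synapse_id = integer(0),
                                      time_ms = numeric(0))
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic per-synapse substream seed from a master seed (kept below
# 2^31 - 1); identical master seed => identical trains
.substream_seed <- function(master, j) {
  (as.numeric(master) * 48271 + j * 16807) %% 2147483647
}
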