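# Somatic input impedance of the soma + Rall-tree model, the single-
# compartment RC reference, the sine-protocol fit used on voltage traces,
# and the exhaustive 7-D grid fit of passive + morphology parameters.

#' Impedance of a single-compartment RC circuit
#'
#' `Z(f) = RM / (1 + 2i pi f RM CM)`. The modulus decays with a -1 log-log
#' slope at high frequency and the phase lag reaches pi/4 at the corner
#' frequency `1/(2 pi RM CM)`.
#'
#' @param RM membrane resistance (MOhm).
#' @param CM membrane capacitance (nF).
#' @param f frequency (Hz), vectorized.
#' @return Complex impedance (MOhm). The phase lag is `-Arg(Z)`.
#' @export
rc_impedance <- function(RM, CM, f) {
  stopifnot(RM > 0, CM > 0, all(f >= 0))
  RM / (1 + 2i * pi * f * (RM * CM * 1e-3))
}

#' Somatic input impedance of the full model
#'
#' Impedance of the lumped RC soma in parallel with the frequency-dependent
#' input admittance of the branched dendritic tree (sealed distal ends).
#' With a `state` supplied, the membrane carries the mean synaptic
#' conductance densities of that stimulation, which is how the model's
#' input conductance under bombardment is obtained; the default is the
#' resting (synapse-free) membrane.
#'
#' @param tree a `tree_morphology`.
#' @param passive a `passive_params`.
#' @param f frequencies (Hz), vectorized; `f = 0` gives the DC resistance.
#' @param syn optional `synaptic_params` (needed when `state` is given).
#' @param state optional `presynaptic_state` for mean-bombardment impedance.
#' @return Complex impedance (MOhm); phase lag is `-Arg(Z)`.
#' @export
model_input_impedance <- function(tree, passive, f, syn = NULL,
                                  state = NULL) {
  stopifnot(all(f >= 0))
  if (!is.null(state) && is.null(syn))
    stop("a synaptic_params is required when a presynaptic state is given")
  cab <- .cable_segments(tree, passive, syn, state)
  omega <- 2 * pi * f
  Z <- 1 / (.soma_admittance(cab, omega) + .tree_admittance(cab, omega))
  Z / 1e6
}

#' Resting somatic input resistance
#'
#' DC limit of [model_input_impedance()]: the reciprocal of the summed
#' somatic and dendritic input conductances at rest.
#'
#' @inheritParams model_input_impedance
#' @return Input resistance (MOhm).
#' @export
input_resistance <- function(tree, passive = passive_params()) {
  Re(model_input_impedance(tree, passive, 0))
}

#' Fit a sine response to a voltage trace
#'
#' Least-squares fit of `V(t) = EL + R I sin(2 pi f t - phi)` after
#' discarding the first `n_discard_periods` periods (transient removal).
#' Linear in `(EL, R cos phi, R sin phi)`, solved with `lm`.
#'
#' @param time time grid (ms).
#' @param voltage membrane potential (mV).
#' @param I current amplitude (nA).
#' @param f stimulation frequency (Hz).
#' @param n_discard_periods initial periods dropped before fitting.
#' @return A list of class `sine_fit`: `EL_est` (mV), `R_est` (MOhm),
#'   `phi_est` (radians, lag positive) and `residual` (mV RMS).
#' @export
fit_sine_response <- function(time, voltage, I, f, n_discard_periods = 3) {
  stopifnot(length(time) == length(voltage), I > 0, f > 0)
  t_s <- time * 1e-3
  keep <- t_s >= n_discard_periods / f
  if (sum(keep) < 16 || max(t_s) < (n_discard_periods + 1) / f)
    stop("trace must cover more than n_discard_periods + 1 periods")
  t_s <- t_s[keep]; v <- voltage[keep]
  S <- sin(2 * pi * f * t_s); C <- cos(2 * pi * f * t_s)
  fit <- stats::lm(v ~ S + C)
  a <- stats::coef(fit)[["S"]]; b <- stats::coef(fit)[["C"]]
  # a sin + b cos = R I sin(theta - phi) with a = R I cos(phi), b = -R I sin(phi)
  RI <- sqrt(a^2 + b^2)
  structure(list(EL_est = stats::coef(fit)[[1]],
                 R_est = RI / I,  # mV / nA = MOhm
                 phi_est = atan2(-b, a),
                 residual = sqrt(mean(stats::resid(fit)^2))),
            class = "sine_fit")
}

# rest-model impedance spectra over the full 5^7 parameter grid, vectorized
# across models (grouped by branch count so segment loops line up)
.grid_axes <- function() {
  list(B = c(2L, 3L, 4L, 5L, 6L),
       lS = seq(5, 20, length.out = 5),
       lt = seq(300, 800, length.out = 5),
       dt = seq(0.5, 4, length.out = 5),
       GL = seq(100, 1000, length.out = 5),
       Ri = seq(10, 90, length.out = 5),
       Cm = seq(0.8, 1.8, length.out = 5))
}

#' Precompute impedance spectra over the 7-D fitting grid
#'
#' Evaluates the analytic somatic input impedance of the resting model at
#' every point of the 7-dimensional parameter grid used for passive-property
#' fitting: branch count B in {2..6}, soma length [5,20] um, tree length
#' [300,800] um, root diameter [0.5,4] um, leak density [100,1000] uS/cm^2,
#' axial resistivity [10,90] Ohm.cm and specific capacitance
#' [0.8,1.8] uF/cm^2, five points per dimension (78,125 models). The result
#' can be reused across many [grid_fit_mean_model()] calls.
#'
#' @param f frequencies (Hz); default 40 log-spaced points in [0.1, 500].
#' @param dS fixed soma diameter (um).
#' @return A list of class `impedance_grid` with the parameter table
#'   (`params`), `modulus` (MOhm) and `phase` (radians) matrices, and `f`.
#' @export
impedance_grid <- function(f = 10^seq(log10(0.1), log10(500), length.out = 40),
                           dS = 15) {
  ax <- .grid_axes()
  params <- expand.grid(ax, KEEP.OUT.ATTRS = FALSE)
  nw <- length(f); omega <- 2 * pi * f
  modulus <- matrix(NA_real_, nrow(params), nw)
  phase <- matrix(NA_real_, nrow(params), nw)
  for (Bval in unique(params$B)) {
    idx <- which(params$B == Bval)
    p <- params[idx, ]
    nm <- length(idx)
    GL <- p$GL * .uS_cm2; Cm <- p$Cm * .uF_cm2; Ri <- p$Ri * .Ohm_cm
    lt <- p$lt * .um; dt <- p$dt * .um
    len <- lt / Bval
    Y <- matrix(0 + 0i, nm, nw)
    iw <- matrix(1i * omega, nm, nw, byrow = TRUE)
    for (b in Bval:1) {
      d <- 2^(-2 * (b - 1) / 3) * dt
      n <- 2^(b - 1)
      perim <- n * pi * d
      y <- perim * GL + iw * (perim * Cm)        # aggregated S/m
      ri <- 4 * Ri / (n * pi * d^2)
      gam <- sqrt(ri * y)
      Yc <- sqrt(y / ri)
      th <- tanh(gam * len)
      Y <- Yc * (Y + Yc * th) / (Yc + Y * th)
    }
    A_s <- pi * (dS * .um) * (p$lS * .um)
    Ys <- A_s * GL + iw * (A_s * Cm)
    Z <- 1 / (Y + Ys) / 1e6
    modulus[idx, ] <- Mod(Z)
    phase[idx, ] <- -Arg(Z)
  }
  structure(list(params = params, modulus = modulus, phase = phase,
                 f = f, dS = dS),
            class = "impedance_grid")
}

#' Fit passive properties and morphology to a mean impedance spectrum
#'
#' Exhaustive scan of the 7-D grid (see [impedance_grid()]): the returned
#' model is the grid point minimizing the residual against the supplied
#' mean spectrum. The default residual compares the *product* of modulus
#' (MOhm) and phase lag (rad) frequency by frequency; `residual =
#' "separate"` instead sums a relative-modulus and a phase residual.
#'
#' @param spectrum a list or data.frame with `f` (Hz), `modulus` (MOhm) and
#'   `phase` (radians, lag positive).
#' @param grid optionally a precomputed [impedance_grid()] on the same
#'   frequency grid; built on the fly otherwise.
#' @param residual `"product"` (default) or `"separate"`.
#' @return A list with `passive` (`passive_params`), `tree`
#'   (`tree_morphology`), `params` (the grid row), `residual` (value) and
#'   `index` (grid row number).
#' @export
grid_fit_mean_model <- function(spectrum, grid = NULL,
                                residual = c("product", "separate")) {
  residual <- match.arg(residual)
  if (is.null(spectrum$f) || length(spectrum$f) < 3 ||
      any(!is.finite(spectrum$modulus)) || any(spectrum$modulus <= 0))
    stop("degenerate spectrum: need f, positive modulus and phase")
  if (is.null(grid)) grid <- impedance_grid(f = spectrum$f)
  if (length(grid$f) != length(spectrum$f) ||
      max(abs(log(grid$f / spectrum$f))) > 1e-8)
    stop("spectrum frequency grid does not match the precomputed grid")
  if (residual == "product") {
    target <- spectrum$modulus * spectrum$phase
    res <- rowSums((grid$modulus * grid$phase -
                      matrix(target, nrow(grid$modulus), length(target),
                             byrow = TRUE))^2)
  } else {
    relmod <- (t(t(grid$modulus) / spectrum$modulus) - 1)^2
    dphi <- (t(t(grid$phase) - spectrum$phase))^2
    res <- rowSums(relmod) + rowSums(dphi)
  }
  i <- which.min(res)
  p <- grid$params[i, ]
  list(passive = passive_params(GL = p$GL, Ri = p$Ri, Cm = p$Cm),
       tree = build_tree(B = p$B, lt = p$lt, dt = p$dt, lS = p$lS,
                         dS = grid$dS),
       params = p, residual = res[i], index = i)
}

#' Read / write impedance spectra as delimited tables
#'
#' Three-column whitespace-delimited tables: `f_Hz`, `modulus_MOhm`,
#' `phase_rad`.
#'
#' @param spectrum list/data.frame with `f`, `modulus`, `phase`.
#' @param path file path.
#' @return `read_impedance_table` returns a data.frame with columns `f`,
#'   `modulus`, `phase`; `write_impedance_table` returns `path` invisibly.
#' @export
write_impedance_table <- function(spectrum, path) {
  tab <- data.frame(f_Hz = spectrum$f, modulus_MOhm = spectrum$modulus,
                    phase_rad = spectrum$phase)
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_impedance_table
#' @export
read_impedance_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  data.frame(f = tab[[1]], modulus = tab[[2]], phase = tab[[3]])
}
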