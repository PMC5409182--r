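---
title: "Somatic fluctuations from dendritic synaptic bombardment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic fluctuations from dendritic synaptic bombardment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrofluct)
```

## The model

`dendrofluct` treats a neocortical pyramidal neuron in the
*fluctuation-driven regime*: the somatic membrane potential hovers below
threshold and spikes are triggered by fluctuations, so the quantities that
matter for firing are the stationary mean $\mu_V$, standard deviation
$\sigma_V$ and global autocorrelation time $\tau_V$ of the somatic
potential. The cellular input-output function is split into two steps:

1. **Dendritic integration** $F_D$: five presynaptic variables — the
   per-synapse release rates $\nu_e^p, \nu_i^p$ (proximal) and
   $\nu_e^d, \nu_i^d$ (distal), plus a synchrony degree $s$ — are mapped
   analytically to $(\mu_V, \sigma_V, \tau_V)$ and to the somatic
   input-conductance ratio $g_{tot}^{soma}/g_L$.
2. **Spike generation** $F_\nu$: a parametric firing-response function
   converts $(\mu_V, \sigma_V, \tau_V)$ into an output rate. The composed
   transfer function is $F = F_\nu \circ F_D$.

The morphology is deliberately minimal: an isopotential cylindrical soma in
parallel with a symmetric dendritic arborescence of $B$ generations obeying
Rall's 3/2 rule ($2\,d_{b+1}^{3/2} = d_b^{3/2}$), all branches of a
generation sharing length $l_t/B$. By symmetry every electrical quantity
depends only on the path distance $x$ from the soma, so the whole tree
collapses exactly onto a piecewise cable (the activity-dependent equivalent
cylinder). The inner fraction $f_{prox} = 7/8$ of the path length is the
proximal domain; the last eighth is the distal domain, with distal quantal
conductances 1.5 times the proximal ones. Conductance-based AMPA/GABAa
synapses are spread at fixed areal densities (30 excitatory and 6
inhibitory per 100 µm² on the tree; 20 inhibitory per 100 µm² on the soma,
driven at the proximal inhibitory rate).

## Presynaptic synchrony

Each synapse receives an independent compound Poisson train: a backbone
Poisson process of rate $\nu/(1+s+s^2+s^3)$ whose events are duplicated to
multiplicity $m \in \{1,2,3,4\}$ with probabilities
$(1-s,\; s-s^2,\; s^2-s^3,\; s^3)$, duplicates landing at the identical
timestamp. The total event rate is exactly $\nu$ for every $s$, so the mean
conductances — and hence $\mu_V$, the conductance ratio and $\tau_V$ — are
unaffected by synchrony, while the variance picks up the factor
$E[m^2]/E[m]$ with $E[m] = 1+s+s^2+s^3$ and $E[m^2] = 1+3s+5s^2+7s^3$.
Multiplicities above four are truncated; the model is used for
$s \le 0.4$, where the quadruple probability stays at or below
$0.4^3 \approx 0.06$, and a warning is raised beyond.

## The analytic estimator

For a given presynaptic state the estimator proceeds in five steps:

1. **Reduction.** Campbell's theorem gives each synapse a mean conductance
   $\nu Q \tau_s$; multiplied by the areal densities this augments the leak
   uniformly within each domain, shortening the effective space constant
   $\lambda_{eff}$ and membrane time $\tau_{eff}$ (the high-conductance
   correction to the classical reduction).
2. **Stationary mean.** The piecewise cable equation with those uniform
   conductances, a lumped-RC somatic boundary (which also carries the mean
   somatic inhibition) and sealed distal ends is solved in closed form per
   segment ($v = v_0 + A\cosh + B\sinh$) with continuity of potential and
   axial current at the interfaces, yielding $\mu_V(x)$.
3. **Linearization.** The driving force of each synapse is frozen at
   $E_{rev} - \mu_V(x)$, so an event becomes the current transient
   $Q e^{-t/\tau_s}(E_{rev} - \mu_V(x))$ and the membrane dynamics around
   $\mu_V(x)$ are linear.
4. **Kernels.** The somatic effect of one event at distance $x$ in a
   branch of generation $b$ is taken as $1/2^{b-1}$ of the response to
   $2^{b-1}$ synchronous image events at $x$ in every branch of that
   generation. On the reduced cable this construction is exact, and the
   kernel is the reduced-cable transfer impedance $Z_T(x \to 0; f)$ applied
   to the single-event current (somatic synapses use the input impedance
   at $x = 0$). Transfer impedances are evaluated by two-port admittance
   propagation with the soma-ward attenuation product.
5. **Shotnoise synthesis.** The two-sided somatic voltage PSD is the sum
   over synaptic populations of
   $n(x)\,\tfrac{\nu}{E[m]} E[m^2]\, |K_x(f)|^2$ integrated over position;
   then $\sigma_V^2 = \int PSD\,df$ and
   $\tau_V = PSD(0) / (2\sigma_V^2)$.

### Definition of $\tau_V$ and its normalizations

$\tau_V$ is the *global* autocorrelation time, the integral of the
normalized autocorrelation function, computed exactly from the PSD as
$PSD(0)/(2\sigma_V^2)$ (for an Ornstein–Uhlenbeck process this returns its
time constant). The simulator measures the matching quantity by
integrating the empirical normalized ACF up to its first crossing of
$e^{-3}$, which truncates the noise-dominated tail. Two normalizations
appear downstream and are kept distinct on purpose: protocol tables report
$\tau_V$ relative to the protocol's own baseline value (so curves start at
100%), while the firing-response machinery uses
$\tau_V^N = \tau_V / \tau_{m0}$ with $\tau_{m0} = C_m/G_L$, the resting
membrane time constant (32.3 ms at the default parameters).

### Numerical choices

The PSD is evaluated on 240 log-spaced frequencies over
$[10^{-2}, 10^4]$ Hz plus DC, trapezoid-integrated, with an analytic
$f^{-4}$ tail correction beyond the grid (the kernels decay at least that
fast). Position integrals use 16-node Gauss–Legendre quadrature per cable
segment; doubling the nodes or the frequency resolution moves
$\sigma_V$ and $\tau_V$ by less than $10^{-3}$ relative (asserted in the
test suite). The stationary solve is a dense $2K \times 2K$ linear system
for $K \le 7$ segments. All internal arithmetic is SI; the user-facing
units are µm, mV, nS, ms, Hz, µS/cm², Ω·cm and µF/cm².

## Parameters and the leak-density calibration

| parameter | default | unit | role |
|---|---|---|---|
| $G_L$ | 32.5 | µS/cm² | leak density; sets $\tau_{m0} = 32.3$ ms |
| $R_i$ | 30 | Ω·cm | axial resistivity |
| $C_m$ | 1.05 | µF/cm² | specific capacitance |
| $E_L, E_e, E_i$ | −65, 0, −80 | mV | reversals |
| $Q_e^p, Q_i^p$ | 0.7, 1.0 | nS | proximal quantals (distal ×1.5) |
| $\tau_e = \tau_i$ | 5 | ms | synaptic decay |
| $B, l_t, d_t$ | 5, 550 µm, 2.25 µm | — | medium morphology |
| $l_S \times d_S$ | 5 × 15 | µm | soma cylinder |

The leak density deserves a comment, because the package's impedance-fit
grid spans $[100, 1000]$ µS/cm² while the model default is 32.5 µS/cm².
The default is the value consistent with the electrophysiology of juvenile
layer V pyramidal cells — a resting membrane time constant of ~32 ms and a
somatic input resistance of a few hundred MΩ — and it is the only decade
in which the model's documented operating points are attainable at all:
with a leak an order of magnitude larger, the sparse baseline rates
(excitation 0.2 Hz, inhibition 1.2 Hz per synapse) could never balance the
cell near −55 mV (the stationary potential would be confined within a few
mV of rest for *any* inhibition level), and the proximal stimulation
protocol could not multiply the somatic input conductance severalfold. At
the default, the printed baseline rates balance the proximal tree at
−55.8 mV locally and the analytic somatic mean sits at −56.8 mV, with an
input-conductance ratio of 2.7; the balance solver confirms that a −55 mV
somatic target is met at an inhibitory rate within 0.3 Hz of the printed
1.2 Hz. The grid-fit module keeps its published parameter ranges verbatim,
and its recovery experiments generate spectra from an on-grid model.

## Stimulation protocols

All protocols start from the common baseline
($\nu_e = 0.2$ Hz, $\nu_i = 1.2$ Hz in both domains, $s = 0.05$). The
balance solver scales a set of free inhibitory rates by a common factor,
found by 1-D root finding, until the analytic somatic mean hits the target
within 0.01 mV; the inhibition-to-mean map is monotone, so the solution is
unique.

- **Unbalanced:** excitation ramps linearly over $[0.05, 0.5]$ Hz in both
  domains while the balance target ramps from the baseline mean to 3 mV
  above it (the −55 → −52 mV window). The printed ramp restarts the
  excitation *below* its baseline value; this discontinuity is reproduced
  as printed, which is why the protocol's $\tau_V$ rises slightly between
  step 0 and step 1 before falling monotonically.
- **Proximal:** $\nu_e^p$ ramps to 1.7 Hz; proximal-dendritic and somatic
  inhibition (one common rate) re-balance the soma at each step.
- **Distal:** $\nu_e^d$ ramps to 0.7 Hz; distal inhibition re-balances.
- **Synchrony:** $s$ ramps from 0.05 to 0.4 at fixed rates.

When a ramp step's target is unreachable from below even with zero
inhibition — which can happen for small synthetic cells whose quantals are
rescaled down — the builders clamp that step at zero free inhibition and
flag it, rather than aborting the protocol.

## The compartmental simulator

The ground-truth simulator integrates the full branched tree explicitly:
$2^B - 1$ branches × `nseg` compartments plus the soma (931 compartments
at the defaults). Each compartment carries one lumped excitatory and one
lumped inhibitory synapse whose event rate is the (real-valued) synapse
count — compartment area × density — times the per-synapse rate, using
Poisson superposition; integer rounding is deliberately avoided because at
`nseg = 30` the expected inhibitory count per thin distal compartment is
below one-half and rounding would silently delete a large fraction of
dendritic inhibition. Conductances decay exponentially between events and
jump by the quantal at each event; each step solves the implicit
(backward-Euler) system with a Hines-ordered direct tree solve, which is
unconditionally stable. Event trains use one seeded substream per
compartment synapse, making runs bit-reproducible given the master seed.

Desk-scale defaults are $T = 2$ s, $dt = 0.05$ ms and 4 seeds — chosen so
the full analytic-versus-simulated sweep suite completes in about a minute
while keeping the seed-to-seed spread of $\sigma_V$ near 0.3 mV; the
spatial and temporal discretizations are separately verified to be
converged (halving $dt$ moves the measured moments by well under 1%, and a
single PSP moves by under 1% from `nseg` 30 to 60).

### Estimator accuracy

Against the simulator at the baseline configuration, the analytic mean is
accurate to about 0.6 mV and the analytic $\sigma_V$ *over*-estimates the
simulated one slightly (0.2–0.5 mV depending on the seed set). The frozen
driving force (step 3) is the dominant bias: it ignores the reduction of
the driving force during each event's own excursion, which inflates event
amplitudes. The image-event construction (step 4) is exact on the reduced
linear cable and contributes no bias of its own in this implementation.
Consequently the synchrony increment that reconciles the analytic with the
simulated amplitude is small and non-positive here, rather than a sizable
positive correction; the `synchrony_correction()` helper computes it by
Newton iteration in either direction and clamps at $s = 0$ when the
simulated amplitude lies below the analytic one at zero synchrony.

## Firing responses and synthetic populations

The default $F_\nu$ is a phenomenological-threshold template,
$$\nu_{out} = \frac{1}{2\tau_V}\,
\mathrm{erfc}\!\left(\frac{V_{thre}^{eff} - \mu_V}{\sqrt{2}\,\sigma_V}\right),
\qquad
V_{thre}^{eff} = V_0 + a_\mu(\mu_V - \mu_a) + a_\sigma(\sigma_V - \sigma_a)
+ a_\tau(\tau_V^N - \tau_a),$$
the family for which the four characterization measures — the excitability
$\langle V_{thre}^{eff}\rangle_D$ and the mean sensitivities to $\mu_V$,
$\sigma_V$ and $\tau_V^N$ over a domain $D$ — are meaningful. $D$ defaults
to $\mu_V \in [-70, -50]$ mV, $\sigma_V \in [1, 7]$ mV,
$\tau_V^N \in [0.1, 1]$, the range the protocols produce. Sensitivities
are computed from the closed-form partial derivatives with the base
threshold rescaled to a common reference, so they are independent of the
excitability by construction (two cells differing only in $V_0$ report
identical sensitivities); the finite-difference agreement is asserted in
the tests. Any other parametric $F_\nu$ can be substituted.

Since the in vitro population behind the original characterizations is not
deposited, `synthesize_population()` emulates it: base thresholds
$V_0 \sim \mathcal{N}(-48, 4^2)$ mV (normally distributed excitabilities),
sensitivity coefficients drawn independently and uniformly
($a_\mu \in [0, 0.5]$, $a_\sigma \in [-0.5, 0.5]$,
$a_\tau \in [-4, 4]$ mV per unit $\tau_V^N$, spanning both signs as
observed for the speed sensitivity), and input resistances log-uniform on
$[280, 850]$ MΩ, which the size map converts to morphologies (sizes
co-modulate $l_t, d_t, l_S$ over a factor range $[0.5, 2]$, spanning
roughly an order of magnitude in input resistance) with quantals rescaled
so that quantal × input resistance is cell-invariant. Cells whose baseline
output falls outside $[10^{-2}, 10]$ Hz are excluded from coupling
summaries: below, the response is unmeasurable; above, the cell is
suprathreshold and out of the fluctuation-driven regime (where the sign of
the amplitude coupling inverts).

**What the generator does and does not emulate.** It reproduces normally
distributed excitabilities, independent sensitivities, and the observed
input-resistance span. It does not reproduce per-cell covariances between
those quantities, real morphological asymmetry, active dendritic
conductances, or shared synchrony across synapses — so a passing
population test demonstrates that the *mechanism* (excitability governs
baseline/unbalanced/distal/synchrony couplings; the speed sensitivity
governs the proximal coupling and its sign) emerges under the stated
heterogeneity structure, not that real cortical populations have these
exact coupling magnitudes.

## Problem sizes used by the checks

The packaged validations run at desk scale by design: simulator
experiments use $T = 2$ s × 4 seeds at $dt = 0.05$ ms and `nseg = 30`;
sweep suites use three points per variable; population analyses use
$n = 30$ cells with 4-step protocol ramps; the impedance fit evaluates the
full $5^7$ grid (78,125 spectra, a few seconds when vectorized by branch
count). All of these are function arguments and can be scaled up.

## Known limitations

- Symmetric Rall branching only; real pyramidal morphologies (distinct
  apical trunk, basal tuft, rule deviations) change high-frequency
  impedance and phase behaviour, which the size-comodulation map only
  partially captures.
- Passive dendrites: NMDA, Ca²⁺ and Na⁺ dendritic nonlinearities are out
  of scope; they would depolarize and slow the fluctuations and raise all
  couplings.
- The frozen-driving-force linearization biases $\sigma_V$ upward by a few
  tenths of a mV at baseline-like conductance loads, and grows with event
  amplitude.
- Synchrony is per-synapse; correlations *across* synapses (shared
  presynaptic sources) are not modelled, and multiplicities are truncated
  at four.
- Stationary inputs only: the estimator describes the stationary
  fluctuation statistics, not transients or rate dynamics.
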