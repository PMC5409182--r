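# dendrofluct

Analytic dendritic integration in the fluctuation-driven regime.

Neocortical pyramidal neurons in vivo sit below spike threshold and fire
on membrane-potential *fluctuations*. What matters for their output is
then not the raw synaptic drive but three somatic statistics: the
stationary mean μV, the amplitude σV and the autocorrelation time τV of
the membrane potential. `dendrofluct` is for computational
neuroscientists who want those statistics — and the firing rates they
imply — *in closed form* for a neuron with a real dendritic extent,
instead of hours of compartmental simulation per parameter point.

The cellular model is a lumped RC soma in parallel with a symmetric
dendritic arborescence obeying Rall's 3/2 branching rule
(2·d³ᐟ²₍b₊₁₎ = d³ᐟ²₍b₎), carrying conductance-based synapses at fixed
areal densities and split into a proximal domain (inner 7/8 of the path
length) and a distal domain (last eighth, with 1.5× quantals). The drive
has five variables: per-synapse release rates νₑᵖ, νᵢᵖ, νₑᵈ, νᵢᵈ and a
synchrony degree s that turns each Poisson train into a compound train
with coincident doublets/triplets/quadruplets (probabilities s−s²,
s²−s³, s³) while conserving the event rate.

The core estimator runs in five steps: activity-dependent reduction of
the tree to its equivalent cable (mean synaptic conductances from
Campbell's theorem, ⟨g⟩ = νQτ, folded into the membrane); closed-form
stationary profile μV(x) with a lumped-soma boundary and sealed ends;
frozen-driving-force linearization; transfer-impedance kernels for
single events (the 1/2ᵇ⁻¹ image construction, exact on the reduced
cable); and shotnoise synthesis of the voltage power spectrum, giving

    σV² = ∫ PSD(f) df,   τV = PSD(0) / (2 σV²),

with synchrony entering through E[m²]/E[m]. Around it the package
provides the somatic input-impedance model and its 5⁷-point passive-fit
grid, an input-resistance → morphology-size map, balanced stimulation
protocols (unbalanced, proximal, distal, synchrony), a ground-truth
implicit compartmental simulator of the full branched tree (Rcpp, Hines
solve), and phenomenological-threshold firing-response functions with
population-coupling analyses on synthetic heterogeneous populations.

## Worked example

```r
library(dendrofluct)

tree <- build_tree()        # medium model: B = 5, lt = 550 um, dt = 2.25 um
pas  <- passive_params()    # GL = 32.5 uS/cm2, Ri = 30 Ohm.cm, Cm = 1.05 uF/cm2
syn  <- synaptic_params()

input_resistance(tree, pas)
#> [1] 477.7                 # MOhm at rest

synapse_counts(tree, syn)$ratio
#> [1] 4.46                  # ~1952 excitatory vs ~437 inhibitory synapses

fluctuation_stats(baseline_state(), tree, pas, syn)
#> somatic fluctuations: mu_V = -56.84 mV, sigma_V = 4.72 mV,
#>                       tau_V = 15.7 ms, g_tot/g_L = 2.74
```

The baseline state (0.2 Hz excitation, 1.2 Hz inhibition per synapse,
s = 0.05) balances the cell a few mV above rest with ~4.7 mV
fluctuations. Ramping only the synchrony leaves the mean, speed and
conductance untouched and scales the amplitude near-linearly:

```r
run_protocol(synchrony_protocol(5), tree, pas, syn)[, c("s", "sigma_V")]
#>      s sigma_V
#> 1 0.05   4.716
#> 2 0.12   5.057
#> 3 0.19   5.418
#> 4 0.26   5.790
#> 5 0.33   6.165
#> 6 0.40   6.536
```

Composing with a firing-response function gives the cell's full
input-output map:

```r
cell_F <- firing_response_params(V0 = -50, a_tau = -2)
firing_rate(cell_F, fluctuation_stats(baseline_state(), tree, pas, syn))
#> [1] 4.625                 # Hz
```

A thin command-line wrapper over the same functions lives in
`inst/cli/fluct.R` (`eval`, `protocol`, `simulate`, `population`,
`fit-impedance` subcommands, JSON/CSV in and out).

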