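# pmcasyn

Quantitative tools for studying how monomeric alpha-synuclein (aSN)
activates the plasma membrane Ca²⁺-ATPase (PMCA), and what that activation
does to calcium levels in a presynaptic terminal.

aSN is the intrinsically disordered protein central to Parkinson disease;
PMCA is the high-affinity pump that extrudes cytosolic Ca²⁺. In acidic
lipid environments, monomeric aSN both raises PMCA's maximal turnover and
sharpens its apparent Ca²⁺ affinity. `pmcasyn` packages the quantitative
workflow around that biology for enzymologists and modellers:

- **Enzymology fits.** Hill-equation fits to Ca²⁺-titration ATPase curves,
  `v = Vmax·C^n/(K_d^n + C^n)`, and fits of the non-essential-activation
  (general modifier) model to aSN titrations. At fixed substrate the
  modifier mechanism reduces to the two-parameter hyperbola
  `FA(A) = (1 + β·A/K_½)/(1 + A/K_½)`, with `FA(0) = 1` structurally and
  saturation at the maximal fold activation β.
- **Free-calcium chemistry.** A Maxchelator-style solver for the coupled
  Ca/Mg/EGTA/ATP equilibria, forward (composition → free Ca²⁺) and inverse
  (target free Ca²⁺ → CaCl₂ to add), with a user-replaceable table of
  apparent association constants.
- **Presynaptic simulation.** A Hodgkin–Huxley membrane model coupled to a
  cytosolic Ca²⁺ balance: VGCC influx, a constant leak, NCX efflux
  (Michaelis form), and PMCA efflux whose Vmax is multiplied by `FA(aSN)`
  and whose apparent K_d shifts from its basal (0.56 µM) to its
  aSN-saturated (0.082 µM) value with activator occupancy. The pump/leak
  balance is calibrated in closed form so the resting steady state moves
  from 0.25 µM Ca²⁺ without aSN to 0.1 µM at saturating aSN.
- **Transient metrics.** Peak height, half-maximum pre-/post-peak widths,
  centered moving-average maximum over spike trains, and trapezoidal AUC
  of indicator traces.
- **Splicing analysis.** Mean exon percent-spliced-in (PSI) per
  gene-expression interval across tissues (VastDB-style tables), with a
  Spearman trend summary.
- **Synthetic data.** Seeded generators for every input type, so the whole
  pipeline is testable without any external data.

## Worked example

```r
library(pmcasyn)

## fit a noisy synthetic Ca2+ titration (generating Kd = 0.56 uM)
curve <- gen_hill_curve(hill_curve_spec(vmax = 5, kd = 0.56, n = 1.5,
                                        noise_sd = 0.05, replicates = 3,
                                        seed = 42))
fit_hill(curve)
#> Hill fit (converged)
#>   vmax   = 5.13937
#>   Kd_app = 0.606752 uM
#>   n      = 1.1369
#>   SE: vmax=0.216, kd=0.0787, n=0.124
#>   SSR = 1.74389

## presynaptic model: resting Ca2+ with and without aSN
params <- model_parameters()
steady_state_ca(params, 0)    #> 0.25 uM
steady_state_ca(params, 50)   #> 0.1070461 uM

## a single action potential and its Ca2+ transient at 5 uM aSN
sim <- simulate_presynapse(params, stimulus_protocol("single_pulse"),
                           asn_conc = 5)
peak_metrics(sim)
#> Ca transient: baseline 0.1499, peak 2.8 at t = 25.8
#>   pre-peak width 2.308, post-peak width 7.317

## 20 Hz / 400 ms spike train: cumulative Ca2+ load
train <- simulate_presynapse(params, stimulus_protocol("spike_train"),
                             asn_conc = 5)
count_action_potentials(train)   #> 8
moving_average_max(train, 50)    #> 0.716749 uM
```

The fitted `Kd_app` recovers the generating 0.56 µM within its reported
standard error despite 5 % noise. The steady states show the aSN effect:
more pump activity means lower resting Ca²⁺. Times are ms, concentrations
µM; the transient's post-peak width (clearance time) shrinks as aSN rises.

A command-line wrapper over the same functions is installed at
`inst/cli/pmcasyn.R` (subcommands `fit-hill`, `fit-activation`, `freeca`,
`freeca-invert`, `simulate`, `dose-response`, `metrics`, `auc`, `psi-bin`,
`synth`); every run that writes an output also writes a provenance JSON.

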