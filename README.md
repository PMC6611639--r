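# qscrosstalk

Quorum sensing (QS) lets bacteria switch on group behaviours once a secreted
signal molecule exceeds a threshold concentration. In communities of
*Bacillus subtilis* strains that produce chemically distinct variants of the
ComX peptide, the variants cross-react: a signal from one strain can
partially activate, or actively inhibit, the ComP receptor of another. Which
strains in a mixed community switch on their QS regulon then depends on the
whole mixture of signals, the ratios of strains, and even the timing of
signal perturbations.

`qscrosstalk` implements a predictive model of this situation for
researchers studying signal interference in microbial consortia. Crosstalk
is represented as a fully connected single-layer neural network: strain *i*
senses the clamped weighted sum of all signal concentrations,

```
C_eff,i = max(0, sum_j w_ij * c_j),        w_ii = 1,
```

which drives Hill-regulated expression of a LacZ reporter and of the signal
itself,

```
dL/dt  = rho_L * n_i * (f_i * H(C_eff,i) + 1) - gamma_L * L,
dc_i/dt = rho_c * n_i * (f_i * H(c_eff,i) + 1) - gamma_c * c_i,
H(c)   = c^m / (c^m + theta_i^m),
```

with logistic growth of every strain under a shared carrying capacity. A
strain's QS is called ON when its simulated LacZ fold change (signal vs. no
signal) meets its activation threshold, defined as the fold change at a
cognate concentration of exactly `theta_i`.

The package provides, as plain R functions over data frames and matrices:

* a forward finite-difference simulator of the coupled model (`qs_simulate`,
  Rcpp core);
* dose-response simulation and RMSE fitting of `(f, theta)` per strain
  (`simulate_dose_response`, `fit_dose_response`, `activation_threshold`);
* binary activation landscapes for signal pairs and their inversion into
  crosstalk-weight intervals (`simulate_landscape`, `extract_weight`);
* community-level binary state prediction and transition scans
  (`predict_state`, `transition_scan`);
* growing co-cultures with inoculation-ratio sweeps and timed signal
  perturbations (`simulate_coculture`, `supernatant_assay`, `ratio_sweep`,
  `perturbation_timing_scan`);
* a synthetic-data generator with known ground truth for every stage
  (`gen_dose_response`, `gen_landscape`, `gen_community_fixture`,
  `emulate_plate_reader`, `lacz_rate`).

`qs_strains()` ships the reference `(f, theta)` parameters of the five
ComX-variant tester strains A–E, and `qs_weights()` a curated example weight
matrix whose sign structure follows the measured five-strain network (see
the vignette for what is and is not claimed for it).

## Worked example

```r
library(qscrosstalk)
strains <- qs_strains()
W <- qs_weights()

# refit a noiseless synthetic dose-response curve for strain C
fit <- fit_dose_response(simulate_dose_response(qs_strains("C")), qs_strains("C"))
#> Dose-response fit (strain C): f = 24.84, theta = 1.364 nM
#>   RMSE = 3.04e-12, activation threshold (fold change) = 13.42

# community state for a five-signal supernatant mixture (volumes in uL)
predict_state(strains, W, signal_mixture(A = 10, B = 4, C = 15, D = 1, E = 0))
#> Community state [A,B,C,D,E]: (1,0,1,0,0)

# ramp signal E: the community passes through two state transitions
transition_scan(strains, W,
                signal_mixture(A = 10, B = 4, C = 15, D = 1, E = 0),
                varied = "E")
#> Community-state scan over E (2 transitions):
#>   volume_ul       state
#> 1         0 (1,0,1,0,0)
#> 2         5 (1,0,1,0,0)
#> 3        10 (1,0,1,0,0)
#> 4        15 (1,0,0,0,1)
#> 5        20 (1,0,0,0,1)
#> 6        25 (1,1,0,0,1)

# co-culture: strain B only activates QS at low A:B inoculation ratios
AB <- strains[strains$strain %in% c("A", "B"), ]
ratio_sweep(AB[1, ], AB[2, ], W[c("A", "B"), c("A", "B")],
            ratios = c(1, 2, 10, 100, 1000))
#> Inoculation-ratio sweep (normalized tester fold changes):
#>  ratio   A_fold    B_fold A_active B_active
#>      1 1.731529 1.5652425     TRUE     TRUE
#>      2 1.735924 0.3287851     TRUE    FALSE
#>     10 1.741683 0.3287851     TRUE    FALSE
#>    100 1.742749 0.3287851     TRUE    FALSE
#>   1000 1.742851 0.3287851     TRUE    FALSE
#>   critical ratio (B inactivates): 1.289836
```

The fitted `f` and `theta` recover the generating reference values; the
mixture state string records which of the five strains activate QS (here A
and C); the ramp shows the community-level state switching twice as signal E
accumulates; and the sweep shows strain A activating at every inoculation
ratio while strain B shuts off above a finite critical ratio.

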