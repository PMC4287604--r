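# ellcorr

Signal and noise correlations between electrosensory pyramidal cells
under spatially local versus diffuse stimulation, in a cerebellum-like
feedback network model.

## What this package is for

In the electrosensory lateral line lobe (ELL) of weakly electric fish,
neighbouring superficial pyramidal (SP) cells are correlated both
because they see the same stimulus (*signal* correlation) and because
they share feedforward receptor input (*noise* correlation). Spatially
diffuse ("global") low-frequency stimulation — but not spatially
restricted ("local") stimulation — additionally recruits parallel-fiber
feedback from cerebellar-like granule cells onto the SP dendrites.
`ellcorr` implements a two-cell spiking network model of this circuit
and the spike-train statistics used to analyse it, for computational
neuroscientists studying correlation control by feedback pathways.

The model couples:

* two leaky integrate-and-fire SP cells with a depolarizing
  afterpotential (DAP) burst mechanism and a dynamic dendritic
  refractory period;
* two disjoint banks of 100 spiking granule cells, phase-tiled across
  the stimulus cycle through per-cell delays;
* anti-Hebbian burst-timing-dependent depression of the parallel-fiber
  weights (2- and 4-spike burst classes with exclusive assignment and
  4-spike priority) against slow non-associative potentiation, which
  sculpts the weight profile into a *negative image* of the stimulus;
* structured input noise: the two SP noise streams share a fraction
  `c`, and each granule cell inherits a fraction `e` of its noise from
  the deep-pyramidal stream of its column.

The analysis side implements binned auto-/cross-correlograms, the
cycle-based shuffle predictor, the noise correlogram
(raw − shuffle, exact at every lag), and correlogram-area correlation
coefficients `R_raw`, `R_signal`, `R_noise`:

    R = <C(tau)>_tau / sqrt(<A1(tau)>_tau <A2(tau)>_tau)

averaged over a ±min(P/4, 10) ms lag window. Doubly stochastic
surrogate spike-train pairs with independently dialled signal and
noise correlations validate the estimators; parameter sweeps
(`sweep_rho()`, `sweep_c_e()`, `sweep_c_f()`) map where feedback
reduces noise correlations.

## Worked example

Train the feedback to its negative-image equilibrium, evaluate frozen
weights under both stimulation geometries, and compare the correlation
coefficients (a few minutes on one core):

```r
library(ellcorr)

cfg <- model_config(noise = noise_params(c = 0.25, e = 0))
ex <- local_global_experiment(cfg,
                              n_trials = 20, trial_duration_s = 20,
                              training_duration_s = 300, seed = 101)
ex$reduction
#> # A tibble: 3 × 4
#>   coefficient local global reduction_pct
#>   <chr>       <dbl>  <dbl>         <dbl>
#> 1 R_raw       0.622 0.125           79.9
#> 2 R_signal    0.543 0.0195          96.4
#> 3 R_noise     0.174 0.108           37.9
```

Read: under local stimulation the pair's stimulus-locked coefficient is
`R_signal ≈ 0.54`; after the granule feedback is recruited and the
plastic weights settle into the negative image, the stimulus-locked
correlation is almost completely cancelled (≈96% reduction). The noise
coefficient falls from ≈0.17 to ≈0.11 (≈40% reduction) because the
granule cells' intrinsic (`e = 0`) trial-to-trial variability dilutes
the shared feedforward noise. The two reductions arise from independent
mechanisms: plasticity for the signal part, granule variability for the
noise part — switch either off (`eta_2 = eta_4 = 0`, or `rho = 0`) and
only the other effect survives.

The fitted objects are tidyverse-friendly: `tidy()` a training run for
the weight-snapshot trajectory, `glance()` a correlogram set for its
coefficients, `autoplot()` correlograms and sweeps, or
`plot_weight_profile()` for the negative image against the stimulus
phase.

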