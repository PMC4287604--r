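---
title: "Signal and noise decorrelation by parallel-fiber feedback: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal and noise decorrelation by parallel-fiber feedback: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Neighbouring superficial pyramidal (SP) cells of the electrosensory
lateral line lobe (ELL) of weakly electric fish respond to amplitude
modulations of the fish's electric field. Their joint activity carries
two kinds of correlation: *signal* correlation, because both cells are
driven by the same stimulus, and *noise* correlation, because they share
feedforward input from overlapping sets of electroreceptor afferents.
When a low-frequency stimulus is spatially diffuse ("global") rather
than spatially restricted ("local"), it additionally recruits a
cerebellum-like feedback pathway: deep pyramidal cells relay the
stimulus to granule cells of the eminentia granularis posterior, whose
parallel fibers contact the SP apical dendrites through plastic
synapses. `ellcorr` implements a two-cell network model of this circuit
and the spike-train statistics needed to ask how feedback recruitment
changes signal and noise correlations.

The package separates two independent mechanisms:

* **Signal decorrelation.** Anti-Hebbian burst-timing-dependent
  depression at the parallel-fiber synapses sculpts the weight profile
  into a *negative image* of the stimulus. The feedback then cancels
  the stimulus-driven modulation of each SP cell, and with it the
  stimulus-locked (signal) component of the pairwise correlation.
* **Noise decorrelation.** Trial-to-trial variability of granule-cell
  firing injects, through the same synapses, variability that is not
  shared between the two SP cells' (disjoint) granule banks. This
  dilutes the shared feedforward noise and reduces the noise
  correlation — but only to the extent that granule variability is
  *independent* of the pyramidal-cell noise (intrinsic, not inherited).

## Model

### SP cells

Each of the two SP cells is a leaky integrate-and-fire neuron with a
depolarizing afterpotential (DAP) that promotes burst firing:

$$C \dot V_i = -g_{leak}(V_i - E_{leak}) + I + \sigma\,\xi_{SP,i}(t)
  + F(\kappa \sin 2\pi f t) + DAP_i(t)
  - g_{GABA}(V_i - E_{GABA}) - \sum_s g_{AMPA,i,s}(t)\,(V_i - E_{AMPA})$$

$F(x) = \max(x, 0)$ half-wave rectifies the stimulus drive (the
electroreceptor afferent population rate cannot be negative); the
rectifier is isolated in one function of the integration core so the
convention is auditable. A spike is registered when $V$ reaches
$V_{threshold}$ at the end of an Euler–Maruyama step; the membrane is
reset to $V_{rest}$ and clamped for the absolute somatic refractory
period $r_s$. With the default constants the cells are subthreshold on
average (quasi-static depolarization peaks 0.06 mV short of threshold)
and fire only through the interplay of noise, stimulus and DAP — a
fluctuation-driven regime with rates around 25–30 Hz under local
stimulation.

The DAP after the spike at $t_n$ is an alpha-shaped current

$$DAP_i(t) = \gamma\,\alpha\,q_n\, s(t - t_n - r_s, \tau), \qquad
  s(t, a) = \frac{t}{a^2} e^{-t/a}\,\Theta(t),$$

where $\gamma$ is the dendro-somatic coupling scale and $q_n$ encodes
dendritic spike failure: a dynamic dendritic refractory period $r_d$
relaxes toward its baseline $D$ with time constant $E$ between spikes
and grows by the factor $B$ at each somatic spike
($E\,\dot r_d = D - r_d$; $r_d \to B\,r_d$ at spikes). When the
inter-spike interval is shorter than $r_d$ the dendritic spike fails
and the DAP amplitude is attenuated, $q \to A\,q$; otherwise $q = 1$.
Because $r_d$ roughly doubles with each spike in a burst, bursts
self-terminate after a few spikes. At the default constants the DAP
peak (≈0.12 µA/cm²) is subthreshold at the stimulus trough and
burst-promoting near the peak, so bursts are concentrated at the
stimulus maxima — the property the plasticity rule depends on. The
intra-burst intervals (≈5–10 ms) are consistent with the 15 ms and
45 ms windows of the burst classifier.

### Granule cells

Granule cells use the same integrate-and-fire formalism (same
threshold, reset and refractory period), without DAP or synaptic input:

$$C \dot V_i = -g_{leak}(V_i - E_{leak}) + I_{gc}
  + \rho\,\xi_{PF,i}(t) + \kappa_{gc} \sin\!\big(2\pi f (t - d_i)\big)$$

with per-cell delays $d_i = (i-1)/(N f)$ tiling one stimulus period, so
each granule cell responds at its own stimulus phase. The two banks of
$N = 100$ cells (one per SP cell) are disjoint. The bias and relay gain
$(I_{gc}, \kappa_{gc})$ are not part of the printed constant set; they
were fixed once so that granule cells are silent without stimulation,
fire deterministically (≈1 spike per cycle) in the noise-free regime
$\rho = 0$, and show clear trial-to-trial variability in spike count
and timing at the default $\rho$. This sharply tuned regime also keeps
the bank's mean synaptic drive at the weight equilibrium comparable to
the constant GABA conductance, so the SP operating point does not run
away under global stimulation. A shallow-drive alternative (cells
hovering at threshold over much of the cycle) was rejected: it makes
granule firing noise-dominated and, when the bank shares noise,
produces population volleys that have no counterpart in the biology.

### Structured noise

All stochastic drive is low-pass filtered Gaussian white noise
(causal order-4 Butterworth, 500 Hz cutoff at the 0.05 ms integration
step), composed from named substreams before filtering:

$$\xi_{SP,i} = \sqrt{c}\,\xi_{shared} + \sqrt{1-c}\,\xi_{unshared,i},
\qquad
\xi_{PF,i} = \sqrt{e}\,\xi_{SP,j(i)} + \sqrt{1-e}\,\xi_i,$$

so the two SP input noises have correlation exactly $c$ and each
granule cell inherits the fraction $e$ of its noise variance from the
deep-pyramidal stream of its own column (taken identical to the SP
stream), the rest being private. Filtering shrinks variance, so each
filtered base stream is rescaled by the deterministic factor
$1/\sqrt{\sum_k h_k^2}$ ($h$ the filter impulse response); because the
composition weights are orthonormal, every composed stream has unit
variance and the printed noise intensities $\sigma$ and $\rho$ multiply
unit-variance processes. Whether the rescaling happens before or after
composition is immaterial (the filter is linear); the choice —
compose, filter, rescale — is recorded here and in the generator
metadata. Each (shared, unshared, private) substream has its own seeded
generator, so any single process is reproducible in isolation and the
stream alignment does not depend on which other processes are consumed.

### Plasticity

Spike trains are scanned online for bursts each time an SP cell fires:
the new spike and its three predecessors form a **4-spike burst** if
none is already assigned and they span ≤ 45 ms; otherwise the 4th- and
5th-most-recent spikes form a **2-spike burst** if unassigned and
≤ 15 ms apart. A spike belongs to at most one burst and the 4-spike
class has priority; the deferred 2-spike test guarantees no spike that
could still join a 4-spike burst is consumed early.

When a burst of class $g \in \{2, 4\}$ is recorded at onset
$t_{burst,post}$ (the first spike of the burst), every synapse whose
presynaptic burst time $t_{burst,pre}$ (the local maximum of that
granule cell's delayed sinusoid, recurring each cycle) falls within the
box window $|t_{pre} - t_{post}| \le L_{Wg}/2$ (circular in the
stimulus period) is depressed multiplicatively:

$$w \to w\,(1 - \eta_g).$$

All weights additionally follow the slow non-associative potentiation
$\dot w = (1 - w)/\tau_w$ (fixed point at the initialisation value
$w = 1$), implemented in closed form per step. The multiplicative form
of the depression is a deliberate design choice: against the slow
potentiation it yields the graded equilibrium
$w_{eq} = 1 / (1 + \eta_g\, r_{burst}\, \tau_w)$, where $r_{burst}$ is
the in-window burst rate seen by the synapse. Because bursts concentrate
at the stimulus maxima, $w_{eq}$ is smallest for granule cells firing at
the maxima — a graded negative image. An additive rule at the printed
gains would pin every weight at a bound (depression flux
$\eta_g r_{burst} \gg 1/\tau_w$ for any plausible burst rate), leaving a
binary rather than graded profile and disconnecting the feedback.

### Protocols

Local stimulation does not recruit the feedback: $g_{max}$ and
$g_{GABA}$ are set to zero and the granule population is silent. Global
stimulation first trains the weights from 1 to equilibrium (1000 s at
full scale; 300 s in the desk-scale protocol, by which time the weight
trajectory has settled), then freezes them and evaluates repeated
trials. Every trial uses an independent noise substream, begins with a
100 ms burn-in (filters and membrane state), and has stimulus phase
zero at trial onset so stimulus cycles align across trials — the
alignment the shuffle predictor requires.

## Spike-train statistics

Spike trains are binned at $dt = 0.5$ ms. Correlogram values are
coincidence rates relative to chance (Hz):
$C_{12}(\tau) = \frac{1}{N_1\,dt}\sum_t X_1(t) X_2(t+\tau) - m_2$, with
the sum over the spikes of cell 1. The scalar coefficient is the
lag-averaged correlogram normalised by the geometric mean of the
lag-averaged auto-correlograms (a correlogram-area correlation
coefficient):

$$R = \frac{\langle C_{12}(\tau)\rangle_\tau}
  {\sqrt{\langle A_1(\tau)\rangle_\tau\,\langle A_2(\tau)\rangle_\tau}}.$$

To separate signal from noise correlations the responses are segmented
into the $M$ stimulus cycles (pooled across trials) and three
correlograms are formed with circular lags spanning one period: the
within-cycle (**raw**) correlogram, the cross-cycle (**shuffle
predictor**, all ordered pairs $j \ne k$ with per-cycle normalisation)
that retains only stimulus-locked structure, and their difference, the
**noise** correlogram; the decomposition raw = shuffle + noise holds
exactly at every lag by construction. Cycles in which the reference
train has no spikes are excluded from its cycle average. Circular lags
are a deliberate choice for the cycle-resolved estimators: with
phase-aligned periodic stimulation, wrap-around respects the stimulus
structure exactly and gives full overlap at every lag; the plain
full-train `acg()`/`ccg()` use ordinary linear lags.

Three scalar coefficients are derived:

* `R_raw` — Eq. above on the raw correlogram, raw auto-correlograms;
* `R_signal` — shuffle predictor over **raw** auto-correlograms: the
  stimulus-locked share of the total correlation. It shrinks as the
  negative image cancels the response modulation, which is the
  quantity of interest; normalising by the shuffle auto-correlograms
  instead would give a shape-similarity index that is ≈ 1 for
  homogeneous cells regardless of modulation depth. The price is a
  mild cross-sensitivity: added trial noise inflates the denominator
  and slightly deflates `R_signal`.
* `R_noise` — noise correlogram over **noise** auto-correlograms, a
  genuine correlation coefficient of the trial-to-trial variability:
  fully shared input noise ($c = 1$, feedback off) gives exactly 1 and
  independent noise gives 0.

The lag window of the averages defaults to $\min(P/4, 10)$ ms — the
classical coincidence window of correlogram-area measures, about 1.4
membrane time constants. A window wider than a quarter period would
average the periodic signal component toward zero, and very wide
windows make the noise coefficient sensitive to slow spectral changes
of the operating point rather than to coincident spiking. The window is
a parameter of every coefficient function and is reported in the
output.

Uncertainty is estimated by a trial-level bootstrap (resampling trials
with replacement, keeping each trial's cycles together), with
percentile intervals.

## Surrogate generator

To validate the analysis stage independently of the network model,
`generate_pair()` draws doubly stochastic Poisson pairs sharing the
rate
$\lambda(t) = \max\{0, \lambda_0 (1 + m_{sig} \sin 2\pi f t +
m_{noise}\,\eta(t))\}$, with $\eta$ a smooth (10 Hz) noise redrawn each
trial and common to the pair; given the rate, the two neurons are
independent (Poisson counts per 0.5 ms bin, spike times uniform within
the bin). `m_sig` moves only the signal coefficient and `m_noise` only
the noise coefficient, which the test suite checks as a rank-correlation
independence property on a 3 × 3 grid. The surrogates emulate the
statistical structure the analysis assumes — common periodic rate plus
shared slow rate fluctuations — and deliberately not the model's bursty
inter-spike-interval statistics: passing these tests validates the
estimators, not the biophysics. A ≤ 20-spike two-cycle fixture with
hand-enumerated correlogram values (`known_answer_fixture()`) pins the
estimator conventions exactly.

## Choices made where the design was open

* **Equation reconstruction.** The model equations follow the LIF-DAP
  lineage of the ELL modelling literature; where a printed constant's
  role admitted more than one reading, the reading was fixed by
  requiring the printed values to reproduce the documented phenomenology
  (superficial pyramidal cells fire below ~30 Hz; 2- and 4-spike bursts
  with intra-burst intervals compatible with the 15/45 ms windows;
  bursts gated by the stimulus). Those checks are encoded in the test
  suite.
* **Headline comparison at intrinsic granule variability (`e = 0`).**
  The default parameter set fixes `e = 1` (granule noise fully
  inherited from the deep-pyramidal stream). In that limit no granule
  variability is independent of the pyramidal cells, so there is
  nothing to dilute the shared noise with — consistent with the sweep
  result that the noise-correlation reduction vanishes as `e` tends to
  one and is greatest for `e` near zero. The headline local-vs-global
  experiment of the acceptance pipeline therefore runs at `e = 0`
  (variability from intrinsic sources such as channel noise), keeping
  every other default; `sweep_c_e()` exposes the full dependence.
* **Desk-scale protocol sizes.** The acceptance pipeline trains for
  300 s and evaluates 20 trials of 20 s (the weight trajectory settles
  well before 300 s); the training timecourse uses 10 × 10 s
  evaluations per snapshot and the ρ sweep 12 × 10 s per grid point.
  The full printed protocol (1000 s training, 100 × 100 s trials)
  remains the default of `protocol_spec()`.

## Known limitations

* The exact printed forms of the model equations were not recoverable
  from the source text (rendered as images); the implementation is a
  faithful reconstruction with every deviation isolated and documented,
  but quantitative anchors that depend on fine details of the original
  implementation may not be met. In particular, the local/global noise
  ratio in the noise-free granule regime ($\rho = 0$) sits below 1
  here (≈ 0.65): at the printed plasticity gains the equilibrium burst
  rate under global stimulation is far below the local burst rate, and
  the recruited conductances double the resting conductance, so
  burst-amplified correlation transfer differs between geometries even
  without granule variability. The ratio still declines with ρ, which
  is the mechanism under test.
* With all weights at 1 (the training initial condition) the network is
  saturated; the test of response cancellation therefore compares the
  steady-state modulation against the strongest uncancelled response
  (feedback off) rather than the saturated t = 0 state.
* Heterogeneity (per-cell parameters), conductance-based membrane
  dynamics, more than two SP cells, and plasticity during local runs
  are out of scope.
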