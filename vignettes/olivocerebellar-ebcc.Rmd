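---
title: "Modeling eye-blink conditioning in an olivocerebellar spiking network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling eye-blink conditioning in an olivocerebellar spiking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Eye-blink classical conditioning (EBCC) is the canonical cerebellum-driven
associative learning task: a neutral conditioned stimulus (CS, e.g. a tone)
repeatedly precedes an aversive unconditioned stimulus (US, e.g. an air
puff), and over tens of trials the animal learns to close the eyelid
*before* the US arrives (a conditioned response, CR). `ebccsim` implements a
spiking model of the olivocerebellar microcircuit that acquires CRs through
supervised synaptic plasticity, together with three structural/functional
lesion operators that emulate cerebellar alterations reported in rodent
models of dystonia, and the spike-to-behavior analysis chain that turns
deep-nuclei spike trains into CR counts and latencies.

The package answers a causal question by simulation: which local cerebellar
alterations are sufficient to degrade EBCC learning, and which leave it
intact?

## Network model

Eight populations are wired according to the standard microcircuit diagram:
mossy fibers (mf, spike sources) excite granule cells (GrC) and Golgi cells
(GoC); GrC excite Purkinje cells (PC) through ascending-axon (aa) and
parallel-fiber (pf) contacts and drive molecular-layer interneurons (MLI),
which inhibit PCs; GoC feed back inhibition onto GrC; PCs inhibit the
glutamatergic deep-nuclei projection neurons (DCN), which also receive
direct mf excitation; the inferior olive (IO) sends one climbing fiber to
each PC and collaterals to DCN and to the GABAergic nucleo-olivary cells
(DCN-GABA), which in turn inhibit the IO.

The connectome is generated statistically rather than from reconstructed
morphologies: each target cell draws its configured number of distinct
sources uniformly at random (`build_connectome()`), which preserves the
population-level convergence statistics that the behavioral claims depend
on while staying fully seeded and serializable. The Purkinje population is
fixed at 99 cells; granular/molecular-layer sizes default to a
reduced "desk" scale (100 mf, 2000 GrC, 16 GoC, 120 MLI, 16 DCN, 16
DCN-GABA, 16 IO) and can be scaled with one factor. The per-target
convergences of the PC afferents (600 pf + 22 aa + 1 climbing fiber
excitatory, 10 MLI inhibitory) are calibrated so that the structural
excitation/inhibition synapse ratio onto PCs equals 62.3 in the control
condition, the reference value for this circuit.

### Neurons

All spiking cells use the extended generalized leaky integrate-and-fire
model (E-GLIF): a leaky membrane plus a spike-triggered depolarizing
current (decay `k1`) and an adaptation current with both spike-triggered
(`A2`, decay `k2`) and subthreshold (`k_adap`) components,

$$\frac{dV}{dt} = -\frac{V - E_{rest}}{\tau_m}
  + \frac{I_e + I_{dep} - I_{adap} + I_{syn}}{C_m},\qquad
  \frac{dI_{adap}}{dt} = k_{adap}(V - E_{rest}) - k_2 I_{adap},\qquad
  \frac{dI_{dep}}{dt} = -k_1 I_{dep}.$$

Integration is exponential-Euler at `dt = 0.1` ms with the coupling terms
frozen over a step; the spike test is applied at the step end, and the
membrane is clamped at the reset potential during the absolute refractory
period. There is no escape noise: all stochasticity enters through the
stimulus realizations and the connectome/initial-state sampling.

Parameter values are not printed in the source literature for every
population, so the defaults shipped in `default_neuron_params()` are
calibrated, not copied: endogenous currents are tuned with
`tune_endogenous_current()` (monotone bisection against a 10-s simulation)
so that isolated cells hit physiological resting rates (GrC silent, GoC
~8 Hz, PC ~60 Hz — a zebrin-negative, high-excitability phenotype — MLI
~20 Hz, DCN-GABA ~5 Hz, IO ~1.5 Hz), and the PC `A2` increment is sized so
that a 500-Hz, 30-ms climbing-fiber burst produces the stereotyped
burst-then-pause response. Each cell additionally receives a small fixed
per-cell offset of its endogenous current (`I_e_jitter`, drawn once per
connectome), emulating intrinsic-excitability heterogeneity; this both
desynchronizes the pacemaking populations and gives the DCN population a
graded, rather than all-or-none, recruitment curve.

Two deliberate departures from a literal three-current cell deserve
mention. The DCN projection neurons are run *without* adaptation
(`k_adap = A1 = A2 = 0`): during calibration, slow DCN adaptation produced
a population limit cycle whose phase was reset by each blink, making the
motor readout depend on trial history rather than on Purkinje suppression;
the memoryless variant reads out PC disinhibition faithfully. Second, MLIs
carry a slow excitatory receptor (`tau_exc = 120` ms, an NMDA-like
component) so that their CS response builds up over the stimulus; this is
what shapes the learned eyelid trace into a ramp that peaks toward US
onset rather than a step at CS onset.

### Synapses and plasticity

Connections are conductance-based with exponential kernels (one excitatory
and one inhibitory receptor per neuron), group-wise delays of 1-4 ms
rounded to the integration grid, and delayed delivery through a ring
buffer. Only the pf-PC synapses are plastic. The supervised spike-timing
rule is rectangular: at each trial boundary, every pf spike that fell
within the 100-ms `teaching_window` ending at a spike of the target PC's
climbing-fiber source is depressed by `ltd_step`, every other pf spike is
potentiated by `ltp_step` (ratio 10:1, so depression wins exactly where
the teaching signal fires), and weights are clipped to
`[w_min, w_max] = [0, 1.2]` nS around the initial 0.9 nS. The window ends
at the IO spike so that eligibility spans the tail of the CS-US interval;
the batch (trial-boundary) update keeps sessions exactly reproducible
while the eligibility window preserves within-trial timing.

Depression scales with the teaching signal's synaptic strength as
`max(1, w_cf / w_cf_control)`: complex-spike LTD triggering is treated as
all-or-none from below (a weakened climbing fiber that still fires still
triggers depression), while an *increased* climbing-fiber synaptic density
proportionally strengthens depression. The asymmetric gain is what lets
the synaptic-imbalance lesions (which strengthen the IO-PC connection)
compensate their loss of excitatory pf synapses with faster learning,
while the reduced-IO lesions act mainly through the disconnected cells.

## Protocol

Each 1000-ms trial delivers the CS as independent 40-Hz Poisson trains on
every mossy fiber for 280 ms ("non-recurrent" is read as non-repeating
patterns, maximizing granule-layer pattern diversity) and the US as a
regular 500-Hz, 30-ms burst injected into every IO cell, co-terminating
with the CS (onset 250 ms). One session is 100 consecutive trials (10
blocks of 10) with full state carry-over. Before trial 1 the network gets
a 1-s unstimulated settling period plus one unrecorded habituation trial
(a CS+US presentation with frozen weights and its own stimulus
realization): the response resets the deep-nuclei populations into their
stereotyped post-stimulus state, so that every recorded trial starts from
statistically identical conditions — the analogue of the habituation
phase of experimental EBCC protocols.

## Behavioral readout

Per trial and population, a spike density function (SDF) is computed by
convolving each cell's spikes with a Gaussian kernel (20 ms for PC, 10 ms
for DCN; truncated at four standard deviations, no edge renormalization)
and averaging across cells. The motor output (eyelid closure) is the DCN
population SDF filtered with a 100-ms *trailing* moving average with edge
shrinkage. A trailing window was chosen over a centered one because the
unconditioned blink that follows the US would otherwise leak backwards
into the CR window and produce spurious anticipatory responses in every
trial; a causal filter is also what a real-time decoder could compute.

A CR is detected when the motor output reaches the threshold inside the CR
window (100-280 ms from CS onset) and is still at or above it at US onset;
because of the trailing average, the value at US onset already summarizes
a sustained elevation over the preceding 100 ms. Traces that sit above
threshold throughout the first 100 ms (the exceedance pre-dates the
window) are improperly timed responses and are not counted. For
anticipatory traces the detector is monotone in the threshold. The CR
onset is the start of the monotonic rise preceding the first in-window
threshold reach, clamped to the window start, and reported as advance
relative to US onset (so it lies in (0, 150] ms). The threshold defaults
to 4 Hz and is, as in the reference experiments, calibrated on the control
session so that the sixth block yields 70% CRs
(`calibrate_cr_threshold()` places it between the 7th and 8th largest
per-trial response strengths of that block); the calibrated value is then
reused unchanged for every lesioned condition.

Learning indices follow the standard definitions: the per-cell SDF change
(time-integral over the CR window in the last block minus the mean of the
first 100 ms times the window length; negative = suppression), baseline
rate and inter-spike-interval coefficient of variation in the 280-1000-ms
window of trial 1, Tukey-fence outlier exclusion with interpolated
(type-7) quartiles, Wilcoxon rank tests for distribution-valued indices
and McNemar's test (exact binomial below 25 discordant pairs, chi-square
with continuity correction above) for the paired per-trial CR flags, at
significance level 0.01.

## Lesion models

* **Reduced olivocerebellar input** (`lesion_reduced_io(fraction)`), at
  25/50/75%: the given fraction of PCs loses its climbing-fiber source
  (those cells then receive potentiation only) and all surviving IO-PC
  weights are scaled by one minus the fraction.
* **Intrinsic PC burst firing** (`lesion_intrinsic_burst()`): a
  whole-session overlay of 20-ms spike trains (500 Hz within the train,
  through a dedicated 45-nS excitatory synapse) separated by pauses drawn
  equiprobably from 20 or 30 ms, shared across the PC population —
  matching the population-level oscillations seen experimentally — plus a
  20% reduction of the PC endogenous current. The unprinted magnitudes
  (train rate, synaptic weight, current factor) are package calibration
  choices that keep the lesioned baseline rates in their physiological
  ranges while clearly transforming tonic firing into bursts.
* **IO-induced burst firing** (`lesion_io_burst()`): 40-ms-on/40-ms-off
  trains injected into all IO cells for the whole session, on top of the
  US.
* **Synaptic imbalance** (`lesion_synaptic_imbalance(level)`): random
  removal of 14%/39% (mild) or 25%/71% (severe) of the pf-PC and MLI-PC
  synapses and scaling of the IO-PC weight by +32%/+57%. The climbing-fiber
  density increase acts multiplicatively on the existing connection so the
  one-climbing-fiber rule is preserved. The printed E/I ratios for the
  lesioned conditions are not jointly reproducible from the printed
  percentage changes alone, so only the direction of the ratio change is
  asserted.

## What the synthetic data can and cannot show

The statistical connectome reproduces convergence statistics, not
geometry: claims that depend on spatial microzones, on morphology-specific
connectivity motifs, or on zebrin banding are outside its reach. The
Poisson CS has no stable per-fiber temporal code, so the model cannot
address pattern-specific (as opposed to rate-driven) granular-layer
computations. Trial-to-trial variability comes only from the stimulus
realizations and the sampled network; biological sources (channel noise,
attentional state) are absent, which makes learning curves somewhat
sharper than experimental ones. Passing tests therefore validate the
population-level learning machinery and the analysis chain, not a
cell-level reconstruction.

## Numerical choices and problem sizes

`dt = 0.1` ms everywhere (at most half the fastest receptor time
constant); delays are rounded to the grid; the analysis grid is 1 ms.
Weight snapshots are taken at block boundaries. Unit tests run the network
at one fifth of the default granular-layer scale; the acceptance checks
and `scripts/acceptance.R` run the full default scale (99 PCs, ~2300
integrate-and-fire cells, 100 trials per session, about half a minute per
session). All randomness is derived from one master seed through named
streams (connectome, CS, lesion, initial state), so any single stochastic
element can be varied while the others stay fixed.

## Known limitations

Plasticity is restricted to the pf-PC site; nucleo-cortical and mf-DCN
plasticity, which contribute to consolidation in vivo, are not modeled.
The severe synaptic-imbalance condition loses a large part of the
MLI-carried suppression amplitude, and in this implementation its learning
curve recovers more slowly than the mild condition; the compensation
through stronger climbing-fiber teaching is partial. CR-onset statistics
are computed over CR trials only, and sessions with very few CRs carry
wide onset uncertainty.
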