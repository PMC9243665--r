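# ebccsim

Spiking-network simulation of eye-blink classical conditioning (EBCC) in
the olivocerebellar microcircuit, with lesion operators for three
dystonia-like cerebellar alterations and the full spike-to-behavior
analysis chain.

## What it is for

EBCC is the standard cerebellum-dependent associative learning task: a
conditioned stimulus (CS; here, 40-Hz mossy-fiber activity lasting 280 ms)
repeatedly precedes an aversive unconditioned stimulus (US; a 500-Hz
inferior-olive burst co-terminating with the CS), and the circuit learns to
drive an anticipatory eyelid closure — a conditioned response (CR) — before
the US. The package is for computational neuroscientists who want to ask,
by simulation, which local cerebellar alterations (reduced olivocerebellar
input, aberrant Purkinje-cell burst firing, imbalanced synaptic densities
on Purkinje cells) are sufficient to degrade this form of learning.

The model: eight populations (mossy fibers, granule and Golgi cells,
Purkinje cells, molecular-layer interneurons, glutamatergic and GABAergic
deep-nuclei cells, inferior olive) wired by a seeded statistical connectome
generator; extended generalized leaky integrate-and-fire (E-GLIF) point
neurons

    dV/dt      = -(V - E_rest)/tau_m + (I_e + I_dep - I_adap + I_syn)/C_m
    dI_adap/dt = k_adap (V - E_rest) - k2 I_adap
    dI_dep/dt  = -k1 I_dep

with conductance-based synapses; and a supervised spike-timing plasticity
rule at the parallel-fiber → Purkinje-cell synapse: a pf spike within
100 ms before a climbing-fiber (teaching) spike of its target cell is
depressed, every other pf spike is potentiated (10:1 step ratio),
weights clipped to bounds, updated at trial boundaries. Learning expresses
itself as progressive Purkinje suppression in the CS-US interval, release
("facilitation") of the deep nuclei, and a rising motor output that is
decoded into CR flags and onsets with a 4-Hz threshold rule calibrated so
the control sixth block yields 70% CRs.

## Worked example

```r
library(ebccsim)

cfg  <- ebcc_config()                    # network/protocol/plasticity/analysis
conn <- build_connectome(cfg$network, seed = 1)
structural_ei_ratio(conn)
#> [1] 62.3

ses <- run_session(conn, cfg$protocol, seed = 1)      # 100 trials, ~30 s
beh <- analyze_session(ses, cfg$analysis)
thr <- calibrate_cr_threshold(beh$trials$strength)    # block-6 = 70% rule
beh <- redetect(beh, thr)
beh
#> EBCC behavior: 56 CRs / 100 trials (threshold 6.83 Hz)
#>  %CR per block: 0 0 0 10 80 70 100 100 100 100
#>  CR onset: 116 +/- 49 ms before US
```

The block percentages trace the acquisition curve (70% at block 6 by
calibration, full acquisition by block 9); `total_crs` counts CR trials
over the session; the onset is the mean anticipation of the eyelid
closure relative to US onset. Lesions are plain operators on the same
objects:

```r
ex <- run_experiment(lesion_reduced_io(0.5), seeds = 1, config = cfg,
                     threshold = thr)
max(ex$blocks$pct_cr)                     # maximum block %CR under lesion
compare_conditions(ex, beh)               # Wilcoxon + McNemar vs control
```

`run_condition_matrix(seed, cfg)` runs the whole eight-condition study
(control, three reduced-IO levels, two burst-firing lesions, two
imbalance levels) with a shared calibrated threshold.

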