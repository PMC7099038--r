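# BetaOpto

Analysis of beta-band (12–30 Hz) network dynamics in electrophysiological
recordings made under optogenetic stimulation protocols — the analysis
setting of studies that silence or rhythmically drive one cortico-basal-
ganglia structure (motor cortex, subthalamic nucleus, globus pallidus)
while recording an ECoG and single units, and ask which node orchestrates
parkinsonian beta synchronisation.

The package provides, as composable S4-based functions:

* **Epochs** — laser events → half-open Pre `[t−4, t−2)` / OFF `[t−2, t)` /
  ON `[t, t+dur)` windows, with the inclusion rules (≥ 30 stimulations and
  ≥ 60 s per state for pulse sessions; ≥ 10 opto-tested cells with > 60%
  modulated for mapping).
* **Beta bursts** — excursions of the band-limited Hilbert envelope above
  its recording-wide 75th percentile lasting > 50 ms; per-epoch counts and
  durations.
* **Beta-AUC** — epoch-wise beta power as the signed area between the
  power spectrum and its 12–30 Hz chord,
  `AUC = ∫ (S(f) − chord(f)) df`, with per-stimulation difference
  distributions `AUC(Pre)−AUC(OFF)` vs `AUC(OFF)−AUC(ON)` and
  best-beta-recording selection.
* **Phase locking** — spike phases interpolated between detected beta
  peaks (peak = 0°), 10° phase histograms, circular mean / vector length
  `R`, Rayleigh test (`Z = nR²`), Watson–Williams F, and phase-lag →
  conduction-delay conversion `Δt = (lag/360)·(1000/f)` ms.
* **Rate responses** — PSTHs (6 s width, 2 s offset, 50 ms bins), the
  ±2 SD / 3-consecutive-bin inhibited/excited classification, pooled
  OFF/ON rates and the modulation index `(f_ON−f_OFF)/(f_ON+f_OFF)`.
* **Coherence control** — Welch spike–field coherence plus random spike
  thinning to separate rate effects from genuine decoupling.
* **Synthetic sessions** — a seeded generator (1/f² background, Gaussian-
  envelope 20 Hz bursts, von Mises phase-locked Poisson units, pulse or
  sinusoidal laser protocols) so the entire chain is testable without any
  recording on disk.

## Worked example

A synthetic pallidal-inhibition-like session: beta suppressed to 20% and
an STN-like unit disinhibited 2.5× during ON.

```r
library(BetaOpto)

cfg <- syntheticConfig(durationS = 310, nStims = 30,
                       onBetaFactor = 0.2, onRateFactor = 2.5, seed = 42)
ses <- genSession(cfg)
res <- runPipeline(ses)

res$epochs
#> EpochSet (pulse protocol): 30 event(s), 90 window(s)
#>   pre: total 60.0 s
#>   off: total 60.0 s
#>   on : total 60.0 s

res$units[, c("unitId", "fOff", "fOn", "mi", "label",
              "rayleighPOff", "rayleighPOn")]
#>   unitId     fOff   fOn        mi   label rayleighPOff rayleighPOn
#> 1     u1 9.883333 23.65 0.4105368 excited 3.314859e-12  0.04323184

colMeans(res$aucRecords[, c("aucPre", "aucOff", "aucOn")])
#>    aucPre    aucOff     aucOn
#>  3592.085  2618.274   148.766
```

Reading the output: the unit fires at 9.9 Hz with the laser off and
23.7 Hz with it on (modulation index 0.41, classified `excited` by the
PSTH rule); it is strongly beta-entrained during OFF (Rayleigh
p ≈ 3×10⁻¹²) and barely so during ON; and the per-epoch beta-AUC
collapses from ≈ 2600 µV²·Hz (OFF) to ≈ 150 (ON) while Pre and OFF differ
only by natural beta fluctuation — the joint signature of pallidal
orchestration of the rhythm.

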