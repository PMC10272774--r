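# synergykit

Deterministic muscle-synergy extraction from surface EMG and EMG-driven
continuous joint-angle estimation, built for the question: *how do you keep
an sEMG-based motion-intention decoder accurate across recording days?*

Surface EMG drifts between sessions (electrode displacement, impedance and
signal changes over time), so regressors trained on raw envelope features
degrade on later days. Muscle-synergy features help — the envelope matrix
**D** (muscles × time) factorises as

```
D = C S + E
```

with **C** (m × r) the synergy weights, **S** (r × n) the activation
coefficients — but only if the factorization is *reproducible*. Random-start
NMF is not: factor order, scale and shape change run to run. synergykit's
core is **MCR-ALS** (multivariate curve resolution — alternating least
squares) with a deterministic **SIMPLISMA** pure-variable initialisation:
identical data give bit-identical synergies, every time. Around it the
package provides:

- NMF (Lee–Seung multiplicative updates) and PCA baselines behind the same
  `SynergyDecomposition` interface;
- synergy-count selection by variance accounted for
  (`VAF = 1 − ‖D−M‖²_F / ‖D−mean(D)‖²_F`, smallest r with VAF > 80%);
- elbow angle from a tri-axial accelerometer under the quasi-static gravity
  model `θ = 90° − arccos(Ax/g)`, with gravity calibration;
- a sequence-to-sequence bidirectional LSTM regressor (5 layers × 48 hidden
  units per direction, dropout 0.3) from activation coefficients to angle,
  implemented in compiled code (RcppArmadillo) with BPTT and Adam;
- cross-day / cross-run synergy-stability and per-day accuracy metrics;
- a synthetic multi-subject, multi-day session generator with known ground
  truth (cyclic 0–90° elbow flexion, per-day gain drift, amplitude groups),
  so the whole pipeline is testable without any data download.

See `vignettes/synergy-extraction.Rmd` for the methods account.

## Worked example

Simulate the default study fixture (3 muscles, 2 generating synergies, 30
movement cycles of 200 samples, 5% envelope noise), pick the synergy count,
and decompose:

```r
library(synergykit)

gt  <- makeGroundTruth(seed = 7)          # ground truth of one subject
ses <- synthesizeSession(gt, day = 1, seed = 8)

sel <- selectOrder(ses$emg, method = "mcr_als", vafThreshold = 0.80, rMax = 3)
attr(sel, "vaf")
#> [1] 0.004463519 0.996413273
as.integer(sel)
#> [1] 2
```

A rank-1 fit explains almost none of the between-muscle structure
(VAF ≈ 0.004) while two synergies reconstruct it almost completely
(VAF ≈ 0.996), so the VAF > 80% rule selects r = 2 — the generating count.

```r
dec <- mcrAls(ses$emg, r = 2)
dec
#> SynergyDecomposition (mcr_als): r = 2, 3 channels, 6050 samples
#>   iterations: 7, VAF = 0.996413
matchSynergies(gt@CTrue, dec)$cc   # recovered vs generating synergies
#> [1] 0.9992026 0.9998866
```

The full five-day experiment — train the Bi-LSTM on day 1, predict days
2–5 against the accelerometer-derived reference angle (runs in a few
minutes on one core):

```r
res <- runPipeline(config = pipelineConfig(), seed = 7)
res$accuracy[["1"]]$perDay
#>   day        cc      mae    n
#> 1   2 0.9941143 2.935744 6050
#> 2   3 0.9900460 3.686700 6050
#> 3   4 0.9917639 3.248120 6050
#> 4   5 0.9893577 3.681942 6050
res$stability[["1"]]$mean          # cross-day synergy stability (MCR-ALS)
#> [1] 0.9991883
```

Every held-out day stays at CC ≈ 0.99 (mean absolute error ≈ 3°), and the
day-to-day synergy correlation of the deterministic extraction is ~0.999
(repeated runs on the same data score exactly 1).

A thin command-line front end over the same functions lives in
`inst/cli/synergykit.R` (`simulate`, `extract`, `angle`, `evaluate`, `run`).

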