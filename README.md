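# gemfluct

Analysis of inter-trial movement variability in redundant goal-directed
tasks, built around a virtual shuffleboard paradigm.

## The problem

When a task can be achieved in many ways, the set of perfectly successful
body states forms a **goal equivalent manifold (GEM)**. For shuffleboard,
releasing a puck at dimensionless position *x* with speed *v* gives goal
error *e* = *f*(*x*, *v*) = *v*²/*μ* + *x* − 10 (friction *μ*, target at 10
length units), and the GEM is the parabola *v*² = *μ*(10 − *x*): every point
on it stops the puck exactly on the target. Skilled performers scatter their
trials near the GEM, but looking at the *shape* of that scatter is not
enough — variance-based manifold signatures depend on the coordinates used
to measure execution. This package instead analyses the trial-to-trial
*dynamics* of the fluctuations, which are coordinate-invariant.

Trial-to-trial fluctuations **u**ₖ about the mean operating point are
modelled by a linear error-correcting update

&nbsp;&nbsp;&nbsp;&nbsp;**u**ₖ₊₁ = B **u**ₖ + **ν**ₖ,

and B is estimated by ordinary least squares from blocked trial series. Its
eigenstructure tells the story: a *weakly stable* eigenvalue λ_w (0 ≪ λ_w < 1)
whose eigenvector hugs the GEM tangent — deviations that don't hurt
performance are left to persist — and a *strongly stable* eigenvalue λ_s ≈ 0
whose eigenvector is transverse — goal-relevant deviations are extinguished
within a trial. Persistence measures (lag-1 autocorrelation, whose
population value equals λ direction-by-direction, and DFA exponents α) probe
the same structure independently. Finally, the goal-level variability obeys
the scaling law

&nbsp;&nbsp;&nbsp;&nbsp;σ_e / σ_ns ≈ β · s / √(1 − λ_s²) ≜ s_TOT,

where *s* = √(1 + (2v\*/μ)²) is the passive sensitivity of the task,
β = sin θ_s the eigenvector geometry, and σ_ns the intrinsic noise in the
strongly stable direction: performance at the goal emerges from the
interaction of task geometry and active error correction. All estimated
quantities get percentile bootstrap distributions (resampling unit: the
(current, next) trial pair), and a built-in simulator generates the full
eight-friction-condition experiment with known ground truth.

## Worked example

```r
library(gemfluct)
cfg <- task_config(mu = friction_set(5))   # friction from a 5 s ideal stop-time
ts  <- simulate_series(simulation_spec(cfg, seed = 42))
fl  <- fluctuations(ts)                    # 45 transition pairs per 50-trial block
fr  <- gem_frame(operating_point(ts), cfg)
fit <- eigenanalysis(fit_update_matrix(fl), fr)
print(fit)
#> Inter-trial linear model: lambda_w = 0.761, lambda_s = -0.053,
#>   theta_w = 0.68 deg, theta_s = 80.45 deg, beta = 0.986

boot <- bootstrap_model(fl, fr, n_iter = 2000, seed = 42)
print(boot$lambda_w)
#> lambda_w: 0.7601 [0.7041, 0.8205] (2000 samples)

sp <- scaling_point(ts, fr, fit, fl)
sprintf("sigma_e/sigma_ns = %.2f vs s_TOT = %.2f", sp$ratio, sp$s_tot)
#> "sigma_e/sigma_ns = 46.19 vs s_TOT = 46.38"
```

Reading the output: the weakly stable direction sits 0.68° from the GEM
tangent with λ_w ≈ 0.76 (fluctuations along the manifold persist over many
trials — about 9 are needed for a deviation to decay below 10%), while the
transverse direction is corrected essentially in one trial (λ_s ≈ −0.05,
i.e. 5% of a deviation survives a single update). The variability ratio
matches the total body-goal sensitivity to better than 1%, the scaling law
in action: with *s* ≈ 47 here, goal-level error is dominated by the task's
passive amplification of transverse noise.

## The analysis workflow

The numbered scripts under `analysis/` run the full study on simulated data
and write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | eight conditions (stop-times 3–5 s), CSVs under `results/data/` |
| `02_estimate.R` | per-condition OLS fit + labeled eigenanalysis |
| `03_persistence.R` | lag-1 autocorrelations, DFA on the 460-trial concatenation |
| `04_bootstrap_report.R` | full bootstrapped pipeline → `results/report.json` (`--full` for 10000 iterates) |
| `05_scaling.R` | bootstrapped σ_e/σ_ns vs s_TOT fit |
| `06_invariance.R` | PCA-whitening stress test of coordinate invariance |

Each is a thin driver over the exported functions; `run_pipeline()` does the
whole chain in one call and `write_report()` serializes it (byte-identical
for identical data, configuration and seed).

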