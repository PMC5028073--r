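---
title: "Inter-trial fluctuation dynamics near a goal equivalent manifold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-trial fluctuation dynamics near a goal equivalent manifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and its redundancy

The package analyses repeated executions of a goal-directed movement task in
which more than one body state achieves the goal perfectly. Its concrete
setting is a virtual shuffleboard game: on each trial a puck is released at
position $x$ with speed $v$, slides under Coulomb friction $\mu$, and stops at
$x_f = x + v^2/(2\mu g)$; the goal-level error is the distance $x_f - L$ to a
target at $L$. After rescaling positions by a length $R$ and speeds by
$\sqrt{2 g R}$ (defaults $L = 200$ cm, $R = 20$ cm, $g = 981$ cm/s$^2$), the
dimensionless goal function is

$$ e = f(x, v) = \frac{v^2}{\mu} + x - \tilde L, \qquad \tilde L = L/R = 10 . $$

Its zero set, the parabola $v^2 = \mu(\tilde L - x)$, is the **goal equivalent
manifold (GEM)**: the one-parameter family of perfect trials. The GEM is a
property of the task alone — it exists before any controller is specified.

Linearizing $f$ about an operating point $\mathbf{x}^* = (x^*, v^*)$ gives the
$1 \times 2$ body–goal matrix $A = (1,\; 2v^*/\mu)$, whose null space spans
the unit tangent $\hat e_t$ and whose row space spans the unit normal
$\hat e_n$. The single singular value

$$ s = \sqrt{1 + (2v^*/\mu)^2} \;\ge\; 1 $$

is the **passive sensitivity**: the gain with which body-level deviations are
amplified into goal-level error, again independent of control. For the
frictions used here ($\mu \approx 0.016$–$0.045$) $s$ ranges roughly from 29
to 47, so the passive amplification dominates everything the controller does.

## The inter-trial model

Writing each trial's release state as $\mathbf{x}_k = \mathbf{x}^* +
\mathbf{u}_k$, skilled performance is modelled by a linear inter-trial
error-correcting update

$$ \mathbf{u}_{k+1} = B\,\mathbf{u}_k + \boldsymbol{\nu}_k , $$

with additive noise $\boldsymbol{\nu}_k$. The analysis makes no assumption
about optimality of the underlying controller and never constructs it:
$B$ is estimated from data by ordinary least squares. The eigenstructure of
$B$ carries the scientific content. With eigenvalues
$\{\lambda_w, \lambda_s\}$ and unit eigenvectors $\{\hat e_w, \hat e_s\}$
(columns of $E$), the eigencoordinates $\mathbf{z}_k = E^{-1}\mathbf{u}_k$
decouple into two scalar AR(1) maps
$z_{\cdot,k+1} = \lambda_\cdot z_{\cdot,k} + n_{\cdot,k}$. The standing
predictions for skilled performers near a GEM are:

* **H1** — one eigenvector is nearly tangent to the GEM
  ($\theta_w \approx 0$) with $0 \ll \lambda_w < 1$: deviations that do not
  hurt performance are only weakly corrected.
* **H2** — the other direction is transverse with $|\lambda_s| \approx 0$:
  goal-relevant deviations are extinguished essentially in one trial.
* **H3** — persistence mirrors stability: lag-1 autocorrelations satisfy
  $R(1) \equiv \lambda$ direction-by-direction, and DFA exponents satisfy
  $0.5 \approx \alpha_s \ll \alpha_w$.
* **H4** — the variability ratio scales as
  $\sigma_e/\sigma_{ns} \approx \beta s / \sqrt{1-\lambda_s^2} \equiv
  s_{TOT}$, with $\beta = \sin\theta_s$; across conditions with different
  $\mu$ the points fall on a line of slope $\approx 1$.

A perfect minimum-intervention controller would put $\lambda_w = 1$ exactly —
but that is a random walk along the GEM, which bounded data rule out; the
interesting regime is weak-but-nonzero contraction along the manifold.

## Estimation procedure

Per participant/condition the pipeline (`run_pipeline()`) does:

1. **Operating point**: the sample mean state over all trials, computed once
   and held fixed everywhere, including inside the bootstrap. Skilled data
   places it near (never exactly on) the GEM; `gem_frame()` evaluates $A$ at
   the given point regardless, which for near-GEM points is indistinguishable
   from using the error-contour tangent.
2. **Trimming**: within each 50-trial block, only trials 5–49 serve as
   current states (successors 6–50), eliminating between-block "state
   updates" and possible re-warm-up transients: 45 transition pairs per
   block, 450 per condition. Both counts are configurable (`trim_head`,
   `use_first`).
3. **OLS**: $\hat B$ minimizes the single-step mean-square prediction error
   over the valid pairs, closed form, no intercept — fluctuations are
   mean-removed by construction, so an intercept would only absorb
   pair-selection effects. Measurement noise at the apparatus' ~2% level
   biases OLS negligibly and is deliberately left untreated.
4. **Labeled eigenanalysis**: weak = larger $|\lambda|$, strong = smaller.
   This matches the expected regime $0 \approx |\lambda_s| \ll \lambda_w$ and
   stays well-defined when $\lambda_s < 0$; an alignment-based labeling
   (weak = eigenvector closest to the tangent) is computed as a diagnostic
   and a warning is raised when the two disagree. Signs are fixed by
   $\hat e_w \cdot \hat e_t \ge 0$, $\hat e_s \cdot \hat e_n \ge 0$, making
   $\theta_w$ a signed angle in $(-90^\circ, 90^\circ]$ and $\theta_s$
   unsigned in $[0^\circ, 180^\circ)$. Complex or repeated eigenvalues are
   errors, not silent fallbacks: the analysis is restricted to the real,
   distinct regime, and the bootstrap counts (and tolerates up to 20% of)
   such degenerate iterates.
5. **Residual noise**: $r_k = E^{-1}(\mathbf{u}_{k+1} - B\mathbf{u}_k)$;
   $\sigma_{nw}, \sigma_{ns}$ are the RMS of the two components. The RMS
   reading resolves an ambiguity in how the strong-direction residual scale
   is written in some accounts (absolute value inside vs outside the
   square).

## Persistence measures

`lag1_autocorrelation()` uses the biased-variance convention
$R(1) = \langle z_{k+1} z_k \rangle / \langle z_k^2 \rangle$ on the
mean-removed series, with lag products restricted to within-block pairs
(mirroring the regression convention). On resampled pairs in eigencoordinates
this statistic reproduces the fitted eigenvalue *exactly*, by the OLS normal
equations — the empirical counterpart of the identity
$R(1) \equiv \lambda$ — so its bootstrap distribution coincides with the
eigenvalue's. It is retained as a consistency check and because the identity
fails (informatively) on data that violate the linear model.

`dfa()` implements detrended fluctuation analysis with linear detrending:
integrate the mean-removed series, cut the profile into non-overlapping boxes
(forward segmentation, tail remainder discarded), remove a least-squares line
per box, and regress $\log_{10} F(n)$ on $\log_{10} n$. Box sizes default to
~12 log-spaced integers in $[4, N/4]$. These are standard choices; the
calibration properties pin them down: white noise gives
$\alpha = 0.5$ (small-sample mean $\approx 0.52$ at $N = 460$, the same mild
upward bias visible in published strong-direction estimates), integrated
white noise gives $\alpha \approx 1.5$, and $\alpha$ increases monotonically
in the AR(1) coefficient. DFA is used strictly as an overall persistence
summary, never as a long-range-correlation claim. Because DFA needs a long
ordered series, it runs on the concatenation of all blocks with the first 4
trials of each removed ($10 \times 46 = 460$ points), not on resampled pairs.

## Bootstrap

Eigen-quantities are noisy functionals of a regression matrix, so all
inference is by pair bootstrap: each iterate resamples the 450
(current, next) pairs with replacement, refits $B$, and recomputes every
derived quantity; 95% CIs are the 2.5/97.5 percentiles of 10000 iterates
(package default; `fast = TRUE` uses 2000, which moves CI endpoints by well
under 5% of their width). For DFA the resampling enters only through the
eigenvector estimate: per iterate the *entire* 460-point concatenated series
is transformed into that iterate's eigencoordinates. Aggregation across
conditions pools raw samples — the pooled CI then reflects both
within-condition estimation uncertainty and between-condition spread, which
is what makes the pooled strong-angle interval wide while the weak-angle
interval stays narrow. Degenerate iterates are dropped and counted rather
than redrawn, preserving iterate independence.

For the scaling law, each iterate resamples every condition's pairs,
recomputes $(\sigma_e, \sigma_{ns}, \beta, \lambda_s)$ ($s$ and the operating
point stay fixed), and fits the cross-condition line, yielding slope and
intercept distributions; a single fit pooling all iterate-points is reported
as a cross-check and agrees with the per-iterate mean to well under 1%.

## The simulator

`simulate_experiment()` generates the eight-condition study the analysis
expects: friction coefficients from ideal stop-times uniform on $[3, 5]$ s via
$\mu = 2L/(g t^2)$ (the exact per-participant values are not published; this
reconstruction follows the stated design rule), an on-GEM operating point at
$x^* = 1$, and per condition a blocked series from the linear update model
with noise specified in eigencoordinates and mapped through $E$ (so the
laboratory-frame noise covariance is $E \,\mathrm{diag}(\sigma^2) E^{\top}$,
$E$ generally non-orthogonal). Defaults are the emulated study conditions:
$\lambda_w = 0.76$, $\lambda_s = -0.03$, $\theta_w = 1^\circ$,
$\theta_s = 80^\circ$, $10 \times 50$-trial blocks.

Choices worth recording:

* **Noise scale** $\sigma_{nw} = \sigma_{ns} = 0.01$ (dimensionless). The
  participants' noise covariance is not published; equal components are a
  neutral choice, and 0.01 puts the RMS goal error near 2.5% of the target
  distance — comfortably inside the <10% skill criterion participants had to
  meet, and small enough that the linearization underlying the analysis
  holds (goal errors agree with $A\mathbf{u}$ to a few percent).
* **Initialization**: $\mathbf{u}_0 = 0$ with a 200-iterate burn-in rather
  than sampling the stationary distribution — simpler and exactly
  seed-reproducible; the burn-in is configurable.
* **Signal-dependent noise is not simulated.** Its leading-order effect on
  the inter-trial dynamics vanishes under linearization, and simulating it
  would require inventing a functional form the analysis never uses.
* **Measurement noise** defaults to 0; 0.02 emulates ~2% apparatus
  precision as a fraction of each component's fluctuation sd (errors are
  then recomputed from the noisy state, as an apparatus would report them).
* **Seeds**: a master seed spawns per-condition sub-seeds deterministically;
  identical seeds give bit-identical series, reports, and JSON files.

The simulator reproduces the statistical structure the analysis assumes —
stationary linear dynamics, Gaussian noise, exact block exchangeability. It
does not emulate motor learning transients, fatigue or drift of the operating
point, within-trial control, or heavy-tailed noise. Tests passing on it
therefore validate the estimator chain under the model's own assumptions;
they cannot certify behavior on data that violate them, which is precisely
what the point-estimate/bootstrap diagnostics (complex-eigenvalue counts,
alignment-label warnings) are there to flag on real data.

## Coordinate invariance

Variance-based signatures of a task manifold depend on the coordinates used
to measure execution. The package makes the dependence explicit:
`pca_whitening_transform()` constructs from the sample covariance
$\Sigma = C \Lambda C^{\top}$ the whitening map $P = \Lambda^{-1/2}
C^{\top}$ and returns the coordinate change with Jacobian $T = P^{-1}$, so
new-coordinate fluctuations $\mathbf{v} = T^{-1}\mathbf{u} = P\mathbf{u}$
have identity sample covariance and the tangent/normal variance ratio
collapses to 1. (The transform is returned via its Jacobian $T$, the matrix
that maps new fluctuations back to old, keeping `transform_fluctuations()`'s
convention $\mathbf{u} = T\mathbf{v}$ consistent for every transform.)
Under any invertible $T$ the refitted matrix is exactly $T^{-1}\hat B T$ on
the same pairs — same eigenvalues to machine precision — and the GEM maps
through $A \mapsto AT$, so the weak-tangent/strong-transverse arrangement
survives in the new coordinates. Stability detects the GEM; variance does
not. Only linear transforms are exercised in tests; nonlinear ones enter
through their Jacobian at the operating point, which is all the linearized
analysis ever sees.

## Problem sizes and numerics

The shipped analysis scripts and tests use: 8 conditions × 450 pairs for
estimation; 2000 bootstrap iterates in the default scripts (10000 via
`--full`, the reference setting) — pooled means are insensitive to this
choice and CI endpoints move by <5% of their width; 200 seeds for recovery
and calibration summaries; 400-iterate bootstraps for coverage sweeps.
Degenerate OLS inputs (rank-deficient current-state covariance), complex or
repeated ($<10^{-9}$) eigenvalues, zero-variance series and unstable
($|\lambda| \ge 1$) specifications all raise immediate errors rather than
propagating NaNs. Ties in the magnitude labeling break toward the larger
algebraic eigenvalue.

## Limitations

Two body-state dimensions only (one-dimensional GEM); single linear update
map per condition (no trial-varying or higher-order dynamics); percentile
bootstrap only (no BCa or block bootstrap); DFA exponents at $N = 460$ carry
the documented small-sample bias and are not evidence about long-range
correlation; the hypothesis verdicts use deliberately loose default
thresholds (10°, 0.2, 15°, 0.2) because the underlying predictions are
orderings, not point values — raw estimates and CIs are always reported
alongside the booleans, and the thresholds are configurable.

```{r, eval = FALSE}
library(gemfluct)
exp8 <- simulate_experiment(seed = 1)
report <- run_pipeline(exp8, n_iter = 2000, seed = 1)
report$aggregate$pooled$lambda_w
report$aggregate$hypotheses$H4
write_report(report, "report.json")
```
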