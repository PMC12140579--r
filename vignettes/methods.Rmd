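---
title: "Models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, the numerical choices, and known
limitations.  It states no empirical result that the test suite does not
itself compute.

## 1. The task and its encodings

The spatial stimulus-response-compatibility (SRC) paradigm alternates
blocks of spatially compatible (Pro) and incompatible (Anti) two-choice
reaction trials.  The default protocol is fixed by the study design the
package emulates: 24 blocks (12 per condition, balanced pseudorandom
order), 13–16 trials per block, 0.2-s lateralized stimuli with
equiprobable sides, inter-onset intervals uniform on [2, 4.5] s, rests
uniform on [15, 19] s, a 2-s instruction before each block, TR = 2.03 s.
Pseudorandomization is a seeded uniform shuffle of a balanced condition
vector; no further order constraints are imposed (the original
randomization scheme is unknown, and balanced shuffling is the weakest
assumption consistent with it).  Jitters are drawn from continuous
uniform distributions on the printed intervals.

Two model-input dialects are supported.  In the *event* dialect the
driving input is 1 on every trial's [onset, onset + 0.2 s) window and
the modulatory input is 1 on Anti-trial windows; in the *block* dialect
boxcars span whole blocks.  Inputs are binary (not mean-centered), so
the A matrix is the coupling of the unmodeled baseline and B the
condition-specific additive change.  The 2-s instruction period is not
encoded as a model input.  A block's duration is defined as the span
from its first trial onset to its last onset plus one nominal 2-s trial
slot (the protocol prints no explicit block-end event).

The behavioral target is the mean reaction time over valid
Anti-condition trials; trials with RT < 150 ms or RT > 1500 ms are
excluded, with strict inequalities (a boundary RT is retained — the
literal reading of the printed filter).

## 2. Forward model

Neural states follow the bilinear state equation
`dz/dt = (A + Σ_k B_k u_k) z + C u`.  On the microtime grid (default
dt = TR/16 ≈ 0.127 s, the coarsest grid that resolves 0.2-s events)
inputs are piecewise constant, so the integrator advances with the exact
matrix-exponential step `z(t+dt) = E z + J⁻¹(E − I) C u`, `E = e^{J dt}`;
step operators are cached per unique input pattern.  Linear test cases
are therefore reproduced to machine precision, and stability of a
candidate A is a hard precondition checked via its eigenvalues.  Grid
convergence is assessed with the stimulus function held fixed (its
boxcars are defined on the encoding grid) while the integration grid is
refined; re-quantizing the trial onsets on a finer grid would instead
measure a property of the encoding, not of the solver.

The observation model is the extended balloon model per node
(vasodilatory signal, flow, volume, deoxyhemoglobin; fixed canonical
constants κ = 0.64 s⁻¹, γ = 0.32 s⁻¹, τ = 2 s, α = 0.32, E₀ = 0.4,
V₀ = 0.04, shared across nodes), integrated by RK4 with z held constant
over each microtime step.  Output is the deviation from hemodynamic
baseline; empirical series are mean-centered per node before fitting, so
arbitrary offsets are ignored.  Self-connections are parameterized on a
log scale, `A_ii = −0.5 exp(a_i)`, which keeps any candidate baseline
stable in its diagonal part.

## 3. Inversion

`invert_dcm()` runs a variational-Laplace scheme: a Gaussian posterior
over the free parameters (all A off-diagonals, all self log-scalings,
all B entries, C restricted to the driving nodes — 164 parameters for
the 9-node network) is obtained by Gauss–Newton ascent on the free
energy with Levenberg-style damping.  Jacobians are one-sided finite
differences (step 1e-4) of the C++ forward model, batched so the input
pattern decomposition is shared.  Candidate steps are screened against
the current Jacobian's free energy and then confirmed against a fully
recomputed one; only confirmed increases are accepted, so the recorded
free-energy trace is non-decreasing by construction (tolerance 1e-9 per
step).  Per-node observation precisions are point-estimated by a damped
fixed-point update, again accepted only if the free energy rises.
Convergence is declared after three consecutive relative changes below
1e-4 (maximum 128 iterations).  Explained variance is
`1 − var(y − ŷ)/var(y)` averaged over non-constant nodes and clipped at
zero; subjects below 0.10 are flagged for exclusion.

Priors are zero-mean shrinkage priors: A off-diagonal variance 1/64,
self log-scaling 1/256, C 1, and B 1/16.  The modulatory variance is
deliberately tighter than the conventional unit variance: with 0.2-s
event-related modulation windows most B directions are barely
identified, and under a unit prior their posterior means absorb
observation noise (posterior spread well above any plausible modulation)
instead of shrinking to zero.  1/16 still supports |B| up to ~0.75 Hz,
larger than any planted modulation.

### A structural limit on per-subject recovery

With the driving input restricted to bilateral IPS and every stimulus an
identical 0.2-s impulse, the data constrain only the action of (A, B) on
the low-dimensional subspace the trajectories explore, smoothed through
the hemodynamic response at TR ≈ 2 s.  The package's own experiments
(reproduced in the acceptance suite) show the consequence: noise-free
data recover the generating parameters well (the 1827 scan values pin
the 164 parameters), but at any realistic SNR the likelihood has a broad
ridge — initializing the optimizer at the generating truth and letting
it converge moves the solution far from truth while changing free energy
by a fraction of a nat.  Pooled true-vs-estimated correlation saturates
near 0.3–0.4 regardless of data quantity or prior width.  The
corresponding acceptance criterion (pooled correlation ≥ 0.8) is
asserted at its stated threshold and is expected to fail; the suite
keeps it red rather than weakening it, because the failure is a property
of the design, not of the estimator (two-node problems, where the input
excites the whole state space, are recovered essentially exactly).
Group-level (PEB) analyses remain well calibrated because they pool the
identifiable fraction across subjects.

## 4. Group level: PEB and BMR

The second level is a Bayesian GLM with the two-column design matrix
(ones; covariate mean-centered within the sample at hand — inside the
prediction workflow that is the training fold only).  Each connectivity
parameter is modeled independently: subject posterior means are the
data, subject posterior variances enter as known first-level
uncertainty, and one between-subject variance component per parameter is
profiled by marginal likelihood on a log grid.  Cross-parameter
posterior covariance is not propagated — the downstream masking only
consumes per-parameter marginals, and the factorization makes the
exhaustive reduced-model search exact and linear in the number of
parameters.  Group effect priors are zero-mean with the parameter-class
first-level variance on both design columns.

Posterior probability of an effect is defined by Bayesian model
comparison: PP = 1/(1 + exp(−ΔF)) where ΔF is the evidence change
between the with-effect and without-effect reduced models, computed by
the analytic Gaussian BMR identity (`reduced_log_evidence()`).  The same
definition powers `pp_mask()` (strict PP > 0.95 by default) and
`bmr_search()`, so the two selection routes agree by construction on
factorized problems.  For generic joint Gaussians, subsets are
enumerated exhaustively up to 16 free parameters and pruned greedily
beyond that; model-averaged PPs use the softmax of model evidences.

## 5. Prediction workflow

Subjects are split into k folds (default k = 5; 10-fold and LOOCV are
supported).  Per training fold, PEB (or BMR) on the training subjects
selects parameters whose covariate-column PP exceeds 0.95; if none
passes, the single highest-PP parameter is used and the event recorded
(every fold stays scorable while weak selection remains visible).
Masked posterior means are z-scored by training-fold statistics and fed
to glmnet (LASSO or ridge); the penalty is chosen by inner 5-fold CV
over a 30-point logarithmic path, using the one-standard-error rule
(the strongest penalty within one SE of the CV optimum) — the plain CV
minimum was observed to leave spurious nonzero coefficients on
pure-noise features.  All folds' test predictions are pooled into one
Pearson r per repetition (not a per-fold average), 100 repetitions by
default.  Two calibration guards apply to the pooled correlation, both
motivated by null simulations.  First, the pooled accuracy is the
pooled *within-fold* correlation: predictions and targets are both
centered within each test fold before correlating.  A fold's regression
intercept equals its training-fold mean target, which anti-correlates
with the held-out targets under exchangeability — with raw pooling,
shuffled-target null accuracies are biased to roughly −0.1 to −0.2
instead of 0, while two-sided centering is unbiased and scores a
perfect predictor at exactly 1.  Second, a
repetition in which every fold collapses to an intercept-only model is
scored r = 0 with a note: such predictions only echo training means and
carry no subject information (under LOOCV, whose singleton folds cannot
be centered, they would otherwise score r = −1 by pure training-mean
echo).  Permutation tests shuffle the
targets, rerun the full round including selection, and report
p = (1 + #{null ≥ observed})/(1 + n); both the mean-vs-null p and the
per-repetition exceedance fractions are returned, since the source
description is ambiguous about which was used.  Cohen's d uses the
pooled n−1 standard deviation.  All randomness flows from one seed
through labeled FNV-1a sub-streams, which is what makes the leakage
guard bitwise-testable.

The FC arm computes full task-evoked FC (Pearson) and task-residual FC
(residuals against HRF-convolved task regressors plus intercept; a raw
boxcar option exists because the source is silent on convolution — the
convolved form matches standard GLM practice).  CPM selection keeps the
top ⌈0.1E⌉ most positively and most negatively target-correlated edges
(ceiling; ties broken by edge index) and the union feeds the same
regression machinery, edges as separate features (not summed).  No
Fisher z-transform is applied by default.

## 6. The synthetic cohort

`sample_cohort_truth()` states the world the tests live in: 60 subjects
by default; an RT-like score ~ Normal(0.55 s, 0.08 s) truncated to
[0.15, 1.5] s; an age-like score ~ Uniform(18, 85) years.  Group-mean A
is a sparse set of strong couplings (each off-diagonal present with
probability 0.25 at |0.20| ± 0.05 Hz, random sign) over a weak
N(0, 0.02) background — magnitudes typical of task-fMRI effective
connectivity reports — redrawn until stable; self-connections are
log-normal around −0.5 Hz.  The age effect (0.005 Hz/year) is planted on
four A edges, the RT effect (2 Hz/s) on four disjoint B edges, plus four
nonzero-mean B edges as distractors; per-edge i.i.d. Gaussian parameter
noise (sd 0.03 Hz) creates subject variability.  The driving gain is
0.5 ± 0.05 into bilateral IPS.  Observation noise is white Gaussian per
node with sd = sd(node signal)/SNR, floored at one quarter of the
strongest node's level (a silent ROI must not receive unrealistically
clean data); target SNR = 3, chosen so that inversion explains well over
10% of variance on essentially all subjects — the calibration rule the
exclusion threshold implies.

What the generator does *not* emulate: temporal autocorrelation and
drifts (the emulated preprocessing removes them), motion and
physiological artifacts, hemodynamic variability across nodes or
subjects, ROI-extraction noise, and any nonlinearity beyond the balloon
model.  A green test therefore establishes that the *pipeline* behaves
correctly on data satisfying its own assumptions — not that real fMRI
meets those assumptions.

## 7. Numerical conventions

Matrices are stored with row = target, column = source (so `dz = A z`
reads canonically); text export transposes to row = "From",
column = "To", and edge lists always carry explicit from/to labels.
File numerics are written with 12 significant digits.  Run
configurations are JSON against a versioned key whitelist (unknown keys
rejected by name); YAML is not supported because no YAML parser is part
of the supported dependency set.  "Switched off" in model reduction
means a reduced prior variance of 1e-8 (exact zeros are handled
separately by fixing parameters at their prior mean).  The exhaustive
BMR cap (16 parameters) keeps 2^k enumeration under a second.

## 8. Known limitations

Per-subject recovery of the full 164-parameter model is
information-limited under this paradigm (section 3); stochastic and
spectral DCM variants, two-state neuronal models, hemodynamic-parameter
estimation, AR noise, multi-column PEB designs, and volumetric I/O are
out of scope.  LOOCV runs a single deterministic split (its repetitions
would be identical).  The permutation test reruns feature selection per
iteration, which is the expensive but leakage-free variant.
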