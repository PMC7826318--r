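---
title: "Latent differential equation modeling of oscillating panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent differential equation modeling of oscillating panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Many psychological and physiological processes self-regulate: perceived
stress, affect, or hormone-driven symptoms drift away from a personal
set-point and are pulled back, often overshooting, producing damped
oscillations. With intensive longitudinal designs — many persons, daily
measurements over a few weeks — one wants the *dynamics*: how fast the
process cycles (frequency), how quickly deviations die out (damping), and
the substantive wavelength of the cycle.

`ldefit` implements the latent differential equation (LDE) approach to
estimating the damped linear oscillator (DLO)

$$\ddot f_{jt} = \eta\, f_{jt} + \zeta\, \dot f_{jt} + e_{\ddot f_{jt}},
\qquad e_{\ddot f_{jt}} \sim \mathcal N(0, V_{e_{\ddot f}}),$$

for persons $j$ oscillating about person-specific equilibria $m_j$, with
$\eta$ and $\zeta$ assumed constant across persons. The process oscillates
iff the discriminant $-\eta - \zeta^2/4$ is positive, and the wavelength is
$\lambda = 2\pi / \sqrt{-\eta - \zeta^2/4}$. Because $\eta$ and $\zeta$
combine under a square root, seemingly small differences in either
parameter move $\lambda$ a lot; `wavelength()`'s documentation and the test
suite contain a constructive example (10% in $\eta$, >20% in $\lambda$).
This sensitivity is why the embedding-dimension diagnostics below matter.

## From panel to model: time delay embedding

Each person's series is cut into overlapping windows of length $D$ (lag
$\tau$, default 1, between window columns) and the windows are row-bound;
the per-series blocks are then column-bound, giving a $D \cdot P$-column
matrix for $P$ indicator series. Windows never span two persons, and
skipped occasions enter windows as missing cells rather than silently
compressing time.

The latent derivatives $(f, \dot f, \ddot f[, f^{(3)}, f^{(4)}])$ load on
the window through a *fixed* Taylor basis: for lag offset $o_i = (i -
(D-1)/2)\,\Delta t$ and derivative $k$, the loading of indicator $s$ is
$l_s\, o_i^k / k!$ (with $l_1 \equiv 1$). Offsets are centered at the
window midpoint; odd $D$ gives the familiar integer offsets
($-2\ldots2$ at $D=5$), even $D$ extends the same symmetric pattern with
half-integer offsets. Centering keeps the zeroth derivative referenced to
the middle of the window for any $D$.

Two models are available:

* **SOLDE** (order 2): latents $(f,\dot f,\ddot f)$; one structural
  regression $\ddot f$ on $(f, \dot f)$ with coefficients $(\eta,\zeta)$
  and residual variance $V_{e_{\ddot f}}$.
* **FOLDE** (constrained order 4): adds $f^{(3)}$ and $f^{(4)}$ via two
  further regressions — $f^{(3)}$ on $(\dot f,\ddot f)$ and $f^{(4)}$ on
  $(\ddot f, f^{(3)})$ — *sharing* $(\eta,\zeta)$. Only the two extra
  residual variances are new free parameters, so SOLDE is nested in FOLDE
  with exactly 2 degrees of freedom. The higher derivatives harvest extra
  time-structured variance, which is particularly helpful when $T$ is
  small.

The model-implied moments are standard latent-variable algebra:
$\Sigma = L \Psi L' + \Theta$ with
$\Psi = (I-A)^{-1} \Phi^* (I-A)^{-\top}$, where $A$ carries the structural
regressions, $\Phi^*$ the exogenous $(f,\dot f)$ covariance plus the
structural residual variances, and $\Theta$ is diagonal with each series'
unique variance repeated across its $D$ columns ("time-constant dynamics").
Row means are $m_j$ propagated through the zeroth-derivative loading
column.

## Estimation

`fit_lde()` maximizes the full-information ML likelihood: each embedded
row contributes the normal log-density of its *observed* cells only
(missing-at-random assumption), with missingness patterns grouped and
their Cholesky factors cached. Key choices:

* **Rows are treated as independent** despite the window overlap. This is
  the standard LDE estimation convention and is what makes the method a
  structural equation model; it biases standard errors downward, so all
  reported SEs are explicitly *naive*.
* **Person equilibria are profiled out.** Given the structural parameters
  the ML estimate of each $m_j$ is closed-form generalized least squares,
  so the optimizer works on the ~11–13 structural parameters only. The
  profiled optimum is exactly the joint optimum; reported estimates,
  log-likelihood and SEs refer to the full joint parameter vector
  (2 + (P−1) + 3 + (1 or 3) + P + N parameters).
* **Transformed scale.** Variances are optimized on the log scale; $\eta$
  and $\zeta$ are unbounded, and oscillation is checked post hoc rather
  than imposed.
* **Restarts.** If an attempt fails, up to `max_extra_attempts` (default
  30) restarts perturb the best solution so far by Uniform($-h$, $h$) per
  parameter on the transformed scale ($h$ = 1 by default; the magnitude
  used by the try-hard tooling this mirrors is undocumented, so it is
  configurable).
* **Convergence.** An attempt converges when BFGS reports success *and*
  an iterated fresh-restart polish cannot improve the objective beyond
  $10^{-6}(1+|\text{objective}|)$. A gradient-norm threshold was
  deliberately not used for the flag: gradient norms are not scale-free —
  at very low measurement noise the optimum's curvature is enormous and a
  "large" gradient corresponds to a negligible parameter displacement.
  The gradient norm is still reported as a diagnostic.
* **Starting values.** The data give them: $\eta_0 = -(2\pi/(T/2))^2$
  (a wavelength of half the series length), $\zeta_0 = 0$, loadings from
  relative within-person spreads, variances from within-person moments.

`likelihood_ratio_test()` compares nested fits, clipping negative
statistics (optimizer noise) to zero with a warning.

## Choosing the embedding dimension

$D$ is bounded below by identification ($D \ge$ number of latent
derivatives) and above by the Nyquist limit: the window span
$(D-1)\tau\Delta t$ must stay *strictly* below the wavelength
(`nyquist_check()`; advisory, because $\lambda$ is only known after
fitting). Within those bounds, `scan_embedding()` fits the model
independently at each $D$ and applies a stabilization rule to the $\eta$
sequence. The criterion in the literature is visual ("find the elbow");
an algorithmic package needs a rule, so two interpretations are provided:

* **relative-change** (default): the smallest $D$ whose $\eta$ all later
  $D$ stay within 10% of — requiring persistence guards against transient
  plateaus, and the last scanned $D$ can never qualify on its own, so a
  never-stabilizing sequence returns no selection;
* **max-curvature**: the interior $D$ with the largest absolute discrete
  second difference of $\eta$.

Both are documented as interpretations, not prescriptions; the 10%
threshold is this package's own default.

## Factor scores and vector fields

After fitting, per-row estimates of the latent derivatives come from the
**regression** method ($\hat F = \Psi L' \Sigma^{-1}\tilde w$, which
weights by the latent covariance and shrinks) or the **Bartlett** method
($\hat F = (L'\Theta^{-1}L)^{-1}L'\Theta^{-1}\tilde w$, conditionally
unbiased: noiseless rows are recovered exactly). Rows are centered with
the *fitted* $\hat m_j$, not person sample means, consistent with the
model's mean structure. Rows with fewer observed cells than latent
derivatives are skipped with a message.

`vector_field()` bins the $(f, \dot f)$ plane (default a 10×10 grid over
the central 95% of scores, arrows only for bins with ≥5 rows — the
defaults are this package's choice, gridding being unaddressed in the LDE
literature) and draws the mean flow $(\dot f, \ddot f)$ per bin. Under the
DLO the analytic flow is $(\dot f, \eta f + \zeta\dot f)$, so arrows near
the $\dot f = 0$ axis should show $\ddot f \approx \eta f$ — a visual
check the test suite automates. In simulations the regression-method field
tracks the analytic flow more cleanly, consistent with it exploiting the
latent derivative covariance.

## The synthetic-data generator

`simulate_panel()` states the world the package is validated in: $N=41$
persons, $T=56$ daily occasions, $P=3$ indicator series (loadings 1, 0.8,
1.2), equilibria $\mathcal N(15, 4^2)$ (a perceived-stress-scale-like
set-point), initial displacement SD 5 and velocity SD 0.5 (oscillation
amplitudes of a few scale points), measurement noise SD 1 per series, and
dynamics $\eta=-0.0095$, $\zeta=-0.05$ (wavelength ≈ 66.7 days, mild
damping). $N$, $T$ and the dynamics mirror the diary-study scale this
methodology targets; the remaining magnitudes are realistic choices fixed
once, documented here, and not tuned.

What the generator deliberately does *not* emulate: dynamic (process)
noise is off by default, because the LDE residual cannot distinguish
endogenous from exogenous sources — an Euler–Maruyama process-noise option
exists for robustness experiments only; missingness is MCAR (the simplest
mechanism consistent with MAR estimation); initial conditions are
independent of equilibria; and $\eta$, $\zeta$ are identical across
persons. A green test suite therefore establishes correct recovery under
a correctly specified, person-homogeneous, measurement-noise-only world —
not robustness to heterogeneous dynamics or model misspecification.

## Numerical notes and limitations

* $(I-A)$ is unit lower triangular; $\Psi$ is formed by forward
  substitution, which cannot be condition-limited even when the optimizer
  wanders to absurd $(\eta,\zeta)$ during line search.
* Non-positive-definite observed submatrices of $\Sigma$ make a
  likelihood evaluation return $-\infty$ (mapped to a large finite
  penalty inside the optimizer), never an exception.
* SEs use the finite-difference observed information on the transformed
  scale, mapped back by the delta method; they are naive (see above) and
  omitted (`se = FALSE`) in large simulation sweeps for speed.
* The LRT between SOLDE and FOLDE involves variance parameters near their
  boundary under a true second-order process, so its null distribution is
  conservative; the test suite asserts a rejection rate at or below
  nominal, not equal to it.
* Boundary effects (bias in the first/last embedded rows of short series)
  and likelihood-based $D$ selection are out of scope.
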