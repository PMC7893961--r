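---
title: "Hierarchical non-stationary Gaussian processes for animal movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical non-stationary Gaussian processes for animal movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movegp)
```

## The model

Telemetry data give timestamped 2-D observations $x(t_i)$ — positions, or
velocities obtained by finite differences — which we model as a latent
function plus white measurement noise,

$$x(t) = f(t) + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_m^2),$$

with a Gaussian-process prior $f \sim \mathcal{GP}(m(t), K(t, t'))$. The two
coordinates are treated as independent univariate GPs sharing one covariance
function; for animal movement the gain from explicitly correlated outputs is
usually negligible, while the shared covariance keeps the movement
parameters interpretable.

The covariance kernel is where the movement model lives. A stationary
Ornstein–Uhlenbeck (OU) process — the classic home-range / persistent-velocity
random walk $dx = -\nu (x - m)\,dt + \eta\,dW$ — corresponds exactly to the
Matérn 1/2 (exponential) kernel

$$K_{OU}(t, t') = \sigma_k \exp(-|t - t'| / L),$$

with lengthscale $L = 1/\nu$ and zero-lag variance
$\sigma_k = \eta^2 / (2\nu)$ (`ou_to_kernel()` / `kernel_to_ou()`). Animals
do not keep one behaviour all day, so we replace the stationary kernel by
its non-stationary generalization (`nonstationary_matern12_cov()`), in which
amplitude $\sigma(t)$ and lengthscale $L(t)$ vary smoothly over time. Those
latent movement parameters are themselves given lower-level GP priors on a
small set of $m \ll n$ support points,

$$\tilde\sigma(t) \sim \mathcal{GP}(\mu_\sigma, K_\sigma), \qquad
  \tilde L(t) \sim \mathcal{GP}(\mu_L, K_L),$$

passed through an exponential transform for positivity, and interpolated to
the data times by the noiseless GP conditional mean (a subset-of-regressors
representation; values at the support points are interpolated exactly). The
mean function gets a zero-mean GP prior per coordinate. Any of the three
components may instead be a fixed value or an estimated constant
(`movement_model()`), in which case the model collapses back towards a
standard OU fit.

Structure is encoded through the lower-level kernels: a strictly periodic
kernel (`periodic_kernel()`, period fixed to 24 h or 1 yr) for diurnal or
annual cycles, and the quasi-periodic product of a periodic and a squared
exponential kernel (`quasiperiodic_kernel()`) for an annual pattern that
drifts across years, e.g. a shifting migration route.

The joint unnormalized posterior multiplies the data likelihood
$N(x \mid m, K_{NS} + \sigma_m^2 I)$ over conditionally independent segments
and individuals, the latent GP priors, and weakly informative $N(0, 2^2)$
priors on every sampled scalar (log kernel hyperparameters, latent prior
means, log constants, $\log \sigma_m$); the prior scale covers three orders
of magnitude on the natural scale of each positive parameter.

## Scalability: local GP experts

Exact GP likelihoods cost $O(n^3)$. Two structural facts rescue large
telemetry sets: individuals are conditionally independent given the latent
movement parameters, and a long trajectory can be split into consecutive
segments (`segment_trajectory()`) that are approximately independent
local GPs when the segment span is much longer than the correlation
lengthscale. The approximation error in the log likelihood falls below 1%
once the span exceeds about $50 L$ (this is tested against the exact
likelihood).

`prepare_likelihood()` adds a further exact saving: segments whose relative
time grids coincide and whose dynamic latents are all strictly periodic
with segment starts congruent modulo the period provably share one
covariance matrix, so a ten-day fit at a fixed collar schedule needs one
Cholesky factorization per posterior evaluation, not ten. Numerically, time
grids are matched after rounding to $10^{-9}$ time units, far below any
collar's timing jitter.

## Inference

Sampling uses the Metropolis-adjusted Langevin algorithm: proposals drift
along the gradient of the log posterior, which is computed analytically
throughout, except that the Jacobian of the small latent-realization map
with respect to kernel log-hyperparameters is formed by central differences
(step $10^{-4}$ on the log scale; the Hastings correction uses the same
gradient function in both directions, so the chain is exact regardless).
Before sampling, an L-BFGS search on the analytic gradient locates the
posterior mode — first in whitened coordinates, where the objective is
well conditioned, then polished in the sampling coordinates, whose density
differs by a hyperparameter-dependent Jacobian — and the local curvature
is measured by finite differences of the gradient; the proposal is then
preconditioned with the inverse curvature (spectrum clipped to the largest
prior variance), chains start overdispersed around the mode, and a
Robbins–Monro recursion tunes the step size towards the MALA-optimal
acceptance rate 0.574 during burn-in. All adaptation freezes at the end of
burn-in, so the post-burn-in chains are valid Metropolis–Hastings.
Convergence is monitored by the Gelman–Rubin potential scale reduction
factor and autocorrelation-based effective sample sizes over all sampled
quantities (`psrf()`, `effective_sample_size()`).

### Whitened and centered latent coordinates

Two coordinate systems are available for the latent functions
(`latent_gp(parameterization = )`). In the *whitened* system the sampler
moves $w \sim N(0, I)$ with support values $f = \mu + R w$, $R$ the
Cholesky factor of the support kernel matrix: the prior is isotropic, which
is the right choice when the data constrain the latent function weakly. In
the *centered* system the support values $f$ are sampled directly under
their GP prior $N(\mu \mathbf{1}, K(\theta))$, with analytic gradients of
the prior in $f$, $\mu$ and $\log\theta$. When the data pin the latent
function tightly — as in both synthetic studies here, where more than a
thousand fixes inform forty support values — the whitened coordinates
develop a curved ridge: any move of the kernel amplitude must be matched by
a coordinated rescaling of the whole whitened vector to leave $f$, and
hence the likelihood, unchanged. No linear preconditioner can follow that
curve, and chains of practical length stall on the hyperparameters. The
centered system removes the ridge (hyperparameters interact with the
likelihood only through the cheap prior term), and the same chains converge
comfortably; it is therefore used for the bundled study fits, while
whitening remains the default contract and is what the prior-equivalence
tests exercise. For very large data sets the package also supports the
optimize-then-sample workflow: point-optimize hyperparameters with Adam on
a data subset (`optimize_hyperparameters()`), freeze them, and sample the
latent functions.

## Synthetic study designs

The package validates itself end to end on two generators whose conditions
are fixed, not tuned.

**Daily activity.** A 2-D OU position process with mean at the origin and
mean-reversion rate $\nu = 12$ (time in hours: a five-minute relaxation
time), whose SDE noise amplitude follows a sawtooth with a one-day period —
base level 0.5, linear rise from 5 am to a peak of 3.0 at 5 pm, sharp drop —
smoothed by a circular Gaussian of width 1 h. The sawtooth levels and
smoothing width are not dictated by the design, so recovery is always
judged against the generated function itself, never against plotted axis
values. Ten days at ten-minute fixes (1,440 points) are simulated by the
exact per-step OU transition with left-endpoint parameters; the exact
transition (rather than Euler–Maruyama) removes discretization bias from
every acceptance check downstream. The fit uses a periodic amplitude
kernel ($P = 24$ h, 40 support points, spacing 0.6 h), an estimated
constant lengthscale, and 4 chains of 10,000 MALA steps (2,500 burn-in,
thinned by 15). Recovery is assessed on the kernel scale, where the
quasi-stationary amplitude is $\eta(t)/\sqrt{2\nu}$.

**Shifting migration.** The north–south mean oscillates annually between a
southern range at $y = 0$ and a northern range that rises from 8 towards 10
over the years, via $g(t) = 1 + \cos(2\pi t)\sqrt{(1+b^2)/(1+b^2\cos^2 2\pi
t)}$ with $b = 5$ and $m^y_t = (5 - e^{-t/3})\,g(t)$. The walker is an OU
process around this route with $\nu = 26\,\mathrm{yr}^{-1}$ (a two-week
reversion time) and $\eta = 3.6$, i.e. a stationary spread of about 0.5
position units around a route of amplitude ten — strong enough signal to
learn the route, realistic enough to leave visible wander. Three years of
weekly fixes (157 points) are fitted with estimated constant $\sigma$ and
$L$ and a quasi-periodic mean kernel ($P = 1$ yr and $\lambda = 5$ yr
fixed; 36 monthly support points per coordinate). The kernel's free
hyperparameters — amplitude $a$ and periodic lengthscale $l$ — see only
three annual cycles and are weakly identified, so this study uses the
optimize-then-sample workflow: $(a, l)$ are point-optimized with Adam and
frozen, then the latent route and the movement constants are sampled with
4 chains of 12,000 steps (4,000 burn-in, thinned to 2,000 draws per
chain). Sampling $(a, l)$ jointly is supported, but their flat,
funnel-shaped posterior needs chains several times longer than everything
else in the problem to clear the same convergence bar.

What these simulations do *not* emulate: irregular and missed fixes,
heavy-tailed GPS errors, terrain and boundary effects, site fidelity and
social interactions. Passing tests therefore demonstrate correct inference
under the model class, not robustness to real-data pathologies — the
posterior-predictive step/turn machinery (`steps_and_turns()`,
`compare_distributions()`) exists precisely to expose such mismatches on
real data, and the reversal-excess property test shows it detects them.

## Numerical choices

* Jitter: $10^{-6}$ times the mean diagonal, doubled up to three times on
  Cholesky failure, then an error. The data covariance additionally
  carries $\sigma_m^2$ on the diagonal.
* Latent support kernels carry a small nugget ($10^{-4}$ on the O(1)
  untransformed latent scale, configurable). Smooth periodic kernels on a
  40-point grid are numerically near-singular, and without the nugget the
  prior's unbounded curvature destabilizes gradient-based sampling; with
  it, latent functions may deviate from strict interpolation by about
  0.01, far below their posterior spread.
* Periodic kernels evaluate $\sin^2(\pi |t - t'|/P)$ on raw lags; no
  modular wrapping is needed and time shifts by multiples of $P$ are exact.
* The amplitude parameter of the stationary kernel is the zero-lag
  variance, making the stationary kernel the exact constant-parameter
  limit of the non-stationary one (tested to machine precision).
* Forward finite differences for velocities sit on the left timestamp,
  matching the causal OU convention; segmentation keeps short tails as
  their own segment rather than discarding data (a final single point is
  merged into the previous segment).
* Support points are evenly spaced, endpoints included on plain intervals;
  periodic domains drop the duplicate wrap point.
* A proposal whose posterior or gradient is non-finite is rejected rather
  than fatal; a non-finite *current* state is an error, since it indicates
  a broken chain.
* Step/turn resampling matches window boundaries to the nearest fix within
  10% of the window and breaks the sequence where no fix qualifies; turn
  angles are signed, in $(-\pi, \pi]$, via planar cross/dot products.

## Problem sizes

The bundled fits are deliberate desk-scale analogues of much larger
analyses (the motivating deployments run to hundreds of thousands of
fixes): 1,440 fixes / 44 unknowns for the daily-activity study and 157
fixes / 76 unknowns for the migration study, each about four to seven
minutes on a single CPU. The local-expert segmentation and
covariance-sharing analysis above is what carries the same code to much
longer records; `scripts/acceptance.R` reruns both studies from scratch.

## Known limitations

* The non-stationary kernel is an approximation to a truly time-varying OU
  SDE; it is excellent when parameters vary slowly relative to the
  relaxation time $1/\nu$ (the regime of both studies) and untested far
  outside it.
* Measurement noise is Gaussian and white; collar-specific error models
  are out of scope.
* Latent means use a zero prior mean; long-term drifts beyond the kernel's
  reach are absorbed only through the kernel amplitude.
* The Laplace preconditioner assumes a roughly unimodal posterior;
  genuinely multimodal posteriors (e.g. aliased periods) would need
  tempering or remodelling.
* Inputs are planar coordinates; projection from geographic coordinates is
  the user's responsibility.
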