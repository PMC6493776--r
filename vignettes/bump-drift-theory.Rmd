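---
title: "Drift and diffusion of bump states under short-term plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift and diffusion of bump states under short-term plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bumpdrift)
```

## The model

A one-dimensional continuous attractor ("ring attractor") stores an analog
variable -- a remembered direction, position, or frequency -- as the center
angle $\varphi$ of a localized packet of elevated firing (a *bump*)
sustained by recurrent excitation.  `bumpdrift` analyzes how reliably such
a network retains $\varphi$ when its recurrent excitatory synapses undergo
short-term facilitation and depression.

Each of $N$ excitatory neurons sits at an angle
$\theta_i = 2\pi i/N - \pi$ and fires at rate
$\phi_i = F(J_i)$, where $F$ is a stationary gain function (with global
inhibition folded into it at its stationary value) and
$J_i = N^{-1}\sum_j w_{ij} s_j$ collects distance-dependent, symmetric
recurrent input.  Each presynaptic neuron carries three synaptic variables
obeying the standard model of short-term plasticity,

$$\dot s = -s/\tau_s + u\,x\,\phi,\qquad
  \dot u = -(u - U)/\tau_u + U(1-u)\,\phi,\qquad
  \dot x = -(x-1)/\tau_x - u\,x\,\phi,$$

with baseline release fraction $U$ (small $U$ = strong facilitation),
facilitation recovery $\tau_u$, depression recovery $\tau_x$, and a slow
(NMDA-like) synaptic decay $\tau_s$.  A stable bump exists when recurrent
excitation is strong and local; depression saturates the synaptic drive at
high rates and is what keeps the bump's amplitude finite.

## The reduction

Because any rotation of the bump is again a stationary state, the
linearized $3N$-dimensional synaptic dynamics $\dot{\delta y} = K\,\delta y$
have a zero eigenvalue whose right eigenvector $e_r = dy_0/d\varphi$ is the
translation mode.  Projecting fluctuations onto the manifold with the left
null vector $e_l$ (normalized to $e_l\cdot e_r = 1$) reduces the network to
a Langevin equation for the center,

$$\dot\varphi = A(\varphi) + \sqrt{B}\,\eta(t).$$

The package computes the left null vector in closed form.  Writing
$t_i = dJ_{0,i}/d\varphi$ for its rate block, the facilitation and
depression blocks follow pointwise from the $u$- and $x$-rows of
$K^T y' = 0$:

$$z_i = t_i\,\frac{u_0\phi_0\tau_x}{1+\tau_x u_0\phi_0},\qquad
  v_i = t_i\,\frac{\tau_u x_0\phi_0}
        {(1+U\tau_u\phi_0)(1+\tau_x u_0\phi_0)},$$

and the normalization $S = y'\cdot e_r$ follows by the chain rule through
the steady-state synapse formulas.  Substituting into the Poisson noise
loadings reproduces the closed-form per-neuron prefactor

$$C_i = \frac{U\left(1 + 2\tau_u\phi_{0,i} + U\tau_u^2\phi_{0,i}^2\right)}
  {\left(1 + U\phi_{0,i}(\tau_u+\tau_x) + U\tau_u\tau_x\phi_{0,i}^2\right)^2},$$

the diffusion strength
$B = \sum_i (C_i/S)^2 (dJ_{0,i}/d\varphi)^2\,\phi_{0,i}$, and drift fields
$A(\varphi_k) = \sum_i (C_i/S)(dJ_{0,i}/d\varphi)\,\Delta\phi_i(\varphi_k)$
for any frozen rate perturbation.  In the static-synapse limit
($U = 1,\ \tau_u \to 0,\ \tau_x = 0$) these reduce to $C_i = 1$ and
$S = \tau_s \sum_i (dJ_{0,i}/d\varphi)^2 \phi_{0,i}'$, the classical
result.  `numeric_null_projection()` recomputes everything from a singular
value decomposition of $K^T$ with no closed-form input and is used
throughout the tests as the independent oracle; on smooth test networks the
two routes agree to better than $10^{-8}$.

Every reported transcription of the normalization constant was re-derived
here from first principles; the closed form shipped in `prefactors()` is
the one that satisfies the numeric null-vector cross-check exactly (its
static limit carries the full factor $\tau_s$, not $\tau_s/2$).

```{r toy}
toy <- toy_ring(N = 64)
th <- attractor_theory(toy$bump)
th
np <- numeric_null_projection(toy$bump)
abs(th$B - np$B) / np$B
```

## Numerical choices

**Spatial derivatives.** All derivatives along the manifold
($dJ_0/d\varphi$, $e_r$) default to spectral (FFT) circular
differentiation, which is exact for band-limited ring profiles; central
differences (`deriv_method = "central"`) carry an $O((2\pi/N)^2)$ error
that dominates the closed-form-vs-numeric comparison already at
$N = 64$.  The spectral route requires smooth profiles, which is why the
oracle-grade toy network uses an analytic softplus gain
(`gain_softplus()`); the saturating threshold-quadratic gain is only
$C^1$ and is kept for solver tests.

**Toy ring.** The smooth toy network uses $w_+ = 14$, kernel width $0.5$
rad, softplus gain ($r = 30$ Hz, center $0.6$, smoothness $0.25$), and
$\tau_s = 100$ ms; with depression in its physiological range
($\tau_x \in [0.1, 0.25]$ s) the bump peak stays between roughly 20 and
120 Hz and the profile's Fourier spectrum decays below $10^{-10}$ within
32 modes, which is what makes $10^{-8}$-level oracle agreement possible at
$N = 64$.

**Bump solver.** `solve_bump()` offers damped fixed-point iteration and a
Newton mode.  With the inhibitory rate frozen into the gain -- the
stationary-inhibition assumption of the theory -- the bump is an
amplitude-saddle of the forward map for conductance-based gains, so the
Newton mode is the default route for those networks; gains whose rate
depends on the rate itself (the mean-voltage correction below) are solved
as a joint fixed point in $(\phi, \langle V\rangle)$.

**Degenerate inputs.** $\tau_x = 0$ is handled exactly ($x \equiv 1$),
`attractor_theory()` refuses $S \le 0$ (beyond the critical depression
time), and `center_phase()` raises an error on (near-)uniform activity
rather than returning an arbitrary angle.

## The conductance-based reference network

The spiking implementation is a two-population conductance LIF ring
(excitatory neurons on the ring, global inhibition, independent external
Poisson drive on fast AMPA-like synapses, recurrent excitation through a
slow channel with spike-based facilitation/depression).  Its stationary
rates are approximated by a first-passage-time gain with the fast-synapse
threshold correction and a mean-voltage correction of the fluctuation
scale; the integration bounds use the threshold potential above and the
reset potential below, the convention that reproduces Monte-Carlo rates.
The physiological constants (capacitances, conductances, reversal
potentials, external drive) are the standard values of the visuospatial
working-memory model family this network descends from; they are *not*
fitted to any output of this package.

`tune_network()` determines the recurrent conductance scales, the
bump-state inhibitory rate and the kernel width so that (i) the uniform
basal state sits at 0.5 Hz (excitatory) and 3 Hz (inhibitory) and (ii) the
bump's rate profile matches the generalized Gaussian
$g(\theta) = g_0 + g_1\exp(-(|\theta|/g_\sigma)^{g_r})$ with
$g_0 = 0.1$ Hz, $g_1 = 40$ Hz, $g_\sigma = 0.5$, $g_r = 2.5$.  Design
choices worth knowing:

* Collocation is imposed exactly on the bump body
  ($\theta \in \{0, g_\sigma/2, g_\sigma\}$); the far tail ($2g_\sigma$,
  a fraction of a Hz) is reported as a residual because the network's
  low-rate tail is set by the gain function and cannot in general be
  collocated simultaneously with the body and the basal state.
* Solver residuals live in input space (through the inverse of the
  monotone rate function), which removes the flat plateaus of saturated or
  silent rates that defeat Newton steps on rate residuals.
* Because the inhibitory reversal equals the leak potential, inhibitory
  self-coupling is purely shunting and saturates; the pair
  $(g_{IE}, g_{II})$ cannot hold both inhibitory operating points, so the
  self-coupling scale is fixed ($T_{II} = 1$) and the inhibitory
  population's external conductance is tuned in its place.
* An outer calibration adjusts the internal collocation targets until the
  *realized* self-consistent bump fits the requested shape
  (`reference_network()`; realized $g_1 \approx 40.3$,
  $g_\sigma \approx 0.50$), and feeds the realized mean rate back into the
  inhibitory equations so the bump-state inhibitory rate is consistent
  with the bump that actually exists rather than with the parametrization.

```{r ref, eval = FALSE}
ref <- reference_network()           # ~20 s; cached per session
attractor_theory(ref$bump)
critical_tau_x(ref$bump, stp_params(1, 1e-6, 0.15, 0.1))  # ~0.22 s
```

With facilitation absent ($U = 1$, $\tau_u \to 0$) the normalization
$S(\tau_x)$ crosses zero at a finite critical depression time; for the
tuned reference bump this sits near 220 ms, and it moves to larger values
as facilitation strengthens.

## What the simulators emulate -- and what they do not

**Stochastic rate network.** `simulate_rate()` integrates the full $3N$
synaptic system with multiplicative Poisson-rate noise (the three equations
of a neuron share one noise increment scaled by $\sqrt{\phi_i}$) by
Euler-Maruyama at $\Delta t = 0.5$ ms.  It emulates the spiking-noise
*variance* exactly at the level the theory assumes -- white, rate-scaled,
perfectly uncorrelated across neurons -- so agreement here validates the
projection algebra, not the Poisson assumption itself.  Development-scale
runs (100-200 repetitions of 15-20 s at $N = 128$) recover the closed-form
$B$ within ten percent.

**Reduced Langevin model.** `langevin_ensemble()` integrates the
one-dimensional equation with a periodic-spline drift field, wrapping to
$[-\pi,\pi)$ each step exactly as the bump-center variable is defined;
$\Delta t = 0.1$ s by default and $0.01$ s in the short distractor
protocol.

**Spiking network.** `simulate_spiking()` is a clock-driven
(exponential-Euler, $\Delta t$ down to $2\times10^{-5}$ s) implementation
at a reduced default scale of $N_E = 200$, $N_I = 50$, with conductances
rescaled as $g = \tilde g/N_{\mathrm{pre}}$.  Three reduced-scale
adaptations are deliberate and documented:

* $g_{EE}$ carries a factor 1.06 compensating the Monte-Carlo-measured
  $\sim$6% overprediction of the rate formula at the bump operating point;
  without it the simulated bump is marginally subcritical.
* Validation repetitions start *on the attractor* (the stationary bump
  rotated to the cue angle) rather than through the Poisson cue protocol:
  at reduced scale the depression depletion accumulated during the strong
  cue reliably destabilizes the handoff at cue offset.  The cue and reset
  protocols are implemented and exercised for what they support (formation
  of a cue-centered state during stimulation; reset to the non-selective
  state).
* Lost-bump exclusion applies the 10 Hz population-max rule to a 0.5 s
  moving average (the instantaneous maximum fluctuates about twice as
  strongly as at full size) plus a physical jump guard: a bump center
  cannot move $\pi/2$ within 100 ms, so larger jumps indicate a transient
  collapse/re-nucleation that must not masquerade as diffusion.

What passing these tests shows is that the projection theory predicts the
slow center dynamics of a network whose fast dynamics it idealizes; what it
does not show is quantitative fidelity of the diffusion approximation for
deeply fluctuation-driven operating points (basal rates of 0.5 Hz), where
Monte-Carlo rates exceed the formula by tens of percent.  That bias is also
the likely reason the absolute working-memory size bounds come out
$\sim$35% below the published ones while their *relative* structure across
plasticity and noise parameters is reproduced almost exactly (a single
common factor): the published reference coefficients were extracted from
spiking simulations, ours from the rate approximation.

## Problem sizes used by the shipped tests

The packaged test-suite runs the rate-network comparison at $N = 128$
($U = 0.3$, so the 20 s window stays in the linear-response regime, far
from circular saturation) with 200 repetitions, the drift-field recovery on an $N = 800$ toy ring
(100 probe angles, deterministic), frozen-noise ensembles of 200
realizations at $N = 64$, and the spiking validation at $N_E = 200$ with
50 repetitions of 5 s -- sizes chosen so each check resolves its tolerance
without Monte-Carlo noise dominating.

## Known limitations

* The theory is stationary: cue-onset transients of the facilitation
  variables and the initial strong-diffusion phase they produce are outside
  its scope, and the estimators discard the first 500 ms accordingly.
* Drift fields are linear responses; at strong heterogeneity (connection
  loss of half the synapses at moderate $N$) the prediction overestimates
  measured fields by tens of percent, with the correct sign structure.
* The distractor treatment assumes the bump shape is unaffected by the
  distractor input except for the center shift; feedback-inhibition
  corrections are not modeled.
* Weight-jitter heterogeneity is implemented but defaults to zero
  (analyses assume no additive weight noise), and the kernel width and the
  weight-noise standard deviation are deliberately distinct parameters
  (`kernel_width` vs `weight_jitter_sd`) despite the field's habit of
  writing both as a sigma.
* Bernoulli connectivity masks treat autapses like any other connection,
  matching the kernel's inclusion of the diagonal.
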