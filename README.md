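# bumpdrift

Drift and diffusion of bump states in one-dimensional continuous attractor
networks with short-term synaptic plasticity.

Ring-attractor networks store an analog variable (a remembered direction,
location, or frequency) as the center angle φ of a self-sustained packet of
elevated firing. Two slow processes degrade that memory: *diffusion* of the
center caused by spiking noise, and *directed drift* caused by frozen
heterogeneities (missing connections, spread of leak reversal potentials,
weight jitter). `bumpdrift` implements a projection theory that reduces the
3N-dimensional synaptic dynamics — with Tsodyks–Markram facilitation and
depression on the recurrent synapses — to a one-dimensional Langevin
equation

    dφ/dt = A(φ) + sqrt(B) η(t),

with closed-form coefficients. Writing φ₀ᵢ for the stationary bump rates,
J₀ᵢ for the steady inputs and dJ₀ᵢ/dφ for their change under center shifts,

    B = Σᵢ (Cᵢ/S)² (dJ₀ᵢ/dφ)² φ₀ᵢ,
    A(φ) = Σᵢ (Cᵢ/S) (dJ₀ᵢ/dφ) Δφᵢ(φ),
    Cᵢ = U (1 + 2 τᵤ φ₀ᵢ + U τᵤ² φ₀ᵢ²) /
         (1 + U φ₀ᵢ(τᵤ + τₓ) + U τᵤ τₓ φ₀ᵢ²)²,

where S normalizes the left null vector of the linearized synaptic
dynamics, U is the baseline release fraction (small U = strong
facilitation), τᵤ and τₓ are the facilitation and depression recovery
times, and Δφᵢ(φ) are the first-order rate perturbations induced by a
heterogeneity. Facilitation lowers both B and the drift fields; depression
raises both, and past a critical depression time the normalization S
crosses zero and the projection (and the attractor) breaks down.

The package contains, as first-class tested code:

* the STP synapse (rate-based and spike-based, with closed-form steady
  states and Poisson-averaged release),
* the ring network: normalized distance-dependent kernel, bump fixed-point
  solver (damped iteration and Newton), stochastic rate-network simulator
  (Rcpp),
* the manifold projection: Jacobian assembly, closed-form prefactors,
  diffusion strength, drift weights, a numeric left-null-vector oracle,
  critical depression time, system-size scaling,
* frozen-noise machinery: seeded realizations, structural inputs, rate
  perturbations, drift fields, the ensemble-expected squared field
  magnitude, expected displacement, and a network-size solver,
* the reduced Langevin integrator on the circle with periodic-spline drift
  fields,
* estimators: population-vector center decoding, exponential rate
  filtering of spike trains, diffusion estimation with BCa bootstrap
  intervals, drift-field estimation, lost-bump exclusion, mutual
  information between initial and final positions, and the distractor
  paradigm,
* a conductance-based LIF rate reduction (first-passage-time gain with
  fast-synapse and mean-voltage corrections, analytic derivatives), a
  network tuning procedure targeting a generalized-Gaussian bump, and a
  scaled-down clock-driven spiking simulator with spike-based STP (Rcpp).

## Worked example

```r
library(bumpdrift)

toy <- toy_ring(N = 64)                 # smooth analytic ring with a bump
th  <- attractor_theory(toy$bump)
th
#> Ring-attractor projection (N = 64):
#>   S = 8.153, B = 0.169 rad^2/s (554.7 deg^2/s, 17.53 idx^2/s)
#>   STP: U = 0.5, tau_u = 650 ms, tau_x = 150 ms, tau_s = 100 ms

# independent cross-check: numeric left null vector of the Jacobian
np <- numeric_null_projection(toy$bump)
abs(th$B - np$B) / np$B
#> [1] 1.567e-11

# drift field of one sparse-connectivity realization, and its ensemble size
real <- sample_frozen(frozen_noise("connectivity", p = 0.5, seed = 1), 64)
fld  <- drift_field_from_noise(real, toy$bump, theory = th)
fld
#> Drift field on 64 centers: RMS 0.5231 rad/s, range [-0.6765, 0.9047]

expected_sq_field(frozen_noise("connectivity", p = 0.5), toy$bump,
                  theory = th)$total
#> [1] 0.6032
```

`B` is the variance growth rate of the stored angle under spiking noise
(here on a deliberately small, noisy 64-neuron toy); the drift field gives
the deterministic center velocity at every position for one frozen draw of
missing connections, and the expected squared field is its ensemble
variance, predicted in closed form.

The conductance-based reference network is tuned on demand:

```r
ref <- reference_network()     # ~20 s, cached for the session
critical_tau_x(ref$bump, stp_params(1, 1e-6, 0.15, 0.1)) * 1000
#> [1] 219.86   # ms: critical depression time of the unfacilitated network
```

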