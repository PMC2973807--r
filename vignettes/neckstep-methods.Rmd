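---
title: "Tethered diffusion and the kinesin chemomechanical cycle: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tethered diffusion and the kinesin chemomechanical cycle: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neckstep)
```

## The model

Kinesin-1 walks along a microtubule protofilament in 8.2-nm steps, one
tubulin dimer at a time.  Each step requires the rear motor head to release,
diffuse past its partner while tethered by the two flexible neck-linker
peptides, and capture the next binding site.  `neckstep` simulates this as a
one-dimensional hybrid system:

* a **continuous-time Markov chain** over five chemical states — (1) both
  heads bound, (2) one head tethered with no nucleotide, (3) ATP bound with
  the neck linker docked, (4) post-hydrolysis, (5) detached (absorbing) —
  with the rate constants carried by `rate_constants()`;
* an **overdamped Langevin equation** for the position $X(t)$ of the free
  head along the protofilament axis,
  $$\mathrm{d}X = \frac{f_\mathrm{tether}(X)}{\xi}\,\mathrm{d}t +
    \sqrt{2D}\,\mathrm{d}B(t),$$
  with Stokes drag $\xi = 6\pi\eta a$ for a sphere of radius $a = 3$ nm in
  water ($\eta = 10^{-9}$ g/nm·s) and $D = k_BT/\xi \approx 7.3\times10^7$
  nm²/s.

The two are coupled in states 2–4: the head advances one SDE step per time
step $\Delta$, then a single uniform variate is compared against ordered
thresholds $k_i\Delta$ for the chemical channels.  In state 4 (and state 2)
the attachment channel is open only while the head is within ±1 nm of an
allowed binding site (the forward zone spans 7.2–9.2 nm).  Binding snaps
the head to the site centre, the head roles swap, and the coordinate frame
re-centres on the new bound head.  State 1 has no diffusing head and is
simulated with an exact exponential (Gillespie) hold.

Processivity emerges from a race in state 4 between tethered-head
attachment — at rate $k_\mathrm{attach}\,p_\mathrm{zone}$, where
$p_\mathrm{zone}$ is the fraction of time the head spends in the binding
zone — and bound-head release at $k_\mathrm{unbind}$.  The expected number
of steps per run is approximately
$k_\mathrm{attach} p_\mathrm{zone}/k_\mathrm{unbind}$
(`processivity_estimate()`), which makes run length the observable most
sensitive to the tether's mechanics.

## The three tether models

ATP binding docks the bound head's neck linker, shifting the tether centre
4.1 nm plus-endward; the free head is then held by its own 14-residue
linker (17 in the extension mutant).  Three mechanical laws are available
via `neck_linker_model()`:

* **Increasing stiffness (WLC).**  The interpolation formula for a
  worm-like chain,
  $f(x) = (k_BT/L_p)\left[\tfrac14(1-x/L_c)^{-2} - \tfrac14 + x/L_c\right]$,
  with persistence length $L_p = 0.7$ nm (alternatively 2 nm) and contour
  length 0.364 nm per residue.  The force diverges as $x \to L_c$.
* **Constant stiffness (Hookean).**  A linear spring, $\kappa = 1$ pN/nm
  for the wild type and 0.8 pN/nm for the 17-residue mutant.
* **Reflecting.**  A nearly force-free tether ($\kappa = 0.01$ pN/nm)
  between hard reflecting barriers at the contour length.  The barrier
  distance for a single wild-type linker is kept at its quoted value of
  5.3 nm (which corresponds to 0.38 nm/residue) and scales with residue
  count for the mutant; the WLC uses 0.364 nm/residue.  Both are
  configurable, since the two conventions are mutually inconsistent at the
  ~4% level.

All three are treated as symmetric restoring forces about the tether
centre: the magnitude is the extension law evaluated at $|x - c|$.  The
1-D model has no excluded volume, and this choice matches the
odd-symmetric force-extension profiles of the state diagram.

With two linkers engaged (state 2) the contour length doubles, Hookean
springs act in series (stiffness halves), and reflecting barriers move out
to twice the single-linker distance.

## Integrators

Each model gets the numerically appropriate scheme:

* **WLC — explicit Euler–Maruyama** at $\Delta = 1$ ns.  Two guards tame
  the divergence at full extension: the force is evaluated with the
  extension capped at `cap_fraction` (default 0.995) of $L_c$, and the
  deterministic drift within one step is limited to the distance to the
  potential centre, so an Euler step can never overshoot the centre no
  matter how large the capped force is.  Positions are kept strictly
  inside $\pm 0.999\,L_c$.  These guards engage only in the far tail
  (cap-hit counts are reported in experiment manifests) and after
  docking transitions, when the centre shift can exceed the new support;
  the transient relaxes within a few nanoseconds.
* **Hookean — exact Ornstein–Uhlenbeck transitions.**  The linear SDE has
  Gaussian transition densities, so steps of any length are sampled
  exactly; there is no discretisation error at any $\Delta$.
* **Reflecting — Euler with a Lépingle-type boundary correction** at
  $\Delta = 10$ ns.  Naive clamping at a barrier piles probability mass
  onto the boundary.  Instead the extremum of the underlying Brownian
  path over the step is sampled from the Brownian-bridge law,
  $m = \tfrac12\!\left(x + y - \sqrt{(y-x)^2 - 2\sigma^2\ln U}\right)$,
  and the Skorokhod reflection $x' = y + (l - m)^+$ is applied at the
  nearer barrier (mirrored at the upper).  The barriers are ≥ 10.6 nm
  apart while one step moves ~1.2 nm rms, so correcting only the nearer
  barrier is adequate; a far-barrier mirror is kept as a safety net.

The time step is validated at configuration time against the fastest
chemical channel so that every Bernoulli threshold sum stays below 0.1 per
step (at the WLC's $k_\mathrm{attach} = 7.5\times10^4$/s and 1 ns this sum
is $7.5\times10^{-5}$).  At 1 ns the rms free displacement
$\sqrt{2D\Delta} \approx 0.38$ nm is well below the 1-nm zone half-width.

### Event thinning and equilibration clipping

Production ensembles need ~$10^9$ SDE steps per run, so the compiled
kernel separates diffusion from chemistry by *uniformization*: the number
of steps to the next candidate chemical event is drawn geometrically at
the state's majorant per-step probability; between candidates the SDE runs
free of chemistry; at a candidate, one uniform draw selects a channel with
probability (actual rate at the current position)/(majorant), the
remainder being a pseudo-event.  The survival product through
pseudo-events reproduces the per-step Bernoulli law exactly — this is a
reformulation, not an approximation.

Two further accelerations exploit that nothing observable happens inside a
candidate gap:

* for the Hookean tether the whole gap collapses into a single exact
  multi-step OU draw;
* for the WLC and Reflecting tethers, gaps longer than ~100–200 tether
  relaxation times (relaxation $\xi/k_0 \approx 33$ ns for the docked WLC,
  $L^2/\pi^2 D \approx 160$ ns for the reflected interval) are truncated
  to that length: the gap endpoint is stationary to within $e^{-100}$
  either way.  Ensemble means were verified to agree with the
  attachment/unbinding race closed form within Monte-Carlo error.

The kernel uses a xoshiro256++ generator with a 128-layer ziggurat for
normals, seeded per run as `base_seed + run index`, so ensembles are
reproducible from a single integer and independent of R's RNG state.  The
plain-R implementations of every step law (`euler_step()`,
`ou_exact_step()`, `reflected_step()`, `diffusive_state_step()`) remain
the readable reference and are tested against the same closed forms.

## Tether centres: two conventions

The description of the cycle admits two readings of where the tether
potential sits in states 2 and 3, exposed as `center_convention`:

* `"results"` (default): state 2 centred at the bound head (0 nm), states
  3 and 4 at +4.1 nm — the convention of the stationary-distribution
  figures ("no positional bias" before ATP, 4-nm bias after).
* `"methods"`: state 2 centred between the sites at −4.1 nm, state 3 at
  0 nm — the convention of the step-by-step algorithm sketch.

The difference is not cosmetic.  Under the `"methods"` convention the
freshly released head (at −8.2 nm) sits in a region where the state-2
tether leaves several percent stationary mass inside the rear rebinding
zone; with $k_\mathrm{attach}$ of $10^4$–$7.5\times10^4$/s this drives
futile release–rebind cycles, each costing a ~4 ms both-heads-bound dwell,
and collapses the mean velocity far below any reported motor behaviour
(to ~400 nm/s for the WLC tether in our measurements).  Under
`"results"`, rear-zone mass is negligible for the spring tethers and the
simulated velocities and run lengths land on the published motor
statistics.  The package therefore defaults to `"results"`; the alternate
convention remains available for sensitivity analysis.

## What the simulations reproduce — and one thing they do not

With the defaults above, the package reproduces the published simulation
statistics of this model family at 1 mM ATP within combined standard
errors: Hookean docked-state zone occupancy 0.058 (Gaussian closed form
$\Phi(2.52)-\Phi(1.53)$), Reflecting occupancy 0.188 (≈ 2 nm of a 10.6-nm
interval), Reflecting wild-type velocity ~880 nm/s with ~1.9-µm runs, and
mutant velocity and run length both reduced relative to wild type.  The
qualitative signature that motivates the model comparison — extending the
neck linker *lengthens* runs under both spring tethers but *shortens*
them under the reflecting tether — reproduces clearly for the spring
tethers (the worm-like-chain mutant runs ~4× farther than wild type).
For the reflecting tether the measured separation is real but modest
(~1680 vs ~1920 nm in large ensembles, i.e. resolved at about 2.5
standard errors only beyond a thousand pooled runs), partly because the
state-2 binding channel — geometrically open only for the reflecting
tether under the default centre convention — adds direct forward steps
to both motors; at 50 runs per ensemble (run-length means carry ~14%
standard errors) the ordering is a statistical statement, not a per-seed
certainty.

The one quantity we cannot reproduce from the stated parameters is the
docked-state zone occupancy of the WLC tether.  Boltzmann quadrature of
the WLC potential ($L_p = 0.7$ nm, $L_c = 14 \times 0.364$ nm, centre
4.1 nm, $k_BT = 4.11$ pN·nm) puts $3.7\times10^{-3}$ of the mass in the
7.2–9.2 nm zone, and the Euler simulation at 1 ns gives
$4.2\times10^{-3}$; occupancies near $8\times10^{-3}$ arise only at time
steps (≈ 5 ns) where the explicit scheme is at the edge of stability for
this force law, or with a longer/softer chain than stated.  The package
reports its converged value.  Quantities downstream of this occupancy
(WLC run lengths, recurrence time) shift proportionally; quantities
dominated by the chemical cycle (velocities) are only mildly affected.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `kBT` | 4.11 | pN·nm | thermal energy (≈ 298 K); chosen so the Hookean occupancy matches its closed form |
| `eta`, `head_radius` | 1e-9, 3 | g/(nm·s), nm | Stokes drag of the head |
| `site_spacing` | 8.2 | nm | tubulin dimer spacing |
| `zone_half_width` | 1 | nm | binding-capture window |
| `docking_bias` | 4.1 | nm | centre shift on ATP binding |
| `dt` | 1 (WLC), 10 (others) | ns | integrator step |
| `cap_fraction` | 0.995 | — | WLC force-evaluation cap |
| `k_attach` | 75000/12000/10000/3500 | 1/s | per-model attachment rate |
| `atp_conc` | 1000 | µM | ATP concentration |
| `n_runs`, `base_seed` | 50, 1 | — | ensemble size and seeding |

The reverse attachment rate (0.45/s) is carried in the configuration but
enters no transition of the simulated cycle — the algorithm sketch never
consumes it; it is retained for completeness, and its intended position in
the cycle is left open.  State 3 is taken to engage one linker (the docked
state), configurable in principle via `tether_configuration()`.

## Problem sizes and statistical design

Stationary quantities use ≥ 10 ms of simulated trajectory ($10^7$ steps at
1 ns), discarding a 10-µs burn-in — hundreds of thousands of independent
tether relaxations, giving zone occupancies with relative Monte-Carlo error
of a few percent.  Recurrence times are means over all completed
excursions out of the zone (~$3\times10^4$ in 10 ms for the docked WLC);
excursions truncated by the end of the run are discarded.  Ensemble
statistics use 50 runs per configuration, matching how motor-assay tables
are reported (per-run velocity = displacement/time, arithmetic mean ±
SEM across runs, not pooled totals).  Zone occupancy from a discrete
trajectory is the sampled time fraction, unbiased as $\Delta \to 0$; the
WLC value carries an $O(\Delta)$ Euler inflation (~13% at 1 ns), which is
why oracle-agreement tests run at $\Delta/4$, where the bias is below the
Monte-Carlo resolution.

## What the generator does and does not emulate

The canned configurations (`fixture_names()`) are a complete in-silico
restatement of the study conditions: four tether models × two motors at
1 mM ATP.  They are not real data.  The model is one-dimensional (no
off-axis excursions, so zone occupancies are upper bounds relative to 3-D
diffusion); there is no external load on the motor; no weak-binding
interaction stabilises the head near its site; ADP release is not
resolved as a separate step; and the microtubule is a rigid lattice of
identical sites.  Passing tests therefore certify the stochastic
machinery and the mechanics of the tether models, not biological fidelity
beyond what this model family claims.

## Known limitations

* The WLC zone-occupancy discrepancy described above.
* The Euler scheme's $O(\Delta)$ stationary bias for the WLC tether is
  visible (~13%) at the default 1 ns; halving $\Delta$ halves it.
* Recurrence times are defined on the sampled chain, so sub-step
  excursions are invisible; the estimate depends on $\Delta$ near the
  zone edge where sojourns last only a few steps.
* `k_attach_rev` is carried but unused (see above).
* The CLI is a thin convenience wrapper (`inst/cli/neckstep.R`); the R
  API is the primary interface.
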