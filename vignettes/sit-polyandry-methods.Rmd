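---
title: "Modelling the sterile insect technique under female multiple mating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the sterile insect technique under female multiple mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitpoly)
```

## The problem

The sterile insect technique (SIT) suppresses a pest population by releasing
mass-reared, sterilized males that compete with wild males for matings. Its
classical theory assumes each female mates once. *Drosophila suzukii*
(spotted-wing drosophila), a major soft-fruit pest, is polyandrous: females
re-mate repeatedly and store sperm from several males, so the outcome of a
release programme depends on *which* stored sperm fertilizes the eggs.
`sitpoly` implements two complementary models of this situation, calibrated
for *D. suzukii* in a ~500 m² strawberry tunnel:

* a **compartmental ODE model** of larvae `L`, wild males `M`, available
  females `F_U`, infertile females `F_I`, fertilized females `F_F` and
  sterilized males `S`, with closed-form equilibrium and threshold analysis;
* a **stochastic daily-step agent-based model (ABM)** in which females are
  individual agents carrying ordered sperm stores, evaluated under six
  sperm-use scenarios.

## The compartmental model

The full model couples oviposition (rate `omega`, throttled by the logistic
factor `1 - L/K`), maturation (`nu`, sex ratio `p`), stage-specific
mortalities (`mu_L`, `mu_M`, `mu_F`, `mu_S`), mating (rate `chi`, allocated
to sterilized males in proportion `eta*S/(M + eta*S)`) and re-mating
(refractory rates `tau_F` after a wild mate, `tau_I` after a sterile mate).
Sterilized males enter at the constant rate `sigma` and obey
`dS/dt = -mu_S S + sigma` independently of the rest of the system.

Because the mating rate (`chi` = 10 per day) exceeds every other rate by two
to three orders of magnitude, the available-female compartment empties
essentially instantly. `sitpoly` implements both the full six-compartment
system (`full_rhs`) and the five-compartment slow-fast reduction
(`reduced_rhs`) in which emerging and re-available females are routed
directly to `F_F` or `F_I` through the mating fractions.
`compare_full_reduced()` quantifies the reduction error numerically; with
the default parameters the two models agree to ~2% in sup-norm and the
discrepancy shrinks roughly tenfold for each tenfold increase in `chi`.
This numerical check deliberately replaces a formal singular-perturbation
argument.

### Thresholds and bistability

Persistence is governed by the basic reproduction number

```
R0 = omega (1 - p) nu / (mu_F (mu_L + nu))
```

(`r round(basic_reproduction_number(suzukii_params()), 2)` at the default
calibration — each female leaves ~171 viable daughters). Infestation
equilibria of the reduced model are the roots of the downward parabola
`zeta(L*) = sigma`; its summit

```
sigma_bar = K gamma mu_S (R0 - 1)^2 (mu_F + tau_I) / (4 eta R0 (mu_F + tau_F)),
gamma = nu p / mu_M
```

is the **eradication threshold**: a saddle-node bifurcation at which the
stable high-infestation equilibrium (E2\*) and the unstable low-infestation
equilibrium (E1\*) collide. Below `sigma_bar` control is all-or-nothing —
the outcome depends on which side of E1\* the population starts; above it
the pest-free state is the only attractor. Note that `sigma_bar` depends on
re-mating only through `(mu_F + tau_I)/(mu_F + tau_F)`: equal refractory
rates leave the threshold exactly at its no-re-mating value, while faster
re-mating after a sterile mate (`tau_I > tau_F`, the realistic case) raises
it.

```{r thresholds}
pr <- suzukii_params()
eradication_threshold(update_params(pr, tau_F = 0, tau_I = 0)) # First
eradication_threshold(pr)                                      # Last
```

`find_equilibria()` solves the quadratic in closed form and rebuilds the
remaining compartments by back-substitution (`M* = nu p L*/mu_M`, `F_F*`
from the stationary `L` equation, `F_I*` from the stationary `F_I`
equation); the substitution order is this package's choice, and the unit
tests verify that the reduced right-hand side vanishes at every returned
state. Stability is classified from the eigenvalues of a central
finite-difference Jacobian (relative step `1e-6`, absolute stability
tolerance `1e-9` per day); values within the tolerance are reported as
`"marginal"` rather than silently binned, and the exact double-root case
`sigma = sigma_bar` is reported as a single marginal infestation
equilibrium.

### Numerical choices

* Integration uses `deSolve::lsoda` with `rtol = atol = 1e-8`; the fast
  mating term makes the full system moderately stiff. Tolerance-level
  undershoots below zero are clipped in returned trajectories.
* The mating fractions are defined as 0 when `M + eta*S = 0`: no males, no
  matings. This removes a spurious 0/0 at the origin without altering the
  dynamics anywhere else.
* For reporting only, a continuous larval density below one individual is
  treated as extinct (`L < 1`); it never feeds back into the dynamics.
* `eradication_threshold()` returns 0 when `R0 <= 1` (any positive release
  suffices) and errors for `eta = 0` with `R0 > 1` (no finite release can
  work if sterilized males never mate).

## The agent-based model

The ABM runs in daily steps on a well-mixed population and keeps the ODE
calibration: every rate `r` becomes a daily probability `1 - exp(-r)`, so
all sojourn times remain exponential (geometric in days) and the ABM is
directly comparable to the reduced ODE. Within each day the order is:
release, sterilized-male survival, wild-male survival, larval survival and
maturation, then the female step (survival, refractory countdown, one
mating opportunity, oviposition).

Only females are true individuals — their ordered sperm stores and
refractory clocks drive everything. Wild males, sterilized males and larvae
are aggregated into counts updated with binomial draws, which is
statistically identical to per-agent Bernoulli draws because none of their
hazards depend on individual state. For the six sperm-use rules the ordered
store reduces to four sufficient statistics per female (counts of fertile
and sterile records, first origin, last origin), which is what the
vectorized simulator tracks; the `sperm_store` API retains the full ordered
history.

The six scenarios (`sperm_scenario()`): `first` and `last` male precedence,
proportional `mixed` use, complete preference for fertile (`preference_w`)
or sterilized (`preference_s`) sperm, and a relative preference
(`preference_i`, default weight 0.8 for fertile sperm when both kinds are
stored). Eggs are laid as a Poisson(`omega`) clutch by every female with a
non-empty store; each egg is viable only if the scenario rule selects
fertile sperm, and viable eggs are admitted as larvae with probability
`1 - L/K`, applied in chunks with `L` updated between chunks so the larval
pool can never exceed `K`.

### Reconstructed per-agent details

The per-agent rules are reconstructed to be mutually consistent with the
ODE rates; where a detail was genuinely open we chose once and kept it:

* **Releases** add a batch of `sigma` males at the start of each simulated
  day (day 1 is the first step; day 0 is the initial snapshot); batch,
  period and start day are configurable via `release_policy()`.
* **Refractory durations** are geometric with daily end-probability
  `1 - exp(-tau)`; `tau = 0` means the female never re-mates. Mated
  initial populations (`females_mated = TRUE`) start with one fertile
  record and a refractory countdown drawn at rate `tau_F`, mirroring the
  ODE's `F_F` compartment.
* **No cap** on lifetime matings (configurable in principle; none is
  imposed by default), no sperm depletion, and one store record per mating
  regardless of ejaculate size; `mixed` therefore weighs records equally.
* **Mortality is hazard-based** (no fixed lifespan), again for ODE
  consistency.
* Eggs blocked by the density factor or fertilized by sterile sperm simply
  produce nothing; damage from sterile oviposition is out of scope.

With no releases and pre-mated females the ABM's replicate-mean larval
trajectory tracks the reduced ODE within 15% over 100 days (verified in the
test suite with 30 replicates from `L = 3000`, `M = F_F = 10000`).

### What the ABM does and does not capture

The simulator reproduces demographic stochasticity, integer populations and
the scenario-dependent "defertilization" of standing females, and the test
suite verifies the qualitative structure: suppression ranks
`preference_s >= last >= mixed >= first >= preference_w`, reductions are
monotone in `sigma`, and last-male precedence cuts a standing infestation
faster than first-male precedence early on. Two caveats matter when
comparing against individual-based implementations with richer life-history
detail:

* Development and longevity are exponential here. Implementations that give
  each larva an explicit emergence time (and adults a bounded lifespan)
  delay the return of wild males into the mating pool and therefore report
  substantially larger area-under-curve reductions at release rates far
  below the eradication threshold; with the ODE-consistent rules used here,
  the 30-replicate sweeps at `sigma = 10,000` per day yield mean reductions
  of ~18% (`preference_w`) and ~38% (`last`), while at `sigma = 60,000`
  they reach ~87% and ~99%. The deterministic reduced model itself gives
  only ~12% and ~52% from the same initial state, so the ABM sits between
  the ODE and delay-structured individual-based variants.
* For the same reason `preference_i` falls between `preference_w` and
  `first` here: persistent fertile re-matings keep re-armed stores common,
  so the 0.8 per-egg preference binds often. In delay-structured variants
  late matings are almost exclusively sterile and `preference_i` collapses
  onto `first`.

### Experiment layer and problem sizes

`replicate_sweep()` pairs every treated run with a no-release (WR) baseline
sharing the replicate seed — a variance-reduction device that also fixes
the confidence-interval definition (`mean ± 1.96 sd/sqrt(n)` over replicate
reductions, n = 100 by default). One WR run per replicate serves every
scenario and release rate. Replicate seeds derive from a single master seed
by one block draw (`replicate_seeds()`), so sweeps are reproducible and
parallelizable. The packaged tests and the acceptance script use 30
replicates and the default tunnel conditions (1000 wild males, 1000
females, no larvae, 100-day horizon — a strawberry production season);
heatmap grids default to 100×100 with the threshold capped at one million
males per day.

## Known limitations

* Both models are well-mixed; no spatial structure, no within-day event
  timing, no time-varying ODE release rates (pulsed releases live in the
  ABM's release policy).
* The carrying capacity `K = 36,000` larvae per tunnel is consumed as a
  calibration constant; its derivation from field densities is not
  re-examined here.
* Stability classification is numerical (finite-difference Jacobian
  eigenvalues); no analytic eigenvalue formulas or basin-of-attraction
  computations are provided.
* The `sigma` of the ABM is interpreted as a per-day release; releasing the
  same number at longer intervals is available through
  `release_policy(period = ...)` but is not the default.
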