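---
title: "Cancer-immune tipping dynamics and lifespan scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cancer-immune tipping dynamics and lifespan scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petolv)
```

## The model

Peto's paradox is the observation that cancer incidence does not
correlate with a species' body size or lifespan, even though more cells
dividing for more years should mean more opportunities for malignant
transformation. `petolv` implements a compartment-level account of this
non-correlation built from three interacting populations inside one
organism: cancer cells $C$, healthy cells $H$, and an *immune-escape
threshold* $I$ — the declining competence level of the aging immune
system, below which a cancer population is assumed to escape control.
Their dynamics are a Lotka–Volterra competition system:

$$\frac{dC}{dt} = r_1 C\left(1 - \frac{C}{K_1}\right) - \alpha C H - \beta C I$$
$$\frac{dH}{dt} = r_2 H\left(1 - \frac{H}{K_2}\right) - \gamma H C$$
$$\frac{dI}{dt} = -r_3 I - \delta I C$$

Cancer and healthy cells grow logistically toward their carrying
capacities $K_1, K_2$ and compete ($\alpha, \gamma$); immune pressure
removes cancer cells ($\beta$); the immune threshold decays with age
($r_3$) and is additionally depleted by the fight against cancer
($\delta$). The model assumes $\delta > 0$ (net depletion — a weakened
condition during disease); `lv_params()` accepts any real $\delta$ but
warns at $\delta \le 0$, since the qualitative analysis below relies on
$I$ being monotonically decreasing. There is no direct healthy–immune
interaction. A variant right-hand side (`lv_rhs_mutation()`) adds a
mutational source $r_1\,p(t)\,H$ to the cancer equation so that tumours
can arise from $C_0 = 0$; $p$ may be a constant or any function of time
with values in $[0, 1)$.

The simulation starts from a nearly healthy organism:
$C_0 = \epsilon K_1$ and $H_0 = (1-\epsilon) K_2$ with
$\epsilon = 10^{-4}$ by default, and $I_0$ at its intact-immune-system
maximum. Explicit initial values may override this, but $C_0 < I_0$ is
always required — otherwise the upward crossing below is undefined.

## Tipping time and cancer incidence

Because $dI/dt \le 0$ while $C$ grows, the two curves may cross. The
*tipping time* $t_c$ is the first time with $C(t_c) = I(t_c)$ (a "dead
cross" of the falling threshold under the rising cancer count). Before
$t_c$ the incidence of clinical cancer is taken as zero; after it,
cancer occurs with a constant probability $q$ per unit time, giving the
lifetime incidence

$$\frac{1}{T}\int_{t_c}^{T} q\, dt \;=\; q\left(1 - \frac{t_c}{T}\right),$$

implemented in `cancer_incidence()` and inverted by
`tipping_from_incidence()`. With $q = 0.5$, a crossing at $t_c/T = 0.6$
yields a 0.2 lifetime incidence, exactly. If the curves never cross
within the lifespan the incidence is 0.

`check_requirements()` scores a parameter set against four
admissibility requirements: the power-law exponent is $m = 4.76$
(applicable only to parameters generated from scaling constants);
tipping happens late in life ($t_c/T > 0.6$); healthy cells stay within
5% of $H_0$ before tipping; and depletion dominates intrinsic immune
decay ($K_1 \delta > r_3$).

```{r}
p <- lv_fixture("case_I")
find_tipping(p)
check_requirements(p)
```

## Lifespan scaling and nondimensionalization

Body mass (equivalently, cell number) and lifespan are linked by an
allometric power law. The package encodes one species' biology as
species-independent constants (`scaling_constants()`) plus a lifespan:

$$K_1 = a T^m,\quad K_2 = b T^m,\quad I_0 = c T^m,$$
$$r_1 = d/T,\quad r_2 = e/T,\quad r_3 = f/T,$$
$$\alpha = g\,T^{-(m+1)},\ \beta = h\,T^{-(m+1)},\ \gamma = k\,T^{-(m+1)},\ \delta = l\,T^{-(m+1)},$$

with $m = 4.76$ by default (an empirical mass–lifespan exponent).
Rescaling states by their characteristic sizes ($C$ by $K_1$, $H$ by
$K_2$, $I$ by $I_0$) and time by $T$ gives a dimensionless system on
$\tau \in [0,1]$ whose coefficients are
$\hat\alpha = \alpha K_2 T$, $\hat\beta = \beta I_0 T$,
$\hat\gamma = \gamma K_1 T$, $\hat\delta = \delta K_1 T$ and
$\hat r_i = r_i T$ (`nondimensionalize()`). For power-law-generated
parameters these collapse to the lifespan-free products

$$\hat\alpha = g b,\quad \hat\beta = h c,\quad \hat\gamma = k a,\quad
\hat\delta = l a,\quad \hat r_1 = d,\ \hat r_2 = e,\ \hat r_3 = f.$$

This is the mechanism behind the non-correlation: if all species share
the constants $(a,\dots,l,m)$, every species' rescaled system is the
*same* system, so the rescaled tipping time $\hat t_c = t_c/T$ — and
with it the lifetime incidence $q(1-\hat t_c)$ — is identical across
species regardless of lifespan. `verify_noncorrelation()` checks this
numerically on a `species_ensemble()`, and
`scaling_product_invariance()` checks the weaker statement that only
the products $gb, hc, ka, la$ matter:

```{r}
ens <- species_ensemble(lv_fixture("fig8"), lifespans = c(1, 10, 100))
verify_noncorrelation(ens)
```

## Equilibria and stability

All fixed points have $I^* = 0$ (the threshold only decays): the
origin, the healthy-only state $(0, K_2, 0)$, the cancer-only state
$(K_1, 0, 0)$, and a coexistence point

$$\left(\frac{r_2 K_1 (r_1 - \alpha K_2)}{r_1 r_2 - \alpha\gamma K_1 K_2},\;
\frac{r_1 K_2 (r_2 - \gamma K_1)}{r_1 r_2 - \alpha\gamma K_1 K_2},\; 0\right),$$

which exists inside the carrying capacities iff
$r_1 - \alpha K_2 \ge 0$, $r_2 - \gamma K_1 \ge 0$ and the denominator
is strictly positive. `equilibria()` evaluates the closed forms,
`lv_jacobian()` the analytic linearization, and
`classify_equilibrium()` the eigenvalue sign rule (stable when all real
parts are below $-10^{-9}$, unstable when any exceeds $+10^{-9}$,
non-hyperbolic otherwise).

The eigenvalues at the boundary points are available in closed form and
pin down the stability structure exactly: the origin (eigenvalues
$r_1, r_2, -r_3$) is always unstable; $(0, K_2, 0)$ (eigenvalues
$r_1 - \alpha K_2, -r_2, -r_3$) is stable iff $r_1 < \alpha K_2$;
$(K_1, 0, 0)$ is stable iff $r_2 < \gamma K_1$; and the coexistence
point is stable whenever it strictly exists. Note that the two boundary
conditions are not mutually exclusive — when $r_1 < \alpha K_2$ *and*
$r_2 < \gamma K_1$ both boundary states are stable simultaneously
(bistability) and no interior point exists; the package's property
tests therefore assert the iff-conditions above rather than an
"only one stable point" phrasing, which is the generic-case reading.
At the doubly degenerate limit $r_1 = \alpha K_2$, $r_2 = \gamma K_1$
the fixed points form the line $C K_2 + H K_1 = K_1 K_2$, reported as a
non-hyperbolic `degenerate_line` row; numerically the coexistence
formula is only evaluated when the denominator exceeds
$10^{-12}\, r_1 r_2$.

## Numerical choices

*Integration.* `lv_simulate()` uses `deSolve`'s adaptive Dormand–Prince
4(5) pair with relative tolerance $10^{-9}$ and absolute tolerance
$10^{-12}$. These are deliberately tight: adjacent rows of the
$\epsilon$-sensitivity table differ by about $10^{-3}$ in $t_c/T$, so
crossing times must be stable to about $10^{-4}$; the defaults achieve
far better (tightening to $10^{-11}/10^{-13}$ moves the pinned
fixtures' $t_c$ by less than $10^{-8}$). An explicit pair is the right
choice here even for the fast-rate fixtures (rates up to 5000 per unit
lifespan): stability-limited steps still integrate a lifespan in well
under a second, and the stiff multistep alternative fails with
step-size underflow on fixtures where $C$ decays to magnitudes near
$10^{-250}$ before rebounding. `method = "lsoda"` remains available as
a switch.

*Event detection.* The crossing is found in two stages: bracket the
first sign change of $e(t) = C(t) - I(t)$ from $\le 0$ to $> 0$ on the
output grid (2001 points per lifespan by default), then refine by
re-integrating from the bracketing grid state inside a bracketing root
search with interval tolerance $10^{-12} T$. The refined root inherits
solver accuracy rather than grid resolution. All upward sign changes
are counted; every pinned fixture crosses at most once, and if a
parameter set crosses repeatedly the first crossing is returned with a
warning.

*Degenerate inputs.* A fixture with no crossing reports
`exists = FALSE` and incidence 0 rather than an error; a member of an
ensemble without a crossing marks the whole ensemble's verdict as
`"violated (no crossing)"` naming the species. Integration failures
carry condition class `petolv_integration_error` and are recorded
per-row in `sensitivity_scan()` rather than aborting the scan.

*Agreement tolerance.* Rescaled tipping times across an ensemble are
compared at $10^{-4}$. The underlying identity is exact; the tolerance
budget is entirely numerical (solver plus root refinement), and the
observed deviations for exact ensembles are at machine precision.

## Reference fixtures and what the experiments pin

The `lv_fixture()` registry carries the pinned parameter sets used by
the reproduction experiments (`run_cases()`, `run_table1()`,
`run_fig8_9()`, `run_fig11()`), spanning one slow-growth regime with
late tipping, three fast-rate regimes with early/late/absent tipping,
the three-species scaling ensemble, and an abrupt-progression set. The
experiments compare recomputed crossing times against reference values
pinned at two levels of precision: $5 \times 10^{-4}$ for the
4-decimal sensitivity table and $5 \times 10^{-3}$ for crossing times
only known to two significant figures. The recomputed values for the
fast-rate regimes (0.2274, 0.2281, 0.8852) sit just outside the latter
band around their 2-figure references (0.22, 0.22, 0.88); they are
tolerance-robust to solver settings, so the `pass` column of
`run_cases()` reports this honestly rather than papering over it. The
4-decimal table reproduces to better than $5\times10^{-4}$ throughout.

The `run_fig11()` "abruptness" statistic — the largest drop of $H$
over any sliding window spanning 5% of the lifespan — is this
package's own operationalization of "sharp decrease"; it is reported
descriptively and never asserted against external values.

## The synthetic ensemble generator

`random_ensemble()` draws lifespans log-uniformly (spanning orders of
magnitude, as real comparative-oncology panels do) and perturbs each
species' constants $(d,e,f,g,h,k,l)$ with independent log-normal
multipliers of scale `sigma`; both choices keep every generated
quantity positive by construction. `sigma = 0` produces an ensemble
that satisfies the shared-constants premise exactly, so
`verify_noncorrelation()` must hold — this is the generator's role as a
positive control. `sigma > 0` breaks the premise; strong perturbations
(e.g. `sigma = 0.5`) often remove the crossing for some members
entirely, which the verdict reports as a violation.

What the generator does *not* emulate: measurement noise, within-species
heterogeneity (the model's coefficients are population averages in the
sense of `population_average_coefficient()`), immune architecture
differences between large and small species, or any real allometric
data. A passing noncorrelation verdict on synthetic ensembles
demonstrates the mathematical mechanism, not that real species satisfy
the power laws.

## Parameters that matter

| Parameter | Meaning | Units | Default | Why |
|---|---|---|---|---|
| `epsilon` | initial cancer fraction $C_0/K_1$ | — | $10^{-4}$ | small seeding population; $t_c/T$ falls by $\approx 10^{-3}$ per 1% increase |
| `q` | post-tipping cancer probability | 1/time | 0.5 | sets the incidence scale; cancels from noncorrelation comparisons |
| `m` | allometric exponent | — | 4.76 | empirical mass–lifespan scaling |
| `rtol`, `atol` | solver tolerances | — | $10^{-9}$, $10^{-12}$ | resolve $t_c$ to $\ll 10^{-4}$ |
| `n` | output grid size | — | 2001 | bracket resolution for event detection |
| `tolerance` | $\hat t_c$ agreement band | — | $10^{-4}$ | numerical budget for an exact identity |

## Known limitations

- The rescaled tipping time is nearly insensitive to the healthy-cell
  growth constant $e$: healthy cells start at $(1-\epsilon)K_2$ and
  remain pinned at carrying capacity, so doubling $e$ for one species
  moves $\hat t_c$ by only $\sim 2\times10^{-5}$ — below the $10^{-4}$
  agreement band. Violations of the shared-constants premise through
  $e$ alone are therefore not detectable at that tolerance, unlike the
  other six constants (shifts between $9\times10^{-3}$ and $0.4$).
- In strongly suppressed regimes $C(t)$ passes through extremely small
  magnitudes ($10^{-250}$) before rebounding. These are mathematical,
  not biological, population sizes; a discrete or stochastic model
  would extinguish such populations.
- The model is well-mixed and deterministic: no spatial structure,
  migration, feedback signalling, or demographic noise.
- Estimating the dimensionless constants from real doubling-time and
  lifespan data (`growth_rate_from_doubling_time()`,
  `dimensionless_constant_from_rate()`) is supported as arithmetic
  only; no biological databases are bundled or queried.

## Problem sizes

All computations here run at desk scale: a lifespan integration is one
ODE solve over 2001 output points (fractions of a second); the full
reproduction suite is a few dozen solves; the stability property checks
use 200 random parameter draws with closed-form equilibria and 3×3
eigenproblems. Seeds are fixed wherever randomness enters.
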