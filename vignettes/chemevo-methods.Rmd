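---
title: "Eco-evolutionary chemostat models of cross-feeding communities: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary chemostat models of cross-feeding communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`chemevo` simulates `n` microbial species growing in a chemostat on `m`
substrates connected by a catabolic pathway. Substrates flow in at
concentration $Q_i$, everything washes out at the dilution rate $D$, and each
reaction converts one substrate into one downstream substrate with 1:1
stoichiometry (pathways may branch and coalesce, but never run "uphill": the
substrate ordering orients every reaction). Species differ in how they
allocate a fixed total enzyme budget over the pathway's reactions: the
allocation $E_{ijk}$ of species $k$ to the reaction $i \to j$ lies in
$[0, 1]$ and each species' allocations sum to 1 (a linear trade-off —
expressing more of one enzyme means less of another).

The per-cell rate of the reaction $i \to j$ in species $k$ is Monod:

$$J_{ijk} = \frac{v_{ijk}\, E_{ijk}^{\,a}\, S_i}{K_{ijk} + S_i},$$

with maximum rate $v$ per unit enzyme, half-saturation constant $K$, and an
optional cost-of-generalism exponent $a \ge 1$ (below). A linear growth law
$J = v E^a S_i$ is also available; several steady states are only tractable
in closed form under it. Growth on multiple substrates is additive, and each
unit of metabolized substrate converts to cell density with yield $c_{ijk}$.
The dynamics are

$$\frac{dS_i}{dt} = D(Q_i - S_i)
   - \sum_{k,j} N_k J_{ijk} + \sum_{k,j} N_k J_{jik}, \qquad
  \frac{dN_k}{dt} = \sum_{i,j} c_{ijk} N_k J_{ijk} - D N_k.$$

Dilution, consumption and cross-feeding production are the only terms.
Because stoichiometry is 1:1, metabolism cancels in the substrate total and
$d(\sum_i S_i)/dt = D(\sum_i Q_i - \sum_i S_i)$ exactly — the test suite
asserts this along trajectories, and its steady-state corollary
$\sum_i \tilde S_i = \sum_i Q_i$ on every converged run.

Units are abstract throughout (concentrations, densities and times on the
scale of the built-in presets); no unit conversions are performed.

## Assumptions worth stating

* Enzyme expression is constitutive — no regulation or plasticity.
* Reactions are irreversible and one-substrate/one-product.
* An enzyme's kinetics (`v`, `K`, `c`) do not depend on which species
  carries it, only on the reaction; branch reactions out of the same
  substrate share kinetics and yields.
* Batch or serial-transfer regimes, spatial structure, and demographic noise
  are out of scope.

## Evolution of enzyme allocation

Each species' allocation vector evolves as a quantitative mean trait:

$$\frac{d\mathbf{E}_k}{dt} = \mathbf{G}_k \nabla \bar W_k,$$

where $\bar W_k$ is the per-capita growth rate and the G-matrix has diagonal
$\mu_k$ (heritable variance in allocation) and off-diagonal
$-\mu_k/(n_E - 1)$, so its rows sum to zero and the enzyme budget is
conserved; with two enzymes the implied genetic correlation is exactly $-1$.
The gradient entry for reaction $i \to j$ is
$c\,v\,a\,E^{a-1} S_i/(K + S_i)$ (the linear law drops the denominator); the
tests validate it against numerical differentiation of the growth function.
At $a = 1$ the gradient is independent of the current allocation, which has
a noteworthy consequence: all species with shared kinetics experience the
*same* selection gradient, so differences between species' profiles change
only through the boundary treatment below.

Three choices here were genuinely open:

* **The trait dimension $n_E$** in the off-diagonal. We count all reactions
  in the pathway (every species may evolve allocation to any reaction);
  `g_matrix_n = "substrates"` switches to counting metabolized substrates.
  The two differ only by a small scalar on the rate of change.
* **$\mu$** is not an observable with an established value; the default is
  `mu = 0.01` per time unit. Endpoint claims (which equilibria are reached)
  are insensitive across `mu` in 0.003–0.03, but *rate-dependent* statistics
  — notably how far profiles have converged by a fixed horizon — are not,
  and should be read as conditional on this choice.
* **Boundary truncation.** Allocation changes that would leave $[0,1]$ must
  be truncated while preserving the zero row sum. A hard projection (zero
  the outward components, re-balance the rest) makes the right-hand side
  discontinuous and the stiff solver chatters at the simplex boundary, with
  step-size collapse in a large fraction of runs. We therefore scale
  outward components down *smoothly* over a boundary layer of width
  $10^{-6}$ and redistribute the removed change across the other components
  in proportion to their room to absorb it. The layer is far below any
  allocation of biological interest, the derivative sum stays exactly zero,
  and the compiled and reference implementations agree to solver tolerance.
  Because boundary truncation is the *only* mechanism that differentiates
  species under a linear trade-off (see above), statistics that measure
  between-species profile convergence are sensitive to this detail.

## Closed-form layer

For a linear chain of specialists under Monod growth the steady state is
analytic: $\tilde S_i = D K_i / (c_i v_i - D)$ independently of supply,
$\tilde N_i = c_i (Q_1 - Y_i)$ with $Y_i$ the cumulative concentration, and
the unmetabolized end product carries the remainder. A species persists only
while its growth on the supply reaching it beats $D$; when it fails, its
substrate accumulates to the full supply and nothing flows further down the
chain (`specialist_chain_solution()` implements this cascade). Derived
quantities include the degradation-maximizing dilution rate
$D_{\mathrm{opt}} = c_1 v_1\,(K_1 + Q_1 - \sqrt{K_1 (K_1+Q_1)})/(K_1+Q_1)$,
validated against a numeric argmax, and the two-species coexistence
threshold under the linear law,

$$E_{\mathrm{thresh}} =
  \frac{c_1 v_1 v_2 Q_1 - v_2 D}
       {c_1 v_1 v_2 Q_1 + c_2 v_1 v_2 Q_2 - v_1 D - v_2 D},$$

which is $1/2$ in the fully symmetric case: two species coexist exactly when
their allocations to substrate 1 straddle the threshold. A single evolving
generalist on two inputs reaches $\tilde S_i = D/(c_i v_i)$,
$\tilde E_1 = E_{\mathrm{thresh}}$ and
$\tilde N = (c_1 v_1 v_2 Q_1 + c_2 v_1 v_2 Q_2 - v_1 D - v_2 D)/(v_1 v_2)$,
collapsing to a specialist when one substrate cannot sustain growth. These
closed forms are the oracle layer: the ODE integrator is tested against
them, and they in turn are tested against the ODE on systems where both
apply. Evolved equilibria are *neutral*: a rare invader with any profile
built from the same enzymes (perfect generalist, either specialist) has
invasion fitness zero there, which `invasion_fitness()` checks.

# Numerical choices

* Integration uses `deSolve::lsoda` (adaptive, stiff-capable) with
  `rtol = 1e-8`, `atol = 1e-10`. The right-hand side is compiled C for
  speed; a pure-R reference implementation (`compiled = FALSE`) is kept and
  the two are cross-checked in the tests.
* The solver may probe slightly negative states; concentrations, densities
  and allocations are clipped at their bounds inside the derivative
  evaluation only.
* Trajectory storage (`n_out` points) is decoupled from solver stepping.
* Convergence is flagged when all derivatives at the final state are below
  $10^{-6}$ on the inflow scale. `detect_steady_state()` reports
  per-variable settling times as the earliest time after which a variable
  stays within 1% of its final value; variables ending at ~0 have no
  meaningful relative criterion and are flagged `NA`. Published
  transient-duration comparisons depend on an unstated convergence rule and
  are treated as qualitative only.
* Survival means final density above `1e-4` (viable densities in the
  presets are 0.1–10 and washed-out species decay exponentially over the
  20000-time-unit runs); counts are insensitive to this cutoff across
  `1e-6`–`1e-3`, which the tests assert.

# The replicate experiments

The diverse-community experiments pair two "packagings" of the same enzymes
on an 11-substrate fermentation pathway (starch and inulin in, propionate,
butyrate and gas out): a *specialist* community with one species per
metabolized substrate, and a *generalist* community in which eight species
share all eight enzymes under a doubly stochastic allocation (each species'
budget sums to 1 and each enzyme sums to 1 across species, so the inoculum
carries the same total of every enzyme in both arms). Per replicate, the
kinetic parameters (`c`, `v`, `K` per substrate, uniform on 0.13–1) and `D`
(uniform on 0.01–0.05) are drawn once and shared bitwise across arms; runs
last 20000 time units; a base seed spawns one child seed per replicate, so
experiments are reproducible bit for bit and any replicate can be re-run in
isolation.

Generator choices that define the study conditions:

* **Inflow**: starch 3, inulin 2 concentration units, nothing else supplied.
* **Initial state**: the vessel starts filled with fresh medium
  ($S(0) = Q$) and an even inoculum $N_k(0) = 0.1$.
* **Allocation sampler**: each species' starting allocation is a
  broken-stick random partition of 1, made complementary across species by
  Sinkhorn–Knopp normalization (`"stick"`). Two alternatives are kept for
  sensitivity analysis: Sinkhorn on i.i.d. uniform entries (more even
  profiles) and Birkhoff mixtures of permutations (more specialist-like
  profiles). The sampler changes how heterogeneous the starting generalists
  are and therefore shifts the survival and dominance statistics; the
  directional contrasts between arms do not depend on it.
* **Pathway topology**: the published figure of the fermentation network is
  an image and its exact edge set is not recoverable from text. The default
  edge set (13 reactions; hexoses feed both lactate and acetate; lactate
  branches three ways; acetate yields butyrate and gas) matches every edge
  named in the source text and makes acetate the highest-flux intermediate.
  It is a *configuration*, not a constant — `gut_pathway(reactions = ...)`
  accepts any alternative — and the acceptance tests re-check the headline
  survival contrast on a variant without the direct hexose-to-acetate
  reactions.
* **Branch handling**: reactions out of the same substrate share kinetics,
  and a species' allocation to a substrate starts equally split among its
  branches (splits are evolvable thereafter; with shared branch kinetics the
  gradient keeps them equal, so substrate-level and reaction-level
  descriptions coincide).
* **Functional divergence**: evolving runs are classified as ending in
  "functionally divergent" species when all eight survive and the mean
  pairwise Euclidean distance between substrate-level allocation profiles
  exceeds `dist_tol = 0.05` — comfortably between genuinely divergent
  communities and the all-species-identical outcome.

What the generator deliberately does *not* emulate: species-specific enzyme
kinetics, regulation, fluctuating supply, mutation-limited or polymorphic
evolution, and any spatial structure. Passing tests therefore demonstrate
internal consistency of this model class and reproduction of its published
statistics, not predictions for real gut communities.

```{r}
library(chemevo)
rec <- run_gut_experiment(reps = 200, seed = 1,
                          arms = c("specialist_eco", "generalist_eco",
                                   "generalist_evo"))
summarize_experiment(rec)
```

# Problem sizes used by the tests and the acceptance script

The test suite runs the chain and two-species systems to steady state
(seconds), the threshold-versus-ODE comparison on 200 random draws
(integrated to $4 \times 10^5$ time units so that near-threshold competitive
exclusion completes; at 20000 time units slowly excluded species are still
above the survival cutoff in several percent of draws), and the paired gut
experiment at 200 replicates. `scripts/acceptance.R` reruns the paired
experiment at the full 1000 replicates. The compiled right-hand side makes
the whole acceptance run a matter of a couple of minutes on one core.

# Known limitations

* Statistics that measure between-species convergence of allocation
  profiles under the linear trade-off depend on the boundary-truncation
  mechanism (see above); our smooth projection converges profiles more
  weakly than the published account suggests, so the evolved mean pairwise
  distance sits above the published value even though every run becomes
  more similar over time and all directional claims hold.
* The gut pathway edge set is a documented reconstruction; absolute
  survival counts of the generalist arm shift by tens per thousand across
  plausible edge sets and samplers.
* Closed forms cover chains of specialists and 1–2 species on two
  substrates; for everything else the ODE is the only oracle.
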