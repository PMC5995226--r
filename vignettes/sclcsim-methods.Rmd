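---
title: "Models and methods of the sclcsim simulator suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the sclcsim simulator suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclcsim)
```

`sclcsim` collects the deterministic and stochastic models that mathematical
oncology applies to small cell lung cancer (SCLC): a lattice cellular
automaton of tumor growth coupled to diffusing oxygen and drug, growth ODEs
with a dynamic carrying capacity, the acid-mediated invasion PDE system with
its single-cell random-walk discretization, an endpoint-constrained
metastasis redistribution simulation, and multifractal image analysis.  This
vignette documents each model, its assumptions, the defaults, and the
numerical choices, in the package's own words.

## The tumor microenvironment: oxygen and drug fields

Both substrates obey the same uptake-coupled reaction-diffusion equation on
a regular lattice,

$$\frac{\partial u}{\partial t} = D \nabla^2 u - \lambda u -
  \sum_{\text{cells } i} U_i\, u,$$

with oxygen measured in mmHg and drug in µM.  The per-cell uptake sink acts
only at lattice sites occupied by a live cell.  Key parameters (all
config-overridable, since the model family fixes no canonical values for
them; defaults follow the published example values of standard
microenvironment solvers):

| parameter | default | units | meaning |
|---|---|---|---|
| `D` | 1e5 | µm²/min | substrate diffusion |
| `lambda` | 0.01 | 1/min | background tissue decay |
| `uptake` | 10 | 1/min | per-cell uptake at occupied sites |
| `dirichlet_value` | 38 (oxygen), 0→5 (drug) | mmHg / µM | far-field value |
| spacing | 20 | µm | one lattice site per cell diameter |

With these values the in-tumor oxygen penetration depth is
$\sqrt{D/U} = 100\,\mu m$ (five cell diameters), which is what makes a
hypoxic core develop once the tumor radius reaches a few hundred µm.

**Numerics.** `step_substrate()` advances one time step with backward Euler
and dimension-wise operator splitting: one tridiagonal (Thomas) solve per
grid line, with the decay/uptake reaction folded into the diagonal of the
first directional solve.  The scheme is unconditionally stable, positivity
preserving, and with no-flux boundaries and zero reaction it conserves mass
to machine precision (the system matrix is symmetric with unit row sums).
An explicit forward-Euler scheme (`method = "explicit"`) serves as an
independent cross-check; it enforces its stability bound
$dt \le h^2/(2\,d\,D)$ and reports the admissible step when violated.
Boundaries are either reflecting (no-flux) or Dirichlet at a far-field
value; oxygen defaults to Dirichlet 38 mmHg, drug to Dirichlet 0 µM until
treatment starts.

In the *coupled* tumor run the fields are not time-stepped at all: substrate
diffusion across the 4 mm domain relaxes within a few minutes, faster than
one 6-minute automaton step, so the fields are equilibrated quasi-statically
each step by `solve_steady_field()` — warm-started red-black SOR on the
discrete steady-state system, verified in the test suite against a dense
sparse-matrix solve.  Time stepping with a 6-minute operator-split step
cannot represent the balance between a stiff per-cell uptake
($dt\,U = 60 \gg 1$) and diffusive resupply; the quasi-static solve is both
more accurate and cheaper here.

## The tumor cellular automaton

Each lattice site holds at most one cell in state VIABLE, APOPTOTIC,
NECROTIC or EMPTY.  A run starts from a single viable cell at the center at
$t = 0$.  Each step, for every viable cell (decisions taken against the
state at step entry, so daughters never act in the step of their birth):

1. **Hypoxic necrosis.** If local $pO_2 \le pO_{2,N}$ (default 5 mmHg) the
   cell becomes necrotic with hazard $d_N^*$ (default 0.1/h).
2. **Perinecrotic contact necrosis.** A viable cell with a necrotic
   neighbor becomes necrotic with the 3% rule (below).
3. **Apoptosis** with rate $d_A = d_A^* + (d_A^{max} - d_A^*)R$, affine in
   the drug response.
4. **Division** into a uniformly chosen empty neighbor (Moore 8-neighborhood
   by default; skipped when none is free) with rate

$$b(pO_2, R) = \begin{cases}
  b_P (1-\eta R) & pO_2 > pO_{2,P}\\
  b_P\, g(pO_2)\,(1-\eta R) & pO_{2,N} < pO_2 \le pO_{2,P}\\
  0 & pO_2 \le pO_{2,N}
\end{cases}$$

All rates convert to per-step probabilities via the exponential hazard
$P = 1 - e^{-r\,\Delta t}$, which keeps every probability in $[0,1]$ and
matches $r\,\Delta t$ in the small-hazard limit.  Dead cells lyse (become
empty) with $P = 1 - e^{-\Delta t / T_D}$; lysis is memoryless, so no death
clock is needed.  Drug exposure accumulates per cell as
$E \mathrel{+}= c_{local}\,\Delta t$ (rectangle rule for
$E_i(t)=\int_0^t c\,ds$) and the response is the Hill curve
$R = E^h/(\alpha^h + E^h)$ with $h = 1$.

**The SCLC parameterization.** The birth rate is a baseline 0.025/h plus the
SCLC increment 0.025/h (a 14-hour effective doubling time when uncrowded and
well oxygenated); the increment's unit is taken as 1/h.  The "viable cell
Hill coefficient 4" enters as the oxygen ramp
$g = s^n/(1+s^n)$, $s = (pO_2-pO_{2,N})/(pO_{2,P}-pO_{2,N})$, $n = 4$, which
suppresses division through most of the hypoxic band; a `ramp = "linear"`
option reproduces the classical piecewise-linear branch.  Where the ramp
enters is a genuinely open choice; both options are exposed.

**The 3% perinecrotic rule.** The package reads "3% rate" as a hazard of
0.03/h (default `perinecrotic_mode = "hazard"`), with a literal
3%-per-step option.  The reason is kinematic: the contact-necrosis front
creeps at about `prob`×(sites/step).  At the default 6-minute step the
per-step reading gives 0.3 sites/h, an order of magnitude faster than the
rim grows (≈ b×1 site ≈ 0.05 sites/h), so the necrotic wave overruns the
tumor and extinguishes it shortly after onset.  The hazard reading makes the
two fronts commensurate, which is exactly the role the rule plays — a brake
that bounds expansion (a carrying capacity), not a kill switch.

**Event ordering and reproducibility.** Necrosis is tested before apoptosis
before division, mutually exclusive within a step; the competing-risk error
is $O(\Delta t^2)$.  Cells are processed in fixed raster order and all
randomness flows through R's RNG, so a run is bit-reproducible from one
seed.  Clone labels (for heterogeneity experiments) are inherited at
division and replaced by a fresh label with probability `mutation_prob`
(default 0.01); labels are neutral — they alter no rates — and the
wild-type/mutant split in the time series is simply clone 1 versus the rest.
Drug treatment raises the drug field's far-field value to 5 µM at
$t = 528$ h (day 22) and lets it diffuse in.

With these defaults the first necrotic cell appears at a median ≈ 210 h
(spread roughly 170–265 h over seeds) on a 200×200 lattice, consistent with
necrosis initiating after 180 h; the necrotic core is interior-enriched and
the radially averaged oxygen decreases toward the tumor centroid (both
asserted in the test suite at 120×120).

## Growth with a dynamic carrying capacity

The deterministic module couples Gompertz growth
$dC/dt = \lambda C \ln(K/C)$ — the standard growth law of
dynamic-carrying-capacity models, consistent with $\lambda = 0.192$/day —
to a carrying capacity driven by angiogenesis:

$$\frac{dK}{dt} = \phi_{stim}\,C - \phi_{inhib}\,C^{2/3},$$

with $\lambda = 0.192$, $\phi_{stim} = 0.00873$, $\phi_{inhib} = 5.85$.
Read literally with those roles, $K$ can only grow once
$C > C^* = (\phi_{inhib}/\phi_{stim})^3 \approx 3.01\times 10^8$, below
which $K$ decays, and the joint fixed point $(C^*, C^*)$ is unstable from
above (no plateau).  The package implements this literal form as the
default — the fixed point is exactly stationary under the integrator — and
offers `form = "hahnfeldt"` with the canonical $K$-multiplied inhibition
$dK/dt = \phi_{stim} C - \phi_{inhib} K C^{2/3}$.  The familiar sigmoidal
curve with plateau $K^* = (stim/inhib)^{3/2}$ arises from the canonical form
with the original rate roles of the cited framework (stimulation 5.85,
inhibition 0.00873), and that is the configuration the worked examples use.

**Metastatic burden** is a deliberately simple, clearly flagged stand-in
for a full size-structured metastatic model: lesions are emitted at rate $\mu C^\theta$ per
day ($\theta = 2/3$, surface shedding; $\mu = 0$ by default, i.e. off) and
each cohort grows from size 1 by the closed-form constant-capacity Gompertz
solution $x(a) = K^{*\,(1-e^{-\lambda a})}$; the burden is the cohort sum,
nondecreasing by construction.  Both the burden and the emission-rate curve
are emitted, since which of the two a "metastatic growth rate" curve shows
is ambiguous.

**Numerics.** Classical fixed-step RK4 with $dt = 0.01$ day; the test suite
checks the trajectory against `deSolve::lsoda` at `rtol = 1e-10` (agreement
better than $10^{-6}$ relative) and step-halving convergence near the
formal 4th order.  Units of $C$ (cells vs mm³) are deliberately not fixed;
the model is scale-free and axes are labeled from configuration.

## Acid-mediated invasion and the biased random walk

The three-field system is implemented in its classical nondimensional form:

$$\partial_t C = \nabla\cdot\!\big(D_C (1-\upsilon)\nabla C\big) + \rho C(1-C),\qquad
\partial_t m = \nabla^2 m + \delta (C - m),\qquad
\partial_t \upsilon = \upsilon(1-\upsilon) - \gamma m \upsilon.$$

Tumor cells diffuse degenerately (only into degraded matrix), acid is
produced by tumor and decays linearly, and matrix regrows logistically while
being degraded at rate $\gamma$.  Note the $\upsilon$ equation keeps the logistic matrix-regrowth term; some
published variants omit regrowth, and that variant is *not* what this
module solves.  Defaults
$D_C = 4\times10^{-5}$, $\rho = \delta = 1$, $\gamma = 2$ sit in the
gap-forming regime: for $\gamma > 1$ the matrix collapses behind the acid
front and a hypocellular interstitial gap (minimum of $C+\upsilon$ at the
interface well below both bulk values) opens, which the tests verify across
$\gamma \in \{0.5, 2, 5\}$.

**Numerics.** Explicit Euler with conservative flux differencing for the
degenerate diffusion (arithmetic face averages of $1-\upsilon$).  The
admissible step is bounded by the fastest diffuser; since the acid field has
unit diffusivity the bound is $dt \le h^2 / (2\,d\,\max(D_C, 1))$ — a bound
based on $D_C$ alone would be unstable whenever $D_C < 1$.  Both
homogeneous steady states (fully invaded, fully healthy) are preserved
exactly.  In the Fisher limit ($\upsilon \equiv 0$, $m$ decoupled) the
tracked front (rightmost $C \ge 0.5$, speed fitted over the last third of
the run) propagates within 5% of $2\sqrt{\rho D_C}$ on a 2000-site grid.

The **single-cell walk** maps the 5-point explicit stencil of
$\partial_t C = D_C \nabla^2 C - \chi \nabla\cdot(C\nabla\upsilon)$ to
movement probabilities: each move carries
$\tfrac{dt}{h^2}\big(D_C + \tfrac{\chi}{4}(\upsilon_{ahead} -
\upsilon_{behind})\big)$ and staying absorbs the remainder, so the set sums
to one, is reflection-symmetric, and biases the walker up the matrix
gradient (haptotaxis).  The haptotaxis term uses the standard
$\chi\nabla\cdot(C\nabla\upsilon)$ form; $\chi = 0$ — the default —
recovers the plain three-field system exactly.  An ensemble of $10^5$ walkers matches the stencil's density
evolution bin-by-bin within Monte-Carlo error in the test suite.

## Endpoint-constrained metastasis redistribution

This module is a visualization-grade simulation whose *endpoint is fixed by
construction*: every agent is assigned a target-organ phenotype up front by
largest-remainder apportionment of the organ-involvement table (liver 20.3%,
bone 18.3%, brain 15.5%, lung 10.0%, adrenal 6.0% — autopsy-cohort
percentages; the residual 29.9% stays at the primary site, a choice the
source table does not dictate but which matches a retained primary mass).
Ties in the apportionment break by descending fraction and then organ name,
so counts are deterministic: 1000 agents yield exactly 203/183/155/100/60/299.

Intermediate dynamics are illustrative: agents drift toward their organ
anchor, are attracted to their phenotype cluster's centroid, and jitter with
Gaussian noise; they stop within a capture radius of the anchor.  The organ
anchor coordinates are schematic layout data.  Because the phenotype counts
are fixed at allocation, the final fractions are exact for every seed — the
constraint is structural, not emergent — and that is what the endpoint
tests assert.  The per-patient organ percentages sum below 100 because
patients can harbor several sites; reinterpreting them as per-cell
fractions is a modeling convenience, not biology.  A cohort helper computes
the distant-metastasis rate 100×152/251 = 60.6% with half-up rounding, as
clinical tables round.

## Multifractal image analysis

* `similarity_dimension(N, r)` evaluates $D_S = -\ln N / \ln r$ for exact
  constructions.
* `box_count()` counts non-empty boxes on origin-anchored grids (dyadic
  sizes by default; powers of 3 suit triadic fixtures) and fits
  $\ln N(\epsilon)$ against $\ln(1/\epsilon)$.  Sizes above a quarter of
  the longer image side are excluded from the fit (boundary saturation)
  but still reported.
* `holder_alpha()` estimates the per-pixel Hölder exponent as the
  least-squares slope of $\ln \mu_\epsilon$ vs $\ln \epsilon$ over square
  centered windows (replicate padding at borders) for four capacity
  measures: `sum`, `max`, `min`, and `iso` (pixels within one intensity
  quantum of the center).  Square windows are a documented choice; the
  window shape is not specified by the underlying method descriptions.
  Zero measures are floored at one intensity quantum before the log so
  that α stays finite on digital images.
* `multifractal_spectrum()` bins α over the support of the measure
  (positive-intensity pixels) and box-counts each level set; bins under the
  noise threshold (default 0.1% of support pixels) are dropped.
  Restricting to the support matters: level sets of near-background "halo"
  pixels otherwise dominate the spectrum and push its peak toward the
  embedding dimension 2 instead of the support dimension.

Fixture generators provide exact test objects: the dyadic Sierpiński gasket
(`bitwAnd` construction, box dimension exactly $\ln 3/\ln 2$ under dyadic
boxes), the Koch curve rasterized at one pixel per elementary segment
(dimension within 0.05 of $\ln 4/\ln 3$ from depth 5, error decreasing with
depth), Euclidean controls, a recursive two-branch fractal tree
($2^{d+1}-1$ segments), and a seeded smooth blob texture for grayscale
tests.  These are *synthetic* fixtures; nothing in the package analyzes or
validates real histology or radiology images.

## Configuration, seeds and the command line

`load_config()` layers defaults < YAML file < overrides, validates against
the per-module schema and suggests the nearest key on a typo.
`run_simulation()` dispatches, writes CSV/PNG/JSON outputs plus a manifest
echoing the fully resolved configuration, and derives one RNG stream per
module from the top-level seed by a stable hash, so identical config and
seed give byte-identical outputs.  A thin wrapper script
(`inst/scripts/sclc-sim`) exposes the same surface from a shell.  Grid-size
keys are spelled `lattice_size`/`grid_size`/`n_agents` because YAML 1.1
would parse a bare key `n` as a boolean.

## Problem sizes, limitations and what the tests do (and do not) show

The test suite runs every model at deliberately moderate sizes: the coupled
automaton at 120–200² lattices for a few hundred simulated hours, the
Fisher front on 2000 sites, walker ensembles of $10^5$, fractal fixtures up
to 512².  The synthetic fixtures and simulation conditions exercise the
*mathematical* properties — conservation laws, hazard limits, fixed points,
front speeds, exact dimensions — and reproduce the qualitative phenotypes
(hypoxic core, sigmoidal growth with plateau, wild-type/mutant burden
curves, endpoint-constrained organ fractions).  They do not validate
the models against patient data: most rate constants of the automaton are
unpublished and were taken from the cited solver tradition, the
metastatic-burden companion is an explicit stand-in, and the clone labels
are neutral tags rather than a mutational model.  The suite checks
invariants and qualitative shapes rather than matching any particular
published simulation output — most of the constants such a match would
require are not publicly fixed — and shapes are asserted only where they
are robust across seeds.
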