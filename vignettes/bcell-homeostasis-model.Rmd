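---
title: "A quantitative model of B-cell homeostasis by BCR saturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quantitative model of B-cell homeostasis by BCR saturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrsim)
```

## The model

`bcrsim` simulates clonal B-cell populations as points on a two-dimensional
map: free antigen concentration $[\mathrm{Ag}]$ on one axis and apparent
dissociation constant $K_D$ on the other, both spanning the working range
$[10^{-14}, 10^{-3}]$ M. The receptor occupancy at equilibrium is

$$\theta = \frac{[\mathrm{Ag}]}{[\mathrm{Ag}] + K_D},$$

so $\theta = 1/2$ exactly when $[\mathrm{Ag}] = K_D$. The model's central
assumption is that a B cell must keep its receptor *partially* saturated to
stay responsive: fully unengaged and fully saturated receptors alike cannot
report changes in antigen concentration. Cells whose log-ratio
$\log_{10}([\mathrm{Ag}]/K_D)$ sits inside a narrow "comfort" band around
zero rest in G0; cells outside it act to return:

* **vertical moves** — proliferation (more receptors per compartment, less
  free antigen in a depletable niche) or death (released antigen raises
  $[\mathrm{Ag}]$);
* **horizontal moves** — receptor editing, isotype switching and somatic
  hypermutation, which change intrinsic or apparent affinity.

When totals rather than free concentrations are known, the simulator solves
the two-component mass-action equilibrium: the complex concentration is the
smaller root of $x^2 - (A+B+K)x + AB = 0$ with $A$ total epitope, $B$ total
paratope, $K$ the dissociation constant, evaluated in the
cancellation-free form $x = 2AB/(S + \sqrt{S^2-4AB})$, $S = A+B+K$. This
matters numerically: over the eleven-decade working range $K$ is routinely
$10^6$-fold below $A$ and $B$, where the textbook quadratic formula loses all
significant digits. Affinities are stored internally as $\log_{10} K_D$ for
the same reason.

Avidity and binding kinetics are out of scope: concentrations are of epitope
and paratope, and only the equilibrium point is used.

## Engagement classes and their defaults

Classification into NEGLECT < UNDER < COMFORT < OVER < SATURATED is
deterministic given a band:

| parameter | default | meaning |
|---|---|---|
| `delta_comfort` | 0.5 log10 units | comfort iff $|\log_{10}([\mathrm{Ag}]/K_D)| \le \delta$; keeps $\theta \in [0.24, 0.76]$, bracketing 50% |
| `theta_neglect` | 0.01 | occupancy below this is no signal at all |
| `theta_saturated` | 0.99 | occupancy above this is unresponsive saturation |
| `delta_b1` | 1.5 log10 units | upper edge of "moderate" over-engagement in blood |

The source model states only that the comfort zone is the region
$[\mathrm{Ag}] \approx K_D$; half a decade on either side is this package's
choice, as are the 1%/99% thresholds (symmetric in odds). The band
constructor enforces that the neglect/saturation thresholds lie strictly
outside the occupancy attained at the band edges, so the five classes
partition the plane and the phase map is monotone along both axes.
$[\mathrm{Ag}] = 0$ is classified NEGLECT by convention (the log-ratio is
undefined, but there is no engagement).

A boundary note: the working-range floor of $10^{-14}$ M is motivated as
roughly ten antigen molecules in the ten nanoliters a single cell might
sample, but `molarity_from_count(10, 1e-8)` evaluates to
$1.66 \times 10^{-15}$ M. The floor is kept at $10^{-14}$ M and the
order-of-magnitude rounding is simply documented; neither value is asserted
as ground truth.

## Niches: the pool contract

A niche is a volume plus an antigen panel. The single most consequential
distinction is **depletable vs inexhaustible**:

* **Blood** (default 5 L) is a fluid tissue whose species are flagged
  `replenished`: no paratope load, division or clearance ever moves their
  concentration. This is asserted, not approximated — a property test checks
  bit-identity over a thousand steps.
* **Bone marrow, follicles, germinal centers and memory sites** are
  depletable: each species carries a mole count, free antigen comes from the
  equilibrium against the summed cognate paratope, and the pool is updated by
  explicit flows (consumed + cleared − released by death, floored at zero
  with a warning).

Consumption is accounted *incrementally*: when a clone divides, the pool
loses the complex newly formed by the daughter cells' receptors (equilibrium
complex after the division minus before), while standing complex is only
reversibly sequestered. An earlier draft consumed the full standing complex
per division; once paratope approaches the pool size that destroys nearly
the entire pool in one step and over-engaged clones crash from OVER to
NEGLECT instead of settling into comfort. The incremental rule is the one
under which the documented convergence property holds: an over-engaged clone
in a depletable niche reaches the comfort band by division-driven depletion
in essentially every seeded run.

Bone-marrow and follicular antigen display (complement- and Fc-receptor
captured material) is modelled as a depletable mirror of the blood panel at
a display efficiency of 0.1× — a placeholder exposed in configuration, since
no quantitative display efficiency is available; the capture mechanism
itself is not modelled.

## Fate rules

The fate machine is deterministic given (stage, engagement, niche, second
signal); every combination returns an action or raises a configuration
error — there is no silent fallthrough, and an exhaustiveness test walks the
whole cube.

* COMFORT → rest in G0, in every niche.
* NEGLECT → death.
* UNDER → in the bone marrow, receptor editing while the editing budget
  lasts (default 3 rearrangement attempts — the biology offers a second
  heavy-chain locus and additional light-chain loci, without an exact
  count), then death; in a germinal center, continued competition; elsewhere
  death.
* OVER → division; with a second signal, germinal-center entry (follicle)
  or isotype switch (blood).
* SATURATED → in the bone marrow, clonal deletion (aggressive
  self-binding); elsewhere division.

Blood immature/transitional emigrants get their own classifier because the
inexhaustible pool changes the logic: division cannot lower $[\mathrm{Ag}]$,
so persistent fates appear. Log-ratios in `(delta_comfort, delta_b1]` give
the self-replenishing, G1-persistent B1 fate (dividing on a fixed cadence,
default every 8 steps). Stronger over-engagement with a second signal gives
the marginal-zone fate: a one-off apparent-affinity adjustment
(`apparent_factor` scaled by $10^{-\mathrm{round}(\text{log-ratio})}$, then
frozen) that parks the clone inside the comfort band. The `delta_b1 = 1.5`
boundary is a modelling choice; the source only says "moderate supraoptimal"
signals. Note that the marginal-zone adjustment requires `apparent_factor`
to drop below 1 (damped engagement), so the package constrains the factor to
be positive rather than ≥ 1; isotype switching multiplies it by
`switch_gain` (default 10), lowering apparent $K_D$.

## Somatic hypermutation

Each mutation event: lethal with probability `p_lethal = 0.3`; otherwise the
heavy chain is hit with probability `p_heavy = 0.6` (rerouted if a chain is
at cap), and the step is deleterious (raises $\log_{10} K_D$) with
probability `p_del/(1 - p_lethal) = 5/7`, beneficial otherwise, with a
half-normal step of scale `sigma_step = 0.4` log10 units. Counters are
hard-capped at 30 heavy- and 20 light-chain mutations, the documented
maxima for affinity-matured antibodies. These rates satisfy the one
qualitative constraint available — most mutations reduce affinity — and were
fixed together with the germinal-center defaults so that the
repeated-immunization ensemble lands near the documented post-vaccination
affinity statistics (see below). Draw order (lethality, chain, direction,
step size) is fixed for replay determinism.

## The germinal center

Each cycle is one light-zone/dark-zone pass:

1. **Capture.** A fraction `f_present = 0.5` of the pool is displayed and
   split across clones in proportion to $n_i \theta_i$ (cells × occupancy at
   the current pool concentration): bigger and higher-affinity clones
   capture more. A stochastic multinomial split is available by
   configuration; the default is the deterministic proportional split.
2. **Division.** Divisions are regulated by captured antigen:
   $\min(\texttt{div\_cap}, \lfloor \alpha \cdot c_i / c_{\mathrm{ref}}
   \rfloor)$ with $\alpha = 4$, cap 6. The reference capture
   $c_{\mathrm{ref}}$ is derived each cycle as the equal share of the
   displayed antigen, scaled so an even split earns 2 divisions — hence a
   lone founder performs exactly 2 divisions in cycle 1, and competition
   stays *relative* as the pool shrinks and the clone list grows. (A
   reference frozen at cycle 1 lets divisions collapse to zero within two
   cycles as the population outgrows it, stalling maturation entirely;
   linearity-with-cap itself is a declared choice, since only "regulated
   by" capture is documented.)
3. **Mutation.** Every division round doubles the clone and hands the
   daughter cohort one hypermutation draw: lethal kills the cohort, a viable
   mutation splits it off as a new clone with shifted $K_D$, cap-exhausted
   cohorts fold back into the parent. Mutants therefore compete as distinct
   clones from the next cycle on — selection acts on inter-clone variance,
   which is what lets affinity improve although deleterious steps outnumber
   beneficial ones.
4. **Selection.** The pool loses the captured antigen plus a 10% decay
   (antibody-mediated clearance placeholder). Clones falling to NEGLECT at
   the new concentration die. Clones reaching COMFORT exit: to MEMORY while
   the pool is above 1% of its initial value; below that threshold the
   clone holding the cycle's largest capture exits as a long-lived plasma
   cell (it captured "the last antigen", losing its BCR and escaping
   antigen regulation), all others as plasmablasts. Comfort clones whose
   intrinsic $K_D$ exceeds the maturation ceiling of $10^{-7}$ M fail
   selection and linger instead of exiting. Exported $K_D$ is floor-clamped
   at $2 \times 10^{-12}$ M, the best documented matured affinity.
5. A carrying capacity (`max_clones = 120`) culls lowest-weight clones.

A dose is one germinal center: initial pool `dose_conc = 1e-6` M in a
`1e-7` L microenvironment, 20 germline founders (log-uniform $K_D$ in
$[10^{-10}, 10^{-6}]$ M), up to 15 cycles. The default immunization schedule
is three identical doses, each seeded with the memory output of the previous
plus fresh founders. With the default parameters the pooled ensemble over 30
seeds has a geometric-mean exported $K_D$ of a few $10^{-9}$ M, inside the
$[10^{-10}, 10^{-8}]$ M calibration band around the documented
post-vaccination average of $1.0\times10^{-9}$ M, with every exported clone
inside $[2\times10^{-12}, 10^{-7}]$ M — numbers the acceptance suite and
`scripts/acceptance.R` recompute rather than assert.

## What the synthetic world does and does not emulate

The antigen-panel generator draws log-uniform concentrations over the
documented mM-to-pM span; panels are compositionally mirrored across blood,
bone marrow and follicles at fixed display efficiency. Real repertoires see
correlated, time-varying, immunologically structured antigen panels;
cross-reactivity beyond a single cognate species is off by default; T-cell
help is a boolean; division is synchronous; one germinal center per dose. A
green test therefore establishes the internal consistency of the stated
model — mass-action arithmetic, fate-machine totality, pool contracts,
replay determinism, and the calibrated maturation statistics — not
biological prediction beyond the model's own assumptions.

## Numerical and design notes

* Determinism: one master seed; per-module substreams derived by a small
  integer hash (`substream_seed`), so module tests and full runs replay
  identically. Two runs with the same configuration hash to byte-identical
  output files.
* Equilibrium: stable quadratic root as above; an independent bisection
  oracle on the mass-action polynomial agrees to $10^{-10}$ relative error
  across the working range (property-tested on 1000 log-uniform triples).
* Conservation: `ag_free + complex = ag_total` and
  `bcr_free + complex = bcr_total` hold to $10^{-9}$ relative by
  construction.
* Configuration is strict JSON with a schema version: unknown keys are
  errors, defaults are resolved at load time, bounds are validated before
  any step runs. (JSON rather than YAML/TOML because no YAML or TOML reader
  is available in the supported dependency set.)
* Trajectory floats are serialized in scientific notation with 9
  significant digits, LF endings, no quoting, for replay-diffing.
* Known limitations: clone-level (not single-cell) granularity; the
  LLPC tie-break makes long-lived plasma cells rare in crowded germinal
  centers (only the cycle's top capturer can take that exit); no antibody
  feedback network; no trafficking or spatial structure beyond discrete
  niches.

## A worked example

```{r example, eval = FALSE}
library(bcrsim)

# occupancy anchor: half-saturation at [Ag] = K_D
occupancy(1e-9, 1e-9)
#> [1] 0.5

# three-dose immunization ensemble, 30 seeds
cfg <- default_config(seed = 1)
ens <- run_gc_ensemble(cfg, n_seeds = 30)
ens$summary$kd_geomean   # 2.110825e-09 M: inside [1e-10, 1e-8]
ens$summary$kd_min       # 2e-12 M: the matured-affinity floor
ens$summary$mut_h_max    # 12: under the 30-mutation heavy-chain cap
```
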