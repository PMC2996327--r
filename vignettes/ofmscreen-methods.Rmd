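---
title: "Models and methods behind ofmscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ofmscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ofmscreen)
```

`ofmscreen` models one experimental programme end to end: measuring how
fast yeast cells lose chromosome III derivatives that lack efficient
replication origins, screening mutants for *originless fragment
maintenance* (Ofm) phenotypes, and simulating the replication dynamics
that explain them. This vignette documents the models, the parameters
that matter, and the choices made where the design was genuinely open.

## 1. Fluctuation analysis

### Model

A culture grown from a single fragment-bearing cell to $N$ cells
accumulates loss events at a constant probability $\mu$ per division.
Each event founds a clone of loss-derived (red) cells that keeps growing
alongside everyone else, so a clone born when the culture had $j$ cells
ends with about $N/j$ cells. The number of events per culture is
Poisson with mean $m = \mu N$, and the distribution of loss-derived
cells per culture is the familiar heavy-tailed ("jackpot")
Luria–Delbrück distribution, computed in `ld_pmf()` by the standard
recursion

$$p_0 = e^{-m}, \qquad
  p_r = \frac{m}{r} \sum_{i=0}^{r-1} \frac{p_i}{r-i+1}.$$

Assumptions worth stating: loss-derived cells grow at the same rate as
fragment-bearing cells (a `relative_fitness` parameter in
`simulate_assay()` lets you break this assumption in simulation, but all
estimators assume 1); divisions per culture are taken as $N$ rather than
$N-1$ (negligible for $N \ge 10^3$); cultures are independent and share
$N$.

### Estimators

* `estimate_p0()`: $\hat m = -\ln(\text{fraction of zero cultures})$.
  Best when $m \lesssim 2$; undefined with no zero culture (a classed
  error points the caller elsewhere).
* `estimate_lc_median()`: the unique positive root of
  $\tilde r/m - \ln m = 1.24$, with $\tilde r$ the median count. The
  constant 1.24 is the classical median-equation constant. The root is
  found by `uniroot()` bracketed on $[10^{-6}, 10^6]$ in log space
  (relative tolerance $10^{-8}$; the left side is strictly decreasing so
  the root is unique). The *lower* median is used for even culture
  numbers — the conservative choice, and the one that keeps the
  estimator monotone in the data.
* `estimate_mss_mle()`: maximises $\sum_i \ln p_{r_i}(m)$ with $p$ from
  `ld_pmf()`, bracketing the optimum a factor of 10 either side of the
  Lea–Coulson (or P0) start. Counts at or above a cap (default 1024) are
  right-censored through the tail mass: a jackpot's exact size carries
  almost no information about $m$ and exact evaluation would cost
  $O(r^2)$.

When only `cells_sampled` of the culture is scored, counts are treated
as a hypergeometric sample of the final population and $\hat m$ is
scaled by $N/s$; whether the original colony-isolation measurements used
such corrections is not documented, so the correction is opt-in.

### Uncertainty

Published tables report "± S.D." without stating how it was computed, so
the package does not attempt to reproduce those numbers.
`bootstrap_ci()` reports a percentile interval over resamples of
cultures (deterministic given `seed`; resamples on which the estimator
is undefined are dropped, with an error if they exceed half). The test
suite checks ~95% empirical coverage at $m = 5$, $n = 100$ cultures.

## 2. The Ofm index

`ofm_index(mut5, base5, mut0, base0)` returns
$(\mu_5^{mut}-\mu_5^{base}) / (\mu_0^{mut}-\mu_0^{base})$ with all rates
in the display unit of $10^{-5}$ per division (the index is
scale-invariant, so raw probabilities work identically). Choices:

* **Degenerate denominators.** A non-positive denominator yields `NA`
  ("not defined"), never ±∞ — this covers the baseline scored against
  itself. A negative *numerator* over a positive denominator is a real
  negative value and is reported as-is.
* **Alternate baselines.** `score_ofm(..., baseline =)` lets a different
  strain (e.g. an *sml1Δ* control for strains that require it) supply
  **both** baseline rates. Applying the alternate baseline to the
  denominator only does not reproduce the published paired values
  (e.g. it gives 79 rather than 83 for the *mec1Δ sml1Δ* row), whereas
  applying it to both does reproduce all three, so both it is.
* **Rounding.** Half away from zero (−3.33 → −3, 18.6 → 19), matching
  the published display convention.
* **Classification.** `Ofm` requires a defined index ≥ 20 *and* at least
  2-fold destabilisation of the origin-depleted construct (a guard
  against large indices without real destabilisation); `non-Ofm` is a
  defined index < 10; everything else is `indeterminate`. The non-Ofm
  cut sits at 10, not 5, because indices of 7 were verbally called
  non-Ofm in the source material while 33 was called Ofm. The 2-fold
  guard leaves a borderline case (index 33 with 1.95-fold
  destabilisation) `indeterminate` under defaults; all three thresholds
  are arguments.
* **Index SD.** `ofm_index_sd()` is the first-order delta method under
  independent errors. It is trustworthy only while the denominator's
  coefficient of variation is small (≲ 20%); for noisy denominators the
  index's sampling distribution is heavy-tailed and the delta SD
  understates the spread — the tests demonstrate both sides of this
  boundary.

## 3. Colony sectoring

### Model

`simulate_sectors()` grows a synchronous binary division tree from one
fragment-bearing founder. At each division of a fragment-bearing cell,
with probability $\mu$ exactly one daughter loses the fragment (this
matches the *per-division* rate definition used in the loss-rate
tables, rather than independent per-daughter loss); each such event in a
white lineage founds one visible red sector. Events inside already-red
lineages are invisible (nested sectors merge under visual scoring), red
lineages keep growing, there is no cell death and no spatial geometry.
The white-cell count therefore evolves as
$W_{g+1} = 2W_g - \mathrm{Bin}(W_g, \mu)$ and the expected number of
visible sectors after $G$ generations is
$\sum_{g=0}^{G-1}\mu(2-\mu)^g$. An exact small-$G$ distribution is
available (`sector_distribution_exact()`) and anchors the simulator in
the tests (total-variation < 0.02 at $G = 3$, $10^5$ colonies).

### The visibility horizon

Only events in the first $G$ generations found a sector big enough to
score by eye; colony size and the minimum visible sector fraction are
not documented anywhere, so $G$ is this model's one calibration knob.
It was set by requiring the three published anchor rates to land in
their verbal classes — $2.1\times10^{-3}$ per division gives 0–3
sectors, $10^{-2}$ gives 5–10, $10^{-1}$ gives ≥ 10. Measured over 500
colonies × 20 seeds, $G = 9$ yields medians 1 / 5 / 36 (exactly the
three classes); $G = 10$ yields 2 / 10 / 70, pushing the middle anchor
into the "high" class. The default is therefore `generations = 9`
(roughly: a sector must comprise ≳ 0.2% of the colony).

`classify_sectors()` maps median counts to classes with boundaries at 4
and 10; a median of 4, which the verbal scale leaves unassigned, counts
as `elevated`. `screen_call()` encodes the duplicate-chromoductant
rules; combinations the verbal rules leave open (e.g. concordant
`elevated` sectoring of the origin-replete construct) fall into
`possible_probable`, the "look again" verdict.

## 4. The gap replication simulator

### Mechanics

Per simulated cell, each origin is licensed with probability
`competence`, draws a firing time from a normal truncated at 0
(`t_mean_min`, `t_sd_min`), and fires only if its locus is still
unreplicated at that time — passive replication silences it, which is
all that "dormant" means mechanistically: a licensed origin whose late
programmed time means incoming forks normally beat it. Firing launches
two forks at `fork_speed_kb_min`. Forks arrest permanently with either
or both of

* a constant per-kb hazard `fork_fail_per_kb` ($f$): survival over $d$
  kb is exactly $(1-f)^d$;
* a fork-aging hazard: survival $\exp(-(d/L)^k)$ with characteristic
  distance `fork_lifetime_kb` ($L$) and Weibull shape
  `fork_lifetime_shape` ($k = 3$ by default). Aging makes *old* forks
  fail, so arrests cluster near the end of long traverses — and rescue
  forks, which travel short distances, almost never die.

Coverage uses true fork semantics: between adjacent *fired* origins only
the two facing forks replicate; a trailing fork merging into an interval
whose leading fork has died does **not** take over the front. A dead
front is rescued only by an origin firing beyond it. Passive-replication
checks during the firing sweep respect the same adjacency (the nearest
fired origin on each side). A cell is scored incomplete — equated with
loss of the construct at the next division — if any position is
unreplicated at `available_min`, the time from the start of S phase
until mitosis.

### Packaged maps and regimes

Coordinates are stylised: they preserve the published relative geometry
(a ~100-kb origin-deleted gap, ARS313 ≈ 20 kb and ARS315 ≈ 50 kb distal
to its right edge, HML-associated dormant origins near the left
telomere, a right arm with regularly spaced efficient origins and
normally-dormant subtelomeric elements) rather than base-pair positions.
Efficiency classes become: efficient = competence 0.9, firing 10 ± 4
min; inefficient = 0.2, 25 ± 5 min; dormant = 0.9, 50 ± 5 min. The
dormant mean sits at 50 min (late in a 55-min S phase): at 45 min the
leftmost dormant origin fired in ~2% of origin-replete wild-type cells,
at 50 min in < 1%, and dormancy should be near-absolute with a full
origin complement. **The simulator's claims are orderings and ratios
between constructs and regimes, never absolute loss rates.**

Regimes model genotypes:

| regime | fork speed | arrest | available |
|---|---|---|---|
| `wild_type` | 2.3 kb/min | none (crippled forks always restored) | 145 min |
| `rad9_like` | 2.3 | aging, $L$ set so survival of 127 kb = 0.9 | 115 min |
| `mec1_like` | 1.15 | constant $f = 2\times10^{-4}$ | 65 min |
| `mrc1_like` | 1.15 | constant $f = 2\times10^{-4}$ | 65 min |

The logic: restoring aged (crippled) forks requires the DNA damage
response, so only the `rad9_like` regime suffers aging arrests; its
scale is anchored so a single leftward fork fails ~10% of the time over
the 127-kb origin-free traverse of the ΔL-6ORIΔ fragment — the
observation the fork-failure arithmetic rests on. A constant per-kb
hazard cannot reproduce the stability pattern: it concentrates deaths
*early* in a traverse, forcing rescue forks to travel nearly the whole
gap and die nearly as often, which caps the dormant-rescue benefit near
8-fold (measured) versus the ≥ 10-fold ordering the data show; the
rising hazard restores the pattern structurally (~60-fold, measured at
$n = 2\times10^4$). Checkpoint-proficient genotypes can delay mitosis
(generous `available_min`); `mec1_like` cannot delay at all, so its
slow forks lose long-gap constructs by running out of time — which is
also why dormant origins barely help it, mirroring the published
contrast. 55 min of S phase and 2.3 kb/min are the standard kinetic
constants; `available_min` defaults to `s_phase_min` in the constructor,
and the packaged values above are calibration, not measurements.

### Numerical details

Firing ties are broken by draw order after sorting on time (ties have
probability zero for positive `t_sd_min`); a cell counts as incomplete
when its unreplicated length exceeds $10^{-9}$ kb; truncated-normal
draws use the inverse CDF, so `t_sd_min = 0` degenerates cleanly to the
mean; arrest distances combine the exponential (constant-hazard) and
Weibull (aging) channels by taking the minimum. All simulations are
deterministic given `seed`, restore the caller's RNG state, and record
the seed in their output.

## 5. The synthetic screen generator

`make_panel()` anchors the wild-type strain at the tabulated reference
rates ($2.1\times10^{-3}$ per division for 5ORIΔ-ΔR, $3\times10^{-5}$
for 0ORIΔ-ΔR). Archetypes draw multipliers: `ofm_like` multiplies the
origin-depleted rate log-uniformly by 5–50 and the origin-replete rate
uniformly by 1–4; `general_instability` applies one shared log-uniform
multiplier of 300–3000 to both (rates capped at 0.5). The lower end of
that shared range is set by detectability, not by the 100-fold
definition of general instability: at exactly 100-fold the
origin-replete rate is $3\times10^{-3}$, which the sectoring calibration
itself maps to 0–3 sectors — indistinguishable by eye from an Ofm
strain — whereas the non-Ofm exemplars sectored heavily on *both*
constructs. `intermediate` (shared 30–300) exists for boundary
exploration and is excluded from default mixes.

`run_virtual_screen()` mirrors the two-stage screen: duplicate
sectoring observations per construct (500 colonies each), verdicts via
`screen_call()`, then fluctuation assays for called strains — 50
cultures of $10^4$ cells for the origin-depleted construct and $10^5$
cells for the origin-replete one, sizes chosen so $m = \mu N$ sits in
the estimators' working range on both sides. Every stage receives an
explicit sub-seed derived from the master seed, so whole screens are
byte-reproducible.

What the generator does **not** emulate: plating efficiency and
adenine-pigment kinetics, chromoduction failure and diploid
contamination, fitness differences of loss derivatives, spatial sector
geometry, and the structural instability (e.g. repair off a balancer
chromosome) that real origin-poor fragments can show. Passing tests
therefore demonstrate that the pipeline recovers truth under the
idealised assay model, not that real screens achieve these error rates.

## 6. Problem sizes and test design

The suite verifies estimator recovery at $m \in \{1, 2, 5, 20\}$ with
200 cultures × 20 seeds; pmf and colony-tree distributions against
$10^5$-draw Monte-Carlo histograms; replication limits at
$10^4$–$2\times10^4$ cells; and ten 200-strain virtual screens. These
sizes keep every Monte-Carlo comparison at least three standard errors
wide of its threshold while the whole suite stays interactive
(~2 minutes).

## 7. Known limitations

* The replication simulator's absolute incomplete fractions are not
  calibrated to measured loss rates; only orderings are meaningful.
* The fork-aging shape ($k = 3$) is a modelling convenience; any
  sharply rising hazard reproduces the qualitative pattern.
* Estimator behaviour is validated for equal culture sizes; mixed-size
  assays must be split before estimation.
* The delta-method index SD degrades for noisy denominators (see §2);
  prefer Monte-Carlo propagation there.
* The Lea–Coulson estimator is coarse at $m \approx 1$ (integer
  medians); use P0 or the MLE at very low rates.
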