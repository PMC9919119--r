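---
title: "The defense–mating-system model: assumptions, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The defense–mating-system model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defmate)
```

## The question the simulator addresses

Plants defend against insect herbivores in two main ways: *resistance*
(preventing herbivory, e.g. trichomes or toxic secondary metabolites) and
*tolerance* (reducing the fitness loss once damage has occurred). Because
both are costly, carrying both — a *mixed defense strategy* — duplicates
costs and is naively expected to be unstable, yet mixed strategies are common
in natural populations. The mating system (the ratio of selfing to
outcrossing) interacts with defense through inbreeding depression and, under
gene-for-gene resistance, through a subtler route: selfing raises
homozygosity, so selfers tend to carry *redundant* resistance alleles when a
single allele already confers full protection, paying resistance costs twice
(a *resistance cost of selfing*).

`defmate` is an individual-based, seeded forward simulator of this system:
a hermaphroditic plant population coevolving with a dioecious herbivore
population, with diploid genetics, discrete generations, panmixia, and no
plasticity, ontogeny or spatial structure. A set of closed-form companions
(`scenario_predictions()`, `optimal_tolerance()`, `load_equilibrium()`,
`curvature_class()`, `fitness_surface_grid()`) gives the analytic
predictions the simulations can be compared against.

## The fitness model

Each plant's expected seed number is the base fitness $w_0$ (default 25)
times a fitness factor combining six terms, each powered by a shared
non-linearity exponent $l$:

* $RC = c_r r^l$ — resistance cost, with $r$ the resistance investment;
* $TC = c_t t^l$ — tolerance cost;
* $HD = c_h d^l$ — herbivory damage cost, with $d \in \{0,1\}$ the realized
  damage;
* $TB = b_t d^l t^l$ — tolerance benefit; tolerance is strictly *inducible*:
  without damage there is no benefit, only the cost;
* overdominance: $O_1 = (h_i/H)^k$ (multiplicative) or a penalty
  $O_2 = k(H - h_i)$ (additive), with $h_i$ the individual's genomic
  heterozygosity and $H$ a fixed reference (0.25);
* dominance load: $D = (u_i s)^l$, with $u_i$ the number of detrimental
  alleles carried and $s$ the per-allele selection coefficient, plus outright
  lethality ($I = 0$) for genotypes homozygous for a detrimental allele at
  any load gene.

Under the **multiplicative** model the factor is
$(1-RC)(1-TC)(1-HD+TB)\,O_1\,(1-D)\,I$ with every parenthesized factor
floored at zero; under the **additive** model it is
$\max(0,\; 1 - RC - TC - HD + TB - O_2 - D)\, I$. Two structural
consequences matter throughout: multiplicative fitness is annihilated by any
single zero factor (in particular $h_i = 0$ is lethal), and the
multiplicative overdominance ratio can exceed one, rewarding
above-reference heterozygosity.

One sign choice was genuinely open: written as a subtracted term, the
additive overdominance penalty must be $k(H - h_i)$ for above-average
heterozygosity to *raise* fitness, which is the stated intent of the term;
the opposite sign (a penalty $k(h_i - H)$) is preserved behind the
`o2_sign_verbatim` flag for comparison, but is not the default.

```{r}
p <- default_params()
fitness_factor(p, r = 0.25, t = 0, d = 0, h_i = p$H, u_i = 0) # 1 - c_r/4
fitness_factor(p, r = 0, t = 1, d = 1, h_i = p$H, u_i = 0)    # tolerance pays
```

Seed numbers are integer: `realize_seeds()` draws from a Poisson with mean
$w_0 F$. The model description samples a Poisson base fitness and "adjusts"
it by the fitness factor without fixing the integer mapping; Poisson
thinning of a Poisson($w_0$) base with probability $F$ is exactly
Poisson($w_0 F$), and the same form extends naturally to $F > 1$, so that is
the implementation.

## Genetics

Every effect — resistance, tolerance, selfing in plants; anti-resistance in
herbivores — is controlled by two unlinked diallelic genes; an individual's
*investment* is its effect-allele dosage over the four slots
(0, 0.25, ..., 1). Effect genes never mutate: effect alleles lost from view
can persist cryptically in heterozygotes and resurge by segregation.

The gene-for-gene encounter rule: a plant gene with at least one resistance
allele is *armed*; a herbivore with at least one anti-resistance allele at
the matching gene *disarms* it; an attack succeeds only if no armed gene
remains uncountered. One retained resistance allele (investment 0.25) gives
full protection, which is why 0.25 is the predicted equilibrium investment
when resistance is costly — and why homozygous selfers overpay.

Inbreeding depression emerges from a load genome of 100 unlinked genes per
plant. Each allele carries a neutral class (A/B) plus a detrimental flag.
Heterozygosity $h_i$ is the fraction of load genes whose two alleles differ
in composite state; the neutral classes exist so that outcrossing
populations can hold $h_i$ near 0.5 while only 10–15 detrimental alleles
segregate. Detrimental mutations arise one-way at rate `mu` per allele per
generation, are lethal when homozygous, and cost $u_i s$ when heterozygous.

The genomic mutation rate is a reconstructed quantity: the model's stated
load equilibria — about $U$ detrimental alleles per individual under fixed
selfing (each new lethal is exposed and purged within about one selfed
generation) and $2n\sqrt{\mu}$ under outcrossing (per-locus equilibrium
$q^* = \sqrt{\mu}$, the exact fixpoint of the recursion
$q' = (q+\mu)/(1+q)$) — pin `mu = 0.00245`, i.e. $U = 0.49$ and an
outcrossing equilibrium near 9.9. `load_equilibrium()` and
`load_equilibrium_recursion()` compute both routes; the tests require them
to agree within 1%.

```{r}
load_equilibrium(0.00245, 100, "outcrossing")
load_equilibrium(0.00245, 100, "selfing")
```

## Mating system

Two selfing architectures are implemented, differing only in how selfer
status is transmitted — which turns out to decide the outcome:

* **heritable**: every plant is self-compatible and selfs each ovule with
  probability equal to its selfing-allele dosage (0 to 1 in steps of 0.25).
  Selfing alleles keep the full "automatic" transmission advantage: selfed
  seeds carry two maternal gametes, and carriers still export pollen.
* **non-heritable**: a binary selfer tag, copied maternally and never
  transmitted through pollen; selfer plants self all ovules, outcrossers
  none. This severs the genic transmission advantage while keeping the
  demography of selfing identical.

Pollen donors for outcrossed ovules are drawn uniformly from all plants
(pollen production is not fitness-weighted, and selfers do export pollen) —
the simplest rule consistent with panmixia that preserves the heritable
mode's pollen-export advantage.

Under the additive model, heritable selfing behaves as a textbook selfish
element: it fixes from frequency 0.5 within tens of generations in the
package's seeded runs, after which purging drives the load toward $U$ and
heterozygosity collapses toward zero. Under the multiplicative model the
package's runs show the opposite: selfing modifiers rise only while the
lethal load is still near its (zero) initial value, and collapse once the
load approaches its outcrossing equilibrium — at ~10 heterozygous lethals a
selfed seed survives with probability $(3/4)^{10} \approx 0.06$, an
inbreeding depression far beyond the one-half threshold that the
transmission advantage can pay for, compounded by the multiplicative
overdominance ratio punishing every halving of $h_i$. The same
race-against-the-load argument explains why strongly elevated inbreeding
costs (high $k$, high $s$) prevent fixation even under the additive model.
The acceptance suite asserts the stronger claim (fixation regardless of
model and cost settings) and records these two settings as failing; the
unit suite asserts the robust additive behavior. Non-heritable selfing is
consistently extirpated under the multiplicative model, as expected when
the tag gains no transmission advantage but inherits all the costs.

## The per-generation loop

`run_simulation()` executes, per generation: herbivore attacks (each
herbivore picks one plant uniformly with replacement; damage saturates at
1), plant fitness and Poisson seed counts, the next plant generation
(selfing decision per seed, gamete formation with free recombination,
load-genome mutation, lethal culling at birth, uniform subsampling of viable
seeds to the plant capacity), and the next herbivore generation (Poisson
broods per fed female, fitness-weighted paternity among males, subsampling
to capacity). Damage precedes reproduction, so tolerance benefits are
inducible within the same generation. Herbivore extinction is a recorded
state and the run continues without damage; plant populations below two
individuals terminate the run.

Lethal offspring are culled at birth rather than carried as zero-fitness
adults — distributionally equivalent for gene-frequency dynamics and much
cheaper. Regulation is uniform subsampling of the viable seed pool, so
populations can shrink below capacity under severe inbreeding depression;
that is what makes inbreeding-driven extinctions possible.

## Determinism and performance

All randomness flows through R's RNG: `run_simulation(p, seed)` seeds once
and two identical calls are byte-identical. Replicates and sweep cells get
seeds from the documented splitting rule in `replicate_seed()`. The
per-offspring load-genome construction is the hot loop and is implemented in
C++ (via Rcpp, still on R's RNG): segregation bits are consumed 16 at a time
from the top bits of single uniform draws, and mutation uses a
Binomial-count plus distinct-position scheme that is exactly equivalent to
independent per-allele Bernoulli(`mu`). Rather than building every seed, the
seed pool is processed in a uniformly random order and the first
carrying-capacity-many viable seeds are kept — identical in distribution to
building all seeds, culling lethals, and subsampling. A default-sized
generation (500 plants, 500 herbivores) takes a few milliseconds, so the
full published-scale horizon (15,000 generations) runs in minutes.

## Parameters

| symbol | meaning | default |
|---|---|---|
| `w0` | base fitness, seeds per unimpaired plant | 25 |
| `c_r`, `c_t`, `c_h`, `b_t` | resistance/tolerance/herbivory costs, tolerance benefit (proportions) | 0.15, 0.4, 0.75, 0.25 |
| `c_a` | herbivore anti-resistance cost | 0.4 |
| `k`, `H` | overdominance shape, reference heterozygosity | 0.3, 0.25 |
| `s` | selection per detrimental allele | 0.005 |
| `l` | non-linearity exponent (0.2–5) | 1 |
| `mu` | per-allele load mutation rate | 0.00245 |
| `model`, `selfing_mode` | allocation model; selfing architecture | multiplicative, none |
| `K_plants`, `K_herbivores` | carrying capacities | 500, 500 |
| `generations`, `replicates` | run length, replicate count | 15000, 3 |

Structural values the model statement leaves open were fixed once:
populations of 500 plants and 500 herbivores (large enough that drift does
not dominate the deterministic predictions at desk scale, small enough for
replicated sweeps), initial effect-allele frequencies of 0.5 everywhere (so
both alleles start common and either fixation or loss is informative),
initial load-genome neutral-class frequency 0.5 (initial $h_i \approx 0.5$),
no initial detrimental alleles, herbivore fecundity 25 (mirroring $w_0$) and
a failed-attack fitness cost of 0.75 (mirroring $c_h$; failure is costly but
not lethal, so herbivores are not trivially extirpated). The non-linearity
range 0.2–5 is validated as a hard bound because those are the extreme
shapes the analysis exercises.

## What the tests and acceptance checks do (and do not) show

The test suite runs reduced problem sizes chosen for statistical adequacy:
population 120–800, horizons of 30–1,000 generations, 2–3 replicates; the
acceptance script runs the target setups (500–1,000 plants, 1,000–2,000
generations, 3 replicates). At these scales the package's seeded runs show:
baseline seed expectation 25; costly resistance settling near allele
frequency 0.25 under coevolving herbivores; a tolerance fixation/loss
boundary near $b_t = 0.5$ on the linked sweep $b_t = 1 - c_t$ (resolved to
half the 0.1 grid step); outcrossing heterozygosity near 0.5 and load near
9–10; selfing-fixed heterozygosity below 0.02 and load below 1.5.

The synthetic populations emulate the model world exactly — they are the
object of study, not a proxy for field data. Passing tests therefore say
nothing about real plant populations beyond what the model architecture
encodes: binary damage, constant herbivory cost, two genes per effect, free
recombination, a constant reference heterozygosity, and no plasticity,
pollen limitation, seed dormancy or spatial structure. Finite-size effects
are visible at desk scale (outcrossing heterozygosity sits slightly below
0.5 because drift erodes neutral diversity faster than weak overdominance
restores it); they shrink with population size but are not removed.

## Known limitations and open edges

* The heritable-selfing fixation claim holds in this architecture only for
  the additive model at moderate inbreeding costs (see the mating-system
  section); the multiplicative and high-cost settings are asserted and
  documented as failing rather than silently relaxed.
* The closed-form scenario maxima are stated at $l = 1$, $d = 1$; the theory
  functions document rather than generalize that restriction. The exact
  product form $(1-c_t t)(1-c_h+b_t t)$ is used for the multiplicative
  non-resistance maximum (its maximizer is the implemented
  `optimal_tolerance()`), with the historical linear form available via
  `scenario_predictions(form = "printed")`.
* The overdominance-only selfing equilibrium and cycling-detection
  statistics are out of scope; cycling is asserted only qualitatively
  (resistance frequencies are non-constant with both signs of change).
* Heterozygosity is defined as the fraction of load genes heterozygous in
  composite state (range 0–1); its realized range under random mating at
  diallelic equilibrium is 0–0.5, which is how the conventional printed
  range "0–0.5" is read.
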