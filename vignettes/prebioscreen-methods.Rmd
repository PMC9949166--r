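---
title: "Screening for precision prebiotics with constraint-based community models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for precision prebiotics with constraint-based community models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prebioscreen)
```

## The problem

A *precision prebiotic* is a nutritional compound that selectively boosts
one target member of a microbial community over the others.  The naive
design — feed the community a compound that only the target can take up —
fails in practice because metabolic niches overlap: as communities grow,
the chance that any member retains a private uptake compound drops
quickly.  `prebioscreen` implements both halves of this argument as
testable code: an uptake-niche analysis that quantifies how rare unique
uptake compounds are, and a three-arm supplementation screen that finds
compounds whose *quantitative* benefit is biased toward the target even
when several species consume them.

The motivating use case is a two-member *C. elegans* microbiome community:
a host-beneficial *Pseudomonas* and a strongly competitive *Ochrobactrum*.
The package does not ship those genome-scale reconstructions; instead a
synthetic generator builds toy models with the same niche structure and a
planted ground truth, so every stage of the pipeline can be verified
end-to-end without external data.

## Flux balance analysis core

All arms rest on flux balance analysis (FBA): given a stoichiometric
matrix $S$ and flux bounds $l \le v \le u$, FBA solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,$$

where $c$ selects the biomass reaction and its optimal flux is read as the
growth rate $\mu$ (1/hr).  Exchange reactions move one external compound
each, with the usual sign convention: negative flux is uptake, positive is
secretion.  A growth medium is applied by setting each exchange lower
bound to minus the compound's availability (mmol/gDW/hr) and closing every
exchange the medium does not list, so the medium fully defines the
environment; a `keep_defaults` whitelist exempts freely available species
(water, ions, oxygen) from the budget.  Compound identifiers are opaque
strings throughout; an illustrative NGM-like medium table ships at
`inst/extdata/ngm_like_medium.tsv` purely as a format example, not as a
curated diet.

Because no linear-programming backend is available as an R dependency of
this package's environment, the LP core is a self-contained dense
bounded-variable two-phase primal simplex (in C++ via Rcpp).  It is
deterministic — Dantzig pricing with a switch to Bland's rule on stalling
— which matters for degenerate community optima: ties are broken the same
way on every run.  The test-suite cross-checks its statuses and objectives
against an independent LP implementation on hundreds of randomized
problems.

Two refinements are used throughout:

* **Parsimonious FBA** (`solve_fba_pfba`): maximizes
  $c^\top v - \lambda \sum_j |v_j|$ in a single LP (fluxes split into
  non-negative forward/reverse parts).  The default
  $\lambda = 10^{-6}$ acts as a secondary objective that removes futile
  cycles and resolves degenerate optima without measurably perturbing the
  growth rate.
* **The uptake test** (`can_take_up`): a compound can be taken up when the
  *minimal* feasible flux through its exchange reaction is below
  $-10^{-6}$ — equivalently, when maximizing its uptake moves it away from
  zero.  No growth requirement is imposed by default (a `min_growth`
  variant exists for sensitivity analysis); the test is therefore
  invariant to biomass-objective scaling, and structurally dead-end
  exchanges always fail it.

Numerical policy: the tolerance $10^{-6}$ is used everywhere, matching the
sixth-digit rounding applied to all raw growth values before relative
changes are computed.

## Uptake niches and community subsampling

`uptake_profile()` computes, per species, the set of medium compounds the
network can absorb.  Profiles are a species-by-medium property, computed
once and reused across community subsets — this makes the subsampling
analysis cheap.  `unique_uptake_compounds()` takes the set difference of
each member's profile against the union of all others;
`unique_fraction_curve()` draws random communities of increasing size (50
iterations per size by default, seeded) and records the fraction of
members with at least one private compound.  On overlapping pools this
fraction declines with community size; the suite checks the sampled means
against exhaustive subset enumeration at sizes 2–4.

## The three screen arms

All arms supplement one compound at a time and ask whether the target
benefits more than the competitor.  Raw values are rounded to six decimals
first; a relative change must strictly exceed 0.01 to count.

1. **Single-species FBA** (`screen_single_fba`): relative growth-rate
   increase $(\mu_{suppl} - \mu_{base})/\mu_{base}$ of the target alone,
   dose 10 mmol/gDW/hr.  This arm asks only "does the compound help the
   target at all" and is deliberately permissive.
2. **Community FBA** (`screen_community_fba`): member models are merged
   into one LP over a shared nutrient pool (species-prefixed internals,
   one community exchange per compound, member↔pool transports unbounded
   toward the member, no fixed biomass composition).  The objective is the
   *sum* of member growth rates minus the flux penalty.  This formulation
   lets whichever member converts the medium into biomass most efficiently
   take the whole pool, so member growth rates are normalized by community
   growth and the screen statistic is the change in the target's
   normalized abundance.  A raw growth-ratio column is reported alongside,
   since the abundance delta is a design choice, not the only defensible
   one.
3. **Individual-based simulation** (`screen_abm`): individuals of both
   species live on a grid (30×30 by default), each solving parsimonious
   FBA against its own cell's nutrient amounts, growing linearly within a
   timestep, dividing at twice the inoculation biomass, moving randomly,
   while substrates diffuse conservatively.  The medium (in mM) is diluted
   1000-fold — otherwise the arena is overgrown before nutrients deplete —
   and 0.01 mM of the supplement is added once at the start.  Per-species
   total biomass after 12 iterations is compared between 15 supplemented
   and 15 control replicates; a compound is selected when the target's
   per-replicate relative changes beat the competitor's by median *and*
   the two-sided Wilcoxon rank-sum p-value survives Benjamini–Hochberg
   adjustment across compounds at $\alpha = 0.05$ (the significance level
   is a package choice, configurable).

The final candidate set is the intersection of the arms, cross-referenced
with Biolog phenotype data: growth on a compound is called when
OD590 − OD750 strictly exceeds 0.1, and compounds not on the plate are
reported as "not assayed" rather than dropped.  Compounds only the target
can take up are excluded from the panel up front — the niche analysis is
exactly the argument for why those are not the interesting case.
`class_enrichment()` then tests the candidate set for over-represented
compound classes (HMDB-style labels) with one-sided Fisher exact tests
over the target model's metabolite background.

## Host colonization expectation

For in-vivo follow-up the package provides the diet-shift null model: if
supplementation acts on the host community only through the lawn (diet),
the expected target proportion in supplemented hosts is

$$E = p^{lawn}_{suppl} \cdot \frac{p^{worm}_{base}}{p^{lawn}_{base}},$$

i.e. the supplemented lawn proportion carried through the host-filtering
shift observed without supplementation.  `chisq_observed_vs_expected()`
compares observed host counts against this expectation (Pearson, df = 1).
Observed enrichment above the expectation indicates a host-context effect
beyond diet.

## The synthetic benchmark and what it does (not) show

`generate_species_model()` builds the smallest network whose FBA optimum
is analytic: per uptake compound, an exchange, a transport and a
conversion into one biomass precursor with stoichiometric yield $y$, so
$\mu = \sum_c y_c u_c$.  `generate_two_species_benchmark()` assembles the
default study conditions:

* 20 uptake compounds split 17/2/1 — 85% shared, 10% target-only, 5%
  competitor-only;
* 8 planted prebiotics among the shared compounds with a 1.5× target
  yield advantage;
* a 1.1× competitor edge on all other shared compounds (the competitor is
  a generally better grower, which is what makes the screen non-trivial);
* base yield 0.05 gDW/mmol with ±20% seeded jitter; batch availability
  10 mmol/gDW/hr and spatial concentration 10 mM per compound;
* a Biolog table supporting all target uptake compounds, with one shared
  compound deliberately left off the plate;
* class annotations with "amino acid" over-represented among the planted
  compounds.

A null benchmark (two identical species plus 40 inert, dead-end
supplement compounds) provides the false-positive control.

These toys capture niche overlap, yield asymmetry, resource competition
and stochastic spatial dynamics.  They do not capture pathway topology,
cofactor coupling, secretion cross-feeding networks, or regulation — so a
passing recovery test certifies the *pipeline logic* (bounds, rounding,
cutoffs, statistics, intersections), not the fidelity of any particular
genome-scale reconstruction.  Counts reported for real reconstructions
depend on the reconstruction tool and version and are not reproducible
from toy models; the acceptance suite is therefore property-based.

## Arena design choices

The spatial simulator is an independent minimal arena, not a re-implementation
of any existing framework.  Where the underlying assumptions were open,
the defaults are: per-individual uptake bound
$u_c = \min(\text{cap}, \; \text{local amount}_c / (B \, \Delta t))$ (the
"maximum available amount" rule applied to the cell); $\Delta t = 1$ h;
cell volume 1 µL (so 1 mM ≙ 10⁻⁶ mmol per cell); inoculation biomass
10⁻⁹ gDW per individual (a microcolony-scale agent); linear within-step
growth $B \leftarrow B(1 + \mu \Delta t)$; division at twice the
inoculation biomass into a random free neighboring cell, with at most one
individual per cell; an 8-neighbor random walk with reflecting boundaries;
and one conservative 4-neighbor diffusion pass (rate 0.5) per step.
Matched-pair supplementation (control and supplemented replicate share a
seed and hence the initial arena and random stream) removes
between-replicate variance from the contrast.  All of these are
configurable; none are claimed to match any published simulator
numerically.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the screen at a 10×10
arena with 20 individuals per species, 12 iterations and 15 replicates,
which preserves every parameter of the default operating point except the
grid area; the benchmark's planted set is recovered exactly across five
master seeds at that size.  The niche curve checks use an 8-species pool
(overlap 0.5, 6 compounds per species), where exhaustive enumeration at
community sizes 2–4 is feasible and the 50-iteration sampled means must
land within twice their Monte-Carlo standard error.  The null control
runs 5 replicates per inert compound.

## Known limitations

* The LP core is dense; it is built for toy-to-moderate networks
  (hundreds of reactions), not for genome-scale models with tens of
  thousands of reactions, where a sparse industrial solver is the right
  tool.
* Community FBA's summed-growth objective is a modeling commitment: it
  assumes fluxes are coordinated to maximize total growth, which
  exaggerates winner-take-all allocation for small communities.  The
  degenerate case of exactly tied members is resolved deterministically by
  the flux penalty and pivoting order, and should be read as "arbitrary
  but reproducible", not as a biological prediction.
* The uptake test imposes no growth requirement; whether a maintenance
  growth constraint should gate "can take up" is exposed as an option
  rather than decided.
* Compound identifiers are opaque strings; mapping between model
  namespaces (e.g. ModelSEED vs BiGG) is out of scope.
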