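---
title: "Formalizing and simulating stage-gate breeding schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formalizing and simulating stage-gate breeding schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`breedsim` treats a breeding program as an industrial process with two
representations: a *scheme* — the ordered table of crossing, evaluation and
selection (CES) decisions a pipeline executes — and a *simulator* that runs
that scheme forward in time over a synthetic genome to measure genetic gain
under alternative decisions. This vignette explains the models behind both,
the parameters that matter, the design choices that were genuinely open, and
what the simulator does and does not capture about real programs.

## The scheme data model

A `breeding_scheme` is an ordered list of stages, each with a role
(`crossing`, `multiplication`, `evaluation`) and decision blocks: crossing
(parents, crosses, progeny per cross, coupling method, reciprocals),
evaluation (locations, reps per location, design label, plot dimensions,
checks), and selection (entries in, selected out, method, surrogate of merit,
recycling-source flag). Validation (`validate_scheme()`) returns violations
as data rather than throwing, so a curator can fix a scheme file breach by
breach. Invariants: exactly one crossing stage, at the head; per stage,
selected-out ≤ entries-in; each stage's entries equal its predecessor's
output; at least one recycling source; non-decreasing years.

Decisions beyond the fixed schema are kept in a free-form `other` map per
stage. Programs record many more CES decisions than any fixed schema
anticipates, and rejecting unknown fields would make the format lossy; the
cost is that free-form fields are carried, not validated.

Derived metrics and their conventions:

* `selected_percentages()` reports `100 · entries(k) / entries(k−1)` to **3
  significant digits** (7.35, 53.3, 37.5 for the bundled cassava baseline).
  Program advancement tables print mixed decimal places that are consistent
  with significant-digit rounding, not fixed decimals.
* `expected_cycle_time()` is the policy-weighted mean of the recycling
  stages' year indices (the year whose data feeds the crossing block). A
  stage spanning a year range contributes its final year — selection cannot
  act before the stage's data are complete.
* `plots_per_stage()` is entries × locations × reps, **excluding checks**:
  the accounting tracks candidate material, and check counts are recorded but
  budgeted separately by programs.
* Canonical JSON (fixed key order, versioned) makes `save(load(f))`
  byte-identical, so schemes can be diffed under version control. CSV is
  accepted as the flat stage × decision table; extra columns land in `other`.

The bundled baseline stores the two UYT years as two stage entries (UYT1,
UYT2) rather than one ranged stage: the pipeline handles seven stage-cohorts
per year, and the engine needs one cohort slot per simulated stage. Ranged
years remain supported in the schema for purely descriptive schemes.

## Founder genomes

Founders carry neutral standing variation from a discrete-generation
Wright–Fisher burn-in:

* **Genome.** 18 chromosomes (defaults), each 1.43 Morgans and 8×10⁸ bp; the
  constant conversion rate 1.43/8×10⁸ ≈ 1.8×10⁻⁹ Morgans/bp maps genetic to
  physical positions. The genome is a *site panel*, not sequence: a fixed set
  of candidate biallelic sites per chromosome (default 500) with uniform
  Morgan positions. Only recombination and causal-site dosages matter to the
  analysis, so simulating full sequence buys nothing.
* **Mutation.** Each candidate site stands for its surrounding window of
  sequence, so its per-generation flip rate is the per-bp rate (2×10⁻⁹) times
  the bp spacing between sites (8×10⁸/500 = 1.6×10⁶ bp → 3.2×10⁻³ per site).
  This keeps the per-site scaled mutation rate θ = 4·Ne·μ — and with it the
  fraction of sites segregating in a founder sample — invariant to the panel
  density a user chooses.
* **Population.** Constant size Ne = 30 with random mating (no selfing),
  mimicking a history of natural and artificial selection only through small
  effective size; no selection model is imposed during burn-in. The default
  1,000 generations is ≈ 16 × 2Ne, far past the mutation–drift equilibration
  timescale min(2Ne, 1/2μ), so the heterozygosity trajectory (returned by
  `simulate_founders()`) is flat at the end; a coalescent-length history
  would change nothing detectable in the founder sample. Both Ne and the
  generation count are configurable.
* **Founders.** `n_founders` diploids (default 4, matching the small crossing
  block of the baseline program) are sampled from the final generation; sites
  monomorphic in that sample are pruned from haplotypes and map, so every
  retained site segregates among founders.

**Meiosis** uses the no-interference Poisson model: per chromosome, crossover
count ~ Poisson(map length in Morgans), positions uniform, starting haplotype
fair. Two-point recombination fractions therefore follow Haldane's map
function, r(d) = (1 − e^(−2d))/2 — the simplest model consistent with the map
lengths, at the price of ignoring crossover interference and obligate
chiasmata. No new mutation occurs during the breeding phase: trait loci are
fixed at founding.

## The trait

A single additive trait stands for a selection index over several traits. For
QTN *i* with dosage *x_i* ∈ {0,1,2}, the allele effect in an environment with
covariate *w* is the Finlay–Wilkinson line *a_i(w) = b_i + m_i·w*, so an
individual's genetic value is

> g(w) = Σ_i x_i·b_i + (Σ_i x_i·m_i)·w = g₀ + s·w,

exactly linear in *w* with genotype-specific intercept g₀ (main effect) and
slope s. Regressing any individual's genetic values on a grid of *w* recovers
(g₀, s) to machine precision — the package's tests assert this identity.

**Architecture.** 100 QTN per chromosome (1,800 at the default genome) are
drawn from the sites segregating in a designated base population; intercepts
and slopes start standard-normal and are rescaled *on the base population's
actual genotypes* (a Monte-Carlo calibration — linked, drifted dosages have
no usable closed form): b so that the population variance of g₀ equals σ²_G,
and m to unit slope variance. With unit slope variance, the environmental
covariate decomposition w[year, loc] = u[year] + v[year, loc] needs only
Var(u) = σ²_GxY and Var(v) = σ²_GxL to hit the interaction-variance targets.
Defaults σ²_G = 1, σ²_GxY = 2, σ²_GxL = 1 (so σ²_GxYxL = 3) are package
defaults, all configurable.

One calibration subtlety: scaling on a *small* base (e.g. 4 founders)
conditions on a noisy variance realization, so descendants' variance regresses
away from 1 even without selection. The engine deliberately calibrates on
the founders anyway — that is the scale the simulated program would have set
its targets on — while the package's own calibration checks use a base
population of 1,000 burn-in-derived individuals and verify the realized
variance on an independent draw of 1,000, where the identity holds to
Monte-Carlo error.

**Phenotypes.** A plot value is g(w[year, loc]) plus Normal(0, σ²_e) noise;
an entry mean averages an individual's locations × reps plots. σ²_e per stage
derives from plot heritability on the single-plot basis

> h² = σ²_G / (σ²_G + σ²_GxYxL + σ²_e)  ⇒  σ²_e = (σ²_G + σ²_GxYxL)(1 − h²)/h².

Stage defaults h² = 0.2 (CE), 0.3 (PYT), 0.4 (AYT), 0.45 (UYT) are package
defaults — unreplicated early stages get lower plot heritability — and should
be replaced with program estimates when available. Field designs (augmented
at CE, RCBD later) are not modeled as designs; their effect enters only
through reps, locations and σ²_e.

## The breeding engine

Each simulated year, on a full ladder of overlapping cohorts:

1. every evaluation cohort is phenotyped at its stage's locations/reps and
   error variance, using that year's covariate row;
2. per-stage genetic means and variances are recorded **at w = 0** (the
   main-effect scale), so gain is comparable across years despite GxE;
3. crossing-block parents are selected from the recycling-policy stages —
   per-stage quotas by largest-remainder apportionment (ties to the earlier
   stage), top entry means within stage (ties by ascending id) — and crossed
   into a new F1 cohort that occupies the nursery the same year;
4. cohorts advance one stage by truncation selection on entry means.

Timing convention: a cohort born in year *t* is in the nursery in year *t*,
CE in *t+1*, PYT in *t+2*, so PYT data appear in a cohort's third year and
AYT data in its fourth; recycling ages (logged per year) are exactly 3, 4, or
3.5 years for PYT-only, AYT-only, and the even mix, matching
`expected_cycle_time()`. Parent merit is the entry-mean phenotype at the
source stage — no BLUP or index, matching a conventionally phenotypic
program — and the crossing block is rebuilt every year from the currently
available cohorts; nobody is held over unless re-selected.

Cross plans sample distinct non-self pairs (unordered unless reciprocals are
allowed) uniformly without replacement; whenever crosses ≥ ⌈parents/2⌉, a
random disjoint pairing seeds the plan first so every parent is used. The
bundled baseline's 12 crosses from 4 parents require reciprocals (half-diallel
cap 6); grid treatments disallow reciprocals and respect the half-diallel
cap. The seedling nursery is pure multiplication (no mortality, no
selection); the two UYT years are product-development bookkeeping — they are
phenotyped and recorded but feed no recycling under the shipped policies.

Initialization fills every stage slot from founder-derived F1 batches with
staggered birth years (later stages are random subsets of a reserve batch);
burn-in years under the scheme's own baseline crossing decisions wash out
this ramp before any treatment is applied.

## The experiment layer

`enumerate_treatments()` builds the resource-allocation grid: parent levels
{4, 8, 16, 32, 64} × cross levels {6, 12, 24, 48, 96, 204, 408, 816},
admitting (nP, nC) only when nC ≤ nP(nP−1)/2, with progeny per cross =
1,632/nC — 24 treatments at the defaults, every one preserving total F1 size.

A *replicate* is one founder realization plus burn-in, forked across all
treatments (`run_grid()`), so treatment contrasts are paired within replicate
and burn-in records are identical across treatments. Sub-stream seeds derive
from one master seed via a label hash (`derive_seed(master, "treatment", r,
id)`), keeping every unit reproducible and replicates independent.
`summarize_gain()` reports gain relative to the end-of-burn-in mean with
standard errors across replicates; `compare_gain()` takes the replicate-level
results (not the summary — pairing would be lost) and labels a direction only
when |difference| > 2·SE.

Problem sizes: the package's default experiment scale, used by its acceptance
script and tests, is 10 replicates × 200 sites per chromosome × 20-year
burn-in + 20 treatment years, which resolves the recycling-policy and
parent-number contrasts on a single CPU in ~1 minute. Larger scales (more
replicates, denser panels, 60-year horizons) are plain parameter changes.

## Numerical choices

* Determinism: all randomness (including the C++ meiosis kernels, which draw
  from R's RNG) is governed by the master seed; identical seeds give
  bitwise-identical results tables.
* Variances are population variances (denominator n) wherever calibration
  targets are asserted exactly.
* Selection ties break by ascending id; quota ties by policy order — both
  deterministic.
* Haplotypes are stored as integer matrices, sites × haplotypes, so meiosis
  reads/writes and dosage scans are contiguous; genetic intercepts and slopes
  are cached per cohort at creation (they are invariant over an individual's
  life).
* Degenerate inputs fail loudly with typed conditions: h² = 0, cross counts
  above the diallel cap, quotas above cohort size, QTN demand above the
  segregating-site supply, zero-entry predecessor stages.

## What the simulator does and does not capture

The synthetic founders emulate *equilibrium neutral variation in a small
outbred population*: realistic allele-frequency spectra, linkage, and
relatedness at the scale the breeding engine consumes. They do not emulate
selective sweeps, domestication bottleneck structure, inbreeding depression
(no dominance), or sequence-level features. The trait is additive with
linear-reaction-norm GxE: no dominance, epistasis, or crossover
interactions; a single trait stands in for a multi-trait index, so
index-weight questions are out of reach. Selection is phenotypic truncation
on entry means — no genomic selection, no family selection, no cost model.

Consequently, passing tests show that the *machinery* — scheme execution,
Mendelian transmission, FW genetic values, variance calibration, selection
response consistent with the breeder's equation, paired treatment
contrasts — behaves as specified, and that the qualitative resource-allocation
findings (mixed PYT+AYT recycling beating AYT-only; intermediate parent
numbers beating very large ones at a 20-year horizon) are reproducible at
reduced scale. They do not certify absolute gain magnitudes for any real
program: those depend on trait genetic architectures, heritabilities and GxE
structures that must be estimated from program data and substituted for the
package defaults.
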