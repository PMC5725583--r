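---
title: "The genomic storage model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The genomic storage model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`recstorage` implements a haploid three-locus model of evolution in a
periodically changing environment. The three loci are:

* a **target locus** with alleles *a* (ancestral) and *d* (derived), coding
  for a seasonally selected trait: *a* is favored for one half of the
  environmental cycle and *d* for the other half;
* a **plasticity modifier** with alleles *m* and *M*: carriers of *M* sense
  the environment and buffer the seasonal fitness effect of whatever allele
  they carry at the target locus;
* a **recombination modifier** with alleles *r1* and *r2* that set the
  recombination rate between the plasticity and target loci.

The eight haplotypes are kept in the fixed canonical order
`r1ma, r1Ma, r1md, r1Md, r2ma, r2Ma, r2md, r2Md`. The seasonal selection
coefficient is sinusoidal, `s_t = s_max * sin(2 * pi * t / C)` with period
`C` generations, and haplotype fitnesses are

```
w(.ma) = 1 - s_t        w(.Ma) = 1 - s_t (1 - p)
w(.md) = 1 + s_t        w(.Md) = 1 + s_t (1 - p)
```

independent of the modifier allele. The plasticity effect `p` is the
fraction of the seasonal effect removed in *M*-carriers: `p = 0` makes the
plasticity locus inert, `p = 1` makes *M*-carriers fitness-neutral at the
target locus. Positive `s_t` favors *d*. Note that *M* is conditionally
adaptive: it shields a currently disfavored target allele but also forfeits
the benefit when that allele comes back into season. This interaction is the
engine of *genomic storage*: disfavored target alleles recombine onto the
buffered *M* background, survive the adverse season there, and return —
maintaining balanced polymorphism at both loci and a linkage disequilibrium
(LD) that cycles in sign over the season.

Each generation applies selection (frequencies reweighted by fitness and
renormalized by mean fitness) followed by recombination; the generation
label increments after recombination. Physical locus order is
modifier–plasticity–target. The modifier–sequence interval recombines at a
fixed rate `R`; the plasticity–target interval recombines at `r1`, `r2`, or
the additive heterozygous rate `r_c = (r1 + r2) / 2`, according to the
modifier alleles carried by the two pairing chromosomes.

### The recombination operator

`apply_recombination()` is built from first principles: random mating with
replacement over ordered parent pairs, independent Bernoulli crossovers in
the two intervals (no interference), both reciprocal products recovered by
the symmetric summation. It is represented as a quadratic form (a
`64 x 8` tensor) so one generation is a single matrix contraction. This
operator is the package's source of truth: it conserves single-locus allele
frequencies to machine precision, is the identity on linkage-equilibrium
states, and restricted to a monomorphic modifier reproduces the classical
two-locus decay `D' = (1 - r) D`. A literal transcription of the model's printed
eight-equation recursion is retained (`apply_recombination_printed()`)
purely for cross-validation: the transcription's compact loss terms carry
typographical sign errors in six of the eight equations, and
`recursion_discrepancy_report()` documents, numerically, exactly which
haplotype equations disagree rather than guessing at the intended form.

### Seasonal phase convention

The starting phase of a run is a free parameter (`phase` in
`seasonal_regime()`), because nothing in the dynamics pins down the season
at which a population is initialized. The default `phase = 0` starts at a
season boundary (`s_0 = 0`), entering the half-cycle that favors *d*. All
long-run results (periodic orbits, invasion outcomes, stationary
distributions) are phase-invariant; only transients depend on it.

## Deterministic stability analysis

`evolve_deterministic()` iterates the map until (i) the plasticity or
target locus loses its minor allele (frequency below `1e-4`), (ii) the
haplotype-frequency sequences of two consecutive environmental cycles agree
coordinate-wise within `1e-8` (a periodic equilibrium; the comparison
metric is the maximum absolute coordinate difference between same-phase
states), or (iii) a generation cap is hit, which is flagged and never
silent. At least 1000 generations are always run.

Stability of a periodic orbit is quantified by the **cycle Jacobian**
(`cycle_jacobian()`): the product of per-generation Jacobians of the
composed selection + recombination map along the orbit. Two routes are
provided and agree to better than `1e-5` relative: the analytic chain rule,
and central finite differences of the full-cycle map with step `h = 1e-6`.
The finite differences perturb raw coordinates rather than renormalized
ones: the selection step renormalizes internally, so the cycle map extends
smoothly off the simplex and raw perturbations differentiate the same map
the chain rule does (a `project = TRUE` option renormalizes instead; the
two differ only along the simplex-normal direction, which is immaterial for
the eigenvalues of interest).

### Pairwise invasion classification

`classify_pair()` decides the contest between two modifier alleles with
two complementary tools, combined as follows.

* **Boundary eigenvalues (primary when available).** Each allele held as
  sole resident defines a boundary system whose polymorphic periodic orbit,
  when it exists, yields an invasion eigenvalue: the leading eigenvalue
  modulus of the invader block of the cycle Jacobian (the Jacobian is
  block-triangular at the boundary). Mutual invasion (`both > 1`) is
  protected coexistence; one-sided invasion means displacement. Eigenvalues
  within `1e-6` of 1 are treated as neutral and classified as coexistence
  (a neutral boundary behaves as a protected polymorphism). Direct
  iteration was tried as the primary decision rule and proved unreliable
  exactly where precision matters: near `|lambda| = 1` the transit times
  exceed any practical horizon, and a thresholded trajectory read
  misclassifies marginal contests. The eigenvalue resolves these contests
  to `~1e-8` at a fraction of the cost.
* **Grid iteration (when a resident cannot store alone).** A
  non-recombining resident, for example, maintains no polymorphism by
  itself, so no boundary orbit exists; there the joint dynamics are run
  directly: plasticity/target frequencies initialized on the factorial
  `0.05–0.95` grid (step 0.1), the invader introduced at frequency 0.01 in
  linkage equilibrium with the background, and the system evolved to an
  attractor. On a converged orbit, persistence is judged against a small
  absorbing tolerance (`1e-3`): under a `1e-8` cycle criterion a
  geometrically decaying allele cannot stall at an appreciable frequency,
  so an attractor frequency above the tolerance is a genuine balanced
  polymorphism — this matters at the fixation/coexistence boundary, where
  the minority allele equilibrates near 1%. Runs that hit the cap use the
  conservative establishment rule (invader above 0.02, double its
  introduction frequency).

Outcomes require the plasticity–target polymorphism to hold (minor allele
frequency at least 0.01 over the attractor cycle); otherwise the pair is
`no_polymorphism` — no storage, hence no indirect selection on
recombination at all.

`find_es_rate()` scans all unordered pairs of a rate grid and reports every
rate that no alternative displaces, excluding rates that never sustain the
polymorphism. Near the evolutionarily stable (ES) rate, adjacent grid rates
can be mutually neutral at grid resolution, so the result is a (usually
small) candidate set rather than forcing a single number; the certificate
lists every pairwise outcome behind the decision.

## Finite populations

Two engines are provided, and they are distributionally identical when
restricted to two modifier alleles: offspring in the individual-based
engine are i.i.d. draws from exactly the post-selection,
post-recombination distribution that the multinomial engine samples.

* `wf_multinomial_step()` applies the deterministic recursion and
  resamples `N` haploids multinomially; `N = Inf` recovers the
  deterministic limit.
* The individual-based engine (`simulate_population()`, compiled core)
  carries a continuum of modifier alleles. Per generation: mutation, then
  reproduction. Parents are rejection-sampled with replacement, accepted
  with probability fitness / maximum fitness; the parental genomes
  recombine interval-by-interval (modifier-controlled intervals at the
  additive mean of the two parental alleles) and a fair coin keeps one of
  the two reciprocal products, until `N` offspring exist.

**Mutation.** "Chance `N*mu` per generation per locus" is implemented
literally: one Bernoulli(`N*mu`) event per locus per generation, hitting
one uniformly chosen individual; modifier mutants draw a fresh rate from
`U[0, 0.5]`, plasticity and target mutants flip allele. The text could also
be read as a per-copy rate `mu`; that variant sits behind
`mut_per_copy = TRUE` and has the same expected event count. The same
switch governs the reversible plasticity/target mutations.

**Recording.** During the recording window every individual contributes
its modifier allele value each generation to a histogram at two-decimal
resolution (an allele-level record, chosen because the reported stationary
distributions are distributions over rate values, not over population
means). Histograms pool across replicates jointly; the recorded mass always
sums to one.

## Multiple target loci

With `k` co-modulated target loci, per-locus seasonal factors multiply and
there is no epistasis term. "Contributing additively" to the phenotype is
rendered as no-interaction multiplicative fitness because the single-locus
fitnesses are themselves multiplicative factors `1 ± s_eff`; a strictly
additive variant (`1 + sum of signed effects`) is available behind
`fitness_mode = "additive"` for sensitivity analysis. The quoted `s_max`
applies to each target locus separately.

The clustering protocols (`run_two_target_protocol()`,
`run_supergene_growth()`) follow the standard protocol designs:

* **Sequential**: the plasticity–first-target distance is held at the ES
  rate while a new polymorphic target, introduced downstream at a random
  distance controlled by a fresh unlinked modifier, evolves its rate `r'`
  to the extant locus. "Downstream" appends the new target after the
  cluster; the "between" placement inserts it into the plasticity–target
  interval. New polymorphic loci are initialized at allele frequency 1/2 in
  linkage equilibrium — the protocol studies the fate of an already-present
  polymorphism, and a mutation-limited origin would only add waiting time.
* **Simultaneous**: both rates start monomorphic at independent
  `U[0, 0.5]` draws and evolve at once; the linked-modifier variant
  (`R1 = 0.01` for the first target's modifier) is supported.
* **Supergene growth**: each stage introduces one further target at a
  random distance into a population carrying an equilibrated `n`-locus
  cluster, with a per-stage burn-in and a short recording window. A stage
  counts as clustered when the majority of recorded rate mass for the new
  interval lies below 0.1; maintenance of the storage polymorphism is
  reported separately, because at desk-scale population sizes drift pushes
  target alleles to the boundary intermittently, from where recurrent
  mutation re-seeds them. The
  co-segregation fraction is the share of chromosomes whose target alleles
  are all-*a* or all-*d*.

Modifiers for different intervals are mutually unlinked (pairwise rate
0.5) by default, the conservative arrangement used for the main analyses.

## What the simulations emulate — and what they do not

The engines emulate the model's stated conditions: sinusoidal, strictly periodic
selection with no environmental stochasticity; constant `N` with
non-overlapping generations; haploid genetics with no dominance, no
interference, no epistasis among targets, no direct cost of recombination;
mutation rare at the population scale (`N*mu` of order 0.1). Passing tests
therefore demonstrate internal consistency of the model and fidelity to its
stated dynamics — not robustness to demographic structure, stochastic
environments, diploidy, or selection on the modifier itself, none of which
are modeled.

## Problem sizes used by the test suite

At full scale the protocols call for `N = 25,000` with `100 N` burn-in and
recording (about 5 million generations per replicate, a thousand
replicates) — a documented long-running mode of this package, not something
a test suite should attempt. The suite instead runs the same protocols at
sizes chosen to finish on a desk machine while keeping the population-scale
quantities (`N s_max`, `N mu`) large enough for storage to operate:

* stability analysis: full two-digit rate grid for the non-recombining
  column; 0.05 grid steps and a 3 x 3 initialization subgrid for the
  four-period ES scan (the full factorial grid is retained in the
  acceptance script's column computation);
* stationary distribution: `N = 2000`, `N*mu = 0.1`, `100 N` burn-in and
  `100 N` recording, single replicate;
* two-target clustering: `N = 2000`, `100 N` burn-in, `50 N` recording;
  supergene growth to three loci at `C = 20`, `s_max = 0.1` and `N = 4000`
  with `50 N` per-stage burn-in and `10,000` recording generations (at this
  period the weaker-selection variant `s_max = 0.075` does not hold the
  storage polymorphism against drift at desk-scale `N`, so the
  stronger of the two standard selection strengths is used);
* engine equivalence: `N = 500`, a thousand replicates of a few cycles,
  compared by a two-sample Kolmogorov–Smirnov test.

## Numerical choices, degenerate inputs, limitations

* Frequencies are renormalized every generation; input states must sum to
  one within `1e-9`, and zero frequencies stay exactly zero (boundary
  invariance is exact, which the eigenvalue analysis relies on).
* Odd periods `C` are permitted (the selection coefficient then never
  revisits zero mid-cycle); the analyses here use the even periods 10, 20,
  40, 80.
* The rate grid is bounded by free recombination at 0.5; mutant rates
  respect `[0, 0.5]` by construction.
* `p = 0` makes the plasticity locus an exactly neutral spectator in the
  deterministic engine — its marginal frequency is invariant — and storage
  degenerates accordingly.
* Local stability is what is computed; global stability of the periodic
  orbits is observed (every examined initialization converges to the same
  attractor) but not proved.
* The ES search is grid-based by design; it does not
  refine between grid points, and near-neutral plateaus at coarse grids are
  reported as candidate sets rather than silently collapsed.
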