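---
title: "Methods: pangenome-scale metabolic reconstruction and flux phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome-scale metabolic reconstruction and flux phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panflux)
```

## The problem

Families of lactic acid bacteria and similar clades are studied through
*pangenome-scale* metabolic models: a single curated pan-reactome — the union
of all metabolic reactions observed across the family, each with one or more
gene–protein–reaction (GPR) rules — serves as a template from which a
strain-specific genome-scale model (GEM) is cut for every sequenced genome.
The collection of strain models then supports comparative questions that no
single model can answer: which reactions are core to the family and which are
species-specific, which amino acids a species cannot synthesize, what each
strain can ferment, and whether reaction content tracks the ecological niche
a strain was isolated from.

`panflux` implements that workflow end to end: template QC, homology-based
strain mapping, minimal-addition gapfilling, constraint-based phenotyping
(FBA/FVA), reactome partitioning, and niche-association statistics — plus a
seeded synthetic pan-genome generator with planted ground truth, so that every
stage of the pipeline is verifiable without downloading genomes.

## The template model and its QC

A `pan_reactome` holds metabolites (with Hill-notation formulas and integer
charges), reactions (bounds in mmol/gDCW/h, a type label, a subsystem), a
long-format stoichiometry table, DNF-form GPR rules, and the identities of the
biomass and NGAM reactions. Three QC operations mirror standard reconstruction
practice:

* **Mass/charge balance** (`check_mass_charge_balance`) sums
  coefficient-weighted element counts and charges per reaction in exact
  integer arithmetic (no float tolerance to tune). Exchange, demand, sink and
  biomass reactions are net drains and exempt; metabolites with pseudo-element
  formulas (`R`, `X` — R-groups and unspecified moieties) exempt their
  reactions with a warning, because biomass-style pseudo-chemistry is never
  balanceable.
* **Thermodynamically infeasible cycles** (`detect_infeasible_cycles`) closes
  every exchange and runs FVA with a zero objective; any reaction whose range
  exceeds 1e-6 mmol/gDCW/h can carry flux without nutrient exchange, i.e.
  participates in an internal loop. The 1e-6 floor sits above LP solver noise
  and far below any meaningful flux.
* **Type accounting** (`classify_reaction_types`) partitions reactions into
  gene-associated, exchange, orphan, spontaneous, demand, sink and biomass.

Models travel as SBML Level 3 with fbc-style parameterized bounds and an
explicit objective; multi-allelic GPRs exceed what standard GPR strings
express, so the DNF alternatives travel in a sidecar TSV (`reaction_id`,
semicolon-joined `allele_set`, one row per alternative). Reaction
directionality is taken as given in the input document — directionality
curation from thermodynamic data is upstream of this package's scope.

## Media and the exchange convention

Exchanges are written export-positive: a metabolite drain `A_e ->` with a
negative flux means uptake. A `medium` is a table of uptake magnitudes;
`apply_medium` sets each listed exchange's lower bound to minus its magnitude
and **closes every unlisted exchange to uptake**. The closed-by-default
convention is what makes omission (auxotrophy) simulations meaningful: a
minimal medium must be exactly what the table says it is. The
non-growth-associated maintenance (NGAM) reaction's lower bound is pinned at
1 mmol/gDCW/h by default, configurable per call. Uptake magnitudes are capped
at the 1000 mmol/gDCW/h convention used for "effectively unlimited" bounds.

## Strain mapping

The pipeline's contract starts at a similarity table — the tabular result of
a bidirectional protein search (strain gene, reference allele, identity in
both directions, mutual-best flag). An allele is called present when a hit is
a mutual best hit **and** the smaller of its two identities is at least 70%
(inclusive boundary, the common BBH convention). A gene-associated reaction is
present when at least one GPR alternative's allele set is fully present;
everything non-genetic (exchanges, orphan, spontaneous, demand, sink, biomass,
NGAM) is carried into every draft, so even an empty presence vector yields a
structurally valid model. Running the aligner itself is deliberately out of
scope: it keeps the package download-free and the contract testable.

## Gapfilling

Draft models assembled from homology evidence can lack reactions needed to
produce biomass on the defined medium. `gapfill` restores growth by adding a
minimum-weight set of template reactions, formulated as a binary-indicator
MILP: minimize the summed weights of added candidates subject to steady-state
mass balance, candidate bounds gated by their indicators, and biomass flux at
least the growth threshold. The MILP is solved by a deterministic depth-first
branch-and-bound over LP relaxations (most-fractional branching, add-first),
so small instances return a *certified* minimum — verifiable by exhaustive
subset search (`gapfill_brute_force`). On hitting the time limit (60 s per
strain by default) a deterministic greedy pass — add everything, then attempt
single-reaction removals in lexicographic order — supplies a feasible repair
flagged `certified_minimal = FALSE`. Candidate costs default to uniform 1.0;
no evidence-weighted cost scheme is assumed. The growth threshold (0.01/h) is
shared with every phenotype call so the package has a single definition of
"grows".

## Flux phenotyping

All simulations maximize the biomass reaction subject to `S v = 0` and
bounds. The linear programs are solved with the `pracma` simplex behind a
wrapper that shifts variables to nonnegative form and, because that simplex
breaks pivot ties randomly, pins the solver's RNG to a fixed internal seed
ladder with deterministic retries — identical inputs give identical answers,
and the caller's RNG stream is never touched. Bounds must be finite (the
±1000 convention); feasibility failures after the full retry ladder are
reported as infeasibility.

* `carbon_source_growth`: glucose uptake closed, target source opened at
  1000 mmol/gDCW/h, growth iff FBA optimum strictly exceeds 0.01/h.
* `single_omission_essentiality`: each medium component's uptake zeroed in
  turn on a fresh model copy; a component is essential (an auxotrophy) iff
  growth falls strictly below 0.01/h. Exactly 0.01/h is neither a growth nor
  an auxotrophy call — ties resolve to "no growth" and "non-auxotroph"
  respectively, matching the strict inequalities of both definitions.
* `fermentation_profile`: exchanges with FBA secretion above 1e-6 mmol/gDCW/h
  form the secreted set; because alternate optima can redistribute secretion,
  the FVA min/max per exchange at a stated fraction of the optimum is the
  unique, reported envelope. The fraction defaults to 1.0 (profiles at
  optimal growth) and is exposed rather than guessed.
* `core_fluxome`: per-strain FVA over a shared core set; a reaction is
  active-in-all if its range is nonzero in every strain, and each reaction's
  maximum flux is Pearson-correlated with the strains' growth rates. A
  zero-variance maximum flux gives an *undefined* correlation, reported `NA`,
  never 1. Media may be supplied per strain (a named list) since growth-rate
  diversity typically enters through strain-specific uptake rates. Fewer
  than three strains is an error — the correlation would be meaningless.

Degenerate optima are a fact of FBA; every call that could be affected
(the FBA flux vector, the FBA-based secreted set) says so in its
documentation, and FVA is used wherever a unique answer is required.

## Reactome partitioning

With `F` the percentage of strains carrying a reaction, the family partition
is core `F > 99`, accessory `15 <= F <= 99`, rare `0 < F < 15` — boundaries
read literally, so `F = 99` and `F = 15` are both accessory. (Published
sensitivity analyses moving the core boundary to an elbow-derived 98.8% leave
such partitions unchanged, so the exact boundary is not fragile.) Reactions
absent from every strain form a fourth, reported-but-unclassified bin: the
three named classes cover observed reactions only. A reaction is *unique* to
a species when at least one strain carries it and every carrier belongs to
that species. Intra-species partitions reuse the same thresholds over one
species' strains; species below a minimum strain count (default 2) are
skipped with a warning. Universal template reactions (exchanges, biomass,
NGAM) are included in the matrix and necessarily land in core; nothing stops
a caller from subsetting to gene-associated reactions first if a
genetics-only partition is wanted.

## Niche statistics

Strain reactomes are compared by Jaccard distance on reaction sets. The
one-factor PERMANOVA uses the classical sums of squares
(`SS_total = (1/N) * sum d^2` over all pairs, within-group sums weighted by
group size), pseudo-F with `(a-1, N-a)` degrees of freedom, and a permutation
p-value `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` under a caller-supplied
seed. When the number of distinct labelings is at most 10,000 the exact
distribution is enumerated instead — at small N the Monte Carlo error would
otherwise dominate the p-value. `vegan::adonis2` is used in the test suite as
an independent cross-check of pseudo-F and R².

Per-reaction enrichment builds one-vs-rest 2×2 tables per (reaction, niche)
over labeled strains, for niches with **more than 10 strains** (read
strictly: at least 11). Fisher's exact test (two-sided, via `stats`),
Pearson's chi-square without continuity correction, and a natural-log odds
ratio are reported; when any cell is zero all four cells get the
Haldane–Anscombe 0.5 pseudocount, since niche-exclusive reactions guarantee
zero cells and the raw odds ratio would be infinite. The enrichment filter
keeps log-OR strictly above 5 (natural log — the base is a package decision,
exposed as a flag, since "log odds ratio" alone does not fix one) and can
require exclusivity: passing the threshold in exactly one niche. Raw p-values
are reported without multiple-testing correction, matching common practice
for these descriptive screens. PCA runs on the column-centered (not scaled)
0/1 matrix — centering without scaling is the standard choice for
presence–absence data — with each component's sign fixed by its
largest-magnitude loading, and k-means clustering is seeded with a default of
nine clusters, mirroring classification into nine major niche groups.

## Validation metrics

Qualitative phenotype validation uses confusion-matrix metrics (accuracy,
precision, sensitivity, F-score, FPR); a metric with a zero denominator is
reported `NA` — undefined, never 0. The *positive class is a declaration, not
an inference*: growth counts as positive for carbon-source panels, essential
counts as positive for auxotrophy panels, and each validation run must state
its polarity, because published metric tables in this area are not always
arithmetically recoverable from their counts. Quantitative growth-rate
validation reports MAPE (observations must be positive), RMSE, and Pearson r.

## The synthetic generator

The generator emulates the architecture of a family-scale study at toy scale
with mock chemistry chosen so every internal reaction is exactly balanced:
real element symbols (C, H, N, O) for the sugar and amino-acid analogues plus
artificial currency elements (`Ad`/`P` for the ADP/ATP moiety, `Nc` for the
NAD pool). The planted network is:

* a glucose→pyruvate core with substrate-level ATP and NADH production, a
  lactate branch that reoxidizes NADH, and a biomass reaction drawing
  lactate, amino acids and ATP — so fermentative overflow is *forced* at
  optimal growth, the analogue of overflow metabolism in lactic acid
  bacteria;
* six mock amino acids, each with an importable exchange and a two-step
  biosynthesis module; deleting a species' module (the `auxotrophy_plan`)
  plants an auxotrophy whose closed-form growth cap is known;
* per-species accessory branches — an alternative carbon source (transport +
  isomerase) and a fermentation overflow branch — plus species-unique and
  family-rare dead-end reactions and one planted enriched reaction per niche;
* multi-allelic GPRs (configurable alternatives, including two-allele
  complexes) and a similarity table with carried alleles at 85–100% identity
  and absent ones at 30–60% (an adversarial mode samples 70–80% vs 60–69.9%
  to probe the BBH boundary), with occasional high-identity non-mutual decoy
  hits.

Defaults are 3 species × 5 strains, dropout 0 (noiseless), glucose uptake 10
mmol/gDCW/h, amino-acid uptakes 1 (the two "glutamate/aspartate analogues"
at 2), NGAM 1 — the medium magnitudes of a chemically defined medium for
lactic acid bacteria. Growth-rate diversity is planted by per-strain glucose
uptake scaling over [6, 14], which makes glycolytic maximum flux affine in
growth rate, so core-fluxome correlations of exactly 1 exist by construction.
Because the planted chemistry is closed-form, every strain's expected growth
rate is `min((2u - NGAM)/4, uptake_cap/0.25)` and the tests compare FBA
against it exactly.

What the generator does **not** emulate: real sequence content, realistic
network size (dozens of reactions, not ~1,900), phylogenetic correlation
structure, or annotation noise beyond identity dropout. Passing the recovery
suites therefore demonstrates the pipeline's correctness on its contracts,
not robustness to real-world annotation error.

## Numerical choices and verification scales

* LP feasibility is accepted from the solver's converged terminations only;
  reported fluxes are clipped to bounds; flux activity and secretion floors
  are 1e-6 mmol/gDCW/h.
* FVA holds biomass above `fraction × optimum` minus a 1e-6 relative slack —
  without it the optimal face is a numerically empty sliver.
* The FBA oracle (`fba_brute_force`) enumerates basic feasible solutions of
  `{Sv = 0, lb <= v <= ub}` directly; it is exponential and used up to ~8
  reactions.
* Verification scales used by the test suite and the acceptance script: 200
  random ≤8-reaction networks for solver equivalence; 100 pathway instances
  with ≤12 candidates for certified gapfill minimality; a 3 species × 10
  strain noiseless bundle for end-to-end recovery; all 2×2 tables with
  N ≤ 30 for the Fisher oracle; 500 replicates × 199 permutations at N = 16
  for the PERMANOVA null-uniformity check.

## Known limitations

* The simplex backend is dense and pure R: comfortable at the package's
  intended toy-to-hundreds scale, not at thousands of reactions.
* Gapfill certification is exact but exponential in the worst case; large
  candidate sets fall back to the greedy, non-certified repair.
* No parsimonious FBA, flux sampling, dynamic FBA, or thermodynamic
  gapfilling; no multiple-testing correction beyond raw p-values; no
  phylogenetically aware enrichment.
* k-means labels follow the R convention (1..k).

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 7, strains_per_species = 10)
rb  <- generate_reactome(cfg)
med <- generate_medium(cfg)
pop <- generate_strains(rb, cfg)

mods <- map_strains(pop$similarities, rb$reactome, pop$metadata)
pam  <- build_presence_matrix(mods, pop$metadata, reactome = rb$reactome)

partition_reactome(reaction_frequency(pam)) |> autoplot()
niche_enrichment(pam) |> select_enriched(lor_min = 5)
permanova(jaccard_distances(pam),
          attr(pam, "metadata")$isolation_source, seed = 1) |> glance()
```
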