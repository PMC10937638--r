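---
title: "Host–microbiome whole-body flux modelling: models, assumptions, design"
author: "wbmflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-microbiome whole-body flux modelling: models, assumptions, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Urinary formate is a terminal product of both human and gut-microbial
metabolism, and lowered urinary formate has been discussed as a candidate
early marker of Alzheimer's disease. `wbmflux` provides the computational
machinery to ask, with constraint-based (COBRA-style) metabolic models, how
much of a host's maximal urinary secretion of a metabolite can be attributed
to (i) direct microbial secretion of that metabolite, (ii) host conversion of
*other* microbial products (host–microbiome co-metabolism), and (iii) the
host's own dietary routes — and which host reactions those routes funnel
through.

The pipeline has five layers:

1. **Constraint-based core.** A metabolic model is a stoichiometric matrix
   $S$ (metabolites × reactions) with flux bounds $l \le v \le u$. Flux
   balance analysis (FBA) solves the linear programme
   $\max / \min \; v_{obj}$ subject to the steady-state mass balance
   $S\,v = 0$ and the bounds; flux variability analysis (FVA) computes the
   attainable $[\min, \max]$ per reaction over the same feasible region. All
   fluxes are carried in mmol/person/day end-to-end.
2. **Pan-species models.** One model per species, built as the union of the
   strain reconstructions: union of metabolites and reactions, widest bounds
   for shared reactions, and a pan biomass reaction.
3. **Community models.** Per-sample microbiome models assembled from
   pan models and relative abundances: member networks are id-tagged, their
   extracellular exchanges are rewired into reversible transfers against a
   shared lumen `[luM]`, which is connected to dietary `[d]` and faecal
   `[fe]` exchange reactions. An abundance-weighted community biomass
   reaction consumes the member biomass metabolites, and every member
   reaction $r$ of member $i$ is coupled to that member's biomass flux
   $b_i$ by the linear constraints
   $v_r - c\,v_{b_i} \le 0$ and $v_r + c\,v_{b_i} \ge 0$ (coupling factor
   $c = 400$), so a microbe is metabolically active only if it grows.
4. **Whole-body attachment.** The community is attached to the
   large-intestinal lumen `[luLI]` of a sex-specific host model: the
   community's own diet/faecal plumbing is removed and each metabolite shared
   by both lumens gets one reversible bridge reaction
   `Micro_EX_<met>[luLI]` (`[luM]` → `[luLI]` positive = microbe-to-host).
   The germ-free host is simply the bare host model. Three objectives drive
   the analyses: maximal urine secretion `EX_<met>[u]`, maximal
   microbe-to-host bridge transfer, and their decomposition
   $\Delta = v^{u,\max}_{personalised} - v^{u,\max}_{germfree}$, with
   co-metabolism excess $\Delta - v^{bridge,\max}$.
5. **Statistics.** Urine metabolome screens (log-scale multivariable
   regressions with age, sex and BMI, heteroscedasticity-robust covariance,
   global Wald test over the group factor plus the AD-vs-control contrast,
   Benjamini–Hochberg FDR), fractional (quasi-binomial logit) regressions of
   relative abundances with APOE adjustment, count-space log-ratio tests of
   increased vs decreased species, and flux-vs-group regressions with APOE
   and host sex.

# Linear-programming core

No linear-programming backend is assumed: the package implements a two-phase
primal simplex for bounded variables (`lp_solve()`, internal). Design points
that matter for reproducibility:

* **Determinism.** Pricing is Dantzig's rule with an automatic switch to
  Bland's smallest-index rule while degenerate pivots stall; leaving-row ties
  are broken by pivot magnitude (or smallest index under Bland). The same
  model always yields the same optimum; alternative optimal vertices are
  accepted (only objective values are interpreted).
* **Tolerances.** Pivot/eligibility tolerance $10^{-9}$; assertion-level
  feasibility $10^{-6}$ (mass balance $\|S v\|_\infty \le 10^{-6}$, bound
  violations $\le 10^{-6}$). Phase 1 stops as soon as every artificial
  variable is at zero (its known optimum) rather than grinding through
  degenerate price-out pivots.
* **Numerical hygiene.** The tableau is refactorised from the basis every
  2000 pivots and again before optimality is accepted, and the final
  solution is reconstructed exactly from the final basis and validated
  against all constraints. If validation fails, the solve is repeated once
  in a safe mode (Bland pricing throughout, refactorisation every 100
  pivots). Coupling constraints are rewritten with slack variables on rows
  scaled by $1/c$, so all coefficients stay near unit magnitude and the
  slack bounds are tight — without this, community-scale bases become
  ill-conditioned.
* **Unboundedness.** Infinite bounds are clamped to $\pm 10^{7}$; an optimum
  pressing against a clamped infinite bound with nonzero objective weight is
  reported `unbounded`.

The test suite checks the solver against an exhaustive
vertex-enumeration oracle (every basic solution of the polytope is
enumerated for networks of ≤ 8 reactions) on twelve structured fixtures and
hundreds of random bounded LPs.

# Tunable parameters

| Parameter | Default | Units | Where | Rationale |
|---|---|---|---|---|
| coupling factor $c$ | 400 | – | `build_community()` | the conventional value for microbiome community models; any positive value accepted |
| community biomass bounds | [0.4, 1.0] | 1/day | `build_community()` | the community-modelling convention for daily microbial turnover; configurable |
| transfer-reaction bounds | ±10⁴ | mmol/person/day | community transfers, lumen bridges | effectively unlimited transfer between compartments |
| attached community biomass lower bound | relaxed to 0 | 1/day | `attach_community()` | lets the microbiome idle, so the germ-free model is always a feasible sub-behaviour and attachment can never lower a urine maximum; the original [0.4, 1] is selectable |
| low-abundance cut-off | 10⁻⁵ | relative abundance | `map_filter_normalise()` | applied per sample after database mapping, before renormalisation |
| detection filter | > 50 % non-zero | – | `filter_detected()` | strictly-more-than rule; surviving zeros are recoded missing (a zero NMR quantification need not mean absence) |
| presence filter | ≥ 50 % present | – | `fractional_abundance_regression()` | taxa present in less than half the samples are excluded |
| secretion threshold | 30 | mmol/person/day | `high_secretion_metabolites()` | mean bridge secretion above which a microbial metabolite is considered highly secreted |
| supplementation bound | 300 | mmol/person/day | `diet_supplementation_screen()` | maximal intake given to one candidate at a time |
| knockout flag threshold | 10 | % reduction | `single_knockout_screen()` | reactions whose single deletion reduces the target by more than this are flagged |
| minimal-set target | 85 | % reduction | `find_minimal_deletion_set()` | the smallest subset achieving at least this joint reduction is returned; ties at the smallest size break lexicographically on sorted ids |

`find_minimal_deletion_set()` searches exhaustively, smallest subsets first,
whenever there are at most 20 candidates (the intended use is the >10 %
pre-filtered list); beyond that a clearly-labelled greedy heuristic is used.

# Statistical choices

* **Robust covariance** is HC3 everywhere ("heteroscedasticity-robust" made
  concrete; HC3 has the best small-sample behaviour of the common HC
  estimators). HC3 is undefined when a hat value equals 1 — e.g. a covariate
  level carried by a single sample — and the code falls back to HC1 for that
  fit only.
* **Fractional regression** is a quasi-binomial GLM with logit mean link,
  i.e. a fractional logit with sandwich standard errors; relative abundances
  in $[0,1]$ are the response, health status the predictor of interest, and
  categorical APOE genotype the adjustment.
* **Log-ratio test**: per sample, $\log(\sum_{up} counts / \sum_{down}
  counts)$, compared between groups with a Welch t-test. Samples with a zero
  numerator or denominator sum are excluded and reported; a pseudocount mode
  (+1 on both sums) is available by argument.
* **Multiple testing** is Benjamini–Hochberg within one screen; both the
  global-Wald and the AD-contrast p-values are adjusted and both q columns
  are reported.
* Natural logarithms throughout.

# What the synthetic generators emulate

The cohort data this kind of analysis runs on (urine NMR tables, stool
whole-genome sequencing) are access-restricted, and the reference
reconstruction resources (thousands of strain models, organ-resolved
whole-body models) are far beyond desk scale. The `synth_config()` family
therefore generates every input the pipeline consumes, with the structure
the analysis assumes:

* **Toy strains** (`make_toy_strains()`): glucose-fermenting microbes with
  species-specific secretion repertoires drawn from formate, acetate,
  L-serine, glycine, L-tryptophan, L-tyrosine, L-cysteine, ornithine and
  ammonium. Species 1 is always the (sole) formate producer and species 2
  the (sole) serine producer, so that the planted depletion of these species
  gives an identifiable community-level signal; every third species is a
  tryptophan auxotroph (and accordingly does not synthesise tryptophan
  itself), exercising diet-dependent viability. The toy serine yield
  (3 per glucose) deliberately exceeds what the toy host extracts from
  glucose directly (2 formate per 3-phosphoglycerate at 2 per glucose), so
  microbial serine creates genuine co-metabolism gains.
* **Toy host** (`make_toy_host()`): a compact whole-body-style model with
  diet, large-intestinal-lumen, systemic, peroxisomal and urine
  compartments, carrying the main formate-producing routes: serine
  synthesis from 3-phosphoglycerate ending in the phosphoserine phosphatase
  PSP_L; the folate one-carbon chain (serine hydroxymethyltransferase,
  glycine cleavage, methylene/methenyl/formyl-THF interconversion) releasing
  formate; choline → betaine → dimethylglycine → sarcosine (peroxisomal
  oxidation) plus methanol and methylamine as formaldehyde sources, funnelled
  through S-formylglutathione hydrolase SFGTH; tryptophan 2,3-dioxygenase
  TRPO2 with formate release at N-formylkynurenine hydrolysis; and a
  nitrogen-limited methionine-salvage route ending in DKMPPD, which is why
  supplementing pure ammonium — no carbon — raises formate. Upstream steps
  exist as redundant isozyme/organ-copy pairs (mirroring the multi-copy
  redundancy of organ-resolved models), while PSP_L, SFGTH, TRPO2 and DKMPPD
  are single-copy endpoints: the deletion screens therefore recover exactly
  this four-set as the minimal deletion set at the 85 % target. The female
  variant differs from the male in one flux bound (methanol oxidation
  capacity), giving the sex covariate real leverage. The default diet
  (`toy_diet()`, mmol/person/day, with cholic and chenodeoxycholic acid
  supplements) was fixed at design time so that every route is limited by
  its own dietary precursor and each of the four endpoints individually
  exceeds the 10 % single-knockout criterion; the magnitudes are toy
  conditions, not nutritional estimates.
* **Abundance counts** (`make_abundance_counts()`): log-normal baseline
  composition over 40 taxa split into 1–3 gOTUs each (plus genus-only gOTUs
  that the taxonomy collapse must drop), planted 3-fold shifts applied to
  the AD group before compositional closure (the formate/serine producers
  are planted *down* in AD), per-sample log-normal biological variation
  (sdlog 0.5), multinomial read sampling at 50,000 reads per sample (a
  desk-scale stand-in for millions of reads), and covariates age ~ N(70, 6),
  BMI ~ N(26, 4), sex ~ Bernoulli(0.5), APOE enriched for E4 among cases.
  The 24 + 24 group sizes mirror a typical matched stool cohort.
* **Metabolome** (`make_metabolome()`): 49 metabolites over groups of
  49/45/49/34 (healthy control, subjective cognitive decline, mild
  cognitive impairment, AD dementia); 16 are measured in essentially all
  samples while the remainder carry 55–90 % zero-inflation, so the 50 %
  detection filter reproducibly reduces 49 to 16. Negative log-scale AD
  effects are planted on formate (−0.4) and fumarate (−0.5) with graded
  milder effects in the intermediate groups; residual sdlog 0.6; age and
  BMI act on the log scale. Effect and noise magnitudes were chosen once so
  that the planted effects are recoverable at the stated cohort sizes with
  conventional power.

Every generator is a pure function of its `synth_config()` (identical
config + seed ⇒ identical output, without disturbing the caller's RNG
stream), and ground truth is returned as a first-class record so recovery
tests never re-derive it from generator internals.

**What the toys do not capture:** phylogenetic covariance among taxa,
realistic NMR peak-shape artefacts, elemental mass balance inside lumped toy
reactions, organ-resolved physiology (organ weights, blood flows), and the
sheer scale of real reconstruction resources. Passing tests demonstrate the
correctness of the machinery and the qualitative behaviours planted in the
toys; they are not evidence about any real cohort.

A behaviour worth knowing when interpreting community secretion capacities:
the maximal-capacity FVA only reflects abundance shifts while the coupling
constraint ($v \le 400\,v_{biomass}$) binds. When a producer species is
abundant enough, substrate availability saturates the capacity and group
differences in its abundance become invisible to the maximum — a property of
capacity-style simulation, not a bug.

# Numerical and degenerate-input conventions

* Diet application uses the uptake-negative convention: entry $m: u$ sets
  the dietary exchange lower bound to $-u$; secretion (upper) bounds are
  untouched; unlisted dietary exchanges are closed (lower bound 0) under the
  default `closed` policy. Diet entries with no matching exchange are
  skipped with a warning and reported.
* Reaction deletion zeroes both bounds but keeps the reaction, so indexing
  is stable across a screen.
* Degenerate alternative optima are accepted; only objective values are
  compared.
* Zero baselines make percent changes undefined: the screens raise an error
  (knockouts) or flag the record (supplementation) instead of dividing by
  zero.
* In `decompose_contributions()` a metabolite absent from the community is
  a zero microbial secretion, not an error.
* A community metabolite with no host-lumen counterpart simply gets no
  bridge reaction; its transfers stay flux-zero.

# Problem sizes used by the shipped tests and acceptance script

The default test run exercises: twelve ≤ 8-reaction fixtures against
exhaustive vertex enumeration plus several hundred random LPs; toy
ecosystems of 2–6 species (two strains each); the 36-reaction knockout
candidate list on the ~105-reaction toy host in both sexes; the
statistical calibration at 1000 null metabolome replicates (n = 180, 16
metabolites), 500 power replicates, 200 null and 100 recovery abundance
replicates (n = 48, 40 taxa), 500 log-ratio and 500 flux-regression
replicates. The acceptance script runs the deterministic host screens plus a
seeded synthetic cohort with three whole-body decompositions per group.
These sizes were chosen to exercise every code path and keep a full run in
the minutes range on a single core; all of them are configuration, not
hard-coded limits.

# Known limitations

* The simplex core is dense and single-threaded; it is comfortable at the
  few-hundred-reaction scale of the toys but is not a substitute for an
  industrial LP solver on genome-scale or full community models.
* SBML support targets Level 3 + fbc flux bounds; coupling constraints have
  no SBML standard and travel in a package-specific annotation element (the
  JSON dialect is the canonical on-disk format).
* Host models are personalised by sex only; physiological personalisation
  (and gene-level, GPR-evaluated deletions) are out of scope — the screens
  delete reactions, not genes.
* Whether community-level secretion FVA should fix the community biomass at
  its upper bound or allow the full range is exposed as an argument
  (`fix_biomass` in `secretion_profile()`, default: full range), since
  either convention is defensible.
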