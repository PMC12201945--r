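---
title: "Models and methods behind phycoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phycoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phycoflow` quantifies directed pairwise interactions between heterotrophic
bacteria that grow on algal exudates, and the consequences of those
interactions for the flow of algal carbon into bacterial biomass. This
vignette explains the statistical models the package implements, the
assumptions behind its synthetic-data generators, the tunable parameters
that matter, and the numerical choices made where the design was open.

## The experimental logic

All three interaction coefficients describe an ordered pair: a *primary*
strain that gets first access to algal spent medium, and a *secondary*
strain that receives the altered metabolite pool. Directionality matters in
a spatially structured environment (the phycosphere): a pair that is
commensal in one ordering can be competitive in the other.

## Expected competitive interaction (ECI)

From untargeted LC--MS exometabolomics of each isolate grown alone on algal
spent medium, each strain gets a vector of consumption proportions
$p_{m,s} \in [0,1]$ over metabolite features $m$. The expected effect of
primary $p$ on secondary $s$ is

$$\mathrm{ECI}_{s,p} = -\frac{\sum_m p_{m,s}\,p_{m,p}}{\sum_m p_{m,s}^2}.$$

It is a (negated) projection of the primary profile onto the secondary's:
identical affinities give $-1$; disjoint consumed sets give $0$; it is never
positive, and it is linear in the primary profile
($\mathrm{ECI}(p_s, c\,p_p) = c\,\mathrm{ECI}(p_s, p_p)$).

**Proportion convention.** A proportion could be read either as the
intensity ratio isolate/control or as the fraction removed. We define
$p_{m,s} = \mathrm{clamp}(1 - I_{s,m}/I_{0,m},\, 0, 1)$, so full depletion
gives 1 and no change gives 0 — the only reading under which two strains
with identical affinities yield $\mathrm{ECI}=-1$. The raw-ratio convention
remains available in `estimate_proportions(convention = "ratio")` for
sensitivity checks.

**Which features contribute.** By default, proportions are nonzero only for
features with a statistically significant *consumed* call; unchanged and
produced features contribute 0. This keeps replicate noise and production
from inflating apparent overlap. `only_consumed = FALSE` uses raw clamped
proportions for every feature instead.

**Testing choices.** Feature filtering keeps features whose mean intensity
exceeds the extraction-blank mean with a significant two-sample t-test;
change calling compares isolate groups to the uninoculated control the same
way. We use Student's pooled-variance t-tests by default (Welch via
`var_equal = FALSE`) and Bonferroni correction with the family defined as
*all* feature-by-group contrasts within one call — the broadest, most
conservative reading; the family size is recorded in the `n_tests`
attribute, and per-ionization-mode retention counts (from feature-id
prefixes such as `Positive-`/`Negative-`) are logged so either per-mode or
joint accounting can be reported. A secondary strain that consumes nothing
has an undefined ECI denominator; we report 0 with a validity flag rather
than `NA`, since no competition is possible and complete matrices simplify
downstream comparison.

## Metabolic resource overlap (MRO)

From per-strain minimal nutrient-requirement sets $M$ (typically derived
from genome-scale metabolic models — reconstruction itself is out of scope,
the sets are inputs):

$$\mathrm{MRO}_{s,p} = \frac{|M_s \cap M_p|}{|M_s|}.$$

We implement exactly this directed two-strain form, not the symmetric
community generalisation found elsewhere, because it is the quantity that
pairs naturally with ECI. A strain's sole-carbon-source growth calls (to
build such sets from phenotype microarrays) are supported by
`growth_call()`: a series must rise by at least 0.05 OD and by twice the
blank's rise, after a 3-point running mean.

## Sequential interaction (SI)

From final cell counts of the secondary strain on primary-processed spent
medium ($G_{s,p}$) versus unprocessed algal spent medium ($G_{s,\mathrm{PtSM}}$):

$$\mathrm{SI}_{s,p} = -\frac{G_{s,\mathrm{PtSM}} - G_{s,p}}{G_{s,\mathrm{PtSM}}}
 = \frac{G_{s,p}}{G_{s,\mathrm{PtSM}}} - 1 .$$

Replicates are aggregated as a *ratio of means* (default): with small or
zero per-well counts, per-replicate ratios are unstable and undefined at
zero baselines, whereas the ratio of means stays finite and unbiased to
first order. The mean-of-ratios estimator is available via
`aggregate = "mean-of-ratios"`. Classification is sign-based
(`classify_interaction()`), with an optional neutral band that defaults to
zero — a strict sign rule.

When SI and ECI matrices are correlated (`compare_matrices()`), the
intraspecific diagonal pairs are *included* by default, giving $n = 100$
ordered pairs for 10 strains; `include_diagonal = FALSE` gives the
off-diagonal-only variant, since either accounting is defensible. The
comparison also reports the fraction of pairs with the first metric above
the second — e.g. the share of SI values less negative than the matching
ECI, the signature of facilitation relaxing the pure-competition
prediction.

## Single-cell isotope accounting

NanoSIMS measures ion counts per cell region of interest. Carbon is
detected as C$_2^-$ dimers, so the atomic ratio is half the count ratio,
$^{13}\mathrm{C}/^{12}\mathrm{C} = (n(^{12}\mathrm{C}^{13}\mathrm{C})/n(^{12}\mathrm{C}^{12}\mathrm{C}))/2$,
while nitrogen is detected as CN$^-$ with a single N atom, so no halving.
Ratios convert to atom fractions $F = R/(1+R)$ and

$$C_\mathrm{net} = 100\,\frac{F_\mathrm{cell} - F_\mathrm{nat}}{F_\mathrm{alga} - F_\mathrm{nat}}\ (\%).$$

Defaults: $^{13}$C/$^{12}$C$_\mathrm{nat}$ = 0.011237 and
$^{15}$N/$^{14}$N$_\mathrm{nat}$ = 0.003676, both configurable;
`estimate_natural_fraction()` replaces the tabulated baseline with the
median of designated unlabelled control cells when available, which is
preferred. $F_\mathrm{alga}$ defaults to the per-run median over algal
cells' ROIs. Because the isotopic enrichment of the *exuded* metabolites is
not measured directly, $C_\mathrm{net}$ should be read as a comparative
estimate across treatments, not an absolute tracer budget. Negative
apparent enrichment is counting noise, so $C_\mathrm{net}$ is clamped to
$[0, 100]$ by default; `isotope_constants(clamp = FALSE)` retains negative
values for QC. The $^{15}$N channel is reported as atom-fraction excess
over natural abundance, the convention least sensitive to instrument
normalisation.

Population totals combine abundance (flow cytometry), mean cell biovolume
and the median single-cell $C_\mathrm{net}$ per well:

$$C_\mathrm{total} = \sum_\mathrm{wells} N\, m_C(\bar V)\, \frac{C_\mathrm{net}}{100},
\qquad m_C(V) = 148\ \mathrm{fg\,C\,\mu m^{-3}} \times V .$$

The linear biovolume-to-carbon factor of 148 fg C µm⁻³ is a
field-standard marine-bacteria conversion and is exposed as a parameter
(an allometric $aV^b$ alternative is provided for larger cells). When a
`microplate` replicate column is present, $C_\mathrm{total}$ is averaged
over microplates and treatment ratios carry a delta-method standard
deviation.

**Rank tests.** Treatment comparisons use the Wilcoxon rank-sum test
(exact for small tie-free samples, as implemented in `stats::wilcox.test`)
and Kruskal--Wallis. For pooled samples of at most 12 observations the
Kruskal--Wallis p-value is computed by *exhaustive enumeration* of all
distinct group assignments (with tie correction), because the chi-square
approximation is unreliable there; larger samples use
`stats::kruskal.test`, and the method used is always recorded.

## Profile clustering and phylogenetic signal

Isolates are compared on vectors of signed log2 fold changes with
non-significant entries zeroed, under Euclidean distance and average
linkage — common, defensible defaults for consumption-heatmap dendrograms;
both are configurable. Clustering delegates to `stats::hclust` with labels
pre-sorted so merge order is deterministic, and dendrograms export to
Newick via `ape`.

The Mantel test is implemented in-package because we need both a seeded
random-permutation mode and an exact exhaustive mode (all $n!$ label
permutations, feasible up to $n = 8$) whose p-value is the enumerated tail
probability; the one-sided positive-association alternative is the default
(a two-sided option exists) and the base statistic is Pearson by default
with Spearman available, since either is common. `vegan::mantel` serves as
an independent cross-check in the test suite, never as the implementation.

## The synthetic-data generators

The generators exist so every estimator in the package can be scored
against known truth; their defaults encode the experimental design the
package targets: 162 metabolite features, 10 isolates, 5 replicates per
isolate with 12 uninoculated controls, 3 replicate wells per sequential
pair, and 300 cells per isotope treatment.

- **Metabolome** (`generate_metabolome()`): per-feature baselines are
  lognormal (`meanlog = log(1e6)`, `sdlog = 1`, typical of LC--MS intensity
  scales); an additive instrument background at 1% of baseline is what
  blanks measure; isolate means are
  $\mathrm{background} + \mathrm{baseline}\,(1 - p + \mathrm{production})$;
  replicate noise is multiplicative lognormal with CV 0.10, matching
  LC--MS replicate practice (the measurement model is an artifact choice —
  no noise model is prescribed by the assays themselves). Consumption and
  production are mutually exclusive per (isolate, feature) because the
  pipeline's call is sign-based, making joint effects unidentifiable.
  Random truths are sparse: each isolate consumes about a third of
  features at proportions Uniform(0.3, 0.95), and produces 2% of the rest.
- **Sequential growth** (`generate_sequential()`): expected counts are
  $\mathrm{baseline}_s (1 + \mathrm{SI}_{p,s})$ with lognormal
  multiplicative noise (CV 0.10) truncated at zero. Random truths mirror
  the observed prevalence of competition: 70% of ordered pairs negative,
  Uniform(−1, 0), and 30% positive, Uniform(0, 1).
- **NanoSIMS** (`generate_nanosims()`): per-cell true $C_\mathrm{net}$ is
  normal around the treatment median with a 1.0-percentage-point IQR
  (truncated to [0, 100]), converted to the expected atom fraction, and ion
  counts are Poisson — the standard ion-counting model — at $10^6$
  major-isotope counts per ROI, with the dimer channel at
  $2R \times$ the major counts so the /2 convention round-trips.
- **Nutrient sets** (`generate_uptake_sets()`): a shared core of
  $\mathrm{round}(\mathrm{overlap} \times k)$ nutrients plus disjoint
  private nutrients makes every directed MRO equal the target overlap up
  to rounding; an undersized universe is an error rather than a silent
  overlap shift.
- **Consumer-resource model** (`simulate_consumer_resource()`): linear
  yields, $G = \sum_m y_m\, \mathrm{pool}_m$, with the primary strain
  removing proportion $p_{m,\mathrm{pri}}$ of each pool. Under binary
  secondary profiles with yields proportional to them and equal pools, the
  implied SI *equals* ECI algebraically — a useful exact bridge between
  the two frameworks that the test suite verifies to machine precision.

What the generators deliberately do **not** emulate: chemotaxis and
diffusion through structured media, dynamic algal physiology and exudation,
matrix effects and ionization suppression in LC--MS, NanoSIMS dead-time or
drift (inputs are ROI-level counts), or cross-feeding mechanisms beyond a
sign change in SI. Passing recovery tests therefore demonstrates estimator
correctness under a clean measurement model, not robustness to every
artefact of real data.

## Determinism and numerical notes

All generators run under a locally seeded RNG (`withr`-style state
restoration), so a fixed design is bit-reproducible and never perturbs the
caller's RNG stream. The pipeline (`run_pipeline()`) flows one root seed
into every synthetic stage; rerunning a config reproduces the bundle
exactly, timestamps aside. Zero-variance t-test groups return p = 1 when
means agree and p = 0 otherwise; a zero control mean with nonzero isolate
intensity reports an infinite log2 fold change and a flag rather than
failing; distance computations cap non-finite fold changes at the largest
finite magnitude observed. ECI of a non-consuming secondary strain is 0
with `valid = FALSE`. Exhaustive enumerations are guarded (permutations up
to $n = 8$; Kruskal--Wallis arrangements up to $2 \times 10^5$).

Test-suite and recovery problem sizes — e.g. 60-feature/4-isolate
metabolome recoveries, 200-seed sequential-recovery sweeps, 300-cell
isotope runs — were chosen so the whole suite completes in well under a
minute on a laptop while leaving the statistical checks comfortably
powered; the full-scale 162 × 10 design is exercised once in the
acceptance tests.

## Known limitations

- Consumption proportions conflate uptake, respiration and extracellular
  modification; "consumed" means "signal significantly decreased".
- ECI assumes proportions measured in monoculture transfer to the pair
  context; saturation, inhibition and induction are ignored.
- The SI estimator's precision is bounded by replicate noise: with
  triplicate wells at CV 0.10 the standard error of SI is about
  $0.082\,(1+\mathrm{SI})$, so single-run SI values near zero carry
  roughly ±0.16 (95%) uncertainty — pooling seeds or replicating plates is
  the only remedy.
- $C_\mathrm{net}$ is comparative, not absolute, unless the exudate pool's
  isotopic enrichment is known.
- The $C_\mathrm{total}$ formula assumes carbon mass scales linearly with
  biovolume within a well and uses the median $C_\mathrm{net}$ as the
  population value; strongly skewed single-cell distributions would bias
  it.
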