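---
title: "Measuring family patriarchy from census microdata: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring family patriarchy from census microdata: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrindex)
```

## The measurement model

The Patriarchy Index treats family patriarchy as a higher-order
construct formed by four reflectively measured domains — domination of
men over women, domination of the older generation, patrilocal bias,
and son preference — a hybrid reflective–formative structure. The
practical consequence is that the eleven component indicators are not
required to be highly inter-correlated, domains are non-interchangeable,
and aggregation uses fixed equal weights rather than data-driven
(PCA or reliability) weights: each domain score is the unweighted mean
of its member indicators' 0–10 scores, and the index is the sum of the
four domain scores, 0–40.

The indicators are computed from *behaviour visible in a census
roster*: headship, marital status by age, co-resident kin
configurations, and child sex composition. They proxy institutions
(parental control of marriage, patrilocality, gerontocratic authority,
son preference) that the census never asks about directly. That is both
the method's strength — it works on any post-1970 harmonized census
extract — and its central assumption: that the behavioural residue of
these institutions in household composition is comparable across
populations once age–sex structure is controlled.

### From rosters to indicators

All kin reasoning runs off the relationship-to-head code plus three
within-household locators (spouse, mother, father person numbers). Two
conventions matter:

* **Head perspective.** Census data encode each member's relation to
  the head only. "Lateral kin present" and "lives without relatives"
  are therefore evaluated against the head's kin classes for every
  member. For the head and spouse this is exact; for others it is an
  approximation (a lodger's own sibling elsewhere in the household is
  invisible). The same limitation motivates the case analysis for the
  husband's-kin predicate: it is resolved exactly for wives who are the
  head's spouse, child-in-law, or the head herself, and returns
  *indeterminate* otherwise; indeterminate women are excluded from both
  numerator and denominator of the patrilocality indicator and counted
  in diagnostics.
* **Couples.** A couple is a symmetric spouse-pointer pair; one-way
  opposite-sex pointers are kept as polygamous unions (one couple per
  wife); when no pointers exist at all, the (head, spouse-of-head) pair
  is formed from the codes. An age tie counts as "wife not older".

Design choices that the data did not fix and we had to: "adult male
kin" in the patrilocality indicator means age ≥ 18 (configurable); the
young-male-independence indicator uses *all* men 20–29 as denominator
(not only heads), reading it as the prevalence of neolocal independence
among young men; a woman living entirely alone counts as "living only
with non-kin"; the residual "other relative" category counts as lateral
kin by default (configurable), since in harmonized extracts it is
dominated by extended kin.

### Standardization

Rate indicators (1–9) are directly standardized: 5-year-cell rates
(restricted to the indicator's age band and reference sex; both sexes
pooled for the female-headship indicator, where sex is the outcome) are
averaged with the weights of a standard population — the unweighted
mean of the weighted national age–sex distributions in the run. Cells
with empty regional denominators are dropped and the remaining weights
renormalized, which avoids imputing rates for absent cells at the cost
of letting the effective standard differ slightly across regions.
Indicators 10–11 are sex-composition measures, not rates, and stay
crude. Whether a published implementation standardizes all nine rate
indicators, and at which granularity, is a convention; ours is declared
here and can be switched off (`standardize = FALSE`).

### Scaling and aggregation

Each indicator is first made unidirectional (negative-direction
proportions are complemented), then scored
`10 * (x - m) / (B - m)`, clamped to [0, 10]. The natural minima `m`
are 0 for indicators 1–9 and the neutral child-sex compositions 0.51
and 105 for indicators 10–11; the benchmark `B` is the maximum
intensity over the region set in the run (a fixed benchmark can be
supplied). Degenerate case: if no region rises above the floor, every
score is 0. Missing indicators are excluded from their domain mean; a
domain with all members missing renders the region's index missing and
is logged — no imputation anywhere.

Two benchmarking modes exist because the choice is genuinely open:
country-level indices are computed by re-running the same pipeline with
countries as units, *not* by averaging regional indices; scores are
always relative to the unit set of one run, and the run metadata
records the benchmarks used.

The direction table (which indicators are complemented) follows the
eleven imperatives of patriarchal family organization the indicators
operationalize, e.g. "women do not head households" makes female
headship negative-direction, and "elders are not left to care for
themselves" makes elder solitude negative-direction — elders living
alone signal *weaker* family patriarchy.

## Evaluation machinery

* **Reliability.** Guttman's λ6 from the squared multiple correlations
  of each item on the rest, computed on the scaled 0–10 scores (the
  index aggregates scores, not raw values). Variances use the n−1
  convention; λ6 itself is denominator-invariant. Items perfectly
  predicted by the rest contribute zero error variance, so duplicated
  items yield λ6 = 1 rather than an error.
* **Validity.** Kendall's τ_b with tie corrections and normal-
  approximation inference, delegated to `stats::cor.test`; the test
  suite checks it against an exhaustive pair-count oracle.
* **Spatial structure.** k-nearest-neighbour weights (default k = 7)
  over great-circle centroid distances, row-standardized, ties broken
  by region-identifier order. Global Moran's I uses a one-sided
  positive-autocorrelation permutation test,
  `p = (1 + #{I* >= I}) / (1 + nperm)`, nperm default 999; the local
  version uses conditional permutation (hold the region, redraw its
  neighbours from the rest) and classes significant regions HH/LL/HL/LH
  by the signs of the deviation and its spatial lag. No
  multiple-testing correction by default (an FDR option exists),
  matching common LISA practice of reporting raw pseudo-significance.
* **Inequality.** Theil-T (GE(1)) with the additive between/within
  decomposition; the polarization index is between/within computed from
  unrounded components, and within-zero cases report +Inf with a flag.
  Units are unweighted regions by default (each data point counts
  once); a weighted mode exists. Additivity is enforced to 1e-10 in
  tests.
* **Outcomes.** Relative female labor-force participation is the
  weighted F/M ratio of labor-force headcounts. Age heaping uses the
  total modified Whipple index over all ten terminal digits,
  `W_tot = sum_d |10 p_d - 1|`, on the classic window 23–62 (four full
  decades, so each digit appears exactly four times under uniformity);
  0 means no heaping, 18 total concentration. The F/M ratio of W_tot
  proxies the relative numeracy of women. The exact published variant
  of W_tot is not fully specified in the literature we implement from;
  the digit-proportion formulation above is this package's declared
  definition and is flagged in outputs.
* **Regressions.** The stepwise decomposition fits, per outcome, five
  OLS models with identical controls (log GNI per capita, % urban):
  the overall index, then each domain sub-index in its place. Listwise
  deletion, ordinary standard errors, no multiple-testing adjustment
  across the five descriptive models; rank-deficient model matrices
  are an error naming the collinear columns.

## The synthetic generator

The generator exists so that every stage is testable without
access-restricted microdata. It draws households from five archetypes —
nuclear couples, patrilocal stem (couple + husband's parents, possibly
his brother), joint (parents + two married sons), elder-centred
households, and non-kin groups — with every indicator-relevant event
governed by one explicit probability: female headship, teen marriage of
eligible daughters, wife-older couples, senior vs. son headship,
neolocal splitting of stem households, elder solitude, lateral kin
presence, child sex composition by age group, labor-force participation
by sex. Spouse pointers are symmetric by construction, locators
resolve, weights are 1, and every generated table passes household
validation with an empty repair report.

Each region runs on a pseudo-random sub-stream derived from the global
seed and the region id, so regions reproduce independently of
generation order. A quota mode (`exact_quotas`) replaces Bernoulli
draws with exact-count assignment; the engineered-extreme scenario uses
it so that the maximal region attains the most-patriarchal benchmark on
every indicator *deterministically*, which pins the top of the scale:
its index is exactly 40 under any seed.

Multi-region datasets can follow a spatially smoothed Gaussian field on
a grid (`sqrt(1-rho)·noise + sqrt(rho)·smooth`, mapped through the
normal CDF to a level in [0, 1] that moves all dials monotonically), so
spatial inference can be exercised against known correlation strength.

What the generator does *not* emulate: realistic age pyramids,
mortality and fertility schedules, migration, household dynamics over
time, measurement error in ages (ages are drawn uniformly within roles,
so age heaping is essentially absent), and correlated indicator
structure beyond what the archetype mix induces. Passing tests
therefore demonstrate that the *computational pipeline* is correct —
indicators recover their generating parameters, scaling and aggregation
obey their contracts, spatial and inequality statistics behave — not
that the index is valid on any real population. Defaults (e.g.
15% female headship, 15% teen marriage, under-five sex ratio 105,
female/male labor-force participation 0.4/0.85) describe a moderately
patriarchal population and give all eleven denominators mass at modest
sample sizes.

## Numerical conventions and problem sizes

Tie-breaks: equal spousal ages count as "wife not older"; k-NN distance
ties resolve by region-identifier order; quota rounding uses
`round(n·p)` with largest-remainder allocation for archetype counts.
Degenerate inputs: constant vectors are errors for Moran's I and τ_b;
zero within-inequality reports an infinite polarization with a flag;
an all-missing indicator column stays missing through scaling.
Tolerances asserted in the test suite: Theil additivity to 1e-10,
λ6 and τ_b oracles to 1e-10/1e-12, Monte-Carlo recovery within three
binomial standard errors.

The shipped tests size their simulations deliberately: parameter
recovery runs each indicator's scenario family at roughly 20,000
persons; the spatial-power checks use 8×8 grids with 30–40 households
per region, one spatially correlated field at rho = 0.9 and forty
independent null fields (seeds fixed a priori at 1–40, 199 permutations
each); the engineered-extreme pair uses 300 households per region.
These sizes make binomial error small relative to the effects being
checked while keeping the full suite in the minutes range on one CPU.

## Known limitations

The head-perspective approximation misclassifies some kin
configurations for non-head members, and the patrilocality indicator's
indeterminate exclusions shrink its denominator where households are
coded loosely. Scores are relative to the run's region set: adding or
removing regions moves benchmarks and therefore every score —
cross-run comparisons require a fixed benchmark configuration.
Reliability of the integration surface against published regional
results depends on a deposited table that is access-controlled; the
package ships the machinery (`read_regional_results`,
`summarize_regional_results`) but not the data.
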