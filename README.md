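# patrindex

Family systems encode durable gender and generational hierarchies —
who heads the household, how early women marry, whether a bride moves in
with her husband's kin, who cares for the old, whether sons are
preferred over daughters. `patrindex` measures these hierarchies from
ordinary census microdata. It computes the **Patriarchy Index (PI)**, a
0–40 composite of eleven family-demographic indicators in four equally
weighted domains, together with the evaluation machinery a measurement
paper needs: reliability, validity correlations, spatial clustering,
inequality decomposition, and outcome regressions. A synthetic
household-microdata generator with known patriarchal parameters makes
the whole pipeline testable without access-restricted census extracts.

The package is aimed at demographers and social scientists working with
harmonized census microdata (IPUMS-International-style person files with
relationship-to-head codes and spouse/mother/father locators).

## The index

Eleven indicators are computed per region from weighted person records
(reference populations in parentheses; `+`/`−` is the direction of
association with patriarchy):

| # | Indicator | Domain | Dir |
|---|-----------|--------|-----|
| 1 | female household heads (heads 20+) | male domination | − |
| 2 | ever-married women (women 15–19) | male domination | + |
| 3 | couples with wife older than husband (couples) | male domination | − |
| 4 | women living only with non-kin (women 20–24) | male domination | − |
| 5 | men under a younger male relative head (men 65+) | generational domination | − |
| 6 | male heads living only with their immediate family (men 20–29) | generational domination | − |
| 7 | persons living with lateral kin (persons 65+) | generational domination | + |
| 8 | persons living without relatives or spouse (persons 65+) | generational domination | − |
| 9 | ever-married women living with the husband's kin (women 15–30) | patrilocality | + |
| 10 | boys among children 10–14 | son preference | + |
| 11 | under-five sex ratio, boys per 100 girls | son preference | + |

Rate indicators (1–9) are directly age(-sex)-standardized with the
average structure of the national populations in the run. Each indicator
x_j is made unidirectional (negative-direction proportions are
complemented), then scaled to a 0–10 score against the region set:

```
score_j(r) = 10 * (x_j(r) - m_j) / (B_j - m_j)
```

with natural minimum m_j (0 for indicators 1–9; the neutral values 0.51
and 105 for the two son-preference indicators) and benchmark B_j the
highest observed intensity, so the most patriarchal region scores 10 and
a region at the natural floor scores 0. Domain sub-indices are
unweighted means of their member scores; **PI = sum of the four domain
scores ∈ [0, 40]**.

Around the index: Guttman's λ6 reliability, Kendall's τ_b validity
tables, k-nearest-neighbour Moran's I and LISA cluster typing with
permutation inference, Theil-T between/within-country decomposition with
the polarization ratio, relative female labor-force participation and
the total modified Whipple age-heaping index (and its F/M ratio), and
the stepwise OLS decomposition regressing outcomes on PI and then on
each sub-index with identical controls.

## Worked example

```r
library(patrindex)

# three synthetic regions with increasing teen-marriage prevalence
tabs <- generate_dataset(list(
  scenario_config("north", "C1", n_households = 400, seed = 7,
                  p_teen_married = 0.05),
  scenario_config("centre", "C1", n_households = 400, seed = 7,
                  p_teen_married = 0.30),
  scenario_config("south",  "C2", n_households = 400, seed = 7,
                  p_teen_married = 0.55, p_wife_older = 0.05)))

res <- compute_pi(validate_households(tabs$table)$table)
as.data.frame(res$pi[, c("region", "male_domination",
                         "generational_domination", "patrilocality",
                         "son_preference", "pi")])
#>   region male_domination generational_domination patrilocality son_preference   pi
#> 1 centre            8.87                    9.53         10.00          5.000 33.4
#> 2  north            7.92                    9.58          8.98          0.741 27.2
#> 3  south            9.91                    8.53          9.86          2.651 31.0
```

Each region's eleven scores are benchmarked against the three-region
set, so at least one region touches 10 on every indicator; the `pi`
column is the sum of the four domain scores. The `male_domination`
domain rises with the teen-marriage dial (7.92 → 8.87 → 9.91 from the
lowest to the highest `p_teen_married`), while the other domains
reshuffle with sampling noise at 400 households per region — a reminder
that relative benchmarking makes every score depend on the region set,
not on the region alone.

`run_pipeline()` drives the same computation from a YAML/JSON
configuration and writes CSV/JSON artifacts (indicator matrix, PI table,
outcomes, reliability, global/local spatial statistics, Theil
decomposition, regression tables, run manifest); a thin command-line
wrapper lives at `inst/cli/patrindex.R`.

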