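---
title: "Simulating positioning and labelling interventions in an online supermarket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating positioning and labelling interventions in an online supermarket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The trial being modelled

`shelfnudge` models a five-arm randomised controlled trial in an
experimental online supermarket. Participants are given a ten-item
shopping list (a savoury pie, cheese, a frozen pizza, a sandwich,
yogurt, a ready meal, meat or a vegetarian alternative, soup, a chilled
or frozen dessert, crackers) and asked to select one product per
category, with checkout permitted between 10 and 15 distinct items. The
five arms are: a control with random shelf ordering; two *positioning*
arms in which shelf order is biased so that healthier (or more
environmentally sustainable) products tend to appear earlier; and two
*positioning + labelling* arms that additionally display A--E
front-of-pack letters for the targeted dimension. Every arm shows a
price-match decoy label on the same fixed random 10% of products so
that label presence alone does not reveal the study purpose.
Randomisation is 1:5:5:5:5 (control : four interventions), reflecting
the smaller effect expected for between-intervention comparisons.

The package provides every stage as a testable unit: catalog synthesis,
nutrient cleaning, health and eco scoring, shelf layout, the shopper
model, exclusion rules, and the statistical pipeline.

## Health scoring

Products are scored with the original FSAm-NPS (Nutri-Score) points
system. "Negative" points (0--10 per component) accrue for energy
(kJ), total sugars, saturated fat and sodium; "positive" points for
fruit/veg/nuts content (0--5; 0--10 for beverages), fibre and protein
(0--5 each). For general foods, protein points are only subtracted when
negative points are below 11 or the fruit/veg component is maximal;
cheese always counts protein, and added fats replace the saturated-fat
component with the saturated-to-total-fat ratio. The component
threshold tables and the A--E letter cut points (general foods:
A at raw $\le -1$, B to 2, C to 10, D to 18, E above) ship as CSV data
files so the algorithm version is explicit and swappable.

The raw score lies in $[-15, 40]$. The trial analyses a 0--100 scaled
score; the mapping is the affine map of the *theoretical* range,
$\mathrm{scaled} = (\mathrm{raw} + 15) \times 100 / 55$, because it is
catalog-independent and exactly reproducible. Min--max scaling over an
observed catalog is available through the `range` argument of
`scale_health()`. Higher scaled scores mean less healthy.

Energy is recorded in kcal (as retailer feeds supply it) and converted
to kJ ($\times 4.184$) before the points lookup. Missing optional
components (saturated fat, fibre, fruit/veg) score zero points with a
warning, so that any product passing the trial's completeness filter
(energy, salt, sugar, fat) can be scored; missing required components
are an error.

## Nutrient cleaning

Raw feeds declare nutrients as text. Cleaning applies, in a fixed
order that makes each rule well-defined on the previous rule's output:

1. comma decimal repair (`"1,2"` becomes `"1.2"`, only when the comma
   is flanked by digits);
2. `"trace"`, `"nil"`, `"negligible"` read as zero for fat, sugar and
   salt;
3. `"<"` prefixes stripped;
4. small-value recodes: fat or sugar below 0.5 g and salt below
   0.01 g read as zero, so a stripped `"<0.02"` salt value keeps its
   0.02 while `"<0.005"` collapses to zero.

The published recode states the `"<"` rule for salt only; we apply the
same strip-then-threshold logic to fat, sugar and saturated fat as the
least surprising completion (the 0.5 g rule is likewise extended to
saturated fat). Unparseable strings become `NA` -- never a silent zero
-- and such products are removed by the completeness filter, mirroring
the study's catalog exclusions. Sodium is derived as salt $\times$ 400
mg/g.

## Eco scoring

Each product carries four per-100 g environmental indicators:
greenhouse gas emissions (kg CO2e), scarcity-weighted water use
(litres), biodiversity loss (species lost $\times 10^{-14}$) and
eutrophication potential (g PO4^3-^e). The composite methodology
behind the published score is not restated in full anywhere we can
implement from, so the package fixes a transparent rule and isolates
it in one function (`eco_composite()`) for substitution: each
indicator is converted to its within-catalog percentile (midrank
convention, $(\mathrm{midrank}-0.5)/n \times 100$, so full ties map to
50), and the composite is the arithmetic mean of the four percentiles.
The A--E eco letter is the catalog quintile of the composite (type-7
edges at the 20/40/60/80th percentiles; a value exactly on an edge
takes the better letter). Higher composite means less sustainable.

## Shelf positioning

Within each shelf, every product draws a uniform sort key whose range
depends on its letter in the arm's targeted dimension -- A: (1, 2),
B: (1.1, 3), C: (1.2, 4), D: (1.3, 5), E: (1.4, 6); control: (1, 6)
for everything -- and the shelf is sorted ascending, paginated at 28
products per page. The overlap structure of the ranges makes better
letters stochastically earlier without determinism; for example
$P(\mathrm{key}_A < \mathrm{key}_E) = 0.9609$.

Keys are drawn fresh for every participant session. The alternative --
freezing one ordering per arm -- is equally consistent with the design
description; per-session draws avoid a single frozen ordering driving
all results, and the choice only matters through Monte-Carlo noise.
The uniform endpoints are treated as half-open intervals, a
measure-zero distinction. Ties (impossible for continuous keys, but
defensively) break on product id.

## The synthetic shopper

The study measured humans; the package substitutes an explicit choice
model so that the pipeline is testable end to end. Within a visited
shelf the shopper picks product $i$ with multinomial-logit probability
proportional to $\exp(u_i)$, where

$$u_i = -\mathrm{rank}_i / \tau + \beta_L \, g_i - \beta_P \,
\mathrm{price}_i,$$

$g_i$ maps the *visible* label letter A..E to $+2..-2$ (zero when the
arm shows no labels), and rank is the product's position in this
session's layout. Defaults: $\tau = 10$ ranks (choice mass
concentrated on page 1, consistent with nearly all online grocery
choices being first-page), $\beta_L = 0.25$ per letter step,
$\beta_P = 0.01$ per GBP. Behavioural nuisance parameters: each list
category is skipped with `p_skip = 0.03`; unprompted extra items occur
at Poisson rate 0.3 per session; sessions are abandoned before
checkout with probability 0.02; 1% of participants rush (completion
time scaled by 0.2, tripping the speeder exclusion). With
$\tau = \infty$ and both $\beta$s zero the shopper is uniform over the
shelf, which is the null model used for type-I-error calibration: all
arms are then exchangeable by construction.

A basket with fewer than 10 items cannot check out; when skipping
leaves a shortfall the simulated shopper fills up with extra items
from random list shelves. This is our resolution of an ambiguity in
the protocol (partial compliance down to 7 categories is analysable,
yet checkout requires 10 items); it means category coverage below 10
coexists with a valid checkout, exactly the population the exclusion
rules must adjudicate.

## The synthetic catalog

The generator emulates a retailer feed of 8400 products: the ten list
shelves (800 products, shelf sizes 32--120 so most shelves paginate)
plus 95 filler shelves of 80. Per-shelf nutrient distributions are
truncated normals with means chosen to be grossly plausible per
category (cheese salty and fatty, desserts sugary, soup light), with
energy and fat coupled through a shared latent factor. Data quirks are
configurable and on by default: a product-level comma-decimal
corruption at rate 326/8400, trace-words and `"<"` prefixes at 2% per
eligible string, a missing required field at 1% per product, and an
alcohol flag (2% of filler products) standing in for the alcohol
exclusion that the real study performed on product metadata.

Environmental indicators are log-normal and correlated within product.
Two generator choices matter downstream and were fixed once, from the
published scale of basket-level eco scores (single digits on a 0--100
composite):

* filler shelves sit 3 log-sd above the list shelves, so list products
  occupy the bottom decile of the catalog-wide percentile scale --
  this is the only way a mean-of-percentiles composite (which averages
  50 over any catalog) can yield single-digit basket means;
* the list-shelf tail is heavy (sdlog 1.5), so a minority of list
  products reach the higher quintile letters, giving eco positioning
  within-shelf variation to act on.

Comma-corrupted products are scored twice: correctly (for analysis)
and from the mis-parsed feed (comma dropped, so "1,6" reads 16) for
the *displayed* letter, reproducing the labelling defect that the
decimal-error sensitivity analysis addresses.

What the generator does not emulate: brand effects, promotions,
search behaviour, within-shelf taxonomy, realistic joint nutrient
distributions, or any covariance between demographics and behaviour
(demographics follow the study sample's margins but are independent of
choice by default). Passing tests therefore demonstrate correctness of
the machinery and calibration of the statistics under a known
generative model -- not that effect magnitudes transfer to humans.

## Exclusions, compliance and analysis

Exclusions follow the pre-registered list, attributed by first failing
rule in its stated order: incomplete session; more than 20 products;
completion under 30% of the median time of completed sessions
(study-level median); fewer than 7 list categories covered. Full
compliance is exactly one product per category and nothing else.

Primary analysis: OLS of basket mean scaled Nutri-Score (health) or
log of basket mean eco score (eco) on arm, control as reference, plus
a separate model of position & labels against position; threshold
0.025. Eco-dimension estimates and 95% CIs are exponentiated, so they
read as multiplicative effects. Secondary models repeat this per
nutrient (identity) and per environmental indicator (log +
exponentiation) at threshold 0.005; interactions are joint F-tests of
the arm-by-covariate block at 0.005 (with "other gender identity" and
income "prefer not to say" dropped and education "none" merged into
the lowest band); spill-over models swap the outcome across dimensions
and are exploratory (no threshold). Basket price uses Levene's test
(median-centred) to choose between classic ANOVA with Tukey HSD and
Welch ANOVA with Games-Howell, pairwise threshold 0.025. The
Games-Howell comparisons are implemented in the package (Welch-type
standard errors and degrees of freedom against the studentized-range
distribution) since no installed package provides them.

Numerical conventions fixed for reproducibility: type-7 quartiles in
the IQR outlier rule (fences at $Q1 - 1.5\,\mathrm{IQR}$ and
$Q3 + 1.5\,\mathrm{IQR}$, bounds inclusive); natural log for all
logged outcomes (immaterial after exponentiation); nonrobust
normal-theory OLS CIs; the 0.025/0.005 thresholds applied as fixed
cutoffs, not as p-value adjustments. The meat-consumption score
follows the 0--5-points-per-meal coding with bands 0--5 / 6--10 /
11--15; an alternative 0--4 coding with bands 0--4 / 5--8 / 9--12 is
available via `meat_score(..., scheme = "table2")` because both
appear in the trial's documentation.

## Power planning

`required_sample_size()` solves the two-sided two-sample noncentral-t
power equation (via `stats::power.t.test`) with $d = 2f$, inflates by
$1/(1 - \text{non-compliance})$ and expands to the allocation ratio.
With $f = 0.1$, power 0.9, $\alpha = 0.05$ it gives 527 per group
uninflated. The trial's published plan (633 per intervention group,
control 127, total 2659) is reproduced by `plan_allocation(633)`; the
exact procedure that produced 633 from the stated inputs is
underdetermined (our computation gives 659 after 20% inflation), so
the printed group size is treated as an input to the allocation
arithmetic rather than re-derived.

## Problem sizes used in the test suite

The suite verifies scoring against an independently coded
component-lookup oracle on $10^4$ random nutrient vectors; key-order
probabilities against closed-form integrals at $10^6$ Monte-Carlo
draws; type-I error of the full simulate-exclude-fit pipeline under
the null shopper over 1000 replicates of 210 participants (99%
binomial band around 0.025); and recovery of a planted multiplicative
eco effect of 0.76 over 200 replicates at 500 per arm (tolerance
0.02 on the mean exponentiated estimate). Distributional invariants
(arm exchangeability under the null, effect-direction checks under the
positional shopper) run at reduced replicate counts chosen to keep the
suite brisk while leaving the tested directions unambiguous.

## Known limitations

The choice model is a stand-in: its parameters are interpretable but
not estimated from human data, so simulated effect magnitudes are
illustrative. The eco composite's aggregation rule is our documented
choice, not the published methodology's (unavailable in implementable
detail); percentile-based alternatives can be swapped in at one
function. Beverage and added-fat scoring variants are implemented but
unused by the default simulation, which scores everything as general
foods (alcohol is excluded and the list contains no beverages).
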