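---
title: "Measuring household poverty dynamics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring household poverty dynamics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(povdyn)
```

`povdyn` analyses two-round panel surveys of smallholder farm households.
This vignette is the package's account of the underlying model, the
defaults it ships, the design of its synthetic data generator, and the
numerical and statistical choices made where more than one defensible
option existed.

## The measurement model

The unit of analysis is the household-round. Every household's activity
portfolio — crops and livestock products produced, consumed and sold, plus
off-farm income — is collapsed into two indicators.

**Total Value of Activities (TVA)**, in PPP dollars per household per
year, is the sum of five components: value of crops consumed, crops sold,
livestock products consumed, livestock products sold, and off-farm income.
Consumption is always valued at the local market price for the site and
round. Sales are valued at the *reported* sale income when one is present,
falling back to quantity × price otherwise: recalled incomes are usually
more reliable than recalled quantities for marketed produce, and surveys
of this kind collect them directly. Local values are divided by a
purchasing-power-parity factor to give international dollars.

**Food Availability (FA)**, in kcal per male adult equivalent per day,
asks a different question of the same portfolio: how many calories could
this household put on the table? Calories of consumed produce are counted
directly; cash (sales plus off-farm income) is converted into the calories
it could buy at the local staple price:

$$\mathrm{FA} = \frac{\sum_i q_i^{cons} e_i \;+\;
  (\text{cash income}) \cdot E_{maize}/p_{maize}}{\mathrm{MAE} \times 365}$$

where $e_i$ is the energy density of product $i$ and $E_{maize},
p_{maize}$ are the staple's energy density and local price. By default
only the staple has an explicit energy density; any other consumed product
is valued at its local price and converted through the same maize route
($e_i = p_i E_{maize}/p_{maize}$). This keeps FA well defined with exactly
the data the survey records; a per-product `kcal_per_kg` table in the
conversion table overrides the price route product by product. A
consequence worth knowing: under the default, FA is proportional to
local-currency TVA within a site and round, so the two thresholds below
act as two cut points on one underlying prosperity axis. With a kcal
table, or across sites with different price levels, the two indicators
decouple.

Two normalisers make households comparable. **MAE** (male adult
equivalents) rescales the roster by age/sex energy-demand factors, adult
male = 1.0. The shipped table (`default_mae_factors()`) is deliberately
coarse — 0.50 under 5 years, 0.75 for 5–10, 0.85 for 11–14, 1.00/0.80
(M/F) for 15–59, 0.80/0.65 above 60 — because no single published factor
table is canonical; it approximates relative energy requirements and is
fully overridable. **TLU** (tropical livestock units) aggregates herds
with 1 TLU = one 250 kg cow; the shipped weights put cattle at 1.0 and
goats and sheep at 0.2 (five goats = 1 TLU), with standard reference
values for other species. The staple energy density defaults to 3580
kcal/kg of maize grain; it, too, is configuration, not code.

## The three strata and the trajectory groups

Two thresholds define three poverty strata per round:

* the **calorie line**, 3000 kcal/MAE/day on FA — below it a household
  cannot cover basic calorie needs;
* the **poverty line**, $1.90 PPP per MAE per day on TVA — the
  international extreme-poverty line applied to the household's total
  activity value.

`classify_stratum()` applies them with an explicit precedence: a household
at or above the poverty line is **High** regardless of its FA; of the
rest, FA at or above the calorie line gives **Medium**, otherwise **Low**.
The precedence matters only for the rare household that is
value-rich but calorie-poor (e.g. a specialised cash earner facing a high
staple price); such discordant households are counted and reported in the
`discordant` attribute rather than silently absorbed. Both comparisons are
closed on the upper side (`>=`): a deterministic, documented tie-break for
households exactly on a line.

Two defensible alternatives exist and are exposed as configuration: the
thresholds themselves (`calorie_line`, `poverty_line`) and the denominator
of the value threshold (`per = "mae"`, the default, or `per = "capita"`).
Evaluating both thresholds per MAE keeps them on one population scale; the
per-capita option exists because the poverty line is conventionally quoted
per person.

A household's **trajectory** is its ordered pair of strata (round 1,
round 2): nine groups, each rising, steady or falling under
Low < Medium < High. `flow_matrix()` tabulates the 3×3 transition counts;
its row and column sums are, by construction, the per-round strata counts
on the matched subsample — an identity the tests assert rather than
assume.

## Statistical harness

* **McNemar's test** for the change in a paired binary status (above vs
  below a line). The statistic is the uncorrected closed form
  $(b-c)^2/(b+c)$ on the discordant counts; with fewer than 25 discordant
  pairs the exact two-sided binomial test on $b$ of $b+c$ replaces the
  chi-squared tail. Both variants are available explicitly. The analysis
  runs the dichotomisation at both lines, labelled separately, since
  "poverty rate" can reasonably mean either.
* **Wilcoxon signed rank** on ordinal stratum codes (1, 2, 3). Zero
  differences are dropped (Wilcoxon's original treatment); tied absolute
  differences get average ranks. Because stratum codes produce heavy ties,
  the exact null distribution is computed by a convolution over the
  doubled (hence integer) ranks — exact for up to 25 non-zero differences,
  after which a tie-corrected normal approximation takes over. The exact
  path is validated in the tests against full $2^n$ enumeration.
* **One-way ANOVA with post-hoc letters** for group comparisons (strata
  within a round, education levels, welfare validation). Tukey HSD uses
  the studentized range with the Tukey–Kramer unequal-$n$ adjustment;
  Fisher LSD uses unadjusted pairwise $t$ tests on the pooled within-group
  mean square. The compact letter display is built by insert-and-absorb,
  so two groups share a letter exactly when their pairwise test is not
  significant at `alpha` (0.05 throughout). No multiplicity correction is
  applied beyond what the post-hoc method itself provides. Group summaries
  report medians (the headline) alongside means; tests always consume the
  full untrimmed data.
* **Asset regression**: ordinary least squares of round-2 farm income on
  round-1 land, TLU and off-farm income, untransformed by default with a
  `log1p` option (income regressions are sometimes run on the log scale;
  nothing in the data dictates one choice). Rank deficiency is an error
  naming the collinear columns rather than a silently dropped term.

Cross-round statistical comparisons of group medians are deliberately
never emitted: the per-round tables carry letters only within a round.

## Welfare instruments and stratum validation

The strata are built from production values alone, so four instruments
collected independently in the resurvey round serve as validation: HFIAS
(nine 0–3 frequency items, score = sum, severity category from the
standard four-class decision rules implemented as an explicit, enumerable
table), HDDS (count of ten food groups, flush and lean seasons), a PPI-style
scorecard (a generic engine over a points-and-lookup definition; the
shipped scorecard is a synthetic fixture in the shape of the published
country scorecards, which are data, not code), and months of food
shortage. `validate_strata()` compares each score across strata
(ANOVA + Tukey) and checks that medians order the way prosperity should
order them — better welfare in higher strata. Instruments with incomplete
responses are missing for that household, never imputed: a welfare score
summed over a partial item set would not be comparable.

## The synthetic panel generator

Archived panels of this kind are access-controlled, so the package
generates its own. The generator works *latent-first*, the inverse of the
analysis direction: each household's round-1 stratum is drawn from
designed proportions, its round-2 stratum from a designed row-stochastic
transition matrix, and only then are survey records generated to land the
household in that stratum. This ordering is what makes parameter recovery
an assertable property — the ground truth exists before the pipeline runs.

Defaults emulate the study conditions the package is shaped around: four
sites of 7 villages × 20 households (560 in round 1) with retention
fractions 0.735, 0.675, 0.80 and 0.80 (round-2 subsamples drawn as simple
random subsets, sizes `round(retention × n)`), household sizes uniform on
4–7, land and herd sizes lognormal with medians near 1.2 ha and 2 TLU,
first-round strata proportions (0.30, 0.33, 0.37), and a transition matrix

```
         Low  Medium  High
Low     0.34    0.33  0.33
Medium  0.30    0.32  0.38
High    0.18    0.32  0.50
```

chosen so the implied second-round marginals are approximately
(0.27, 0.33, 0.41) and a majority of households change stratum. Each site
has its own pseudo-random stream split from the master seed, so adding a
site never perturbs the draws of existing ones, and identical seeds give
identical panels.

Observables are generated backwards from a latent prosperity target on
the FA axis: Low households centre on 1500 kcal/MAE/day (s.d. 450), Medium
on 3500 (s.d. 300), and High is placed in value terms at 2.5 × the $1.90
line (s.d. $1.2/MAE/day) and mapped onto the FA axis through the staple
price. The target is split into the five TVA components by a Dirichlet
draw whose means shift with stratum (more sales and off-farm income with
rising prosperity), spread over site-specific crops and products at local
prices, and topped with a small unsold production remainder inside the 5%
recall tolerance. The noise scales leave each stratum's mass
overwhelmingly on its own side of the lines, so the pipeline recovers the
latent stratum for ≈95–98% of households — noisy enough to be honest,
clean enough that designed proportions are recoverable within a few
percentage points at n = 600. Within-round distributional families
(lognormal land and herds, gamma-flavoured value shares) are a modelling
choice: right-skewed, median well below the mean, as such survey
variables are; no survey publishes its generating distributions.

Welfare responses are drawn with stratum-dependent shifts of roughly one
standard deviation (better scores in higher strata), for the resurvey
round only, mirroring when such instruments are actually fielded.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: informative attrition (dropout is
purely random here; real attrition correlates with poverty), spatial and
village-level clustering, price shocks and drought years, seasonal
disaggregation, recall bias beyond the symmetric tolerance, and the
specific crop mixes of any real site. Results on synthetic data validate
the *machinery*, not any substantive finding.

## Numerical conventions and degenerate inputs

* Quantities and incomes read from CSV treat missing cells as 0; welfare
  items stay missing (and propagate to a missing score).
* A crop or product row whose consumed + sold exceeds production by more
  than 5% (relative) is excluded and reported — recall data deserve a
  tolerance, but not an unbounded one.
* Intensity ratios (crop value/ha, livestock value/TLU, off-farm/MAE):
  0/0 is 0 (a household with no livestock and no livestock income has
  zero livestock intensity); positive value over a zero denominator is
  missing and excluded from group summaries, never infinite.
* Share-table ratios are computed from unrounded shares and reported at
  two decimals.
* Degenerate test inputs are flagged, not errors: no discordant pairs
  (McNemar p = 1), no movement (Wilcoxon p = 1), zero within-group
  variance with equal means (ANOVA marked degenerate).

## Problem sizes used by the test suite

The shipped tests run the full pipeline on a two-site synthetic study of
90 round-1 households, check strata-proportion recovery on a 600-household
panel, transition-matrix recovery on a 5000-household single-site panel
(±0.03 per cell), exact-test equivalences by complete enumeration up to
n = 12, and regression coverage with 1000 replicates at n = 500. These
sizes were chosen as the smallest that make the stochastic assertions
statistically comfortable.

## Known limitations

* The default maize-route conversion couples FA and TVA within a
  site-round; analyses that need genuinely independent calorie accounting
  must supply a per-product energy table.
* PPP factors are applied per site as scalars; multi-year panels with
  strong inflation would need per-round factors (the structure allows
  adding them, the default tables do not populate them).
* The MAE factor table is an approximation; any serious nutritional claim
  should substitute a table matched to the study population.
* No survey weights, no attrition modelling, no mixed effects: the
  analysis treats the matched panel as a simple random sample, as the
  underlying survey designs did.
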