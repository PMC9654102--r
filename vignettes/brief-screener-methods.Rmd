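---
title: "Deriving brief food-insecurity screeners: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving brief food-insecurity screeners: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfssm)
```

## The measurement problem

Household food insecurity unfolds as a broadly ordered ("managed")
process: worry about food running out comes first, then compromised
diet quality, then reduced intake, and finally whole days without
eating. The adult HFSSM exploits this by asking ten items of increasing
severity and counting the affirmed "food-insecure conditions". The full
module is considered too long for busy clinical settings, which
motivates two-item OR-rule screeners drawn from the mildest, most
frequently affirmed items, validated against the full module as the
reference standard.

This package implements the full chain — coding, scoring, screener
evaluation, recommendation — plus a synthetic respondent generator, so
the pipeline can be developed and validated although real survey
microdata of this kind are typically confidential.

## Coding and scoring rules

Raw answers map to binary condition indicators: on the trichotomous
items (1–3) both *often true* and *sometimes true* affirm; on yes/no
items *yes* affirms; on the frequency follow-ups (5 and 10) *almost
every month* and *some months* affirm while *only 1 or 2 months* does
not. A follow-up is answered exactly when its parent item (4 or 9) is
affirmed; the skip pattern is validated on input and the coupling
`a5 <= a4`, `a10 <= a9` therefore holds for every legal record.

Severity classifications are pure threshold rules on the condition
count: 0 / 1–2 / 3–5 / ≥6 for the 10-item module and 0 / 1 / 2–4 / 5–6
for the 6-item form. Two wording ambiguities in circulating
descriptions were resolved by the standard conventions: the
trichotomous coding sentence is sometimes printed self-contradictorily
(we use often/sometimes = 1, never = 0), and "more than five" for the
6-item very-low category would leave a score of 5 unclassified (we use
the standard 5–6 band). A household is *food insecure* on an instrument
whenever it is not in the food-secure category; the reference standard
for screener evaluation is the 10-item score at `reference_threshold`
(default 3, i.e. low or very low food security), exposed as a parameter
throughout.

Records with any missing instrument answer are excluded listwise and
counted in the run manifest; a record missing only demographics is still
scored overall and simply never enters a subgroup stratum.

## Diagnostic evaluation and the recommendation rule

Each candidate pair is an OR-rule screener. From the 2×2 cross-tab
against the reference, the package reports sensitivity, specificity,
accuracy and reference prevalence on the percentage scale; these
satisfy the exact identity

$$\text{acc} = \frac{\text{sens}\cdot\text{prev} +
\text{spec}\cdot(100-\text{prev})}{100},$$

which the tests verify to 1e-12. Undefined metrics (a stratum with no
reference-insecure or no reference-secure records) are reported as
missing values with a warning, never as 0 or 100. Subgroup rows are
computed by filtering the records and re-running the full cross-tab,
not by reweighting, so a partitioning pair of subgroups sums exactly to
the all-households table.

"Best sensitivity and specificity" needs a scalarization to be a
selection rule; `select_best()` maximises all-households **accuracy**,
breaking ties by higher sensitivity (screening favours not missing
insecure patients — a false positive costs little) and then by lower
item numbers for determinism.

## The synthetic respondent generator

`simulate_respondents()` draws, per respondent,

* five independent Bernoulli demographic flags with configurable
  prevalences (0.35 children, 0.35 high-school/diploma education, 0.15
  not living with spouse, 0.25 income under $70,000, 0.13 welfare),
* latent severity $\theta = \mu + \sum_k \beta_k f_k + \sigma
  \varepsilon$, $\varepsilon \sim N(0,1)$,
* item affirmations $P(a_i = 1 \mid \theta) =
  \operatorname{logistic}(a(\theta - b_i))$ — a two-parameter logistic
  IRT model with common discrimination $a$ — with the follow-up items
  generated only when their parent is affirmed,
* presentation detail (often vs sometimes, almost-every-month vs
  some-months) from a fixed secondary threshold $b_i + 0.9$ that never
  affects a score, and
* the single item from its own cut-point with the same logistic noise.

Defaults (in `inst/extdata/generator-default.yaml`): $\mu = -2.2$,
$\sigma = 1$, $a = 3$, thresholds $(0.00, 0.50, 0.20, 1.10, 1.10, 1.35,
1.10, 2.20, 2.60, 2.60)$, severity shifts $(0.15, 0.35, 0.65, 1.25,
0.85)$ for the five flags, single-item cut-point 0.65. The threshold
ordering $b_1 < b_3 < b_2 < b_4 = b_5 = b_7 < b_6 < b_8 < b_9 = b_{10}$
reproduces the canonical affirmation ranking among the food insecure
(worry first, whole days without food last); the location puts the
overall 10-item insecurity prevalence in the 10–20% band with the
reference (≥3) prevalence near 6%, and the covariate shifts give the
low-income, welfare and not-living-with-spouse subgroups clearly
elevated prevalence. This is a qualitative calibration of population
structure, not a fit to any dataset. Setting `discrimination = Inf`
gives the deterministic Guttman limit, where responses are exactly
cumulative in the threshold order and every pair from items {1,2,3}
attains 100% sensitivity against the ≥3 reference — a useful exact
test case.

What the generator deliberately does **not** emulate: correlated
demographics, multidimensional response behaviour (e.g. item-specific
"worry" unrelated to overall severity), differential item functioning,
and household-size effects. One visible consequence: under *any*
unidimensional common-discrimination model with this threshold
ordering, a pair that excludes the mildest item necessarily has better
specificity — mildly affected households affirm item 1 without reaching
the reference cut — so the default-data recommendation is items 2+3,
whereas real survey data, which are never perfectly unidimensional, can
and do favour items 1+3. Passing tests on simulated data therefore
validate the *machinery* (coding, counting, cross-tabulation,
selection logic), not any claim about which pair wins in a particular
human population.

## The population oracle

`population_diagnostics()` computes exact operating characteristics by
integrating over severity. Given $\theta$, items are conditionally
independent except for the follow-up pairs, so the score distribution
is the convolution of eight unit distributions: six Bernoulli items and
two parent–child units with trinomial counts $(1-p_P,\; p_P(1-p_C),\;
p_P p_C)$. Screener-negativity constraints zero out the affirmed states
of the constrained items within their unit. The marginal over $\theta$
is a 32-component normal mixture (one component per demographic-flag
combination); `stats::integrate` evaluates the four confusion cells to
relative tolerance 1e-10, and a computed check that the cells sum to 1
within 1e-6 guards against quadrature failure. In the Guttman limit the
integrand is piecewise constant, so the cells are evaluated exactly as
mixture-CDF mass on the inter-threshold intervals instead.

```{r oracle, eval = FALSE}
cfg <- generator_config(n = 2e5, seed = 314159)
population_diagnostics(cfg, items = c(1, 3))
diagnostics(cross_tabulate(simulate_respondents(cfg), c(1, 3)))
```

The test suite requires the empirical sensitivity and specificity at
n = 200,000 to lie within one percentage point of the oracle.

## Numerical choices and degenerate inputs

* Percentages are stored at full precision; only the printers round,
  half-up, to one decimal (`round_half_up` sheds binary representation
  error before flooring, so 0.15 prints as 0.2).
* `sigma` must be strictly positive; tests that need a pinned severity
  use `sigma = 1e-9` with zero covariate effects.
* Empty strata produce rows with `n = 0` and missing metrics rather
  than errors; an input with no reference-insecure records yields a
  report with undefined sensitivities and a warning, and no
  recommendation.
* All simulation draws happen in a fixed order (flags, severity noise,
  item uniforms, single-item uniform) under one `set.seed`, so a seed
  reproduces a dataset byte-for-byte.
* Problem sizes in the shipped checks — 1,000 datasets of n = 300 for
  the nesting property, n = 100,000 for the qualitative-structure
  checks, n = 200,000 for oracle recovery — were chosen as the smallest
  sizes at which Monte-Carlo noise is comfortably below the assertion
  margins.

## Limitations

The generator's independence assumptions make simulated screeners
slightly "too easy": conditional independence given a single trait
understates real response heterogeneity, so empirical sensitivities here
run higher than one should expect in the field. The package evaluates
only OR-rule item subsets (no weighted or three-item screeners, no
confidence intervals for the diagnostics, no Rasch-type continuous
severity scores), and the 8 child-referenced items of the 18-item HFSSM
are out of scope.
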