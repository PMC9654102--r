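# hfssm

Food insecurity — not reliably having access to enough safe, nutritious
food — is measured in surveys and clinics with the adult items of the US
Household Food Security Survey Module (HFSSM). The full instrument is too
long for routine clinical use, so practitioners need *brief screeners*:
one or two HFSSM items combined with an OR rule ("flag the patient if
either item is affirmed") whose performance is judged against the full
module. This package implements that measurement-and-derivation pipeline
for researchers evaluating food-insecurity screening, e.g. in antenatal
care:

* **Scoring.** Raw survey answers are coded into ten binary
  "food-insecure condition" indicators (often true / sometimes true and
  yes answers affirm; frequency follow-ups affirm at *some months* or
  more, and honour the skip pattern — items 5 and 10 are asked only when
  items 4 and 9 are affirmed). Severity is classified from the count of
  affirmed conditions *s*:

  | instrument | food secure | marginal | low | very low |
  |---|---|---|---|---|
  | 10-item | s = 0 | 1–2 | 3–5 | ≥ 6 |
  | 6-item (items 2–7) | s = 0 | 1 | 2–4 | 5–6 |
  | 2-item (items 1–2) | s = 0 | — | s ≥ 1 insecure | — |

  plus the single national-survey item ("ran out of food and could not
  buy more"), scored yes/no.

* **Screener evaluation.** Every pair from a candidate item set
  (default items 1–3, the most-affirmed items among the food insecure)
  is applied as an OR-rule screener and cross-tabulated against the
  10-item reference standard (insecure at ≥ 3 affirmed conditions).
  Sensitivity = 100·TP/(TP+FN), specificity = 100·TN/(TN+FP), accuracy =
  100·(TP+TN)/n, overall and within five sociodemographic subgroups.
  `brief_screener()` fits the whole evaluation and recommends the pair
  with the highest accuracy (ties: sensitivity, then lower item numbers).

* **Synthetic respondents.** Because real survey microdata are usually
  confidential, a seeded generator draws a latent severity
  θ = μ + Σ βᵏ·flagᵏ + σε and affirms item *i* with probability
  logistic(a·(θ − bᵢ)) — a two-parameter logistic IRT model whose ordered
  thresholds b₁ < b₃ < b₂ < … < b₉ = b₁₀ reproduce the canonical
  "managed process" severity ordering. `population_diagnostics()` is an
  exact quadrature oracle for any screener's population operating
  characteristics, the recovery target for empirical estimates.

## Worked example

```r
library(hfssm)
d   <- simulate_respondents(generator_config(n = 2000, seed = 11))
fit <- brief_screener(d)
fit
#> Brief food-insecurity screener
#>   n = 2000 respondents; reference: 10-item score >= 3
#>   recommended pair: items 2 + 3 (affirm either)
#>   sensitivity 98.2%, specificity 93.4%, accuracy 93.7%

prevalence_table(d)
#> Food-security prevalence (n = 2000), % of respondents
#>
#>                 single_item two_item six_item ten_item
#> food_secure            94.1     85.3     87.6     82.7
#> food_insecure           5.9     14.8     12.5     17.3
#> marginal                 NA       NA      6.4     11.9
#> low_or_very_low          NA       NA      6.1      5.5
```

Reading the output: 17.3% of these simulated households report at least
one food-insecure condition on the 10-item module (11.9% marginal, 5.5%
low or very low), the 2-item and 6-item short forms flag fewer, and the
single item fewest — the expected nesting, since each short form counts a
subset of the ten conditions. Of the three candidate pairs, items 2 + 3
classify 93.7% of households correctly against the ≥ 3-condition
reference; `summary(fit)` prints the full pair-by-subgroup table and
`predict(fit, newdata)` applies the recommended screener to new
respondents. `read_records()`/`write_records()` move real survey CSVs in
and out of the same pipeline, `run_score()`/`run_evaluate()` write CSV
reports with a manifest accounting for records excluded for missing
answers, and `inst/scripts/hfssm-cli.R` wraps it all for the shell.

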