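# balex

Linguistic markers of **behavioral activation (BA)** in text-based therapy.

Behavioral-activation therapies treat depression by increasing patients'
engagement in meaningful, rewarding activities. Assessing the underlying
construct normally requires standardized questionnaires such as the BADS
(Behavioral Activation for Depression Scale), which burden patients and
providers. In chat-based therapy, however, every word a patient writes is
archived — so activation-related language can be measured directly,
longitudinally, and at no extra cost to the patient.

`balex` is for computational mental-health researchers who want to build and
validate such measures. It provides the full pipeline:

1. **Lexicon construction** — skip-gram-with-negative-sampling (SGNS) word
   embeddings trained on a message corpus; each clinician-curated seed term
   (one list per BADS Activation-subscale item) is expanded with its `k = 30`
   cosine nearest neighbors; expansions are pruned by a versioned blocklist
   and combined into 7 partially overlapping subconstructs (satisfaction,
   breadth, decisions, accomplishment, long-term, effort, structure) plus a
   deduplicated overall *activation* category.
2. **LIWC-style scoring** — for each pooled message document, the percent of
   tokens matching each category: `100 * matches / token_count`, plus the
   composite emotional tone `100 * pos / (pos + neg)` (50 = balanced affect).
3. **Longitudinal analysis** — linking markers to PHQ-9 depression severity:
   severity-band means with percentile-bootstrap CIs; marker-vs-PHQ mixed
   regression with patient random intercepts; a 109-model variable-subset
   grid scored by mixed-model R² and AIC; and per-group
   random-intercept-and-slope trajectory models

   ```
   Y_ij = β₀ + β₁·X_ij + γ₀ᵢ + γ₁ᵢ·X_ij + ε_ij
   ```

   (patient *i*, week *j*; fixed time effects β, per-patient random effects
   γ), with a Wald z comparison of the weekly slopes of improving vs
   nonimproving patient groups.
4. **Synthetic cohorts** — a generator that emits weekly token streams and
   PHQ-9 series with exactly this statistical structure, so the whole
   pipeline is testable without access to private therapy transcripts.

## Worked example

```r
library(balex)
library(dplyr)

cfg    <- cohort_config(n_patients = c(improving = 150, nonimproving = 150))
cohort <- simulate_cohort(cfg, seed = 7)
cohort
#> <ba_cohort> 300 patients, 4500 weekly messages, 1500 PHQ assessments

docs   <- pool_by_week(cohort$messages)
scores <- score_all(docs, dictionary = load_dictionary(),
                    lexicon = generator_lexicon())
scores |> select(patient_id, window_label, token_count, i, tone, activation) |> head(3)
#> # A tibble: 3 × 6
#>   patient_id  window_label token_count     i  tone activation
#>   <chr>              <int>       <int> <dbl> <dbl>      <dbl>
#> 1 P-imp-00001           -3         314  8.28  21.4       3.82
#> 2 P-imp-00001           -2        1036  6.66  53.3       6.47
#> 3 P-imp-00001           -1         711  5.34  43.2       3.23

scored <- inner_join(scores, cohort$truth[, c("patient_id", "group")],
                     by = "patient_id")
fits <- lapply(split(scored, scored$group), fit_trajectory,
               outcome = "activation")
fits$improving
#> <ba_lmm_fit> ML, 2250 obs, 150 groups
#>         term  estimate          se
#>  (Intercept) 3.9236760 0.066604047
#>         week 0.0442175 0.006906567
#> logLik -3393.26  AIC 6798.53  R2m 0.023  R2c 0.374

cmp <- compare_group_slopes(fits$improving, fits$nonimproving)
round(c(difference = cmp$difference, z = cmp$z, p = cmp$p), 4)
#> difference          z          p
#>     0.0399     4.1992     0.0000
```

Reading the output: each weekly document is scored as percent of tokens per
category (`activation = 3.82` means 3.82% of that week's words were
activation-lexicon terms; `tone = 21.4` means negative emotion words
dominated that week). The improving group's fitted trajectory rises by about
0.044 activation percentage points per week (generating value 0.039, within
one standard error), and the difference between the two groups' slopes is
strongly significant (z ≈ 4.2) at this cohort size.

A command-line front end wrapping the same functions ships in
`inst/cli/balex` (subcommands `simulate`, `lexicon`, `score`, `analyze
study1|study2|study3`); every run writes a manifest with its options, seed,
and input checksums.

## Limitations

The bundled category dictionaries are small open fixtures, not the
proprietary LIWC 2015 lists: absolute scores are not comparable to LIWC
output, though relative and longitudinal behavior is. Scoring counts words
and phrases without negation handling. See the methods vignette
(`vignettes/ba-language-markers.Rmd`) for the full model description,
parameter defaults, and design rationale.
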