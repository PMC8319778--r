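---
title: "Measuring behavioral activation in therapy chat text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring behavioral activation in therapy chat text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

The behavioral theory of depression holds that depressed individuals engage
in fewer pleasant, rewarding activities, and that this disengagement is
self-reinforcing. Behavioral-activation (BA) therapies target exactly this
mechanism, so a longitudinal measure of activation is clinically valuable —
but the standard instrument (the BADS Activation subscale) must be filled in
repeatedly by the patient. In asynchronous chat therapy every client message
is archived, which makes an unobtrusive linguistic measure possible: count
how often patients use words related to planning, participating in, and
enjoying activities, and track that rate against depression severity
(PHQ-9, integer 0–27, administered at weeks 0, 3, 6, 9, 12 of a 12-week
course).

`balex` implements that measure end to end. This vignette documents the
models, the tunable parameters and their defaults, the synthetic-data
generator used for validation, and the design decisions that were genuinely
open.

## Tokenization and pooling

A token is a maximal run of Unicode letters/digits with internal apostrophes
and hyphens retained, lowercased; punctuation and whitespace separate
tokens. No stemming is applied — the lexicon-building step captures
inflected surface forms directly, which keeps the dictionary consistent with
the texts being scored. Under these rules a contraction ("don't") is one
token; the tokenizer reproduces the conventional 40-word count on the
package's worked scoring example.

Messages are pooled into analysis documents two ways:

* **By assessment** — for a PHQ-9 taken at the beginning of week *w*, all of
  the patient's messages from weeks *w−2* and *w−1* are concatenated. The
  window is `[w−2, w−1]`, strictly before the assessment week, because the
  questionnaire asks respondents to reflect on the two *previous* weeks.
  Assessments with no messages in the window yield empty, flagged documents
  rather than being dropped, so joins with PHQ stay aligned; analyses then
  exclude `token_count == 0` rows explicitly.
* **By week** — one document per patient-week over study weeks −3..11 (up to
  15 per patient), for trajectory analysis.

## Lexicon construction

Word vectors are trained on the pooled corpus with skip-gram with negative
sampling (SGNS). Defaults: 100 dimensions, context window radius 2,
frequency-subsampling threshold 1e-5, minimum corpus frequency 5, 10
training epochs. The negative-sample count (5) and the initial learning rate
(0.025, linear decay) are the canonical defaults of the algorithm and are
stated here because they affect reproducibility. Training is single-threaded
with a private deterministic RNG, so a fixed seed yields bit-identical
vectors — a property the test suite asserts.

Each seed term from the BADS-derived table (104 seed tokens over the 7
items; 66 unique terms) is expanded with its `k = 30` cosine nearest
neighbors. `k` is a configurable default, not a constant: 30 balances
coverage against manual-review workload. Ties in cosine similarity break
lexicographically so builds are deterministic. Multiword seeds (e.g. "water
coloring") first try an underscore-joined phrase token; failing that, each
constituent word is expanded and the results unioned. Seeds absent from the
vocabulary are skipped with a warning rather than failing the build.

The per-seed expansions are unioned into the 7 subconstruct categories, and
the overall *activation* category is their deduplicated union (so shared
terms such as "goals" are not double counted). Manual pruning is realized as
a versioned plain-text blocklist (one term per line, `#` comments), applied
to every category; the operation is idempotent and its version is recorded
in the lexicon metadata. Seed terms are retained in the final categories.
Lexicons serialize to a LIWC-style `.dic` dialect plus a JSON sidecar
holding per-term provenance (`seed` or `neighbor-of:<seed>`).

## Scoring

A category score is the percent of a document's tokens matching the
category's term set; a matched multiword phrase counts as one match, and a
token consumed by a phrase match does not additionally match the same
category as a single word (longest match wins, scanning left to right).
A 40-token document with 4 matches scores 10%.

The composite emotional tone is `100 * pos / (pos + neg)`, with 50 when both
are zero. The exact published tone standardization is proprietary and
unpublished; this ratio form was chosen because it satisfies every property
the composite is defined by — range [0, 100], 50 at balance, high values
meaning positive words predominate — and the analyses here only use its
relative and longitudinal behavior. Likewise the bundled dictionaries for
the established categories (`i`, `we`, `posemo`, `negemo`, `sadness`,
`body`, `health`, `sexual`, `ingestion`; `biology` is the composite of the
last four) are small open fixtures: absolute scores are *not* comparable to
LIWC 2015 output. Negation is not handled ("did not plan" counts toward
planning); this is a known limitation of word counting, shared with the
measure the package implements.

## Longitudinal models

All mixed models are fitted with `lme4` by **maximum likelihood**, not REML,
so AIC is comparable across fixed-effect structures in the model grid.

* **Severity bands.** PHQ-9 maps to minimal (≤4), mild (5–9), moderate
  (10–14), moderately severe (15–19), severe (≥20); the bands partition
  0–27. Band means are reported with percentile-bootstrap CIs (default
  2,000 resamples, seeded).
* **Marker vs PHQ.** `marker ~ phq9 + (1 | patient)`; the slope is the
  average marker difference per PHQ unit.
* **Variable-subset grid.** PHQ-9 as outcome, patient random intercept,
  predictors from {∅, i, we, tone, i+we+tone, sadness, health, biology,
  sadness+health+biology, all six} × {∅, overall, each of 7 subconstructs,
  all 7, all 7 + overall} minus the empty model: 10 × 11 − 1 = 109 models.
  Both marginal R² (fixed effects over total variance) and conditional R²
  (fixed + random over total) are emitted; reporting defaults to the
  conditional form because variance explained "including the patient effect"
  is the quantity that reaches the high ranges seen in practice, but the
  choice is surfaced rather than hidden. Grid models use a random intercept
  only; non-convergent or singular fits are flagged per model and the run
  continues.
* **Trajectories.** Per group, `Y_ij = β₀ + β₁X_ij + γ₀ᵢ + γ₁ᵢX_ij + ε_ij`
  with week as `X`, i.e. `(1 + week | patient)` with a freely estimated
  intercept–slope covariance. Slopes of two groups are compared with a
  two-sample Wald z on the separately fitted models — matching the per-group
  model formulation — rather than a pooled interaction model; per-group 95%
  Wald CIs are returned for plotting.

Convergence is reported as the optimizer's own status; `lme4`'s post-hoc
gradient checks, which are known to misfire on boundary fits (e.g.
noise-free data where the residual variance collapses), are surfaced as
flags instead of being folded into the convergence verdict.

## The synthetic cohort generator

Because therapy transcripts are private, validation uses simulated cohorts
with the statistical structure the analyses assume. Per patient *i* in group
*g* and week *j* ∈ −3..11:

* target activation percent `μᵢⱼ = β₀ᵍ + β₁ᵍ·j + γ₀ᵢ + γ₁ᵢ·j + εᵢⱼ`,
  clamped to [0, 100]. Group defaults: improving `3.837 + 0.039·j`,
  nonimproving `3.598 + 0.006·j`. Random-effect SDs default to 0.8
  (intercept) and 0.05 (slope), correlation 0, residual SD 0.6 — calibration
  choices putting simulated dispersion on the order of the observed baseline
  SD (≈0.9) of the overall activation score; they are not estimated
  quantities.
* token count for the week ~ negative binomial, mean 770, size 5 (the mean
  matches the average words-per-week of the population being emulated; the
  size parameter adds realistic overdispersion).
* the week's tokens are a multinomial draw whose activation-cell probability
  is `μᵢⱼ/100`; the other categories' probabilities are
  `base + link·(severity − 13)` with the documented default rates, and the
  remainder is neutral filler vocabulary. Emission term sets are made
  **disjoint** (other categories and filler exclude activation terms), which
  is what makes the scored activation percent an unbiased estimator of μᵢⱼ
  and lets the closed loop simulate → pool → score → fit recover the
  generating fixed effects.
* latent severity is `baseline + slopeᵍ·max(j, 0)` with baseline
  ~ N(13.4, 4.9) (matching the emulated population's baseline PHQ mean and
  SD) and group slopes −0.75 (improving) and −0.10 (nonimproving) per week;
  PHQ-9 observations add N(0, 2) noise at the scheduled weeks and are
  rounded and truncated to 0–27. The linkage coefficients for the
  non-activation categories are invented, documented defaults — they exist
  so marker-severity associations are present by construction, not to match
  any reported effect size.

What the generator does **not** emulate: linguistically realistic text
(tokens are category draws plus filler, with no word order), dropout and
missed assessments, therapist messages, and the multi-cluster trajectory
taxonomy (group labels are assigned directly as improving/nonimproving).
Passing closed-loop tests therefore shows the pipeline's statistical
machinery is correct and calibrated — not that the lexicon generalizes to
real clinical language, which requires a real corpus and human review of
the expanded categories.

## Numerical choices and problem sizes

* Nearest-neighbor ranking, expansion, and grid enumeration are fully
  deterministic (lexicographic tie-breaks, stable orderings); every
  stochastic stage takes an explicit seed.
* Clamping μ to [0, 100] introduces negligible bias at the default operating
  point (μ ≈ 3.6–3.9, ≥5 residual SDs from the boundary).
* Empty documents propagate `NA` scores with an `is_empty` flag; they are
  never silently scored 0.
* The test suite validates the closed loop at 250 patients and the
  acceptance script at 2,000 patients per group (weeks −3..11, 770 tokens
  per week), sizes at which the Wald standard errors of the recovered fixed
  effects are small enough to make the recovery check informative while the
  full run stays comfortably desk-scale. Oracle-equivalence checks (brute
  force cosine sorts, per-token scoring scans, OLS limits of mixed fits)
  run on small random instances with fixed seeds.

## Known limitations

Single-round lexicon builds (iterative clinician feedback is supported by
re-running with an updated blocklist or seed table, but no state is carried
between rounds); no negation or syntax awareness; open fixture dictionaries
rather than proprietary category lists; binary trajectory labels only. The
model grid's "all established variables" column is the six-variable set
{i, we, tone, sadness, health, biology}; with the two empty options this
reconstruction yields exactly 109 non-empty models.
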