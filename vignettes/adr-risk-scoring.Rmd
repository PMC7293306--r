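---
title: "Patient-tailored ADR risk scoring: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-tailored ADR risk scoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrisk)
```

## The problem

A patient on several drugs at once faces a combined adverse-drug-reaction
(ADR) burden that no single product label describes. Two public kinds of
evidence speak to it: product-label side-effect frequency tables (how often
each drug elicits each ADR, SIDER-like) and spontaneous-report corpora
(what happened to real patients who developed ADRs, FAERS-like). `adrisk`
combines the two into a per-patient risk profile: a ranked list of the most
clinically relevant candidate ADRs and aggregate probabilities of at least
one severe event.

## The scoring model

All scores are probabilities built from two primitives.

**Frequency score.** For a candidate ADR (a MedDRA-style Preferred Term,
PT) and a drug combination, each drug that lists the PT contributes its
label frequency $f_i$. Treating the drugs as independent Bernoulli trials,
the number of drugs eliciting the ADR is Poisson-binomial, and the score is
the probability of at least one event:

$$\mathrm{Frequency} = 1 - \prod_{i=1}^{n} (1 - f_i).$$

**Severity score.** A severity model (below) predicts, for *this* patient
and *this* ADR, the probability of hospitalization $p_h$ and of death or
life threat $p_m$, should the ADR occur. Under independence these combine
by inclusion–exclusion:

$$\mathrm{Severity} = 1 - (1 - p_h)(1 - p_m).$$

**Per-ADR score and ranking.** The combined score is the product
$\mathrm{Frequency} \times \mathrm{Severity}$ — the probability that the
ADR both appears and leads to a severe event. Only ADRs with severity
$\geq 0.7$ (inclusive; configurable via `scoring_config()`) are considered
clinically relevant; they are ranked by combined score, ties broken
lexicographically by PT (the field convention is unstated, so a
deterministic, reproducible rule was chosen), and truncated to the top 20.

**Aggregates.** Over the passing set $J$, the Total Score is
$1 - \prod_{j \in J}(1 - \mathrm{Score}_j)$: the probability of at least
one severe-ADR event. The same complement-product applied within each
System Organ Class (SOC) yields SOC scores; because every PT belongs to
exactly one SOC, $\prod_\mathrm{SOC}(1 - \mathrm{SOC\ score}) =
1 - \mathrm{Total}$, a conservation law the tests enforce to $10^{-9}$.
The cumulative hospitalization and mortality risks use
$1 - \prod_{j \in J}(1 - \mathrm{Frequency}_j \cdot p_{o,j})$ for outcome
$o$ — the natural outcome-specific analogue of the Total Score. No
published formula exists for this stratification, so the form is isolated
behind `cumulative_outcome_risk()` where it can be swapped; by
construction each term is bounded by the combined score term, so each risk
never exceeds the Total Score.

Products are accumulated smallest-first for numerical stability on long
lists; at these magnitudes double precision needs no log-space arithmetic.

## The severity model

Each training instance is one spontaneous report: scaled age
(`age / 100`), a male indicator, and binary indicators for the report's
drugs, its comorbidities (the canonical six: renal insufficiency, hepatic
insufficiency, diabetes mellitus, hypertension, cardiac failure,
thrombosis risk factors) and its full ADR set, labelled by the report's
hospitalization and death/life-threat flags. At scoring time the query
instance carries a single candidate-ADR bit. (An alternative reading of
the instance construction — one instance per report-ADR pair — is
arithmetically inconsistent with report-level train/test counts, so the
report-level construction is used.)

Each outcome is predicted by an ensemble of five single-hidden-layer
perceptrons (`nnet`), hidden size 40, logistic activation, entropy loss,
at most 500 optimizer iterations and absolute fit tolerance 0.1, the
members differing only by their random seed (weight initialization; a
bootstrap-resampling mode exists behind `ensemble_config(bootstrap=)` but
is off by default, since seed-only variation is the minimal reading of an
"ensemble of five"). The ensemble prediction is the unweighted mean of the
member probabilities — the simplest combination rule, and one that can
never leave the members' range.

Two choices deserve explanation:

* **Weight decay.** `nnet`'s BFGS optimizer will happily drive a 40-unit
  network into overconfident overfit on tens of thousands of reports; the
  reference training setups in this field typically rely on aggressive
  early stopping instead. We regularize explicitly: the default per-instance
  L2 penalty of `1e-3` (total decay `1e-3 * n_train`) was selected from a
  coarse sweep on synthetic corpora as the point where held-out reliability
  slopes sit near 1 while discrimination is unaffected; it is configurable.
* **Class imbalance.** The death/life-threat class is rare. The mortality
  training set is rebalanced by random repetitive oversampling — minority
  rows duplicated uniformly at random until the configured per-class
  targets are met (default: parity with the majority). The hospitalization
  outcome is far less imbalanced and is trained as observed; no class
  weighting is applied, since any particular weighting scheme would be an
  unverifiable guess. Oversampling deliberately trades calibration for
  sensitivity: training at an inflated positive rate shifts the mortality
  ensemble's probabilities upward relative to the true base rate, so its
  hold-out Brier score sits above the Bayes floor and its severity
  contributions are conservative (risk-inflating), while its *ranking* of
  patients — the AUC — still matches the oracle. The calibration-recovery
  requirements are therefore defined on the hospitalization ensemble,
  which is trained on the observed class balance.

Age scaling by 100 and male = 1 are conventions fixed here for
reproducibility; neither has a field standard.

## The synthetic study

Real frequency tables and report corpora are license-encumbered, so the
package ships a generator whose ground truth is fully known.
`simulate_knowledge_base()` draws a drug–ADR table (frequencies
Beta(1.2, 6), right-skewed like label tables, clipped to (0, 1]); each
ADR gets exactly one SOC. `simulate_report_corpus()` then draws reports in
a fixed per-report order (age, gender, drugs, pathologies, ADR firing,
outcomes) from one seeded RNG stream, so corpora are pure functions of
(knowledge base, spec, n). Ages are truncated-normal Normal(60, 15) on
[18, 100]; gender a fair coin; 1–8 drugs per report; pathology prevalence
0.1 each — fixtures representing a plausible elderly polypharmacy
population, not estimates from data. Each candidate (drug, PT) fires
Bernoulli(frequency); reports with no fired ADR are redrawn from the top
(rejection sampling), which keeps the per-drug frequency law interpretable
at the cost of a slight conditioning bias — the frequency-convergence test
is therefore formulated conditionally, using a near-certain anchor ADR.

Outcomes follow logistic models on the same features the classifier sees.
`random_generative_spec()` fixes the study conditions used throughout the
tests and the acceptance script: age coefficient 2.0 per scaled-age unit,
gender 0.3, drug effects N(0, 0.5), pathology effects 0.4, ADR effects
N(0, 0.8), intercepts −1.6 (hospitalization) and −3.6 (mortality). At the
study scale (12 drugs, 20 ADRs, 5 SOCs, 20 000 reports) this yields
roughly 60% hospitalization — spontaneous reports skew severe — a ~20%
mortality minority, and a Bayes ROC AUC near 0.8, the regime reported for
real severity classifiers on spontaneous-report data.

Because the generating model is known, `true_outcome_probability()` is the
Bayes-optimal predictor: its hold-out AUC upper-bounds (to sampling error)
any classifier trained on the same corpus, and its Brier score is the
irreducible noise floor. The recovery tests require the trained
hospitalization ensemble to come within 0.05 AUC and 0.02 Brier of that
oracle, with a 10-bin reliability slope in [0.8, 1.2], on a 20% hold-out
of 20 000 reports — sizes chosen so sampling error is small relative to
those margins while a single-CPU run stays comfortable.

What passing these tests does *not* show: the generator produces clean,
independent, fully observed reports. Real spontaneous-report data carry
duplicate reports, reporting biases, missingness, correlated prescribing
(confounding by indication) and drug–drug interactions — none of which are
emulated, and all of which degrade real-world calibration. Synthetic
recovery demonstrates the pipeline's statistical machinery is sound, not
that any particular fitted model is clinically valid.

## Validation module

`holdout_split()` shuffles once under a seed (no stratification) with test
size `round(n * fraction)`. `classification_metrics()` thresholds at 0.5
by default with `>=` at the cut; precision/recall with empty denominators
are reported `NA` rather than 0 so F1 is never silently deflated.
`roc_auc()` is the Mann–Whitney statistic via midranks (ties count ½),
identical to the trapezoidal ROC area; `brier_score()` the mean squared
error against the 0/1 labels. `reliability_curve()` uses 10 equal-width
bins, right-open except the last, omitting empty bins.

## Degenerate inputs and edge policies

Empty drug sets yield empty profiles (not errors); unknown queried drugs
warn and contribute nothing, so partial knowledge bases remain usable;
frequency tables accept `%`-suffixed percentages (divided by 100);
duplicate (drug, PT) rows merge under a configurable policy, defaulting to
`max` — the conservative worst-case frequency; harmonization maps must be
idempotent (no canonical term may itself be a synonym), making the
operation a fixed point after one application. Name matching is
case-insensitive after trimming, with drugs stored lower-case and terms
sentence-case.

## Known limitations

Dose and treatment duration do not modulate any score; pharmacokinetic
drug–drug interactions are not modelled; the frequency score assumes
independent per-drug causation; the severity ensembles are only as good as
the report corpus they are trained on. The average-frequency provenance of
the knowledge-base table is taken as given — the package does not attempt
to reconstruct it from frequency bounds.
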