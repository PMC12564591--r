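---
title: "Configurational analysis of HIV disclosure and social isolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Configurational analysis of HIV disclosure and social isolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoqca)
```

## The problem

For people living with HIV (PLHIV) in rural communities, disclosing one's
status is a double-edged decision: it can unlock support, or it can invite
rejection, harassment and institutional mistreatment in settings where
anonymity is scarce. With pilot samples of a dozen or two respondents,
regression-style inference is hopeless; the appropriate tools are
case-oriented — composite indices, typologies, and crisp-set Qualitative
Comparative Analysis (csQCA), which asks which *configurations* of binary
conditions consistently co-occur with which outcomes.

This package implements that toolkit end to end, together with a
constraint-satisfaction reconstruction of the 17-respondent pilot dataset
the analysis was designed around, so that every published table cell can be
re-derived from participant-level data without access to the restricted
microdata deposit.

## The measures

**Social Isolation Index.** Fifteen binary exclusion indicators, spanning
seven domains of social life, are summed without weights into a score
$S_i \in \{0,\dots,15\}$. A respondent is classified *isolated* when
$S_i \ge 7$. The cutoff is taken as the constant 7 — it was originally
motivated as "above the sample mean", but the mean itself is not published,
so recomputing it from data would manufacture precision; the constant also
keeps the classification stable across datasets. The same sum, read as a
count of distinct exclusion experiences, is the *cumulative burden* score;
`isolation_score()` is deliberately the single implementation of both.

The full wording of the 15-item instrument is not published. The shipped
`default_catalog()` contains every named item (having no one to turn to,
friends distant after disclosure, LGBT-community belonging, workplace
unfairness, and the five QCA outcome items) and fills the remaining slots
with plausible items so all seven domains are populated. The
LGBT-belonging item is positively worded on the instrument and is stored
already reverse-coded as a burden indicator (1 = exclusion); converting raw
instrument responses is the ingester's responsibility. The catalog is a
YAML-serializable configuration (`read_catalog()`), so the true instrument
can be substituted. Consequences of the stand-in are confined to the
*domain* profiles (`domain_profile()`), whose item-to-domain mapping has no
published ground truth; every tallied analysis depends only on the five
outcome items, which are pinned down.

**Disclosure.** Two measures: `told3plus` (disclosed to three or more
people — the inclusive threshold is a conceptually grounded marker of
support-seeking openness, not a statistical optimum) and
`informed_sex_partners`. Crossing them yields four disclosure groups;
crossing `told3plus` with `isolated` yields the four-quadrant typology
(Adaptive Disclosure, High Exposure, Concealed/Resilient, Hidden
Vulnerability).

**Identity and race conditions.** Sexual identity is recorded as
gay/lesbian, bisexual or straight; `lgb` pools the first two. The truth
tables condition on `lgb`/`straight` as two one-hot columns, and race on
`black`/`white` likewise — mirroring the published condition columns and
allowing the (0,0) race pattern of a respondent of another race. The
subgroup heatmap instead uses `gay_or_lesbian` (excluding bisexual
respondents), so both flags are derived and kept distinct.

## Truth tables

`build_truth_table()` groups respondents by their configuration over 2–5
binary conditions (few conditions, to avoid overfitting a tiny sample) and
tallies each of the five outcomes. A minimum frequency of one keeps every
observed configuration; unobserved configurations (logical remainders) are
never listed, and rows are ordered ascending-lexicographically — the
canonical published order. *Consistency* is the within-configuration
outcome proportion (the quantity printed as a percentage); *coverage* —
the outcome-conditional share of a configuration — goes beyond the
published tables but is standard csQCA practice, and is computed on the
unfiltered tallies so that coverages over observed configurations always
sum to one. Boolean minimization (Quine–McCluskey, prime implicants,
parsimonious solutions) is deliberately out of scope: raw truth tables are
the published product at this sample size.

`identify_consistent()` takes its consistency threshold explicitly; with
17 cases any default would be arbitrary, and rows are returned with their
case counts so 2-of-2 configurations are not over-read.

## Reconstruction by constraint satisfaction

`compile_ledger()` encodes every usable published marginal as a
machine-checkable constraint: n = 17; identity counts 11/2/4 and race
counts 13/3/1; the disclosure joint counts 9/1/7/0; the isolated count 10;
quadrant counts 4/6/3/4; both truth tables in full (case counts and all
five outcome tallies per configuration); and the prose heatmap cells.
Published *rounded means* are encoded as exact integer sums by rounding
inversion — 84, 46 and 3 are the unique integer burden totals consistent
with the printed one-decimal means 9.3, 6.6 and 3.0 at the printed group
sizes — which keeps the whole system integral and avoids floating-point
feasibility questions.

`build_fixture()` solves the ledger in stages, every choice drawn from a
generator seeded by the single `seed` argument:

1. **Demographic skeleton.** All joint identity-by-race assignments
   consistent with both truth tables' case counts are enumerated
   (contingency matrices with fixed margins per disclosure group), and
   bisexual labels are placed among LGB respondents by seeded search.
2. **Outcome bits.** The participant × outcome 0/1 matrix is solved by
   backtracking with constraint propagation: saturated count constraints
   force their remaining cells to a fixpoint before any branching, and a
   derived budget constraint (the bisexual members' outcome total implied
   by the LGB-versus-gay/lesbian tallies) lets impossible placements die in
   propagation rather than search.
3. **Scores and fillers.** Which members are isolated, and each member's
   integer score, are chosen to satisfy the burden sums and the
   isolated/quadrant counts; the ten non-outcome indicators are then
   sampled to realize each score.
4. **Disclosure counts.** Exact `people_told` values are unpublished, so
   they are drawn from {0,1,2} or {3,…,10} compatibly with each
   respondent's flag; the scatterplot's median reference line is therefore
   fixture-dependent and never asserted.

Infeasible ledgers produce an error naming the constraints at the deepest
point the search reached. The solved fixture is re-audited against the
full ledger before it is returned, and `export_ledger_json()` writes the
constraint-by-constraint audit. Note the deliberate division of labour:
the solver consumes the printed *marginals*, while the analysis pipeline
re-derives each cell from the participant-level rows — and every pipeline
computation is additionally cross-checked against brute-force oracles on
random synthetic data it was never fitted to.

The reconstruction matches the published margins, not the true microdata:
individual response patterns beyond what the marginals force (for example,
which specific member of a configuration endorses an outcome) vary with
the seed.

One forced deduction is worth knowing about: combining the identity truth
table with the gay/lesbian heatmap tallies implies the two bisexual
respondents report neither name-calling nor family rejection; the solver
discovers this, it is not hardcoded.

## Known inconsistency in the published robustness summary

The published threshold-robustness summary states that under stricter
thresholds (told ≥ 4, isolation ≥ 8) no respondent falls in the High
Exposure or Hidden Vulnerability quadrants — implying no isolation score
reaches 8. That contradicts the burden means: a group total of 84 over 9
respondents forces several scores of 8 or more. The fixture therefore
satisfies the burden means and both truth tables, the stricter-threshold
claim is excluded from the ledger and from all assertions, and
`run_robustness()` reports what actually happens under the alternate
thresholds (both typologies, both truth tables, consistency deltas, and a
movement list whose directions are checked against threshold
monotonicity).

## The synthetic generator

`generate_random()` draws independent respondents: a disclosure count, a
partner-disclosure flag conditional on disclosure breadth, identity and
race categories, and independent Bernoulli indicators whose prevalence may
differ by a subgroup flag. The defaults mirror the pilot sample's
composition: n = 17; disclosure-count mass 7/17 over 0–2 and 10/17 over
3–10 (uniform within each range); partner disclosure with probability 0.9
given broad disclosure and 0 otherwise; identity probabilities 11/17,
2/17, 4/17; race probabilities 13/17, 3/17, 1/17; and indicator
prevalences 0.58 / 0.44 for broad/narrow disclosers, the observed group
burden rates (84/135 and 46/105).

What it emulates is the *marginal and first-order subgroup structure* the
pipeline consumes. What it does not emulate: correlation between
indicators within a respondent (real exclusion experiences cluster),
respondent-driven sampling dependence, item nonresponse, or any causal
coupling between disclosure and subsequent exclusion. Tests passing on
this generator therefore certify the bookkeeping — tallies, groupings,
truth-table algebra — on data with known structure, not substantive
conclusions about real populations.

## Numerical conventions and degenerate inputs

* All thresholds are inclusive (≥), matching "three or more" and
  "7 or higher".
* Percentages and means are rounded half away from zero
  (`round_half_up()`), whole percents in heatmap prose, one decimal in
  tables; unrounded values are retained in every returned object.
* Empty input to `typology_table()` and empty groups in
  `domain_profile()` are errors (undefined percentages); empty heatmap
  subgroups are returned flagged with n = 0 and `NA` percents; an empty
  disclosure group appears with n = 0 and no mean.
* Coverage for a never-observed outcome is an error, not 0/0.
* Scatter jitter is uniform ±0.15 on both axes from a dedicated seed; the
  published figure says only "random jitter", so a fixed dialect was
  chosen for reproducibility.
* Missing data are not modeled anywhere: the published analyses are
  complete-case, and any `NA` fails validation loudly.

## Problem sizes in the test suite

The property-based suites run each tabulation against independent
loop-and-count oracles on 200 seeded random datasets of up to 50
respondents, check threshold monotonicity on dozens more, verify CSV
round-trip identity, and check generator prevalence recovery within 99%
binomial intervals at n = 2000 — sizes chosen so the full suite exercises
every code path in a couple of minutes on a single core while keeping the
binomial checks sharp. The fixture perturbation scan flips each of the
17 × 15 indicator bits and confirms every flip violates at least one
ledger constraint (any flip perturbs its group's burden sum, and outcome
flips additionally break truth-table tallies).

## Limitations

* The indicator instrument is a documented stand-in; domain profiles have
  no published ground truth.
* The fixture reproduces printed marginals, not the deposited microdata;
  seeds change the unconstrained details.
* csQCA output here is descriptive — consistencies over subgroups of
  1–7 cases are hypothesis-generating, and the package deliberately
  reports case counts beside every proportion to keep that visible.
* No survey weighting, item-response modeling, or recruitment-network
  (RDS) structure is modeled.
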