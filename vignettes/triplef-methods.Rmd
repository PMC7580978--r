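---
title: "Methods: the triple-F algorithm, its statistics, and the synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the triple-F algorithm, its statistics, and the synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplef)
```

## Scope and model

`triplef` operationalizes a bedside decision problem: an ED patient has a
pathological urinalysis — is this asymptomatic bacteriuria (ABU), localized
urocystitis, or a urinary tract infection with systemic involvement (SUTI)
that needs systemic antimicrobials and source control? The package encodes
the decision as a deterministic rule cascade over raw encounter fields, so
every classification is reproducible and carries a rule trace
(`classify_encounter()$rationale`).

The pipeline has four stages:

1. **Inclusion filter.** Quantitative urine cultures are *significant* at
   ≥ `cfu_threshold` (default 10^3 CFU/mL) of a uropathogen in pure culture
   or mixed culture of ≤ 2 pathogenic species. Cultures with no growth,
   flora only, > 2 pathogens, or all pathogens below threshold are excluded
   (sterile/contaminated), mirroring the screening flow of a paired
   urine/blood-culture cohort.
2. **Blood-culture adjudication.** Organisms other than
   coagulase-negative staphylococci and viridans streptococci count as true
   bacteraemia from one positive set. The review groups require ≥ 2
   positive sets, or ≥ 1 set plus an intravascular device. The published
   procedure was a case-by-case review listing exactly these factors
   (positive-set count, devices, focus, risk factors); we codified it as
   this explicit rule so it is testable, and left the set count
   configurable (`review_min_sets`).
3. **Accordance.** A true bacteraemia is *accordant* when a blood organism
   matches a significant urine organism (species-level string match after
   normalization; methicillin resistance does not affect matching),
   *discordant* otherwise. In mixed bacteriuria the blood culture
   identifies the dominant uropathogen; with two matches the higher-CFU
   urine isolate is reported (a tie-break the data rarely exercises).
4. **Classification.** With F1 (fever), F2 (organ dysfunction), F3
   (genitourinary symptoms), *systemic features* := F1 ∨ F2 ∨
   PCT ≥ 0.25 ng/mL, and *alternative focus* := documented non-urinary
   focus ∨ discordant bacteraemia, the rules fire in fixed precedence:

   | order | condition | category |
   |---|---|---|
   | R1 | *S. aureus* bacteraemia + *S. aureus* bacteriuria | SA_ALT_FOCUS |
   | R2 | accordant bacteraemia | BACTEREMIC_SUTI |
   | R3 | F3 ∧ systemic ∧ ¬focus | PROBABLE_SUTI |
   | R4 | (F3 ∧ systemic ∧ focus) ∨ (¬F3 ∧ systemic ∧ ¬focus) | POSSIBLE_SUTI |
   | R5 | lower-tract symptoms only ∧ ¬systemic | UROCYSTITIS |
   | R6 | otherwise | ABU |

   The precedence resolves cases the prose definitions leave implicit: an
   accordant *S. aureus* bacteraemia is a disseminated infection
   (SA_ALT_FOCUS), not bacteremic SUTI; febrile patients whose systemic
   reaction is fully attributed to a documented focus (¬F3 ∧ systemic ∧
   focus) land in ABU, which is how febrile ABU arises; and the cell
   "lower-tract symptoms, no systemic features, focus present" is
   urocystitis (R5 ignores the focus) because urocystitis is defined purely
   by local symptoms and absent systemic involvement. These choices are
   verified by an exhaustive enumeration test over all feature
   combinations.

**Assumptions.** Fever, organ dysfunction and symptoms are documented
flags, not measurements (an optional triage temperature is accepted and
thresholded at `fever_temp_threshold_c` = 38.0 °C, a conventional cut the
source material does not state). PCT is always available (it is an
inclusion criterion) and is treated in ng/mL ≡ µg/L throughout; 0.25 ng/mL
is the established clinical threshold. PCT ≥ 0.25 alone (with F-score 0)
counts as systemic involvement: such patients never reach blood cultures
under the workup rule, but the choice matters when classifying
retrospective data, and we opt to let the laboratory signal qualify.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `cfu_threshold` | 1000 | CFU/mL | urine significance |
| `pct_cutoff_ng_ml` | 0.25 | ng/mL | systemic features, workup rule, accuracy tables |
| `fever_temp_threshold_c` | 38.0 | °C | optional temperature-based F1 |
| `review_min_sets` | 2 | sets | contaminant adjudication |
| `ci_level`, `ci_method` | 0.95, Clopper–Pearson | — | interval estimates |

## Statistics

Sensitivity, specificity, PPV and NPV are simple binomial proportions of
the 2×2 cross; intervals are Clopper–Pearson exact by default (computed
from beta quantiles), with Wilson as an alternative. Exact intervals
reproduce the printed interval widths of the published accuracy table,
which is why they are the default. A zero denominator renders that metric
`NA` and leaves the others intact. Youden's J = sens + spec − 1;
`select_youden_cutoff()` scans every distinct observed marker value plus
+∞ under the rule "positive iff marker ≥ threshold" and breaks ties toward
the smallest threshold (a 1e-12 tolerance guards the comparison against
floating-point noise). Cohen's kappa uses the marginal-product expected
agreement with the large-sample standard error; degenerate marginals
(expected agreement 1) yield `NA`. Computed from the published 2×2 counts
the kappas are 0.250 (any bacteraemia) and 0.223 (accordant) — the source
table prints 0.22/0.25 in the opposite column order, an apparent
transposition, and this package reports the computed values.

## The fixture cohort

`build_fixture_cohort()` produces one admissible 403-record cohort whose
raw fields push the pipeline to reproduce, exactly, every hard constraint
in `default_constraints()`: the 403 → 138 sterile + 82 contaminated → 183
analyzable flow, the diagnosis partition 44/26/51/1/56/5, the criterion
marginals F1 = 140, F2 = 115, F3 = 54, score-0 = 14, the PCT bins
(53 below 0.25 ng/mL, 34 below 0.1, 6 of the score-0 group below 0.25),
the bacteraemia counts 65/49/16 with 6 bacteraemic and 2 accordant cases
below the PCT cutoff, 24/44 bacteremic cases without genitourinary
symptoms, 94 *E. coli* bacteriurias, 32 mixed cultures and 91 women. The
builder writes no derived labels — the checker (`check_constraints()`,
counting code independent of the builder) re-derives everything through
the pipeline.

A handful of published cells cannot all hold simultaneously under the rule
semantics, and these are *soft* constraints with notes in the ledger:

- probable SUTI requires genitourinary symptoms, so its F3 joint is 26,
  not the printed 25; the F3 marginal of 54 then caps the F3-positive
  possible-SUTI group at 6 (printed: 7);
- a possible-SUTI encounter can only carry an alternative focus via rule
  R4's first arm, which requires F3 — so at most 6 of the 51 can have a
  focus, not the printed 20;
- an ABU encounter without any focus can never show systemic features
  (rule R4's second arm would fire), so the focus-free ABU group is capped
  at the 6 score-0, low-PCT encounters, not the printed 14.

Every headline quantity (category totals and the derived percentages, the
accuracy tables, the stewardship eligibility fractions 56/183 and 107/183)
is invariant to these within-category splits and is reproduced exactly.
Documented focus labels (pneumonia, port infection, SSTI, influenza) are
assigned within ABU, approximating the published label distribution;
discordant-bacteraemia and *S. aureus* encounters derive their focus from
the blood culture itself.

The seed only shuffles record order (and is restored after use); the
aggregates are identical for every seed, which the test suite asserts.

## The stochastic generator

`sample_cohort()` draws independent encounters from a latent
diagnosis-type category with the published prevalences, then conditional
Bernoulli criterion indicators (rates from the published
category-by-criterion cross), urine organisms from a frequency table,
bacteraemia with per-organism accordance probabilities (0.853 *E. coli*,
0.60 *P. mirabilis*, 0.50 *K. pneumoniae* and *P. aeruginosa*, 0.167
*E. faecalis*, 0 *E. faecium*), documented foci, and a PCT log-normal
mixture by bacteraemia status. The mixture components were calibrated once
from the printed dichotomized fractions: bacteraemic meanlog log(0.95)
and sdlog 1 (≈ 9% below 0.25 ng/mL, matching 6/65), non-bacteraemic
meanlog −0.601 and sdlog 3.04 (matching the fractions below 0.25 and 0.1
ng/mL). Bacteraemic draws receive pure single-organism urine cultures so
that the per-organism accordance parameter coincides exactly with the
estimand of `organism_accordance_table()`; mixed two-pathogen cultures
(rate 0.175) occur among non-bacteraemic draws only.

What the generator emulates: the marginal and conditional rates the
analysis consumes. What it does not: within-patient correlation beyond the
latent category, comorbidity and catheterization structure, time-to-result
dynamics, laboratory measurement error, or any susceptibility data beyond
the MRSA flag. Passing parameter-recovery tests therefore shows the
pipeline's estimators are consistent for the generative rates — not that
the algorithm would achieve the published accuracy on new clinical data.

## Degenerate inputs and errors

Zero blood-culture sets, accordance on non-significant urine, single-class
labels in cutoff selection, and empty 2×2 tables raise errors; unknown
organism names are demoted to flora with a warning at classification time
and rejected with the record id at file-reading time; under-age records
are read but flagged. An empty analyzable cohort yields an explicit
"no analyzable encounters" report rather than an error.

## Problem sizes

The test suite runs the 403-record fixture end to end, exhaustive rule
enumerations (48 feature combinations), 45 randomized Youden/kappa
instances at n ≤ 200, and parameter recovery on one sampled cohort of
n = 5000 at 3-binomial-SE tolerance (plus a 1500-draw smoke check); these
sizes make the conditional-rate standard errors small enough for the
3-SE bands to be informative while keeping the whole suite around a
minute of runtime.

## Limitations

The fixture is one admissible cohort consistent with the published
aggregates, not a reconstruction of the study's patients; per-organism
accordance percentages and the MSSA/MRSA breakdown are generator
parameters, not fixture invariants. The Youden-optimal cutoffs of the
original analysis (0.25/0.95 ng/mL) depend on patient-level PCT values
that were never published, so the package ships the selection *algorithm*
(tested against brute force) rather than asserting those cutoffs. No
treatment recommendations beyond the workup/threshold outputs, no sepsis
severity scoring, no susceptibility interpretation, and no cost or outcome
modelling are attempted.
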