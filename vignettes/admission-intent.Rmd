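---
title: "Classifying childhood-cancer admissions by indication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying childhood-cancer admissions by indication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admitintent)
```

## The problem

Children with cancer are admitted to hospital for very different reasons —
to receive scheduled chemotherapy, to undergo a tumour-directed procedure,
to treat an infection, or to manage a non-infectious toxicity of the disease
or its therapy — and the reason for admission is a major driver of resource
use. Administrative discharge datasets such as the Kids' Inpatient Database
(KID) record each admission only as ordered lists of ICD-9-CM billing codes,
so the reason for admission has to be inferred. `admitintent` implements a
stepwise, mutually exclusive classification of cancer-related admissions
into those four indications plus an UNDEFINED remainder, together with the
validation arithmetic (PPV, sensitivity, Wald intervals) and utilization
summaries that make the classification auditable.

## The model and its assumptions

Raw ICD-9 codes (~12,000 diagnoses, ~3,500 procedures) are first collapsed
with HCUP's Clinical Classifications Software (CCS) into 260 diagnostic and
231 procedure groups, and those groups into a handful of clinical
categories. The classifier rests on two assumptions:

1. **A cancer or cytopenia diagnosis is not a reason for admission.**
   Cancer is a chronic condition, and uncomplicated cytopenias (neutropenia,
   anemia, thrombocytopenia) are managed as outpatients.
2. **When the primary diagnosis is one of those insufficient codes, the
   secondary diagnosis substitutes for it.** Only diagnosis slot 2 is
   consulted; later slots carry comorbidities in no particular order.

The cascade, first match wins:

| Step | Intent | Trigger |
|---|---|---|
| 1 | CHEMO | chemotherapy procedure (CCS proc group 224) on day 0–2, or — when the record carries no usable procedure days — chemotherapy as the primary procedure |
| 2 | PROCEDURE | cancer-directed procedure on day 0–2 |
| 3 | INFECTION | infection as primary dx, or as secondary behind a malignancy / chemotherapy-encounter / cytopenia primary |
| 4 | TOXICITY | same lookup for non-infectious toxicity (cytopenias included) |
| 5 | UNDEFINED | everything else |

Chemotherapy precedes procedures so that minor procedures done before, but
not delaying, chemotherapy (line placements, lumbar punctures) stay
chemotherapy admissions. Infection precedes toxicity so that "cytopenia +
infection" resolves to infection.

The cancer cohort itself is any admission with a malignancy code (CCS
diagnostic groups 11–43) in **any** diagnosis slot. Group 44 (neoplasms of
uncertain behaviour, dominated by benign lesions) and group 45 alone
(maintenance chemotherapy, which also occurs for non-malignant disease)
never qualify.

## Design choices where the design was open

* **"First 2 days" means procedure day ∈ {0, 1, 2}** (day 0 = admission
  day); `window_last_day` is an argument everywhere it matters.
* **The secondary-substitution trigger set is {malignancy, chemotherapy
  encounter, cytopenia}.** A chemotherapy-encounter primary must be
  substitutable: admissions admitted for chemotherapy but coded with an
  infection secondary do occur and belong to infection when no chemotherapy
  was actually delivered in the window.
* **Negative procedure days qualify for nothing.** A negative day is a
  corrupt date; the record keeps going through the cascade and is flagged
  (`negative_day_flag`) so a reviewer can treat the eventual label as
  suspect. A negative day also counts as a *recorded* day, so it blocks the
  missing-date rescue.
* **The missing-date rescue applies to chemotherapy only.** Chemotherapy is
  one CCS procedure group, so "primary procedure = chemotherapy" is a safe
  dateless proxy; the analogous rescue over a thousand-odd procedure codes
  would be imprecise, so states that omit procedure days under-ascertain
  procedure admissions by design.
* **Evidence tie-break**: earliest qualifying day, then lowest slot index.
* **CCS group 237** ("complication of device, implant or graft") mixes
  infectious and non-infectious codes; it is split at the ICD-9 level
  (999.31, 996.62, 996.67, 996.69 → infection; all others → toxicity).
* **Unassigned CCS groups default to OTHER with a warning** when a scheme
  config is loaded. OTHER never triggers anything, so an incomplete config
  pushes admissions toward UNDEFINED rather than mislabelling them.
* The full consensus table mapping all 491 CCS groups to categories is a
  clinical product that ships with licensed data; the bundled map
  (`ccs_map_synthetic.csv`) and default scheme are a partial reconstruction
  of its stated rules, sufficient for the bundled code vocabulary. Users
  with the full table supply it via `read_ccs_map()` and a YAML scheme.

## Validation arithmetic

A chart review of assigned admissions yields, per intent, the number
reviewed (`tp + fp`) and — where misassignment was tallied — false
negatives. `ppv()`, `sensitivity()` and `asymptotic_ci()` turn these into
the usual accuracy statistics. With review denominators in the tens of
thousands, the simple asymptotic (Wald) interval
$p \pm z_{0.975}\sqrt{p(1-p)/n}$ is appropriate; it degenerates to zero
width at $p \in \{0, 1\}$, and a Wilson interval is available
(`method = "wilson"`) for small-sample use. Percentages are conventionally
reported rounded to one decimal.

```{r tallies}
validation_report(published_review_tallies(), percent = TRUE)
```

`confusion_matrix()` produces the same tallies from synthetic ground truth,
which is how the test-suite exercises the whole path without restricted
data.

## Utilization measures

Costs are estimated as `charge × cost-to-charge ratio × CPI factor`, in
2009 US dollars (bundled factors 1.166 / 1.064 / 1.0 for 2003 / 2006 / 2009,
from All-Urban CPI annual averages). Cost per day divides by
`max(LOS, 1)` so same-day discharges stay defined. HCT is flagged by CCS
procedure group 64 (ICD-9 41.xx), ICU-level illness by diagnosis groups 131
(respiratory arrest/failure), 107 (cardiac arrest) and 249 (shock).
Admissions with uncomputable cost are excluded from cost means only, never
from LOS or event rates. `anova_oneway()` compares intents with a classical
one-way F test; degenerate inputs resolve explicitly (no between-group
variance → F = 0, p = 1; separated groups with zero within-group variance →
an epsilon-guarded large finite F). Costs are analysed raw by default;
`log_transform = TRUE` analyses `log(x + 1)` for right-skewed costs.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces wide KID-like records (25 diagnosis slots, 15
procedure slots with day integers, LOS, charges, death flag, demographics)
whose codes are real ICD-9 codes assembled so that the rule trace recovers
the ground-truth label whenever no noise interferes. Defaults are fixed at
the study conditions: intent mixture 36/15/14/20/10% plus a 5% non-cancer
admixture (the reported 38/15/15/21/10% cohort shares rescaled to leave
room for non-cancer records), 14.1% of records from states omitting
procedure days, 0.3% of dated chemotherapy days corrupted negative,
chemotherapy delivered on days 0/1/2 with probabilities 0.78/0.16/0.06, and
dataset years 2003/2006/2009 in shares 30.9/32.7/36.4%. Length of stay and
charges are log-normal per intent with medians of a few days and tens of
thousands of dollars — realistic scales chosen once, since the source
figures' absolute dollar values cannot be reproduced without the restricted
files.

What passing tests on this generator show: the classifier implements the
stated rules exactly (oracle agreement), recovers designed labels perfectly
without noise, and degrades in the predicted, *targeted* way (missing
procedure days hurt procedure recall only). What they do not show: accuracy
on real claims, where coding practice, the full ICD-9 vocabulary, and the
complete CCS category table introduce error sources the generator does not
model. The published review tallies are the evidence on real data; the
synthetic results are evidence about the implementation.

## Problem sizes and numerics

The bundled checks run at desk scale, chosen as the package's own test
conditions: label recovery on 4,000-record cohorts, oracle agreement on
10,000 records, ANOVA calibration over 1,000 null simulations of four
groups of 25. The classifier is O(records × code slots); a 10,000-record
cohort classifies in seconds. All randomness flows from a single integer
seed; `z` is fixed at `qnorm(0.975)` ≈ 1.95996 for 95% intervals.

## Known limitations

* Admissions are the unit of analysis; patients are de-identified, so
  repeat admissions cannot be linked and no per-patient statistics exist.
* The bundled CCS map covers the generator's vocabulary, not the full ICD-9
  space; real-data use requires the licensed CCS tables.
* Survey weights for national estimates are out of scope, as is ICD-10.
* The infection/toxicity group sets beyond those pinned by the published
  rules (the 237 split, cytopenias 59/60/62–64, fever 246, shock 249) are a
  reconstruction; users can override any assignment via the YAML scheme.
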