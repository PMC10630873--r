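---
title: "Quantitative difference scoring of paired laboratory panels: model and design notes"
author: "qdscore maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QD scoring: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdscore)
```

## The problem

In acute-on-chronic liver failure (ACLF), treatment response is judged from
panels of laboratory indicators measured before and after an intervention
(here, an extracorporeal artificial-liver procedure vs conventional care).
A p-value on each indicator says whether a change is detectable, not how
large it is, and static severity scores such as MELD summarize one time
point, not a trajectory. The quantitative difference (QD) algorithm
scores the pre/post *change* of each indicator and composes the
per-indicator scores into one efficacy number per patient; higher is
better.

## The model

**Ratio response.** Following the Weber–Fechner view that perceived change
scales with the logarithm of a stimulus ratio, the magnitude of a change
is measured by the *golden logarithm*

$$L_\tau = \frac{\ln\!\big(\max(x_{pre}, x_{post}) / \min(x_{pre}, x_{post})\big)}{\ln \varphi},
\qquad \varphi = \tfrac{1+\sqrt5}{2},$$

a unit-free, symmetric, scale-invariant quantity. The base is the golden
ratio; note $\ln(1/\tau) = \ln\varphi$ for $\tau = (\sqrt5-1)/2$, so the
two natural readings of a "golden-section base" coincide numerically.
`goldenLog()` implements it.

**Per-indicator components.** Each indicator contributes a product of
three integers:

* **A** (`directionScore`): $+1$ if the value fell, $-1$ if it rose.
  An exact tie yields $0$ (the source defines only the strict branches; a
  tied indicator then contributes nothing, which is the conservative
  reading).
* **B** (`magnitudeScore`): $L_\tau$ bucketed against a threshold scheme.
  The default molecular scheme uses cuts $0.80 / 1.22 / 1.69$
  (health / subhealth / disease), lower-inclusive exactly as printed:
  $L_\tau \le 0.80 \to 0$, $\le 1.22 \to 1$, $\le 1.69 \to 2$,
  $> 1.69 \to 3$. Alternative published schemes (cellular/molecular
  0.80/1.22, organ/tissue 0.47/0.80, body 0.27/0.47) are selectable via
  `thresholdScheme()`; all Results-level significance statements in the
  source use the three-cut molecular scheme, hence the default.
* **C** (`normalRangeScore`): whether the change moves the value toward
  the reference interval. The flowchart defining this step is not
  recoverable from the source text, so the package uses the minimal
  faithful reading: the *relative distance* of a value to the interval is
  0 inside and, outside, the distance to the nearer bound divided by that
  bound; C is $+1$ when the post distance is smaller or both are 0, $-1$
  when larger, $0$ when equal and non-zero. The rule handles values that
  overshoot the interval; it is isolated in one function so alternatives
  can be swapped. Whether C can be 0 is our choice — the tie case is not
  specified at the source.

**The liver modification.** Four liver-function indicators — alanine
aminotransferase, aspartate aminotransferase, total bilirubin, conjugated
bilirubin — enter the total only through a gated modification
(`liverModification`): gate **D** opens when all four A values are $+1$,
gate **E** when $\sum B \ge 9$ (boundary inclusive, "at least three
indicators changed at top magnitude"). The source states the modification
is *added* but never prints its formula; the package's default is

$$\text{liver contribution} = D \cdot E \cdot \sum_{4\ \text{liver}} A\,B\,C ,$$

which makes non-responding panels (gates closed) contribute exactly 0,
matching the source narrative that non-survivors had only two reduced
liver markers. Two alternatives ship behind the `rule` argument: a flat
bonus $D\cdot E\cdot k$ (default $k = 12$, the maximum attainable gated
sum) and the ungated sum plus that bonus.

**Composite.** `scorePatient()`/`scoreCohort()` return
$\text{QD} = \sum_{\text{non-liver}} A\,B\,C + \text{liver contribution}$.

**A deliberate oddity.** The literal $A\times B\times C$ algebra lets a
*worsening* indicator score positive through a double negative ($A=-1$
moving away from range gives $C=-1$). The package keeps the algebra as
stated, and `perIndicatorScores()` exposes all components so the effect
is auditable.

**Missing data** are never imputed: an indicator missing either value is
skipped, contributes 0 and is flagged; a patient with an incomplete liver
panel gets contribution 0 with gates marked `NA` and a warning.

## MELD comparator

`meldScore()` implements the original formula
$9.57\ln(\text{creatinine}) + 3.78\ln(\text{bilirubin}) +
11.2\ln(\text{INR}) + 6.43$ (mg/dL). Inputs are floored at 1.0 by
default — the standard convention, since logs of sub-unity labs would
subtract points — and the floor is switchable; no creatinine cap or
dialysis override is applied because only the printed formula is in
scope. Panels tabulated in µmol/L are converted with the standard molar
factors (creatinine ÷ 88.4, bilirubin ÷ 17.1, `normalizeUnits()`);
`meldFromPanel()` draws the three inputs from the cohort's own indicator
panel rather than duplicate columns, so the conversion path is a single
auditable step.

## What the synthetic generator emulates — and what it does not

No patient-level data were deposited, so `simulateCohort()` generates
cohorts with the *statistical shape* the analysis assumes:

* **Pre-treatment marginals** are log-normal, moment-matched to the
  published per-arm group means/SDs of the 21-indicator panel (shipped as
  the editable `cohort_baselines.csv`). Log-normality is the standard
  choice for positive, right-skewed labs — the source transaminase SDs
  exceed their means, which a Gaussian cannot produce without negative
  values.
* **Treatment effects** are multiplicative:
  $x_{post} = x_{pre}\cdot m \cdot e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma^2)$. Built-in profiles take $m$ from the
  published post/pre group-mean ratios of each arm
  (`"dpmas_responder"`, `"conventional"`); `"non_responder"` is a
  constructed deteriorating profile (bilirubins ×1.30, transaminases
  ×0.60/0.80, everything else unchanged) satisfying the stated
  constraint that its bilirubin multipliers are ≥ 1. The dispersion
  $\sigma = 0.30$ (log scale) for every indicator was chosen once as a
  realistic acute-phase between-patient ratio spread and is not tuned.
* **Outcome labels** follow the two arms' published counts
  (10/4/1 of 15 recovered/dropped-out/died; 2/7/3 of 12); clinical-status
  flags (fatigue, abdominal distension, anorexia, jaundice, lower-limb
  oedema) are drawn independently with a per-profile improvement
  probability (0.65 / 0.45 / 0.20) and a 10% absence rate.
* **Randomness** is a per-patient sub-stream derived from the cohort seed
  and the patient index, so a cohort is byte-reproducible and enlarging
  it never reshuffles existing patients.

Not emulated: inter-indicator correlation (the source publishes no
covariance; indicators are independent), longitudinal trajectories,
dropout mechanisms, or any link between the simulated labs and the drawn
outcome labels. A green separation test therefore establishes that the
scoring pipeline ranks a strongly responding effect profile above a
deteriorating one — it does not validate the clinical claims, nor can any
test here reproduce the source's cohort-level numbers.

## Group-level aggregation ambiguity

The published per-group "QD value" column is ambiguous: taking the golden
log of the two group means reproduces some printed values closely
(hemoglobin ratio 1.256 → 0.474 vs printed 0.502) but not others (alanine
aminotransferase 5.43 vs printed 3.480, consistent with a *mean of
per-patient* $L_\tau$ instead). Without patient data this cannot be
resolved, so `groupQDValue()` and `comparisonTable()` report **both**
aggregations and assert neither.

## Statistical choices

The source reports mean (SD) with p-values but never names its tests.
Defaults: paired t (pre vs post within arm), Welch t (two-group
contrasts), Pearson correlation with an OLS line for the QD–MELD
association; Wilcoxon/Mann–Whitney variants are one argument away. No
multiple-testing correction is applied by default (none is applied at the
source across the 21 indicators); `adjust = "BH"` enables
Benjamini–Hochberg. Outcome and clinical-flag contrasts pool patients
across arms, because the published flag counts (e.g. fatigue 10 + 8 = 18)
exceed either arm alone. Degenerate cases are flagged rather than
errored: all-zero paired differences report p = 1 with
`degenerate = TRUE`; zero-variance scores make the correlation undefined.

## Numerical and interface notes

* Boundary semantics are exact (`<=` on the printed cuts); no epsilon
  fuzzing anywhere.
* Non-positive or non-finite laboratory values are rejected with the
  indicator named, never clamped; the generator guarantees positivity.
* Reference intervals ship as an editable CSV of standard adult values
  (the source prints none); registries are validated at load time — an
  indicator with no usable bound is a configuration error there, not
  during scoring.
* Cohort I/O is a comma-separated UTF-8 long table
  (one row per patient × indicator) with decimal points only; it
  round-trips losslessly to 15 significant digits.
* A thin command-line front end (`inst/scripts/qd.R`, subcommands
  `simulate` / `score` / `compare`) wraps the exported functions and
  echoes every setting in effect as `key=value` lines on stderr. The
  figure-producing `report` subcommand was left out: each figure is a
  one-liner from the returned tables.

## Worked example

```{r example, eval = FALSE}
dpmas <- simulateCohort(15, effectProfile("dpmas_responder"), seed = 1)
conv  <- simulateCohort(12, effectProfile("conventional"), seed = 2)
cohort <- cbind(dpmas, conv)

scores <- scoreCohort(cohort)
patientScores(scores)          # QD total, gates, MELD per patient
comparisonTable(cohort)        # per-indicator two-arm table
qdMeldAssociation(scores)      # Pearson r + OLS line
outcomeContrast(cohort, scores)
```

## Known limitations

The C-value construction and the liver combination rule are documented
reconstructions of steps the source describes only in prose or in
illegible figures; both are isolated behind single functions with
alternatives exposed. The double-negative product behaviour is inherited
from the stated algebra. Synthetic cohorts share none of the real
cohort's correlation structure, and none of the published cohort-level
table values are (or can be) reproduced.
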