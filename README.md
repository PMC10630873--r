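# qdscore

Quantitative difference (QD) scoring of paired pre/post-treatment clinical
laboratory panels, with the MELD score as comparator, a seeded synthetic
cohort generator, and cohort-level comparison statistics. The package is
aimed at biostatisticians and hepatology researchers who want to evaluate
therapeutic efficacy — the motivating application is artificial-liver
support in acute-on-chronic liver failure — from the *trajectory* of a
laboratory panel rather than a single-time-point severity score.

## The score

For each indicator with pre/post values \(x_{pre}, x_{post} > 0\):

- **A** (direction): \(+1\) if the value fell, \(-1\) if it rose, 0 on a tie.
- **B** (magnitude): the golden logarithm
  \(L_\tau = \ln\!\big(\max(x_{pre},x_{post})/\min(x_{pre},x_{post})\big)/\ln\varphi\),
  \(\varphi=(1+\sqrt5)/2\), bucketed against lower-inclusive cuts
  0.80 / 1.22 / 1.69 → B ∈ {0,1,2,3}.
- **C** (reference-interval correction): \(+1\) if the value moved toward
  (or stayed inside) its reference interval by relative distance, \(-1\)
  if away, 0 on equal distances.

The four liver-function indicators (ALT, AST, total and conjugated
bilirubin) enter only through a gated modification:
D = 1 iff all four decreased, E = 1 iff their summed B ≥ 9, and the liver
contribution is \(D \cdot E \cdot \sum_4 A B C\). The patient's QD total is
the sum of the non-liver \(A B C\) products plus that contribution; higher
means better therapeutic efficacy. The comparator
MELD = 9.57 ln(creatinine) + 3.78 ln(bilirubin) + 11.2 ln(INR) + 6.43
(mg/dL, inputs floored at 1.0 by convention).

See `vignettes/qd-scoring-methods.Rmd` for the model, assumptions, the
reconstructed steps and their alternatives, and the generator's stated
world.

## Worked example

```r
library(qdscore)

dpmas <- simulateCohort(15, effectProfile("dpmas_responder"), seed = 1)
conv  <- simulateCohort(12, effectProfile("conventional"),   seed = 2)
cohort <- cbind(dpmas, conv)          # QDExperiment: 21 indicators x 27 patients

scores <- scoreCohort(cohort)
scores
#> QDScores: 27 patients, 567 scored indicator pairs (scheme 'molecular_beta', liver rule 'gated')
#> qd_total: mean 5.67, range [-3, 19]

head(as.data.frame(patientScores(scores)), 4)
#>   patient_id   arm     outcome d_gate e_gate liver_contribution non_liver_sum qd_total     meld
#> 1  dpmas_001 dpmas   recovered      1      1                  9            -1        8 19.99547
#> 2  dpmas_002 dpmas        died      1      1                 10             0       10 17.21838
#> 3  dpmas_003 dpmas   recovered      1      0                  0            -2       -2 24.43519
#> 4  dpmas_004 dpmas dropped_out      1      1                  9             3       12 15.07386
```

Each row is one patient: the D/E gates show whether the liver panel
qualified for its modification (patient 3's summed B stayed below 9, so
its liver contribution is 0), `qd_total` is the composite efficacy score,
and `meld` is the comparator computed from the panel's post-treatment
creatinine, total bilirubin and INR. Cohort-level views mirror the usual
reporting layout:

```r
head(comparisonTable(cohort)[, c("indicator", "arm", "p_value",
                                 "qd_mean_patient_ltau", "qd_ltau_of_means")], 3)
#>                indicator   arm      p_value qd_mean_patient_ltau qd_ltau_of_means
#> 1             hemoglobin dpmas 0.0028656407            0.8374731        0.5999183
#> 2 white_blood_cell_count dpmas 0.0069847771            0.7529526        0.6951640
#> 3   red_blood_cell_count dpmas 0.0005401783            0.9158571        0.6891832

qdMeldAssociation(scores)[c("r", "p_value")]   # Pearson r + p of QD vs MELD
outcomeContrast(cohort, scores)$byOutcome      # QD mean (SD) per outcome group
```

Both group-level QD aggregations are reported because the published
aggregation is ambiguous (vignette, "Group-level aggregation ambiguity").
Cohorts round-trip through a delimited long format with
`writeCohort()` / `readCohort()`, and a thin CLI
(`inst/scripts/qd.R`, subcommands `simulate` / `score` / `compare`) wraps
the same functions for shell use.

## Acceptance script

`scripts/acceptance.R` recomputes, from a fresh run of the installed
package, the analytic target values of the scoring rules (magnitude
buckets at given golden-logarithm values, the direction-score branch) and
exercises the full simulate → score → compare pipeline at the published
arm sizes:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
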