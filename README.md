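# readerstudy

Analysis of multi-reader multi-case (MRMC) diagnostic accuracy studies with
binary findings and **no external reference standard** — the setting of
reader studies in which a panel of radiologists plus an AI system each
label radiographic findings *normal* or *abnormal*, and the truth of each
finding must be proxied by the panel itself.

It is aimed at researchers evaluating diagnostic software (or readers)
against a human panel: veterinary and medical imaging groups comparing an
AI observer to radiologists, and methodologists who want the whole
analysis reproducible and testable without access to clinical data.

## The method

For finding *k* in study *j*, observer *i* gives an assessment
f̂<sub>j,k,i</sub> ∈ {0, 1}. The consensus ground truth is the majority
label

&nbsp;&nbsp;&nbsp;&nbsp;f<sub>j,k</sub> = 𝕀( (1/n) Σᵢ f̂<sub>j,k,i</sub> ≥ 0.5 ),&nbsp;&nbsp;n ≥ 5,

with an exact tie resolved to abnormal. Each assessment is then a TP, TN,
FP or FN against the consensus, and per-observer accuracy, sensitivity and
specificity are **micro-averaged** (counts pooled before dividing) over
exactly the findings that observer assessed — unmentioned findings having
first been imputed as normal. Disagreement per finding is the variance of
assessment V<sub>j,k</sub> = (1/n) Σᵢ (f̂<sub>j,k,i</sub> −
f<sub>j,k</sub>)², which stratifies non-unanimous findings at the median V
into low- and high-ambiguity subsets (strict split; at-median findings are
reported separately). Observers are compared with pooled two-proportion
z-tests under Bonferroni correction, and against the accuracy of always
guessing "normal" (= the normal prevalence). A synthetic panel generator
with latent truth, heterogeneous observer operating points and a
per-finding difficulty mixture makes every stage testable.

## Worked example

```r
library(readerstudy)

panel  <- generate_panel(synthetic_config(seed = 1))  # 50 studies, 11 humans + AI
bundle <- run_pipeline(panel$table)

bundle$distribution
#>        subsample n_findings normal_pct abnormal_pct
#>              All      17253      78.18        21.82
#>     No unanimity      12784      73.52        26.48
#>    Low ambiguity       6027      84.19        15.81
#>   High ambiguity       6190      62.31        37.69

bundle$benchmark$p0
#> [1] 0.7817771

format_metric_table(bundle, "all")
#>  observer accuracy sensitivity specificity
#>        R2    0.839      0.703*       0.878
#>        R5    0.832    0.774***     0.849**
#>        R1    0.832       0.697       0.868
#>      *AI*    0.830       0.607       0.893
#>        ...
#>       R11 0.783***    0.825***    0.771***
```

Reading the output: 17,253 observer-level findings were assessed, 78.2% of
them consensus-normal — so a reader who guesses "normal" everywhere scores
0.782, the benchmark every observer must beat. In the metrics table
observers are sorted by accuracy descending, the italic-flagged `*AI*` row
is the AI observer, stars mark Bonferroni-adjusted two-proportion tests of
each human against the AI (\*, \*\*, \*\*\* at adjusted p < 0.1, 0.05,
0.01), and a dash marks an undefined metric (e.g. sensitivity for an
observer whose studies contained no consensus-abnormal finding in a
stratum). Here the simulated AI sits near the best human in accuracy, is
more specific (0.893) and much less sensitive (0.607) — the qualitative
signature its configured operating point (Se 0.688, Sp 0.944) imprints
through the consensus analysis. Prevalence is higher in the high-ambiguity
stratum (37.7% abnormal) than the low one (15.8%): difficult findings are
disproportionately abnormal.

Per-subsample tables (`non_unanimous`, `low`, `high`), the human-vs-AI
test results (`bundle$tests`), benchmark tests (`bundle$benchmark$tests`)
and a run log with excluded findings, imputed fraction and at-median
counts are all in the bundle; `write_report_bundle(bundle, dir)` emits
everything as CSV, and re-running on that output reproduces the bundle.

A thin command-line wrapper lives at `inst/cli/readerstudy.R`
(`simulate`, `analyze`, `demo` subcommands).

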