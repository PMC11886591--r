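---
title: "Consensus-based analysis of multi-reader diagnostic studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-based analysis of multi-reader diagnostic studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readerstudy)
library(dplyr)
```

## The problem

In a multi-reader multi-case (MRMC) study, several observers — here,
board-certified radiologists and one AI system — each read a set of
radiographic studies and label every codable finding as *normal* (0) or
*abnormal* (1). No biopsy, follow-up or expert adjudication is available,
so there is no external reference standard: the only information about the
true state of a finding is the panel of imperfect assessments itself.

`readerstudy` implements the standard crowd-consensus analysis of such
data:

1. **Imputation** of unmentioned findings as normal (reading reports are
   sparse — an observer writes down what they judged worth stating);
2. **Consensus ground truth**: per finding, the majority label across all
   its observers;
3. **Micro-averaged** accuracy, sensitivity and specificity per observer;
4. **Ambiguity stratification** of findings by inter-observer assessment
   variance;
5. **Proportion z-tests** with Bonferroni correction comparing each human
   with the AI, and every observer with a probabilistic-guessing benchmark;
6. A **synthetic reader-panel generator** with latent truth, so every stage
   is testable end to end without clinical data.

## The model

### Consensus truth

Let $\hat f_{j,k,i} \in \{0,1\}$ be observer $i$'s assessment of finding
$k$ in study $j$. The consensus label is

$$
f_{j,k} \;=\; \mathbb{I}\!\left(\frac1n \sum_{i=1}^n \hat f_{j,k,i} \ge 0.5\right),
\qquad n \ge 5 ,
$$

i.e. the median assessment, with an exact tie (possible for even $n$)
resolved to *abnormal*. We follow the indicator form literally: the
$\ge$ makes the rule asymmetric, and tests assert both branches. Findings
assessed by fewer than five observers carry no meaningful consensus; they
are excluded and counted in the run log rather than labelled.

Each assessment then falls into one of four outcomes against the
consensus: TP, TN, FP or FN. Metrics are micro-averaged — counts are
pooled over all findings an observer assessed before dividing:

$$
\text{Acc}_i = \frac{\sum TP_i + \sum TN_i}{\sum (TP_i+TN_i+FP_i+FN_i)},\quad
\text{Se}_i = \frac{\sum TP_i}{\sum TP_i + \sum FN_i},\quad
\text{Sp}_i = \frac{\sum TN_i}{\sum TN_i + \sum FP_i}.
$$

Observers read different subsets of studies, so denominators differ
across observers. A metric whose denominator is zero (an observer whose
read studies contained no consensus-abnormal finding in a stratum) is
*undefined* — reported as `NA` and rendered `"-"`, never coerced to 0 —
and that observer drops out of rankings and test families for that metric
only.

### Ambiguity

Per-finding disagreement is the variance of assessment

$$
V_{j,k} = \frac1n \sum_{i=1}^n \left(\hat f_{j,k,i} - f_{j,k}\right)^2 ,
$$

with the binarised consensus as the reference, under which $V$ is exactly
the minority fraction: 0 at unanimity, 0.5 at an even split. A
mean-reference mode ($V = \bar f(1-\bar f)$, the population variance) is
provided as an explicit option because published analyses are not always
clear about which convention they used and the two differ for split
panels; the consensus reference is the default. Neither convention is
calibrated against any reported worked example — for a half/half panel the
two give 0.5 and 0.25 respectively, and we treat no intermediate value as
reproducible.

Findings with $V = 0$ are **unanimous**. Among non-unanimous findings the
median $V$ splits **low** from **high** ambiguity with *strict*
inequalities; findings exactly at the median belong to neither stratum and
are reported separately as `AT_MEDIAN`. This choice is deliberate: with
strict splitting the low and high observation counts need not sum to the
non-unanimous total, which is exactly the accounting pattern seen in
published reader studies of this design. The median is taken over unique
findings by default; an observation-weighted median
(`median_scope = "observation"`) is available since the choice is not
dictated by the formulas.

### Inference

Human-vs-AI comparisons use the pooled two-proportion z statistic

$$
z = \frac{\hat p_1 - \hat p_2}
  {\sqrt{\hat p (1-\hat p)\left(\tfrac1{n_1}+\tfrac1{n_2}\right)}},
\qquad \hat p = \frac{x_1+x_2}{n_1+n_2},
$$

two-sided against the standard normal, on each observer's own
numerator/denominator pair for the metric in question. The Bonferroni
family is the set of human-vs-AI comparisons within one metric within one
subsample; undefined metrics shrink the family. Adjusted p-values are
`min(1, m p)`; significance is declared below 0.05 on the adjusted scale,
with display stars at 0.1 / 0.05 / 0.01.

The tests are *unpaired* although observers overlap on findings. The
method names only a z-test for proportions, and the unpaired pooled form
is its default reading; correlation between observers' errors on shared
findings makes the test conservative or anticonservative in directions
that depend on the error structure. Paired or clustered MRMC variance
models (Obuchowski–Rockette, DeLong) are out of scope by design.

The guessing benchmark is the accuracy of the constant-"normal"
classifier, which equals the prevalence of consensus-normal observations;
each observer is compared with it by a one-proportion z-test on their own
denominator ($p_0$ = the benchmark). Whether a one- or two-proportion form
was intended by the original design is not documented; we chose the
one-proportion form because the benchmark is a deterministic function of
the consensus table, not a sampled observer.

When a pooled proportion is 0 or 1 the two-proportion statistic is
undefined; both samples are then constant and equal, so the test
degenerates to "no evidence of a difference" and is reported as $p = 1$
with a `degenerate` flag rather than an error — this arises routinely in
noiseless simulations.

## The synthetic generator

`synthetic_config()` describes a study design; `generate_panel()` draws a
panel plus a latent truth table that the analysis path never sees. The
defaults emulate a 50-study, 11-radiologist design with one AI observer:

| parameter | default | meaning |
|---|---|---|
| `n_studies` | 50 | radiographic studies |
| `findings_per_study` | Poisson(51), truncated at 1 | codable findings per study |
| `n_humans` | 11 | human readers |
| `human_read_fraction` | 0.5 | each human reads each study w.p. 0.5 (≈ 25 reports each) |
| `ai_reads_all` | `TRUE` | the AI reads all 50 studies |
| `abnormal_prevalence` | 0.16 | latent P(abnormal) per finding |
| `human_profiles` | Se 0.64–0.95, Sp 0.80–0.94 | heterogeneous operating points with the usual Se/Sp trade-off |
| `ai_profile` | Se 0.688, Sp 0.944 | a high-specificity, lower-sensitivity AI |
| `difficulty` | 0 w.p. 0.5, else U(0.1, 0.6) | per-finding ambiguity |
| `mention_prob_normal` | 0.3 | P(a normal judgement is written down) |
| `min_readers` | 5 | consensus gate; deficient studies are redrawn |

An observer with class-conditional accuracy $q$ (their Se on truly
abnormal findings, Sp on truly normal ones) assessing a finding of
difficulty $d$ is correct with probability $(1-d)\,q + d/2$: difficulty
acts as a coin-flip mixture rather than shifting operating points
directly. One parameter then produces the unanimous / low / high variance
structure while keeping a closed form
(`expected_assessment_accuracy()`) for parameter-recovery tests.
Abnormal calls are always recorded; normal calls only with probability
0.3, specifically to exercise the imputation path that real report coding
requires. Under these defaults a panel carries roughly 16–17&nbsp;thousand
observer-level findings and each radiologist contributes about 25 reports.

What the generator does **not** emulate: correlated errors between
observers beyond what the shared difficulty induces, per-body-region or
species covariates, reader drift over time, and any image content. The
redraw rule that guarantees five readers per study slightly inflates the
per-human report count above `n_studies × read_fraction` (conditioning on
panel sufficiency), and selective reporting removes findings that no
observer mentioned at all — both effects are visible in the design
summary and are properties of real studies too. Consequently, passing
tests demonstrate the pipeline's arithmetic and its statistical
calibration under this generative model, not the clinical
representativeness of any particular panel. In particular the generator
is not calibrated to reproduce a specific unanimity fraction; with the
default operating points roughly a quarter of observer-level observations
are unanimous, less than in the motivating class of studies, because even
zero-difficulty findings draw independent errors from up to twelve
readers.

## Numerical and design choices

* **Tie at the consensus**: `mean >= 0.5` ⇒ abnormal, exactly per the
  indicator. For a six-reader panel at Se = Sp = 0.9 this asymmetry is
  the dominant error source on the normal side: a consensus-normal
  finding flips whenever 3 of 6 readers err
  (`1 - pbinom(2, 6, 0.1)` ≈ 0.016), so expected truth agreement under
  those conditions is ≈ 98.6%, not arbitrarily close to 1. An odd panel
  avoids the tie entirely.
* **AI in the electorate**: the AI's votes count toward the consensus by
  default (it is an observer like any other); this mildly flatters the
  AI's measured specificity, so `exclude_ai_from_consensus = TRUE` is
  provided to quantify the effect.
* **Ranking**: best / median / worst humans are re-determined per metric;
  with $h$ defined values sorted descending the median is the element at
  position $\lceil h/2 \rceil$ (the 6th of 11). The AI never ranks.
* **Determinism**: all randomness lives in the generator behind a single
  seed; the analysis path is a pure function of its input table, and
  re-running the pipeline on its own emitted CSVs reproduces the bundle.
* **Problem sizes in tests**: parameter-recovery suites use 5,000-finding
  panels (50 studies × 100 findings, six readers) and the error-control
  suite uses 200 small null panels (15 studies × 10 findings, 11 humans);
  these sizes put Monte-Carlo error well inside the asserted tolerances
  while keeping the default test run fast.

## A worked run

```{r demo}
panel <- generate_panel(synthetic_config(seed = 1))
bundle <- run_pipeline(panel$table)
bundle$summary
bundle$distribution
format_metric_table(bundle, "all")
```

The distribution table shows the heavily normal case mix; the benchmark
accuracy `bundle$benchmark$p0` equals the "All" normal share by
construction. In the metrics table observers are sorted by accuracy
descending, the AI row is asterisk-flagged, stars mark Bonferroni-adjusted
human-vs-AI differences, and dashes mark undefined metrics.

Because truth is latent in real data but known here, the generator's
operating points can be recovered:

```{r recovery}
tab <- impute_unmentioned(panel$table)
joined <- dplyr::inner_join(tab$records, panel$truth,
                            by = c("study_id", "finding_code"))
joined |>
  dplyr::summarise(se_hat = mean(assessment[truth == 1]),
                   sp_hat = mean(1 - assessment[truth == 0]),
                   .by = observer_id) |>
  head(4)
```

Measured values sit below the configured profiles by design: the
difficulty mixture degrades every observer toward the coin flip on hard
findings.

## Limitations

* The consensus is a proxy, not truth; it is least reliable exactly where
  the analysis is most interesting (high ambiguity), and observers are
  scored against a standard they themselves helped set.
* Unpaired z-tests ignore reader overlap (see above).
* Micro-averaging weights every finding equally, so prolific studies
  dominate; no per-study or per-region macro-average is offered.
* The pipeline consumes already-binarised finding codes; mapping free-text
  reports to codes, and the normal-variation vs. insignificant-abnormality
  coding convention, are upstream data-preparation contracts.
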