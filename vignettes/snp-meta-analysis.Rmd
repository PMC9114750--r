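---
title: "Case-control SNP meta-analysis: models, calibration, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control SNP meta-analysis: models, calibration, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## The problem

A biallelic SNP with alleles A and G is genotyped in a collection of
case-control studies. Each study reports its genotype counts
$(n_{AA}, n_{AG}, n_{GG})$ in cases and controls, or at least its arm sizes
and a Hardy-Weinberg check on the controls. The questions are the standard
ones of genetic epidemiology: does carrying G change disease odds, is the
effect consistent across studies and subgroups (cancer type, organ system,
ethnicity, control source), and is the literature we observe a biased sample
of the studies that were run?

`snpmeta` implements that pipeline end to end: genetic-model contrasts,
per-study odds ratios, Hardy-Weinberg screening, fixed/random pooling with
heterogeneity statistics, publication-bias tests, meta-regression, power,
and a synthetic-data generator with known truth so every stage can be tested
without any external download. The package ships a transcription of an
87-study roster (29,464 cases, 35,858 controls) for the CTLA-4 rs231775 A/G
variant as a worked, real-shaped input; that roster carries no per-study
genotype counts, so it exercises the count/subgroup machinery while all
effect-estimation behaviour is validated on synthetic data.

## Genetic-model contrasts

The $3 \times 2$ genotype table is recoded into a $2 \times 2$
exposure-by-disease table in five standard ways, with G fixed as the
exposed allele throughout:

| model | exposed | unexposed |
|---|---|---|
| allelic | G alleles ($2n_{GG}+n_{AG}$) | A alleles ($2n_{AA}+n_{AG}$) |
| heterozygote | AG | AA (GG excluded) |
| homozygote | GG | AA (AG excluded) |
| dominant | GG + AG | AA |
| recessive | GG | AG + AA |

The allelic contrast treats the $2N$ alleles of an arm as independent
observations. Under Hardy-Weinberg equilibrium this is exact (allele counts
are binomial); under departure from HWE it is the standard, documented
approximation used throughout this literature.

For a table $(a, b, c, d)$ the study effect is the log odds ratio
$y = \ln(ad/bc)$ with Woolf variance $v = 1/a + 1/b + 1/c + 1/d$ and Wald
interval $\exp(y \pm z_{0.975}\sqrt{v})$. When any cell is zero the
Haldane-Anscombe correction adds $0.5$ to all four cells of that study's
table (flagged in the output, logged by the pipeline). The correction is
applied per study and per contrast, uniformly across the five models; with
`correction = 0` a zero cell is an error rather than a silent infinity.

## Hardy-Weinberg screening

Controls are screened with the Pearson chi-square test on one degree of
freedom: $\hat p$ is the A-allele frequency, expected counts are
$n\hat p^2,\; 2n\hat p(1-\hat p),\; n(1-\hat p)^2$, and classes with zero
expectation contribute nothing when also observed empty, so a monomorphic
sample lying exactly on HW proportions gives $\chi^2 = 0$, $p = 1$ rather
than an error. The asymptotic test matches the screening convention of this
literature; an exact test is deliberately not offered. Roster entries whose
HWE p-value is reported only as a bound ("<0.001") are stored at half the
bound with a `hwe_below_detection` flag; only the comparison against the
0.05 screen is ever consumed, so the placeholder cannot leak into any
statistic.

## Pooling

*Fixed effect.* Two estimators are available. Mantel-Haenszel,
$\widehat{OR}_{MH} = \sum_i (a_i d_i / n_i) \big/ \sum_i (b_i c_i / n_i)$,
with the Robins-Breslow-Greenland variance for $\ln \widehat{OR}_{MH}$, is
the default for pooling contrast tables — it is the binary-outcome default
of the Stata-style workflow this pipeline mirrors and behaves well with
sparse cells. Inverse-variance weighting ($w_i = 1/v_i$) is available by
flag and is what the heterogeneity machinery is built on.

*Heterogeneity.* Cochran's
$Q = \sum_i w_i (y_i - \hat\theta_{IV})^2$ is referred to
$\chi^2_{k-1}$, and $I^2 = \max(0, (Q - (k-1))/Q) \cdot 100$. The
standalone Mantel-Haenszel fit reports Q centred on its own pooled estimate
(the usual tabulation convention); the pipeline always reports the
IV-centred Q, because that is the statistic its model-selection rule
consumes, keeping the reported `method` and `p_h` exactly consistent within
every cell.

*Random effects.* DerSimonian-Laird:
$\hat\tau^2 = \max\!\big(0,\, (Q - (k-1)) \big/ (\sum w_i - \sum w_i^2 /
\sum w_i)\big)$, then weights $1/(v_i + \hat\tau^2)$. When
$Q \le k - 1$ the estimate collapses onto the fixed-effect fit exactly,
and the suite asserts bit-level agreement. No Hartung-Knapp adjustment is
applied and $\tau^2$ for pooling is always the moment estimator; REML
exists only as a meta-regression option.

*Model selection.* The fixed-effect model is retained iff the Q-test
p-value is strictly greater than 0.05 ("no evidence of heterogeneity");
otherwise random effects. Both the threshold and the strictness follow the
screening convention stated with the roster; the threshold is configurable.
The pooled log odds ratio is tested with $z = \hat\theta / se$ against the
standard normal, and intervals are 95% ($z_{0.975} = 1.959964$) to match
the roster's reporting; the level is a configurable constant.

## Publication bias

*Egger.* The classic 1997 unweighted formulation: OLS of the standardized
effects $t_i = y_i/\sqrt{v_i}$ on precisions $x_i = 1/\sqrt{v_i}$; the
intercept, its OLS standard error, and a Student-t test on $k-2$ degrees of
freedom. The weighted variant is intentionally not offered — one canonical
output. A perfectly collinear input (all effects equal) is reported as
intercept exactly 0 with $p = 1$, the analytic limit, rather than `NaN`.

*Begg-Mazumdar.* Kendall's rank correlation between the standardized
deviates $u_i = (y_i - \hat\theta_{IV})/\sqrt{v_i - \bar v}$ and the
variances $v_i$, with tie-adjusted $\tau$, the untied null variance
$k(k-1)(2k+5)/18$ for the normal deviate, and no continuity correction.
The concordant-minus-discordant count is checked against exhaustive pair
enumeration in the suite.

Both tests are computed per contrast and per subgroup on demand, and the
funnel export (`funnel_data()`/`write_funnel()`) provides points and
pseudo-CI guide lines for external plotting; no figures are rendered here.

## Meta-regression and power

`metareg_fit()` fits univariable weighted least squares of $y_i$ on an
intercept plus one covariate, the four conventional ones being publication
year, ethnicity, control source, and genotyping method — fitted separately,
one model per covariate, which is how such analyses are conventionally
reported. Publication year is treated as continuous by default (binning is
the caller's choice); categorical covariates are dummy-coded against their
most frequent level, and genotyping-method levels carried by fewer than
three studies can be merged into `other_method` to avoid rank-deficient
designs (the pipeline's CLI does this; the threshold is an argument).
Residual $\tau^2$ uses the generalized method of moments
($Q_E$ and the trace of the weighted projection), with REML as an option;
coefficients are tested by Wald z. A constant covariate degrades gracefully
to the intercept-only model, which is numerically identical to
DerSimonian-Laird pooling — asserted in the suite.

`power_two_proportions()` computes the power of the two-sided
two-proportion z-test on allele counts: the case G frequency implied by an
odds ratio $OR$ against control frequency $p_0$ is
$p_1 = OR\,p_0 / (1 + p_0(OR - 1))$, and power uses the unpooled-variance
normal approximation without continuity correction — the simplest member of
the standard power-calculator family, chosen because it is directly
verifiable by simulation: the suite checks it against 20,000 Monte-Carlo
replicates to ±0.015. At $OR = 1$ it returns exactly $\alpha$.

## The synthetic-data generator

`simulate_meta_dataset()` emulates the statistical structure the analysis
assumes, with every generating parameter exposed and recorded in a `truth`
attribute:

- **Study sizes** are drawn uniformly on 50-2200 per arm, the range spanned
  by the packaged roster.
- **Control G-allele frequency** is drawn uniformly on 0.25-0.70, spanning
  the roster's Caucasian (~0.40) to Asian (~0.62) control frequencies.
- **Control genotypes** are multinomial with HW proportions, or with an
  inbreeding coefficient $f$: $P(AA) = (1-q)^2 + fq(1-q)$,
  $P(AG) = 2q(1-q)(1-f)$, $P(GG) = q^2 + fq(1-q)$, giving a heterozygote
  deficit of exactly $2fq(1-q)$ in expectation — the handle for testing the
  HWE screen's power.
- **Case genotypes** come from exponential tilting of the control
  distribution by $e^{\theta_i}$ per G allele (retrospective case-control
  logic, no prevalence parameter). Under HWE controls, tilting preserves
  the binomial form, so the allelic contrast's estimand equals $\theta_i$
  exactly — the generator's defaults make the per-allele model the truth,
  and dominant/recessive generation would be a misspecification experiment,
  not the default.
- **Between-study variance**: $\theta_i \sim N(\theta, \tau^2)$.
- **Metadata** (ethnicity 60:25:2 Asian:Caucasian:African, source 53:34
  HB:PB, cancer-type frequencies) mirror the roster's composition, so
  pipeline runs on synthetic data produce subgroup tables of realistic
  shape.
- **Publication selection**: each study with two-sided allelic $p \ge 0.05$
  is suppressed with probability `selection_prob`. Because that p-value is
  a function of the standardized effect alone, this two-sided filter is
  symmetric in the effect's sign and independent of precision: at a null
  true OR it hollows the funnel without tilting it, and funnel-asymmetry
  tests gain essentially no power against it. The additional
  `direction = "greater"` mechanism (suppress studies lacking a significant
  risk-increasing result) is the classical directional selection under
  which Egger's test demonstrably gains power; the suite shows both
  behaviours.

What the generator does *not* emulate: shared control groups across rows,
linkage with neighbouring variants, population stratification, genotyping
error, or covariate-confounded effects. Green calibration tests therefore
certify the arithmetic and its sampling-theory behaviour, not robustness to
those real-data pathologies.

## Numerical and design choices

- Genotype class order everywhere is AA, AG, GG (ascending G dosage); G is
  always the exposed allele. Relabelling the alleles inverts every OR and
  swaps the dominant and recessive models — asserted as a property test.
- The cancer-type → organ-system mapping is shipped as an editable data
  file (`system_map.tsv`), not code; types outside the five systems map to
  "no system". The spelling "Tumor of urinary tract" follows the roster's
  row-level source. One roster quirk is preserved deliberately: the
  urinary-tract control total sums to 2092 from the study rows, while the
  summary table alongside the original roster prints 2002; the row-level
  values are kept and the discrepancy documented rather than "fixed".
- Studies contributed by one author team across several cancer types keep
  separate rows with synthetic ids `author_year_cancertype`; overlap of
  shared controls between such rows is not deduplicated, matching the
  source roster's arithmetic.
- Cancer types represented by a single study are pooled into an "others"
  group; the group exists only on the cancer-type axis.
- Subgroups with a single effect-bearing study are analysed (crude OR) but
  flagged; the minimum is configurable.
- Ties in Begg's statistic are handled in the $\tau$ denominator only;
  output ordering ties are broken by study id, never inside the statistic.
- Machine-precision TSV output is the canonical report; the human-readable
  variant rounds ORs to 2 and p-values to 3 decimals and is derived from
  the same report object.

## Problem sizes in the test suite

The suite runs entirely on packaged and generated data: oracle equivalence
of the pooling estimators on 500 random small meta-datasets at $10^{-12}$
relative tolerance; HWE type-I error on 2,000 replicates and Egger's on 200
(k = 20); 95% CI coverage at true OR 0.85 over 500 replicates of k = 50
studies; meta-regression slope recovery over 300 replicates of k = 40; the
power formula against 20,000 simulated tests; and recovery of
$\theta \in \{\ln 0.85, 0, \ln 1.5\}$, $\tau^2 \in \{0, 0.05\}$ grids at
reduced replication. These sizes keep the whole suite around a minute on
one core while leaving Monte-Carlo error well inside each assertion's
margin.

## Limitations

The package analyses one biallelic autosomal variant at a time; X-linked,
multi-allelic, and haplotype models are out of scope, as are study quality
scoring, trim-and-fill, cumulative/leave-one-out meta-analysis, and
rendered forest/funnel graphics (exports are provided instead). The
roster's pooled estimates cannot be reproduced from the package's own data
because the source tables do not print per-study genotype counts; all
effect-level validation is by construction against synthetic truth and
independent reference implementations.
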