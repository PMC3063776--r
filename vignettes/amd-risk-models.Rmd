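---
title: "Models and methods: AMD risk classification with amdrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: AMD risk classification with amdrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdrisk)
```

# The problem

Age-related macular degeneration (AMD) has a handful of well-replicated
susceptibility factors: advancing age, cigarette smoking, and common
variants in CFH (Y402H), ARMS2 (A69S), CFB (R32Q, protective) and C3
(R102G). `amdrisk` builds classifiers that turn these six factors into a
high-/low-risk call for an individual, evaluates them honestly on
independent samples, and expresses predictive values at population
prevalences rather than at the case:control ratio of a clinic sample.

Three modelling strategies are deliberately compared on identical inputs.
They differ in how they use the data, in how they fail, and in whether they
can decline to classify.

# The three classifiers

## Additive logistic regression

`fit_logistic()` estimates

$$\mathrm{logit}\, P(\text{AMD}) = \beta_0 + \beta_{age}\,\text{age} +
\beta_{smk}\,\text{smoking} + \sum_{g} \beta_g\, g$$

by maximum likelihood (IRLS via `stats::glm`, convergence tolerance 1e-10,
at most 100 iterations), with age in years, smoking as an ever-smoker
indicator, and each SNP as a 0/1/2 risk-allele count. No interaction terms
are fitted: at a few hundred cases, six main effects are already at the
edge of what the CFB stratum (risk-allele frequency ~7%) supports. Complete
separation is reported as an explicit error. Odds ratios are
`exp(coefficient)` with 95% CIs `exp(coefficient ± 1.96·SE)`.

`classify_prob()` applies an inclusive threshold (`p ≥ t` is high-risk).
The default 0.5 is arbitrary; `optimal_threshold()` scans the ROC curve
(`roc_curve()`) for the cutoff maximizing the number of correct calls, with
ties broken toward the higher (more specific) threshold. That tie-break is
a design choice: when two cutoffs classify equally well, the more
conservative screen is preferred. Note the optimal threshold is a property
of the sample it is computed in; recalibration is needed before carrying a
threshold across populations.

The empirical AUC is computed by the trapezoidal rule, which equals the
Mann-Whitney rank statistic with ties counted 1/2 (the test suite asserts
this identity). Its confidence interval uses DeLong's placement-value
variance estimator, implemented directly and cross-checked against the pROC
package in the tests.

## MDR cell-ratio classification

`mdr_build()` tabulates every observed combination of age bin, smoking and
the four genotypes. A combination is labelled high-risk exactly when its
training case:control ratio **strictly** exceeds the overall training
ratio; ties go to low-risk. Cells containing only cases are high-risk
(infinite ratio); cells containing only controls are low-risk. At test
time, `mdr_classify()` looks the combination up; unseen combinations are
`"cnc"` — could not classify — a first-class outcome, not an error.

Age must be discretized for MDR. It enters as its training-sample quantile
bin; the number of quantiles is not fixed by the method, so `k` is a
parameter defaulting to 4 (quartiles). Bin edges are type-1
(order-statistic) quantiles, which balance training occupancy to within one
individual when ages are distinct; test ages always use the
training-derived edges (no leakage) and clamp to the extreme bins outside
the training range. With `k = 1` and constant smoking the classifier
degenerates to a pure 4-locus genotype lookup, a useful sanity check.

## Grammatical evolution of neural networks (GENN)

`genn_evolve()` evolves both the architecture and the weights of a small
feedforward network whose internal nodes are weighted additions (PADD) and
whose output passes through a sigmoid; outputs ≥ 0.5 are high-risk. Age
enters as the same training-derived quantile bin as in MDR, keeping the
three methods' inputs comparable.

The original GENN software's grammar is not published, so the package
defines its own minimal PADD grammar (`genn_grammar()`), in full:

```
<net>    ::= sig(PADD(<leaf> x6, <bias>))
           | sig(PADD(<w>*<hub2>, <w>*<hub4>, <bias>))
           | sig(PADD(<w>*<hub3>, <w>*<hub3>, <bias>))
           | sig(PADD(<w>*<hub4>, <w>*<hub2>, <bias>))
<hubN>   ::= PADD(<leaf> xN)
<leaf>   ::= <w> * <input>
<input>  ::= age | smoking | CFH | ARMS2 | CFB | C3
<bias>   ::= <w> | 0
<w>      ::= <sign><digit>.<digit>        (signed constants -9.9 .. 9.9)
```

Design choices, and why:

* **Topologies.** A flat weighted sum plus three two-hub splits (2+4, 3+3,
  4+2). Two-hub shapes are what these networks settle into on real AMD
  data, with genetic and environmental factors in separate hubs; richer
  recursion would enlarge the search space faster than a population of a
  few thousand can exploit.
* **Activation.** Hidden PADD nodes are pure weighted additions (that is
  what PADD means); the single sigmoid sits at the output. The whole
  network therefore collapses to an effective linear score, which the
  implementation exploits for fast fitness evaluation while keeping the
  genotype-to-network mapping fully general.
* **Bias.** An optional signed constant feeds the output node. Without it,
  the decision boundary is forced through the origin of the factor space,
  which cripples step-function targets.
* **Constraint.** Only networks containing each factor exactly once are
  propagated — weights and wiring evolve, variable selection does not.
  Handling is by rejection: a non-conforming derivation scores fitness 0.
  Input choices stay free during derivation, so the constraint genuinely
  binds (a uniformly random assignment of six leaves is a permutation about
  1.5% of the time, enough to seed a population of a few hundred).
* **Mapping.** Standard grammatical evolution: 8-bit codons choose
  production alternatives modulo the alternative count, reading wraps over
  the genome up to 2 times, incomplete derivations are invalid values.
  Genomes are 25–1000 bits; crossover (probability 0.9) is single-point,
  mutation flips each bit with probability 0.01, selection is a size-2
  tournament with one elite (tournament and elitism are unpublished details
  of the original software; these are standard GE practice and
  configurable).
* **Fitness.** Balanced accuracy, so the prevailing class cannot dominate
  a case-control sample with unequal arms.

Population size defaults to 5000 and generations to 50; tests and the
worked examples run reduced searches (population 500, 30 generations),
which suffice for six-input networks.

## Consensus

`consensus_call()` votes: high-risk iff at least two methods say high-risk,
low otherwise. A CNC vote is simply not a high vote (the default), because
the rule counts high votes only; a `"propagate"` mode that returns CNC
whenever any method is CNC is provided for sensitivity analyses, since how
unclassifiable individuals should enter consensus denominators is genuinely
ambiguous.

# Evaluation

`confusion_summary()` and `classification_metrics()` score calls against
clinician-assigned status. Where CNC occurs, every rate is reported under
two denominators: classifiable individuals only, and the full tested
sample. Both are informative — the first describes the rule's accuracy when
it speaks, the second its usefulness as a screen. Rates with zero
denominators are `NA` (undefined), never silently 0 or 1. Internally all
rates are exact count fractions; formatting to one-decimal percentages
happens only at the reporting edge (`metrics_table()`).

`adjust_predictive_values()` re-expresses PPV/NPV at a chosen population
prevalence via Bayes' rule; when the supplied prevalence equals the sample
case fraction, the adjusted values provably coincide with the unadjusted
ones, a property the tests verify numerically. Adjusted PPV is strictly
increasing, and adjusted NPV strictly decreasing, in prevalence.

`hwe_test()` is the 1-df chi-square goodness-of-fit against Hardy-Weinberg
proportions at the sample allele frequency; an exact test would be
preferable for very rare alleles but the chi-square matches how genotype QC
is conventionally screened at these frequencies, and monomorphic samples
are reported as undefined rather than tested.

# The synthetic cohort generator

The clinical datasets behind the original analysis are not public, so
`generate_cohort()` emulates them:

* **Genotypes** are independent Binomial(2, q) draws (Hardy-Weinberg at
  risk-allele frequency q). The four loci lie in different genes, so no
  linkage disequilibrium is modelled.
* **Age** is normal, truncated to [50, 100] years by redrawing — only the
  mean and SD of the clinic samples are known, and AMD cohorts are elderly
  by ascertainment.
* **Smoking** is Bernoulli at the sample prevalence.
* **Disease status** comes from case-control rejection sampling: draw a
  covariate vector, compute its disease probability under the generative
  logistic model, and route it to the case pool with that probability,
  filling fixed case/control quotas. This mirrors clinic ascertainment
  with fixed arm sizes rather than prospective sampling. A draw cap turns
  unreachable quotas into an explicit error.

The presets (`cohort_preset()`) carry the published sample sizes, allele
frequencies, age distributions and smoking prevalences of the three
samples, with the published six-factor model (`amd_risk_model()`, constant
-10.48; age 0.13/yr, smoking 0.48, CFH 1.04, ARMS2 0.69, CFB -1.10, C3
0.41) as generative truth. With those settings, refitting the logistic
model on simulated 349/216 cohorts recovers each generative coefficient
within the published 95% CI in well over 90% of replicates (the acceptance
suite runs 100).

What the generator does **not** emulate: family structure (relatives are
treated as independent), population stratification, linkage
disequilibrium, genotyping error, or the cohort heterogeneity of real
multi-site samples. Consequences worth knowing: synthetic test cohorts are
drawn from almost the same distribution as training, so MDR's
could-not-classify fraction (typically 9–25% at these sizes) sits somewhat
below the ~20% seen with heterogeneous clinical samples, and
cross-population degradation (the main reason thresholds need
recalibration) is milder than in reality. Passing tests demonstrate the
algorithms' internal correctness and behaviour under the stated sampling
model, not clinical transportability.

# Numerical choices and degenerate inputs

* Threshold comparisons are inclusive (`≥`) everywhere a probability or
  sigmoid output is dichotomized.
* MDR's ratio comparison is strict (`>`); a cell tied with the overall
  ratio is low-risk.
* `optimal_threshold()` ties break toward the higher threshold; the
  candidate set is every distinct score plus `Inf` (call nobody high).
* Monomorphic SNPs: HWE test undefined (`NA`); logistic fits will drop or
  fail on constant columns with an explicit error rather than a silent
  answer; `sample_genotype()` handles the degenerate frequencies 0 and 1
  exactly.
* Reproducibility: every stochastic component takes a seed; pipelines use
  one master seed with per-component streams derived via a deterministic
  label hash (`derive_seed()`), so adding a method does not perturb the
  cohorts.
* Problem sizes in the shipped tests are chosen to keep the full suite
  comfortably interactive: recovery simulations use 100 replicates at the
  published 349/216 sizes; evolutionary checks use population 500 for 30
  generations at n = 500, ten seeds per condition.

# Known limitations

* The GENN grammar is this package's reconstruction; the original
  software's grammar, wrap policy and selection scheme are not published,
  and evolved networks here are linear-in-inputs by construction (PADD
  nodes), so genuinely non-additive structure is only expressible through
  the discretization of age and the dichotomization at the output.
* MDR stability degrades quickly as cells thin out; with six factors and a
  few hundred observations, many cells hold one or two individuals, and
  the per-cell labels are correspondingly noisy. This is a property of the
  method the package intentionally reproduces, not a defect to be patched.
* Prevalence adjustment assumes sensitivity and specificity transport to
  the target population; that assumption fails exactly when the covariate
  distributions shift, which the cross-population analyses illustrate.
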