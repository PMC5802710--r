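---
title: "Cutoff behavioral criteria: model, assumptions and design choices"
author: "cbcprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cutoff behavioral criteria: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbcprofiler)
```

## The profiling model

Cutoff behavioral criteria (CBC) classification treats the control group as
the reference for "normal" behavior. For each of *m* behavioral measures the
control distribution defines a percentile cutoff at level *q*; an animal is
*deviant* on a measure when its value falls in that measure's deviant tail at
or beyond the cutoff, and *affected* when it is deviant on at least *k* of
the *m* measures. The group-level quantity of interest is not a mean but the
affected:unaffected split, compared to reference proportions with a
two-category Pearson goodness-of-fit test (df = 1, no continuity
correction).

The approach rests on three assumptions worth keeping in mind:

* the control sample is large enough for its empirical percentiles to be
  stable (the package refuses fewer than `min_control_n = 10` controls by
  default);
* the m measures jointly capture the phenotype, so that requiring k
  simultaneous deviations trades per-measure sensitivity for specificity;
* classification is relative to the *concurrent* control group, so batch
  effects shared by all groups cancel, but nothing corrects for effects that
  differ between groups.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q` | 0.20 | percentile level of the control cutoffs (fraction, unitless) |
| `k` | 4 | minimum number of deviant measures for "affected" |
| `measures` | 7-measure EPM panel | names, units, and deviant tail per measure |
| `reference` | 0.20 : 0.80 | goodness-of-fit reference proportions |
| `min_control_n` | 10 | smallest accepted control group |
| `inclusive` | `TRUE` | boundary rule at the cutoff |
| `estimator` | nearest-rank | percentile estimator |

The seven-measure default panel (open-arm distance and duration, closed-arm
distance and duration, total distance, and the open/closed distance and
duration anxiety indices) is a documented stand-in for "seven distance and
duration measures": published CBC analyses do not standardize the panel, and
any set of column names can be configured. Deviant tails are low for all
defaults except closed-arm duration (anxious animals hide more, so its
deviant tail is high).

## Numerical choices

**Percentile estimator.** Cutoffs use the nearest-rank order statistic at
rank ⌈q·n⌉ (mirrored for upper tails) rather than an interpolated quantile.
Two properties motivated this: the flagged fraction inside the control group
is then *exactly* ⌈q·n⌉/n when there are no ties, and the whole
classification is invariant under strictly increasing transforms of any
measure — both are enforced by property tests. An interpolated (type-7)
estimator is available behind `estimator = "interpolated"` for comparison
with software that defaults to it.

**Boundary rule.** Comparisons with the cutoff are inclusive by default
(`<=` for low tails, `>=` for high tails), so the control animal that defines
the cutoff is itself flagged; "under/above the percentile" is ambiguous and
the strict variant is one switch away. A measure that is constant across all
controls makes the inclusive rule flag every tying animal; the package warns
and keeps the measure, because silently dropping it would change m and hence
the k-of-m criterion.

**Goodness of fit.** The Pearson statistic is computed without Yates
correction. This is not merely convention: for the canonical six-group
design the integer affected counts recoverable from the published statistics
reproduce those statistics to two decimals only without the correction
(`verify_reference_stats()` demonstrates this; the Yates-corrected statistic
for the 11-of-31 split is ≈ 3.73, not 4.65). For the same reason the
stressed-baseline reference is used as the rounded 35:65, not the exact
11/31: only the rounded proportions reproduce the printed companions 5 and
2.87.

**ANOVA.** The averaged-group analysis uses Type III sums of squares with
sum-to-zero contrasts, matching the default of the commercial software
typically used for this design; Type II and sequential Type I are available.
With unbalanced cells the SS type genuinely matters, and since raw data for
the reference design are not public the choice is a documented convention,
not a verified one. Edge cases are pinned down: a factor collapsed to one
level reproduces the one-way analysis of the other factor; an all-constant
response reports F = 0, p = 1 (the 0/0 limit resolved by convention); empty
cells and saturated designs are refused. Bonferroni post hoc comparisons are
pairwise t tests on the two-way residual mean square, adjusted only across
the pairs of the named factor (the drug treatment, in the canonical design).

## The synthetic cohort generator

No raw data accompany the reference design, so validation runs on synthetic
cohorts. The generator draws, per animal, a latent affected status
Bernoulli(π) and correlated standard-normal latents (equicorrelation ρ via a
single shared factor), exponentiates them into five positive, right-skewed
primitive measures (log-normal marginals: open/closed-arm distance and
duration, center distance), scales affected animals' measures by
(1+δ)^(−w) with per-measure exponents w that push *every* measure toward
its deviant tail, and derives total distance and the two anxiety indices.
This emulates the salient structure of real EPM summaries — positivity, right
skew, mutual correlation, a shifted subpopulation — but not trajectory-level
features, floor effects at zero open-arm time, or the discreteness of entry
counts; passing tests on synthetic cohorts therefore validate the *pipeline
arithmetic*, not any claim about real maze data.

`generate_jvs_study()` reproduces the canonical six-group design shape
(n = 30, 12, 12, 31, 19, 12). Its latent affected fractions were calibrated
once, by simulating the classifier's operating characteristics under the
default δ = 2.5 and ρ = 0.45 (false-positive rate ≈ 0.10, sensitivity
≈ 0.92 with n = 30 control cutoffs), so that the *expected classified*
proportions approximate the affected rates characteristic of the design
(0.20, 0.08, 0.17, 0.35, 0.11, 0.58). Two groups have latent π = 0 because
their target rates sit at or below the classifier's false-positive rate —
the classified proportion of such a group cannot fall below that rate. The
nonzero ρ matters: a real control group showing ~20 % affected under a
k-of-4-of-7 rule is only consistent with strongly co-varying measures, since
independent measures would yield the binomial tail
`kofm_null_rate()` ≈ 3.3 %.

**Parameter recovery.** The classified proportion is a biased estimator of
the latent affected fraction: E[p̂] = π·sens + (1−π)·fp. The package exposes
the standard misclassification correction (Rogan–Gladen)
`recover_affected_fraction()`, π̂ = (p̂ − fp)/(sens − fp), truncated to
[0, 1]. The acceptance-level recovery simulation uses an
independent-measure model at ρ = 0 with strong separation (δ = 3), where fp
is the closed-form binomial tail and sensitivity ≈ 1, and recovers π = 0.35
to within Monte-Carlo error over 200 replicate cohorts of n = 31 with a
fresh n = 30 control per replicate.

## Problem sizes

The test suite exercises exhaustive count inversions up to n = 40,
enumeration oracles on tables up to 8 × 3, a 100 000-animal null-rate
simulation, 200-replicate recovery simulations, and 20 000-animal
correlation-limit checks; the full suite runs in well under a minute.

## Known limitations

* The default measure panel is a stand-in; results depend on the configured
  panel, and the package deliberately refuses to impute missing measures.
* Cutoffs from the control group are sample quantities; with n = 30 controls
  a new animal's per-measure flag probability is 6/31 ≈ 0.194 rather than
  exactly 0.20, and the control group is classified against cutoffs computed
  from itself (no leave-one-out), mirroring standard CBC practice.
* The six per-group goodness-of-fit tests are reported unadjusted, as is
  conventional for this design; apply your own multiplicity control if your
  design demands it.
* Repeated-measures designs (body weight, fluid intake over time) are out of
  scope.
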