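---
title: "Methods: prognostic-index risk groups for gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic-index risk groups for gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survsig)
```

## The model and its assumptions

`survsig` evaluates a fixed gene signature against right-censored outcomes
through the Cox proportional-hazards model. The per-sample risk score is
the model's linear predictor, the prognostic index
$PI = \sum_i \beta_i x_i$, with $x_i$ the log2 expression of signature
gene $i$. The central assumptions are those of the Cox model: hazards of
any two samples are proportional over time, covariate effects are linear
on the log-hazard scale, and censoring is uninformative. None of these are
checked automatically; the time-dependent ROC and the per-group
concordance indexes give some purchase on how the signature's
discrimination varies over follow-up, but a formal proportionality test is
out of scope.

Coefficients come from one of two sources. In `cox` mode all signature
genes enter a single multivariate fit; coefficients are therefore adjusted
for one another, and collinear or near-constant genes will destabilize the
fit (constant genes are detected and dropped with a warning). In `user`
mode the signature's published weights are used verbatim, which is the
right choice when validating a score defined outside the Cox framework —
no refitting occurs and the evaluation cohort is used only for testing.

## Risk-group generation

Two stratification methods are provided.

**Quantile split.** Samples ordered by PI are cut into $k$ contiguous
blocks whose sizes differ by at most one; remainder samples go to the
lower-risk blocks. For $k = 2$ and even $n$ this is exactly the median
split. The split is deterministic: ties in PI are broken by input order
during sorting, and tied PI values never straddle a boundary — all samples
sharing the boundary value are kept on the lower-risk side, so the group
label is a function of the PI value alone. In degenerate data with heavy
ties this can unbalance group sizes; we consider that preferable to
assigning equal PI values to different risk groups.

**Optimized split.** For two groups, the two-sample log-rank statistic is
evaluated at every admissible cut along the PI-ordered samples and the
boundary with the smallest p-value wins (the first such position on exact
ties). A cut is admissible when both sides have at least `min_group_size`
samples and the PI strictly increases across the boundary. The default
floor is $\max(5, \lceil 0.1\,n \rceil)$: an unconstrained scan will
happily isolate one or two extreme samples, which produces spurious
"risk groups" no clinician would accept. For $k > 2$ the boundaries are
initialized from the quantile split and refined coordinate-wise,
left-to-right, each boundary re-scanned with the others held fixed; a
boundary moves only when it strictly improves the full $k$-group log-rank
statistic, so the refinement cannot cycle, and a hard cap of 100 cycles
guards pathological inputs (hitting it is logged). Convergence is declared
after a full pass with no boundary change.

The scan's minimum p-value is a maximally selected statistic and is
optimistically biased. The package reports it as-is — fidelity to the
interactive tool this engine models comes first — but
`split_pvalue_bias_check()` computes an honest selection-adjusted p-value
by permuting the (time, event) pairs against the PI, re-running the full
optimization per permutation, and returning the fraction of permuted
minimum p-values at or below the observed one (at least 100 permutations
are required). The acceptance suite verifies that under the null the naive
optimized p rejects far above nominal while the adjusted p is calibrated.

## Survival statistics

The estimators are implemented from first principles; the test suite
cross-checks each against the `survival` package and against brute-force
oracles (direct product-limit enumeration, explicit O−E/V log-rank sums,
$O(n^2)$ concordance pair counting).

* **Kaplan–Meier**: product-limit over distinct event times,
  right-continuous.
* **Log-rank**: $k$-sample Mantel–Haenszel chi-square with hypergeometric
  variance, df $= k - 1$; a singular covariance (degenerate grouping)
  falls back to a generalized inverse; data with no events return
  statistic 0, p = 1.
* **Cox fitting**: Newton–Raphson on the partial likelihood with Efron
  (default, matching common practice for tied event times) or Breslow
  ties. Convergence when the gradient max-norm falls below 1e-8 or the
  relative log-likelihood change below 1e-9, capped at 50 iterations with
  step-halving; monotone likelihoods (e.g. a perfectly separating
  covariate) are flagged `converged = FALSE` with a warning rather than
  silently reported. Standard errors come from the inverse observed
  information.
* **Hazard ratio**: univariate Cox fit on the 2-group indicator, Wald CI;
  a group without events is flagged as unbounded.
* **Concordance**: Harrell's C. A pair is comparable when censoring leaves
  the ordering determinable (earlier time is an observed event, or equal
  times with exactly one event); tied scores earn half credit. Per-group
  concordance is computed by restricting to the group's samples — the
  within-group restriction is our reading, chosen because it matches how
  per-group insets are usually displayed.

## Time-dependent ROC

`td_roc()` implements the cumulative-case / dynamic-control ROC at a
user-supplied horizon $t$ (the horizon is never chosen automatically).
The `km` estimator plugs subset Kaplan–Meier survival into Bayes' rule;
it is fast and, with no censoring, reduces *exactly* to the empirical ROC
whose trapezoid AUC is the Mann–Whitney statistic — the property the test
suite asserts to 1e-10. Because the subset-KM plug-in need not produce a
monotone curve, the points are walked in decreasing threshold order and
isotonized by cumulative maxima. The `nne` estimator (default) smooths
$S(t\mid M=m)$ with a symmetric nearest-neighbour window of span
$0.25\,n^{-1/5}$ on the marker's percentile scale — the span published
with the original estimator — and is monotone by construction. Both
variants are exposed because the literature uses both; results at
moderate $n$ are close.

## Preprocessing, identifiers, probes

Expression is expected on the log2 scale. `preprocess()`'s `auto` mode
applies $\log_2(v + 1)$ only when the matrix maximum exceeds 50 — a value
no log2-scale microarray or RNA-seq matrix reaches but essentially every
linear-scale one does — making `auto` idempotent. Quantile normalization
(through `limma`, with tied values receiving the mean of the quantiles
they span) is optional and off by default, since public matrices are
usually already normalized. Missing values are imputed by the probe's
across-sample mean immediately before modeling (Cox requires complete
rows); a drop-sample policy is available by flag, and the imputation count
is always reported.

Identifier resolution against an NCBI `gene_info` index uses the
precedence exact Entrez id > official symbol > Ensembl/HGNC
cross-reference > synonym; synonym hits carry a lower-confidence note, and
a token matching several genes resolves deterministically to the lowest
Entrez id with an ambiguity note. This precedence is our policy — the
identifier types are standard but no authoritative ordering exists.
Multi-probe genes collapse by `max_row_average` (keep, verbatim, the probe
with the largest across-sample mean; ties to the lexicographically
smallest probe id), element-wise `mean`, or `max_variance`.

## Meta-base merging

`merge_cohorts()` follows a fixed recipe, in this order: per-cohort
quantile normalization; per-probeset mean equalization; merge on the
probeset intersection. The equalization target is the *unweighted* grand
mean of the cohort means, so a large cohort cannot drag the target toward
itself; each cohort's values are shifted, never scaled, which preserves
the cohort's standard deviation exactly (the audit table records pre/post
means and SDs per cohort × probeset). Probesets absent from any cohort
are dropped rather than merged with missingness, because the downstream
Cox model cannot represent structurally missing rows. No empirical-Bayes
batch correction is attempted — the recipe is deliberately simple and
auditable.

## The synthetic generator

`simulate_dataset()` draws per-gene normal expression on the log2 scale
(gene means uniform on 6–10, SDs on 0.5–1.5, the range typical of
normalized microarray data), centers the signature genes, and generates
event times from an exponential baseline scaled by $\exp(PI)$, so
`lambda` is the event rate of a median subject and the inverse-transform
is available in closed form for distributional checks. Censoring is an
independent exponential whose rate targets a 30% censored fraction by
default (rate $= \lambda f/(1-f)$, exact under null coefficients), or an
administrative cutoff. Defaults are $n = 200$, five signature genes with
coefficients $(0.7, -0.5, 0.3, 0, 0)$ — two strong effects, one moderate,
two nulls — and twenty noise genes.

What the generator does *not* emulate: probe-level measurement noise,
probe saturation, correlated gene modules, non-proportional hazards, and
informative censoring. Tests passing on these fixtures therefore
demonstrate the *estimators and the pipeline* are correct, not that any
particular signature works on real tumors; external cohorts remain the
only validation that matters clinically.

## Problem sizes and numerical tolerances in the test suite

The suite sizes its simulations for tight statistical checks at desk
scale: coefficient recovery uses 20 cohorts of $n = 2000$; the split
optimizer is checked against an exhaustive-scan oracle on 100 fixtures of
$n \le 200$; null calibration of the median split uses 2000 replicates of
$n = 60$, and of the permutation-adjusted optimized split 200 replicates
of $n = 40$ with 100 permutations each; time-dependent ROC null behavior
uses 20 cohorts of $n = 500$. Exact-agreement checks (KM, log-rank,
concordance, meta-base equalization, Mann–Whitney reduction) run at
1e-9 to 1e-12; agreement with `survival` for Cox coefficients at 1e-6.

## Known limitations

* No time-varying covariates, stratified baselines, frailty terms, or
  penalized (lasso/ridge) fits; signatures wider than the cohort's event
  count will produce unstable coefficients (a warning fires when events
  are scarce relative to signature size).
* The optimized split's naive p-value is biased by construction; use the
  permutation adjustment when the split location was not prespecified.
* The boundary located by the log-rank scan carries intrinsic positional
  noise; at moderate effect sizes (hazard ratio around 3) its localization
  error spans a few positions even at $n = 300$, so planted-boundary
  recovery to within ±2 positions is only reliable for sharp separations
  (hazard ratio around 6 or more). This is a property of maximally
  selected statistics, not of the implementation — the scan provably
  returns the exact argmin of its objective.
* `auto` log2 detection keys on the matrix maximum only; exotic scalings
  (ratios, z-scores with large outliers) should set `log2` explicitly.
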