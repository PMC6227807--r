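---
title: "Entropy landscapes of single-cell differentiation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy landscapes of single-cell differentiation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroscape)
```

## The model

`entroscape` treats single-cell gene expression "digitally": for each gene
and cell only the distinction *detected* (expression > 0) versus
*undetected* (exactly 0) is kept. This deliberately discards the continuous
part of the signal. The justification is statistical as much as
biological: discretizing a continuous expression scale into more than two
bins requires a bin count that is hard to justify when no natural
separation between expression levels exists, and entropy estimates depend
strongly on that choice, whereas zero versus non-zero is an instrumentally
defined boundary (the qPCR detection limit). Continuous (differential)
entropy is out of scope.

Within one cell population, each gene then has an empirical Bernoulli
distribution with on-fraction $p_1$, and the binary Shannon entropy

$$H(P) = -p_0 \log_2 p_0 - p_1 \log_2 p_1, \qquad 0 \log 0 := 0,$$

measured in bits, quantifies how heterogeneous the population is in that
gene's usage: 0 for a homogeneous population (all on or all off), 1 when
half the cells express it. For a gene pair, the joint distribution over the
four on/off states gives $H(P_{12}) \le 2$ bits, normalized by 2 for
comparability. Because

$$\bar H - \tfrac12 H(P_{12}) = \tfrac12 I(P_1; P_2)$$

whenever the two marginals coincide (and, after averaging over all pairs,
for the population aggregates exactly — see below), the gap between
marginal and joint profiles measures coordination between regulators.

The scientific question is how these entropies evolve along a
differentiation course. A population that mixes several discrete
configurations of a differentiation gene-regulatory network ("GRN
substates" — e.g. several alternative entry routes into a committed state)
has per-gene on-fractions pulled toward 1/2 *and* strongly correlated gene
pairs; it therefore shows a marginal-entropy peak with a joint entropy
noticeably below the marginal mean. The pipeline's trajectory stage makes
that signature visible and testable.

## Estimation

Three entropy estimators are provided, all operating on per-state counts:

* **ml** — the plug-in estimator, entropy of the empirical frequencies.
  Zero-probability states contribute exactly 0 through the
  $0\log 0 := 0$ convention; frequencies are never regularized with
  pseudocounts.
* **miller_madow** — plug-in plus the bias correction
  $(\hat m - 1)/(2n)$ nats (converted to bits), with $\hat m$ the number
  of *occupied* states. The correction is additive and ignores the
  $\log_2$ ceiling, so near-uniform small samples can exceed 1 bit per
  gene (counts (2,2) give 1.18 bits); such values are reported and
  flagged, not clipped, because the overcorrection is a property of the
  estimator worth seeing.
* **james_stein** — the Hausser–Strimmer shrinkage estimator: plug-in
  entropy of $\hat p_\lambda = \lambda/k + (1-\lambda)\hat p_{ML}$ with
  the closed-form intensity
  $\lambda = (1 - \sum\hat p^2)\,/\,[(n-1)\sum(1/k - \hat p)^2]$, clipped
  to $[0,1]$ and set to 1 when the denominator vanishes. A boundary case
  worth knowing: for counts (3,1) the unclipped $\lambda$ is exactly 1,
  so the estimate is exactly 1 bit, at the upper end of the interval
  between the plug-in value and the uniform maximum rather than strictly
  inside it.

All three were cross-checked against an independent reference
implementation during development; the agreement values are frozen in the
test suite. On populations of realistic size the three estimators never
reorder populations (a property test asserts identical rank order at 100
cells), so conclusions about *where* entropy peaks do not hinge on the
estimator; `ml` is the default.

### Uncertainty

Standard errors come from the non-parametric delete-one jackknife:
recompute the statistic $n$ times leaving out one observation unit, then

$$\mathrm{se} = \sqrt{\frac{n-1}{n}\sum_i (\hat\theta_{(i)} - \bar\theta)^2}.$$

Two design choices here were genuinely open:

* **The observation unit is the cell**, not the (cell, gene) entry. Cells
  are the independent sampling units of a single-cell experiment; genes
  within a cell are not independent (that dependence is precisely what the
  joint entropies measure), so deleting entries would understate the
  error. Deleting cell $i$ recomputes the full per-population aggregate
  from the remaining $n-1$ cells.
* **The reported central value is the full-sample estimate**, not the
  jackknife mean $\bar\theta$; the latter is retained in
  `jackknife()`'s result for diagnostics, but profiles plot estimates
  with error bars, not bias-corrected estimates. No jackknife bias
  correction, bootstrap, or grouped jackknife is attempted.

For the special case of a single gene the leave-one-out estimates take
only two values (delete an "on" cell or an "off" cell), which
`gene_entropy_table()` exploits; the result is bit-identical to the
generic loop, and a test asserts so.

## Aggregation

A population's **marginal entropy** is the unweighted arithmetic mean over
genes of per-gene entropies; its **joint entropy** is the unweighted mean
over all unordered gene pairs of $H(P_{12})/2$. The published per-population
numbers this mirrors do not state their aggregate; the mean is the only
simple choice that keeps aggregates on the per-gene $[0,1]$ scale, and it
has a second virtue: because every gene appears in the same number of
pairs, the identity

$$\text{mean marginal} - \text{mean normalized joint}
  = \tfrac12\,\overline{I}$$

holds *exactly* (to machine precision) for the aggregates, where
$\overline I$ is the mean pairwise mutual information — so the
marginal/joint gap retains its interpretation after averaging. Genes with
zero variance contribute entropy 0 and are **not** excluded; excluding
them would bias comparisons between populations with different numbers of
silent genes.

## Input conventions

Two published Ct-to-expression transformations are built in:

* `transform_ct_guo`: expression $= \max(0,\,28 - \mathrm{Ct})$, the
  log2-above-background convention with background Ct 28;
* `transform_dct_pina`: expression $= (30 - \Delta\mathrm{Ct})\ln 2$ below
  the detection limit of 30 cycles, else 0. The source description of
  this transform is typeset ambiguously (it can be parsed as
  $\ln(2^{30-\Delta Ct})$ or as $\ln(2^{30} - \Delta Ct)$); we implement
  the former. The choice is immaterial downstream: both readings agree on
  which values are undetected, and binarization consults nothing else.

Binarization is strict (`> 0`), matching the two-level convention; missing
values are rejected rather than imputed, because all estimators assume
complete binary observations. No cross-plate normalization is attempted.

## Trajectories and peak calling

The differentiation ordering is **user input** — a linear path or a
parent→child edge tree — never inferred from expression. Per edge, the
entropy delta and a combined-SE z-flag are reported; the significance
multiplier (`z = 2` by default) is configurable and recorded in every
report header, since the underlying studies report "significant" changes
without specifying a test. A population is a **peak** when its entropy
exceeds its predecessor's and every successor's along its root-to-leaf
path (the root qualifies on a monotone decreasing path; two siblings both
above their parent are both reported). If ties leave no strict peak, the
path argmax is reported.

## The synthetic generator: what it emulates, and what not

`stage_spec`/`sample_population` model a population as a **mixture of
static GRN substates**: each cell draws a substate by weight, each gene
then fires independently with that substate's on-probability (near 0 or 1
for "near-deterministic" configurations), and detection-limit dropout
censors each fired call to zero independently at a fixed false-negative
rate. Positive expression levels are log-normal; their parameters are
deliberately irrelevant — binarization erases them — and exist only to
exercise the transforms (both Ct output conventions invert the io
transforms exactly). There are no false positives: detection limits censor
low expression, they do not invent it.

Defaults, fixed once as the stated world of the tests: 3 stages ×
100 cells × 20 genes; one near-deterministic substate before and after
commitment; 2 equally weighted, pattern-rotated substates at the
commitment stage; firing probabilities 0.95/0.05; dropout 0.10 (a
plausible qPCR false-negative rate — no quantitative noise model is
available from the motivating datasets, so this is a fixture choice, not
an estimate). Under these defaults the commitment stage's true marginal
entropy (≈0.99) far exceeds the flanking stages' (≈0.43), and
`true_population_entropy()` supplies the exact mixture-implied values
(total probability over substates, genes conditionally independent within
a substate) as an oracle, aggregated exactly as the pipeline aggregates.

What the generator does **not** emulate: GRN dynamics (no ODEs or Boolean
updates — substates are static snapshots), plate/batch effects, expression
false positives, doublets, or realistic gene–gene dependence *within* a
substate. A green synthetic test therefore establishes that the pipeline
recovers entropy structure from substate-mixture data with dropout; it
does not establish anything about a particular biological dataset.

## Numerical choices and degenerate inputs

* All entropies in bits (base-2 logs); the Miller–Madow correction is a
  nats-scale quantity divided by $\ln 2$.
* Probability-sum invariants are enforced to $10^{-12}$; the
  $\tfrac12 I$ identity and jackknife closed forms are asserted to
  $10^{-12}$ in tests.
* Jackknife requires $n \ge 2$ cells (and the shrinkage estimator
  $n \ge 2$ observations, hence $n \ge 3$ cells under delete-one);
  single-cell populations are an error, not a silent NA.
* Mutual information is clipped at 0 against $-10^{-16}$-scale rounding.
* Determinism: a single integer seed drives everything stochastic;
  per-stage seeds are derived arithmetically from it, and results are
  independent of the order in which jackknife deletions are evaluated.

## Known limitations

* The entropy profile depends on the gene panel; panels are chosen for
  relevance to the process under study, so entropies are informative
  about that process only.
* Reproduction of the published six-population table is approximate by
  nature: the published aggregate is under-specified, and the uncertainty
  quoted there is labelled a standard deviation while the method described
  is a standard error; we implement the cell-deletion jackknife SE.
* Only pairwise joints are computed (no $k>2$ joint entropies), and only
  two expression levels are distinguished.
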