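# entroscape

Entropy landscapes of single-cell gene expression along differentiation
trajectories.

## The problem

During differentiation, stem and progenitor cells are often pictured as
rolling down a potential landscape, with gene-expression "disorder"
expected to decrease monotonically toward the mature cell type. Single-cell
RT-qPCR panels make that picture testable: for each cell population one can
ask how heterogeneous the on/off usage of a regulator panel actually is.
The informative statistic is the **binary Shannon entropy**. For a gene
whose detection probability in a population is *p*,

    H(P) = -p0 log2 p0 - p1 log2 p1        (bits; 0 log 0 := 0)

which is 0 when the gene is uniformly silent *or* uniformly expressed and
maximal (1 bit) when half the cells express it. For a gene pair with joint
on/off probabilities *p00, p01, p10, p11*,

    H(P12) = -sum_ij p_ij log2 p_ij        (at most 2 bits; normalized by /2)

and the gap between mean marginal and mean normalized joint entropy equals
half the mean pairwise mutual information `I = H(P1) + H(P2) - H(P12)`, a
direct readout of coordination between regulators.

`entroscape` implements this analysis end to end:

* **io** — delimited-table reader/writer, the two published qPCR
  conventions (raw Ct below a background of 28; delta-Ct below a detection
  limit of 30), strict `> 0` binarization;
* **entropy** — maximum-likelihood, Miller–Madow and James–Stein
  (Hausser–Strimmer) shrinkage estimators, joint entropy, mutual
  information, Bernoulli variance;
* **resampling** — delete-one-cell jackknife standard errors,
  `se = sqrt((n-1)/n * sum((theta_(i) - theta_bar)^2))`;
* **pipeline** — per-population marginal/joint entropy profiles, per-gene
  entropy tables, pairwise joint-entropy matrices, and entropy trajectories
  with peak detection along a user-supplied linear or branching population
  ordering (the ordering is an input; no pseudo-time inference);
* **synthetic** — a seeded generator in which each population is a mixture
  of discrete GRN substates (static on/off configurations) with
  detection-limit dropout, plus an exact analytic oracle for the implied
  entropies.

The scientific signature the pipeline is built to detect: a population that
mixes several regulatory substates — as at a commitment point reachable by
multiple paths — shows a transient **entropy peak**, not the monotone
decrease the landscape metaphor suggests.

## Worked example

A bundled synthetic dataset (three stages of 30 cells, 10 genes; the middle
stage mixes two complementary GRN substates) ships in `inst/extdata`:

```r
library(entroscape)
path <- system.file("extdata", "synthetic_commitment.csv", package = "entroscape")
m <- read_expression_table(path, dialect = "csv")
b <- binarize(m)
profile <- population_entropy_profile(b, estimator = "ml")
print(profile, digits = 3)
#>   population marginal_entropy marginal_se joint_entropy joint_se n_cells n_genes
#> 1        pre            0.349      0.0437         0.342   0.0418      30      10
#> 2     commit            0.982      0.0290         0.783   0.0378      30      10
#> 3       post            0.409      0.0495         0.400   0.0483      30      10
entropy_trajectory(profile, c("pre", "commit", "post"), z = 2)
#> entropy trajectory (marginal, z = 2): peak at commit
#>   parent  child      delta   se_delta significant
#> 1    pre commit  0.6327663 0.05248003        TRUE
#> 2 commit   post -0.5733064 0.05739415        TRUE
```

Reading the output: each population's `marginal_entropy` is the mean over
genes of the per-gene binary entropy (0 = homogeneous, 1 = maximally
heterogeneous), with a jackknife SE from deleting one cell at a time;
`joint_entropy` is the mean over gene pairs of `H(P12)/2` and sits below
the marginal mean exactly when genes are correlated. Here the commitment
stage's entropy (0.98) towers over its neighbours (0.35, 0.41); both edges
of the trajectory change by more than `z = 2` combined SEs, and the peak is
called at `commit`. The per-gene view (`gene_entropy_table(b)`) adds the
on-fraction `p1`, distinguishing "entropy 0 because always on" from
"entropy 0 because always off".

The same analysis runs from the shell:

```sh
Rscript inst/scripts/entroscape run \
  --input inst/extdata/synthetic_commitment.csv \
  --ordering inst/extdata/synthetic_ordering.txt \
  --outdir out --estimator ml --seed 1
Rscript inst/scripts/entroscape simulate \
  --scenario inst/extdata/synthetic_commitment_scenario.txt --seed 7 --out sim.csv
```

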