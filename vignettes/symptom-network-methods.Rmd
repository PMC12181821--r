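---
title: "Methods: comorbidity and symptom-network analysis for prolonged grief and complex PTSD"
author: "griefnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comorbidity and symptom-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(griefnet)
```

## Scope and model

`griefnet` analyses item-level interview and questionnaire data from
bereaved, trauma-exposed samples along two tracks:

1. **Comorbidity**: ICD-11 diagnostic algorithms for probable prolonged
   grief disorder (PGD, from the 22-item TGI-SR+ on a 1–5 scale), PTSD and
   complex PTSD (from CAPS-5 items and the five COPISAC items, 0–4 scale),
   with multiple imputation of missing item responses and Rubin-rules
   pooling of prevalences and correlations.
2. **Symptom network**: a regularized partial-correlation network over 13
   symptom nodes — seven PGD symptoms (preoccupation `Pr`, yearning `Ye`,
   difficulty accepting the loss `AL`, bitterness/anger `BA`, difficulty
   engaging in activities `ML`, emotional numbness `Nu`, feeling one has
   lost part of one's self `PD`) and six cPTSD symptom clusters
   (re-experiencing `Re`, avoidance `Av`, sense of current threat `Th`,
   affective dysregulation `ad`, negative self-concept `NSC`, disturbances
   in relationships `DR`). Four clusters are two-item sums (`Re`, `Av`,
   `Th`, `DR`); the rest are single items.

The network model is a Gaussian graphical model on latent continuous
symptom variables: observed ordinal responses are treated as discretized
latent normals, their correlation matrix is estimated polychorically, and
the sparse precision matrix is estimated by the graphical lasso

$$\hat\Theta = \arg\max_\Theta \;\log\det\Theta - \mathrm{tr}(S\Theta)
  - \lambda \sum_{i \ne j} |\Theta_{ij}|,$$

with the penalty chosen by the extended BIC,
$\mathrm{EBIC}_\gamma = -n\,[\log\det\Theta - \mathrm{tr}(S\Theta)] +
E\log n + 4 E \gamma \log p$, where $E$ counts selected edges. Edge
weights are the regularized partial correlations
$w_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gamma` | 0.5 | EBIC hyperparameter; larger favours sparser graphs. 0 reduces to BIC. |
| `n_lambda`, `lambda_min_ratio` | 100, 0.01 | log-spaced penalty path from $\lambda_{max}$ (empty graph) down to $\lambda_{max}/100$. |
| `m` | 20 | number of imputations. |
| `max_iterations` | 10 | FCS sweeps per imputation chain. |
| `donor_pool` | 5 | PMM donors per missing cell. |
| `max_predictors` | 15 | predictors per conditional imputation model (highest absolute Spearman correlation on pairwise-complete data), keeping conditional models small relative to $n$. |
| `n_boot` | 1000 | bootstrap replicates for edge and centrality stability. |
| `cs_correlation`, `cs_probability` | 0.7, 0.95 | CS-coefficient rule: largest drop fraction whose subset centralities correlate $\ge 0.7$ with the full sample in $\ge 95\%$ of replicates. |
| `drop_range` | 0.05–0.75 | case-dropping range, in fractions of $N$; drop counts are sampled as integers, which at $N = 92$ yields the $k/92$ granularity visible in CS values. |

## Stacked estimation over imputations

Estimating one network per imputed dataset can select different graphs per
imputation. Instead all $m$ completed datasets are concatenated and a
single polychoric matrix and EBIC-glasso fit are computed, with the
effective sample size set to the original $N$ (not $N\,m$): stacking
duplicates information rather than adding observations, and using $N$
keeps the EBIC's complexity penalty honest. With $m$ identical imputations
this reduces exactly to single-dataset estimation (a tested contract).

## Centrality

Strength is the sum of absolute incident edge weights; bridge strength
restricts the sum to edges crossing between the two theoretical
communities, which are fixed to PGD = {Pr, Ye, AL, BA, ML, Nu, PD} versus
cPTSD = {Re, Av, Th, ad, NSC, DR} — PTSD and DSO clusters are one
community because a cPTSD diagnosis requires both. "Sum of edges" is read
as sum of absolute weights (the signed variant is available via
`absolute = FALSE`); z-standardized versions are computed alongside, and
the raw absolute sums are the headline values.

## Stability

Interval estimates under missing data use bootstrap-then-impute: resample
$N$ participants with replacement from the *original incomplete* data,
impute each bootstrap sample `m_per_boot` times, re-estimate the stacked
network, and take percentile confidence intervals of the replicate edge
weights. Centrality stability uses case-dropping subset bootstrap: a drop
count $k$ is drawn uniformly from the integer range spanned by
`drop_range`, $N-k$ participants are subsampled without replacement, the
whole impute–estimate–centrality pipeline is rerun, and the Pearson
correlation with the full-sample centralities is recorded. The
CS-coefficient is the largest $k/N$ such that *every* level up to $k$
retains correlation $\ge 0.7$ with probability $\ge 0.95$; requiring all
smaller levels to pass makes the definition monotone and robust to
single-level sampling flukes. Replicates with undefined correlations
(zero-variance centralities, e.g. an empty selected network in a small
subset) are recorded as missing and excluded from CS with a warning;
bootstrap samples with a constant node column are redrawn.

## Numerical choices

- **Graphical lasso**: blockwise coordinate descent with an Rcpp inner
  loop, warm starts along the penalty path, and convergence certified by
  the off-diagonal KKT residual of $\Theta^{-1} = S + \lambda\,
  \mathrm{sign}(\Theta)$ falling below $10^{-7}$ (a scalar trace identity
  proved too weak and accepted suboptimal fits). Off-diagonal entries
  below $10^{-8}$ are snapped to exact zero so edge support is well
  defined — without this, a phantom $10^{-17}$ coefficient at
  $\lambda_{max}$ leaves no truly empty model on the path. The solver
  matches an independent ADMM solution of the same objective to
  $\sim 10^{-7}$ elementwise. EBIC ties select the smallest penalty.
- **Polychoric correlations**: two-step estimation (thresholds from
  marginal quantiles, then univariate likelihood optimization over
  $\rho \in (-0.999, 0.999)$), with the bivariate normal CDF computed by
  Gauss–Legendre quadrature of the arcsine-transformed correlation
  integral and an asymptotic tail branch for $|\rho| > 0.925$ (accuracy
  ~$10^{-10}$ against a quadrature oracle). Pairwise matrices are made
  positive definite by eigenvalue clipping at $10^{-6}$ and rescaling to
  unit diagonal. Perfectly associated pairs clip at $\pm 0.999$; constant
  columns are an error naming the node.
- **PMM**: Bayesian least squares (residual variance from its scaled
  inverse chi-square, coefficients from the normal posterior), type-1
  matching, uniform draw among the $k$ nearest donors with random
  tie-breaking; singular designs fall back to a small fixed ridge.
  Logistic imputation draws from the asymptotic posterior; complete
  separation falls back to a ridge-penalized fit, a single observed class
  is imputed deterministically.
- **Reproducibility**: every stage derives its stream from one integer
  seed via a label-hashing splitter, so toggling stages does not shift
  other stages' draws, and identical seeds give bitwise-identical
  artifacts.

## The synthetic cohort generator

No raw study data are distributable, so the generator emulates the data
*structure*: a ground-truth sparse partial-correlation network over the 13
nodes (default density 0.5, weights drawn uniformly in $[-0.04, 0.49]$
with ~5% negative, then made positive definite by support-preserving
diagonal inflation, which shrinks realized weight magnitudes), latent
multivariate normal draws cut at per-node thresholds, two-item clusters
split uniformly over feasible item decompositions, and the remaining
instrument items generated from a general severity factor (loading 0.7).
Thresholds are equiprobable because item marginals are not publishable;
latent mean shifts per instrument (defaults 0, +0.8, −0.4 for
TGI/CAPS/COPISAC) were fixed once so that realized probable prevalences
fall in the regime reported for treatment-seeking refugee samples (PGD
~30%, PTSD ~55–65%, cPTSD ~15–20%); months since loss follow a gamma
distribution with mean 96 and SD 80 months; everyone is bereaved and
trauma-exposed (inclusion criteria). Missingness is injected per scale
(MCAR by default, MAR via a logistic model on a fully observed covariate)
at rates within the 0.8–5.7% range typical of such studies.

What the generator does **not** emulate: sociodemographic structure,
interpreter or cultural response effects, item-level marginal skew, and
the coupling of severities is simpler than reality (a single general
factor makes severity scores correlate more strongly across instruments
than the low cross-instrument correlations seen in heterogeneous trauma
samples). Passing tests therefore validate the *algorithms* under a
realistic data shape, not distributional fidelity to any particular
cohort.

## Test and simulation scale

Deterministic contracts are tested exactly; simulation-based checks use
fixed seeds at sizes chosen to keep the default suite fast: polychoric
recovery at $n = 5000$, edge recovery at $n = 500$, bootstrap checks at
$B = 200$–400 with shortened penalty paths (25–40 penalties), and the
end-to-end script runs $N = 92$ with $m = 20$ imputations and $B = 100$
stability replicates with `m_per_boot = 2`. The algorithms are identical
at full scale ($B = 1000$, `m_per_boot = 20`); only the replicate counts
are configuration.

## Known limitations and open design points

- With a dense generating graph (density 0.5) and uniform weights, EBIC
  selection at $\gamma = 0.5$ favours sensitivity over specificity at
  moderate $n$: at $n = 500$ the selected support recovers the strongest
  true edges reliably (the 4 largest in 8/8 seeds) but re-includes ~30% of
  true zeros. High-specificity behaviour re-emerges at small $n/p$ (e.g.
  $N = 92$), where the selected graph is much sparser.
- Whether the original instruments' DSO severity sum includes the
  relationship item from the CAPS is ambiguous; the default DSO severity
  is the three COPISAC DSO items with `dso_include_caps13 = TRUE` as an
  option. The node table, by contrast, always builds the relationship
  cluster as CO3 + CAPS 13.
- The CAPS duration criterion is consumed as a duration-satisfied
  indicator (any rating $\ge 1$ on the stored column), since the
  algorithms treat it as a gate, not a severity.
- Unknown months-since-loss must be supplied by the caller (imputed, or a
  documented floor value such as 12 months); the diagnosis function never
  assumes one.
- Mean edge weight is reported under both conventions (all pairs /
  nonzero edges); all-pairs is the headline.
- Case-dropping re-imputes each subset rather than reusing imputations,
  mirroring the edge-weight bootstrap.
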