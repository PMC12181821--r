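# griefnet

Comorbidity and symptom-network analysis for prolonged grief disorder
(PGD) and complex post-traumatic stress (cPTSD) from item-level clinical
data.

Bereaved, trauma-exposed people — refugee and other treatment-seeking
populations in particular — frequently meet criteria for both prolonged
grief and (complex) PTSD. Understanding that comorbidity requires two
complementary analyses: classic prevalence/comorbidity rates from ICD-11
diagnostic algorithms, and a symptom-network view that asks which
individual symptoms connect the two syndromes. `griefnet` implements the
full pipeline for both, designed for the realistic situation of a small
clinical sample (N ≈ 92) with item-level missingness:

- **Diagnostic scoring** for the TGI-SR+ (22 grief items, 1–5), CAPS-5
  and COPISAC (0–4) instruments: severity sums, probable ICD-11 PGD /
  PTSD / cPTSD algorithms (cPTSD supersedes PTSD), and McDonald's ω from
  a one-factor model.
- **Multiple imputation** by fully conditional specification with
  predictive mean matching (donor pool of 5) and logistic steps, plus
  Rubin-rules pooling of prevalences and Fisher-z pooling of
  correlations.
- **Network estimation**: polychoric correlations (data modelled as
  ordinal), graphical lasso over a penalty path with extended-BIC
  selection (γ = 0.5), estimated once on all imputations stacked with the
  effective sample size reset to N. The model is

  $$\hat\Theta = \arg\max_\Theta\; \log\det\Theta - \mathrm{tr}(S\Theta)
     - \lambda\textstyle\sum_{i\neq j}|\Theta_{ij}|,\qquad
     w_{ij} = -\hat\Theta_{ij}/\sqrt{\hat\Theta_{ii}\hat\Theta_{jj}}$$

- **Centrality**: strength and bridge strength over the two theoretical
  communities (7 PGD symptoms vs 6 cPTSD symptom clusters).
- **Stability**: bootstrap-then-impute percentile CIs for edge weights,
  case-dropping subset bootstrap for centralities, and CS-coefficients
  (largest proportion of cases droppable while subset centralities
  correlate ≥ 0.7 with the full sample in ≥ 95% of replicates).
- **Synthetic cohorts**: a generator for ground-truth networks and full
  instrument-level datasets (latent Gaussian → ordinal items, per-scale
  missingness), so the whole pipeline is testable without confidential
  patient data.

## Worked example

```r
library(griefnet)

# synthetic study-scale cohort: N = 92, 13-node true network of density 0.5,
# per-scale missingness in the 0.8-5.7% range
net    <- true_network(p = 13, density = 0.5, weight_low = -0.04,
                       weight_high = 0.49, seed = 1)
cohort <- generate_cohort(92, net = net, seed = 1)
cohort <- inject_missingness(cohort, c(TGI = 0.03, CAPS = 0.008,
                                       COPISAC = 0.02, META = 0.057), seed = 1)

# impute, diagnose, pool
stack <- fcs_impute(cohort$data[-1], imputation_config(m = 20, seed = 1))
prev  <- prevalence_and_comorbidity(stack)

# stacked ordinal network + centrality
fit <- symptom_network(stack, gamma = 0.5)
print(fit)
centrality(fit)
```

Output:

```
PGD 31.41% (n=29), PTSD 56.68% (n=52), cPTSD 20.49% (n=19)
among PGD cases: 52.42% comorbid PTSD, 47.58% comorbid cPTSD

Regularized partial-correlation network (EBIC graphical lasso)
  nodes: 13, n = 92, gamma = 0.50, selected lambda = 0.1267
  edges: 36 of 78 (density 0.462)
  edge weights: mean (all pairs) 0.058, range [0.007, 0.331]

 node community strength bridge_strength
   AL       PGD    1.337           1.005
   Pr       PGD    1.027           0.681
   Re     cPTSD    0.956           0.956
   BA       PGD    0.913           0.610
```

Read: with 20 imputations pooled, 31% of the synthetic cohort meets
probable PGD and half of those also meet PTSD or cPTSD criteria. The
EBIC-selected network keeps 36 of 78 possible edges (density 0.46, mean
weight over all pairs 0.058); *difficulty accepting the loss* (`AL`) has
the highest strength and bridge strength, i.e. the most absolute
partial-correlation mass overall and across the PGD–cPTSD boundary.

`run_pipeline()` chains every stage (impute → diagnose → network →
centrality → stability) on a cohort CSV and writes all artifacts (edge
lists, GraphML, centrality/replicate tables, CS coefficients) with a
manifest; reruns with the same seed are bitwise identical. See the
methods vignette (`vignettes/symptom-network-methods.Rmd`) for the model,
estimation and design choices.

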