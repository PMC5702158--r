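---
title: "Gene-tissue expression signatures for warfarin dose: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-tissue expression signatures for warfarin dose: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosesig)
```

## The problem

Warfarin's therapeutic weekly dose varies more than tenfold between patients.
The IWPC pharmacogenetic algorithm — a published linear model on the
square-root weekly-dose scale using age, height, weight, VKORC1 and CYP2C9
genotype classes, race, enzyme-inducer co-medication and amiodarone — explains
roughly half of that variance. `dosesig` implements a transcriptomic approach
to the *residual*: impute each patient's genetically regulated, tissue-specific
gene expression from their genotypes alone, and ask whether a stable set of
gene-tissue pairs ("a signature") explains the dose variation the IWPC
algorithm leaves behind.

Because both the multi-tissue reference panel and clinical warfarin cohorts
that motivate this design are controlled-access, the package pairs the
analysis pipeline with a first-class synthetic-data module that generates
reference panels and patient cohorts with the statistical structure the
analysis assumes — and with ground truth, so every stage can be tested for
recovery, calibration and determinism.

## The model, stage by stage

### Cis-genetic control of expression (synthetic reference panel)

For gene $g$ in tissue $t$, expression of individual $i$ is

$$ e_{i} = \sum_{j \in \mathrm{causal}(g,t)} w_j \, d_{ij} + \varepsilon_i,
 \qquad \varepsilon_i \sim N(0, \sigma^2), $$

where $d_{ij} \in \{0,1,2\}$ is the alternate-allele dosage (drawn
Binomial(2, MAF), MAF uniform on a configurable range, SNPs independent) and
$\sigma^2$ is scaled so that the genetic fraction of expression variance
equals the configured cis heritability $h^2$:
$\sigma^2 = \mathrm{var}(g)\,(1-h^2)/h^2$. A configurable fraction of
gene-tissue pairs (`prop_regulated`, default 0.5) carries nonzero weights;
the remainder is pure standard-normal noise, giving the eQTL-eligibility
filter genuine negatives. This linear-in-dosage Gaussian model is the
simplest one consistent with every downstream linear method; it deliberately
omits linkage disequilibrium, population structure and any non-genetic
covariance between tissues (see *Limitations*).

### Cis window and eQTL eligibility

A variant is *cis* to a gene when it lies within 1 Mb of the gene's outer
bounds; the boundary is inclusive (a SNP at exactly 1 Mb qualifies), a
convention we fix and test explicitly because boundary SNPs are otherwise an
invisible coin toss. The eQTL scan regresses each tissue's expression on each
cis dosage (two-sided t-test on the slope) and converts p-values to q-values
by Benjamini–Hochberg within each tissue. A gene-tissue pair enters the
feature universe when its minimum q-value is at or below 0.05 — again
boundary-inclusive.

### Expression imputation

Per eligible pair, a LASSO regression of reference expression on cis dosages:

* penalty grid: 100 log-spaced values from $\lambda_{\max}$ (smallest penalty
  with an all-zero model) down to $10^{-3}\lambda_{\max}$;
* fivefold cross-validation, minimal mean squared error; ties resolved toward
  the larger penalty (the sparser model);
* refit on all reference individuals at the chosen penalty;
* predictors and response are used on their raw scales (no standardization),
  so weights read as expression change per alternate allele, and the
  intercept absorbs centering.

Path fitting is delegated to `glmnet` at a moderate convergence threshold
(full-accuracy paths are needlessly slow near the grid's small-$\lambda$ tail
when $p \gtrsim n$); the model returned at the selected penalty is then
polished by cyclic coordinate descent to subgradient optimality ($10^{-8}$),
so every fitted model verifies the L1 optimality (KKT) conditions via
`kkt_violation()`, which the test suite checks systematically at
$10^{-6}$. Single-predictor designs use the closed-form soft-threshold
solution.

Two deployment strategies mirror two realities of genotyping platforms:

* **cohort-specific** — retrain each model using only the SNPs the target
  cohort actually measured (after harmonization), so the model transfers
  without substitution; its support is contractually a subset of the
  cohort's SNP set and violation is an error, not a warning;
* **generic** — one pre-trained weights database applied to any cohort; a
  model SNP the cohort did not measure contributes its reference-panel mean
  dosage, which (after centering) equals dropping the term. The database is
  a plain TSV (gene, tissue, variant, alleles, weight, reference mean;
  intercept rows flagged `__intercept__`), round-trip tested.

### Genotype plumbing

Cohort and reference platforms are harmonized by `(chrom, pos)`: exact
ref/alt matches map directly; swapped alleles map with the dosage flip
$d \to 2-d$; strand-ambiguous swaps (A/T, C/G) and allele mismatches are
excluded, because for the A/T and C/G pairs an allele swap cannot be
distinguished from a strand flip without allele-frequency heuristics that a
controlled synthetic world cannot test. Missing genotype calls (the module
plants 0–1.1% missingness, the range seen across real warfarin cohorts) are
imputed by k-nearest neighbours ($k = 5$): distance is the Euclidean distance
over variants non-missing in both individuals normalized by their count,
each missing entry takes the unrounded mean of the $k$ nearest donors
observed at that variant, and ties at the $k$-th donor break by input order.
Imputed dosages are deliberately left fractional — every downstream model is
linear in dosage. Cross-platform concordance counts any disagreement or
missing call as a mismatch.

### Signature learning

On a training cohort, weekly dose (mg/week) is regressed on the full imputed
feature matrix with the same LASSO-plus-fivefold-CV convention. The
procedure is repeated 100 times with different random CV partitions (repeat
$r$ reseeds the fold assignment with `seed + r`), and the signature keeps
the pairs with a nonzero coefficient in a *strict* majority of repeats:
51/100 is in, 50/100 is out. We train on raw observed dose rather than IWPC
residuals or square-root dose — residualization belongs to validation in
this design — but `fit_lasso_cv()` accepts any response vector, so either
convention is one argument away. Dichotomized (extreme-dose) training
cohorts are handled as continuous doses of the retained patients; no
classification model is involved.

### Validation and empirical nulls

For a validation cohort, the IWPC prediction is computed from covariates
(coefficients ship as a data file with provenance in its header — they are
configuration, not code), the residual dose is `observed - predicted`, and
the signature's in-sample $R^2$ from OLS of residuals on all signature
features jointly is compared against two empirical nulls:

* **shuffled dose** — residuals permuted 10,000 times against fixed features;
* **random signatures** — 10,000 equal-sized feature sets drawn uniformly
  without replacement from the non-signature pairs, scored on the true
  residuals.

Empirical p-values use the add-one rule $p = (1 + \#\{R^2_{\mathrm{null}}
\ge R^2\})/(1+N)$, so $p$ is never 0 and bottoms out at $1/(N+1)$. FDR
control (Benjamini–Hochberg, 0.05) is applied across all signature-by-cohort
tests, separately per null family, since the two nulls answer different
questions. Permutation scoring uses a precomputed orthonormal basis of the
design's column space, so $10^4$ permutations cost a single matrix product.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| cis window | 1e6 | bp | field-standard cis definition; inclusive bounds |
| eQTL q threshold | 0.05 | — | eligibility filter, boundary inclusive |
| CV folds | 5 | — | model selection for both imputation and signatures |
| penalty grid | 100 pts, $10^{-3}$ span | — | fixed so fits are reproducible; ties → sparser |
| stability repeats | 100 | — | resolves selection frequencies to 1% |
| selection threshold | 0.5 (strict) | — | majority vote over repeats |
| permutations / draws | 10,000 | — | p-value floor ~1e-4 |
| kNN neighbours | 5 | — | genotype missingness imputation |
| dichotomization | ≤35 / >49 | mg/week | extreme-dose training design |
| `h2` | 0.5 | — | simulation: cis heritability of regulated pairs |
| `prop_regulated` | 0.5 | — | simulation: gives the eligibility filter true negatives |
| `dose_noise_sd` | 4 | mg/week | simulation: residual dose noise |

The simulation parameters (`h2`, planted effect sizes, `dose_noise_sd`,
`prop_regulated`) are not quantities any clinical study reports; the
defaults were chosen once so that recovery tests have statistical power at
desk scale, and are not tuned per test.

## Randomness and reproducibility

All randomness flows from one master seed through a documented splitting
rule (`derive_seed()`): stage code times a large constant plus a repeat
index, modulo $2^{31}-1$. Reference panel, each cohort, fold assignments,
stability repeats and both nulls therefore re-run independently and
bit-identically. The pipeline manifest records the master seed, derived
stage seeds, stage timings and an MD5 digest of every artifact; identical
seeds reproduce identical digests (timings aside).

## Numerical choices and degenerate inputs

* LASSO path threshold 1e-5, final coordinate-descent polish to KKT 1e-8;
  violations verified at 1e-6.
* Rank-deficient evaluation designs drop collinear columns (pivoting order,
  deterministic) with a warning rather than ridge-stabilizing.
* Zero-variance dosages are skipped in the eQTL scan; zero-variance features
  are excluded from correlation averages; a constant feature in
  `single_feature_report()` returns a defined-failure row, not an error.
* Negative predicted sqrt-doses clamp to 0 with a warning (unreachable for
  sane coefficient files).
* `h2 = 1` forces zero expression noise; `h2 = 0` removes all true weights.
* Empty harmonization mappings and empty weights databases are legal,
  logged states; an empty predictor set for a requested model is an error
  distinct from ineligibility.

## What the synthetic world does and does not show

The generator emulates: sparse cis control with tunable heritability,
multi-tissue structure, partial SNP overlap between platforms,
0.02–1.1% MCAR missingness, IWPC covariates from simple independent
distributions, and dose as IWPC prediction plus planted gene-tissue effects
plus Gaussian noise, with optional extreme-dose dichotomization. It does
*not* emulate linkage disequilibrium, population structure or admixture,
cross-tissue expression correlation beyond shared genotype, realistic
covariate joint distributions, or platform-specific genotyping error.
Passing recovery tests therefore demonstrate that the pipeline's inference
machinery is correct and calibrated under its own assumptions — not that the
signature approach succeeds on real cohorts, where LD, ancestry mismatch
between reference panel and patients, and hidden confounding all bite. That
caveat is the honest boundary of any synthetic validation.

A related empirical observation from our simulations: with the CV-minimal
penalty, stability selection does not control false selections tightly.
On pure-noise data a dataset's strongest spurious features can survive
majority voting because all repeats share the same data; in the regime the
method targets (features ≫ samples) this dilutes and null signatures are
empty or near-empty in the large majority of draws, but at feature counts
comparable to the sample size they are not. With strong planted signal the
CV-minimal penalty deliberately under-shrinks, admitting on the order of
20 features per repeat, and the strict majority then retains a sizeable
cohort of stable false pairs alongside a perfectly recovered planted set
(the acceptance script reports both medians). The permutation machinery
downstream — not the selector — is what guards error rates; we document
this rather than pretend stability selection is a hypothesis test.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the whole pipeline at reduced
scale, chosen as the package's own testing design: reference panels of
120–300 individuals, 4–60 genes over 2–3 tissues, 12–50 cis-SNPs per gene,
cohorts of 60–200 patients, 100 stability repeats where selection frequency
matters (fewer in smoke tests), and 500–10,000 permutations depending on the
check. Null-calibration checks use 1,000 replicate datasets at 500
permutations each.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_ref = 150, n_cohort = 100, n_genes = 10, n_tissues = 2,
  snps_per_gene = 15, n_causal_snps = 3, h2 = 0.6, prop_regulated = 0.8,
  signature_pairs = data.frame(gene_id = c("G001", "G003"),
                               tissue = "tissue01", effect = c(6, -5)),
  dose_noise_sd = 2, seed = 1)

run <- run_pipeline(cfg, repeats = 100, n_perm = 2000)
run$report          # R^2, empirical p, q per signature x validation cohort
autoplot(run$signatures[[1]])
autoplot(run$evals[[1]])
```

## Known limitations

* Independent SNPs only; block-LD is future work, and without LD the
  "clumps of correlated predictors" failure mode of the LASSO is untested.
* The generic-versus-cohort-specific comparison shares one synthetic
  reference panel; real PredictDB-style databases built on other panels are
  not consumed (the weights TSV is this package's own minimal schema).
* In-sample validation $R^2$ (by design, matching the analysis it
  implements) — no further train/test split inside validation cohorts.
* Training uses raw dose; the alternative conventions (sqrt dose, residual
  dose) are exposed but not the default.
* IWPC coefficients ship for the published pharmacogenetic algorithm only;
  the clinical-only variant is out of scope.
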