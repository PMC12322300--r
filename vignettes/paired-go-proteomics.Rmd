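---
title: "Methods: paired tumor/skin DIA proteomics with GO-level mixed models"
author: "pairProteo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired tumor/skin DIA proteomics with GO-level mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairProteo)
```

# The scientific problem

Cutaneous neurofibromas (cNFs) are benign nerve-sheath tumors that occur
by the hundreds in people with neurofibromatosis 1. Because any therapy
must act on the tumor without harming the skin directly above it, the
relevant comparison is not tumor versus arbitrary skin but each cNF
versus the skin overlying that same lesion. pairProteo implements the
statistical pipeline for such matched-pair comparisons of
data-independent-acquisition (DIA) mass-spectrometry protein
quantities: each excision yields one tumor and one skin sample, giving
a nested design of patients, excision pairs ("lesions"), and two
tissues per pair.

The pipeline starts from an already-normalized protein × sample
quantity matrix (normalization is performed upstream by the DIA search
software); raw spectra, spectral libraries and acquisition parameters
are out of scope.

# Data model

A `ProteinQuantMatrix` extends `SummarizedExperiment`: the `quantity`
assay holds positive intensities with `NA` marking undetected cells,
the `npep` assay peptide counts, `rowData()` the per-protein
identification P value, and `colData()` the design (patient, lesion
pair, tissue, growth status). Tissue is a factor with skin as the
reference level, so every exponentiated model coefficient is a
cNF/skin ratio. GO annotations live in a `GOAnnotationMap`, restricted
to proteins present in the dataset; annotations are used exactly as
listed, with no propagation to ancestor terms over the GO graph
(term-level results then reflect the annotation source, not a graph
closure — a deliberate, configurable choice, `propagate = FALSE`).

# Confidence filtering

A protein is retained when its identification P value is strictly
below 0.05 and it was identified by at least two peptides in at least
one sample. Both thresholds are configuration entries
(`filters$p_max`, `filters$min_peptides`); the comparisons are strict
(`<`) and inclusive (`>=`) respectively, and the filter is idempotent.

# Missing values: informative versus random

DIA matrices mix two missingness mechanisms. A value can be missing at
random (MAR: technical dropout unrelated to abundance) or missing
because the protein's expression lies below the limit of detection
(LOD) — which is informative. The classification rule assumes at most
20% MAR: if a protein is quantified in at least 80% of the samples of
one tissue, detection of that protein is considered reliable, and a
missing fraction in excess of 20% in the *other* tissue is attributed
to below-LOD expression. Those cells are imputed with the single
minimum quantity observed anywhere in the dataset; all other missing
cells stay missing and are simply absent from model likelihoods. A
protein below 80% detection in both tissues is never imputed, so
proteins that are merely labile or poorly measured are not pushed to
the detection floor.

Three numerical choices matter here:

* **Boundary arithmetic.** 12 detected out of 15 is exactly 80%, and
  `0.8 * 15 > 12` in double precision. Detection and missingness
  fractions are therefore compared exactly (the threshold is
  rationalized to denominator 10^6 and both sides compared as
  integer-valued products), so the `>= 80%` and `> 20%` boundaries
  behave as written for any sample count.
* **All versus excess.** "Missing in excess of 20%" could mean
  imputing all missing cells of a qualifying protein/tissue, or only
  the count above the 20% allowance. Missing cells within a tissue are
  exchangeable, so imputing an arbitrary subset is hard to defend; the
  default mode imputes all of them (`imputation$mode = "all"`), and an
  `"excess"` mode (first cells in sample order) is provided for
  sensitivity analysis.
* **Ordering.** The dataset minimum is computed on the
  confidence-filtered matrix, before imputation; the choice is
  recorded in the run report.

`classifyMissingness()` is validated against an independently written
brute-force implementation of the rule on hundreds of random matrices.

# GO-term roll-up and the mixed model

A GO term is analyzed when more than four distinct dataset proteins
carry the annotation (at least `go$min_proteins = 5`). For each term,
every non-missing (protein, sample) cell becomes one observation of

log quantity ~ tissue + (1 | protein) + (1 | patient) + (1 | lesion pair)

fit by REML through lmerTest. Natural logs are used; the base only
rescales coefficients and cancels on exponentiation, so reported
ratios are base-invariant. The tissue coefficient, exponentiated, is
the cNF/skin abundance ratio for the process; its 95% CI uses the
Satterthwaite degrees of freedom (`df_method` in every result row
records this). Imputed below-LOD values enter as ordinary
observations; MAR cells contribute nothing.

"Nested random intercepts for each patient and sample" is read with
"sample" as the excision pair — the grouping that encodes cNF/skin
matching. Intercepts for individual specimens are also estimable in
term-level models (many proteins per specimen) and are available via
`sampleUnit = "specimen"`; the lesion-pair reading is the default
because it reflects the paired design directly.

**Convergence fallback.** When a fit does not converge (optimizer
failure, a reported convergence failure, or a non-finite standard
error) the model is simplified in a fixed order: drop the patient
intercept, then the lesion intercept. A singular (zero-variance
boundary) fit counts as converged — boundary estimates are legitimate
REML solutions, and treating them as failures would silently change
the model for exactly the terms with small variance components. The
level actually used is reported per result row
(`model_structure_used`), and the cascade is testable via an
injectable failure hook. Exactly noiseless inputs (zero residual
variance) make the mixed likelihood degenerate; the tissue contrast is
then returned from the fixed-effects fit and flagged `degenerate`.

Single proteins are tested with the same machinery minus the protein
intercept; their fallback cascade ends in ordinary linear regression.

**Multiplicity.** P values are Bonferroni-corrected, `min(1, p * m)`.
The family size defaults to the number of terms actually tested in the
run and can be set explicitly (`model$family_size`), since published
corrected values generally imply a family much larger than the rows
shown in any one table.

# Sensitivity subsets

`subsetSamples()` restricts a study to growing lesions, one patient,
or an explicit lesion list, always keeping both members of each
selected pair so the paired structure survives. A subset that removes
an entire tissue is a hard error.

# GO indices and their correlation

For process-level correlation, each protein is normalized to its mean
observed quantity over *all* samples (both tissues — the literal
construction, even when the correlation is later restricted to one
tissue), and the normalized values of a term's proteins are averaged
per sample. The index is scale-invariant and centered at 1 on complete
data. Within one tissue, log-indices of two terms are related by a
linear mixed model with a patient random intercept; the first-listed
term of a pair is the response. Panel P values are reported
uncorrected. Samples with partially missing term proteins use the mean
of the available normalized values, with `n_proteins_used` reported
for audit.

# Clustering

Samples are clustered by complete-linkage agglomeration, the only
stated algorithmic choice; metric and scaling are open and therefore
config-exposed, defaulting to Euclidean distance on per-protein
z-scored log quantities (z-scoring stops a handful of abundant
proteins from dominating the distance). Proteins with any remaining
missing value are excluded (complete-case); zero-variance proteins are
dropped under z-scoring because their z-score is undefined. Complete
linkage makes merge heights monotone, which is asserted in tests, and
the implementation is checked against a brute-force O(n^3)
agglomerator on small inputs. Distance ties are broken by the
agglomeration order of `stats::hclust`, which is deterministic for a
given input; ties have measure zero for continuous data. Both pooled
and per-patient dendrograms are produced, and a two-cluster tissue
purity (majority-tissue fraction after cutting the tree into two)
summarizes tumor/skin separation: 1 is perfect separation, while
random labels give ≈0.5–0.6.

# The synthetic-data generator

`simulateStudy()` is the generative mirror of the analysis model: per
protein and sample, log quantity = per-protein baseline + term-level
tissue effect (cNF only) + patient intercept + lesion-pair intercept +
residual; the realized value is censored below a detection threshold
(`lod`, acting on the full realized measurement, not the protein mean),
and surviving cells drop out independently at `mar_rate`. Ground truth
records every term's true ratio, each missing cell's cause
(`censored_lod` / `dropout_mar`), and the realized random effects. A
single seeded RNG stream in a fixed draw order makes outputs
bit-reproducible.

Defaults are the emulated study conditions: 4 patients with 3, 4, 4, 4
lesions (15 matched pairs, 30 samples); 20 terms × 10 proteins plus 60
unannotated background proteins (≈260 proteins — deliberately
desk-scale rather than proteome-scale; term count, not protein count,
drives the statistics being validated); true ratios recycled over
{0.4, 0.6, 0.76, 1.0, 1.13, 1.5, 2.1}, spanning the effect magnitudes
typical of reported tumor/skin GO comparisons; log-intensity baseline
10 ± 1.5 across terms; variance components sd_patient = 0.10,
sd_lesion = 0.15, sd_protein = 0.50, sd_residual = 0.30. No published
variance decomposition exists for this design, so these are chosen
once as plausible for normalized DIA data (within-protein technical
noise smaller than between-protein spread; patient and excision
effects modest after normalization) and recorded in the ground truth;
they are a modeling choice, not an estimate of the original cohort.
Growth status marks two donors' lesions as growing (8 of 15) and the
rest as not.

What the generator does *not* emulate: peptide-level quantification
and roll-up noise, correlated missingness across proteins (e.g.
retention-time batches), heavy-tailed or intensity-dependent error,
shared-peptide ambiguity, or annotation errors. Passing
parameter-recovery tests on these simulations therefore demonstrates
the estimator and pipeline logic are correct under the stated model —
not that real DIA data satisfy that model.

# Validation performed by the test suite

The suite (and `scripts/acceptance.R`, which re-runs the pipeline end
to end and writes its headline numbers as JSON) computes:

* exact agreement of the 80/20 classification with a brute-force
  oracle on 500 random matrices;
* the ordinary-regression limit of the mixed model (coefficients match
  OLS to 1e-6 when no random variance was generated) and exact
  recovery of constructed folds;
* parameter recovery at the study design over true ratios 0.4–2.1
  with 5–25 proteins per term, 200 replicates: median log-ratio bias
  within ±0.02, 95% CI coverage within [0.90, 0.99], type-I error at
  the null within binomial bounds of 0.05;
* Bonferroni arithmetic, monotonicity and capping;
* the hand-computed GO-index example, scale invariance, and exact
  protein-mean normalization;
* clustering agreement with the brute-force agglomerator, monotone
  merge heights, purity 1.0 under strong simulated signal and
  chance-level purity under label permutation.

Simulation sizes in the tests (e.g. 200 replicates, 500 random
matrices, ≤12-sample clustering oracles) were chosen as the smallest
sizes at which the Monte-Carlo tolerances above are meaningful.

# A worked run

```{r example, eval = FALSE}
sim <- simulateStudy(simulationConfig(seed = 7L, lod = 6.5))
res <- runPipeline(sim$matrix, sim$annotations,
                   proteinTargets = rownames(sim$matrix)[1:3],
                   outDir = "results")
head(res$go_results)
res$report$imputation$n_imputed_total
res$clustering$pooled$purity
```

# Known limitations

* Estimate/CI-level agreement with other mixed-model software is
  expected, but exact t-statistics can differ with the
  degrees-of-freedom approximation.
* The "excess" imputation mode must pick which missing cells to
  impute; its sample-order choice is deterministic but arbitrary.
* The GO index weights every protein equally; a single extreme protein
  can dominate a small term's index.
* No FDR alternative to Bonferroni is offered, mirroring the modeled
  analysis.
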