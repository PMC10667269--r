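---
title: "Methods: longitudinal multi-omic biomarker discovery for infant epilepsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal multi-omic biomarker discovery for infant epilepsy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizomics)
```

## The problem

Infants with tuberous sclerosis complex (TSC) face a 70–90% risk of
epilepsy in the first two years of life, and pre-symptomatic antiseizure
treatment is only justifiable if the high-risk infants can be recognised
early. A molecular biomarker measurable at enrollment — from serum
proteomics, metabolomics, blood RNA, miRNA panels, genotypes, or clinical
covariates — would change how such infants are managed. `seizomics`
implements the complete statistical path from raw analyte tables to ranked
multivariate predictors, with three confound corrections in between, and a
synthetic cohort generator that lets every stage be validated against known
ground truth. Real birth-cohort data of this kind are access-controlled, so
the package treats the generator as a first-class module: the statistical
machinery is identical whichever source the tables come from.

## Data model

Analyte tables are analyte × sample matrices with an explicit missing-value
mask (`analyte_matrix`). Protein and metabolite intensities and miRNA
abundances are handled on the log2 scale; RNA enters as raw counts and is
converted to log2(CPM+1) with median-of-ratios size factors (a plain
column-total CPM lets a few strongly regulated genes drag the scaling of
every other gene — in simulations this alone manufactured age associations
in ~12% of null genes). SNP genotypes are collapsed to carrier status
(major-allele homozygote = 0, heterozygote or minor homozygote = 1).

The sample metadata table carries the longitudinal design: subject id (the
grouping factor of the mixed model), age in weeks, measurement batch,
vigabatrin exposure at draw, diagnostic group, per-draw seizure/EEG flags,
and 24-month outcomes.

## Confound corrections

Corrections run in a fixed order: batch → drug → age.

**Z/un-Z correction.** Within each confound group (batch, vigabatrin
exposure, or age tertile) every analyte is standardised and then rescaled by
the global pre-correction centre and SD, equalising group distributions
while preserving each analyte's overall location and spread. Standard
deviations use the population convention (denominator *n*); with sample SDs
the correction would shrink values by `sqrt((N-k)/(N-1))` on every
reapplication, whereas with population SDs it is exactly idempotent (the
test suite checks 1e-9). Batch and drug corrections centre on the mean; the
age-tertile path centres on the median by default (both are exposed).
Constant or nearly-unobserved analyte/group combinations pass through
unchanged rather than dividing by ~0.

**Drug correction.** Vigabatrin strongly perturbs part of the metabolome
(the generator plants effects up to 52-fold). Affected metabolites are
identified by a two-sided Wilcoxon rank-sum test between exposed and
unexposed samples older than 40 weeks — the age window where developmental
effects are minimal — with Benjamini–Hochberg control at FDR < 0.05, and
only those are Z/un-Z corrected with exposure as the grouping.

**Age correction, two independent routes.** Developmental change dominates
every analyte class in this age range, so age correction is done twice and
downstream results must replicate under both:

1. *Mixed model*: per analyte, `value ~ age_weeks + (1 | subject)` fitted by
   REML (lme4), giving a fixed slope per week and a shrunken random
   intercept per subject. The correction subtracts `age * slope +
   b_subject`, deliberately keeping the global intercept so values stay on
   their original scale. Analytes with an exactly linear signal are detected
   (OLS residual < 1e-10) and solved directly; a non-converging fit flags
   the analyte out of this route. Subjects with a single sample receive
   shrunken intercepts, and in the all-singleton limit the slope equals the
   OLS slope.
2. *Age tertiles*: Z/un-Z with the three fixed strata 0–10, 11–40, > 40
   weeks (ages 10.0 and 40.0 close the lower strata).

The mixed-model route removes any subject-constant signal along with the
subject intercept — that is what subtracting `b_subject` means. A group
difference that is literally constant over a subject's whole trajectory is
therefore invisible to this route; signals concentrated in a
developmental window (as enrollment-stage biology is) survive. The
synthetic generator plants its group gradients accordingly (see below).

## Univariate analysis

Analytes are first filtered on observability: RNA, metabolites and miRNA
need non-zero values in ≥ 50% of samples, protein groups in ≥ 70%. Zeros
count as unseen even when unmasked.

Two-group comparisons are assumption-gated: Shapiro–Wilk normality per
group and an F-test of variance homogeneity, each at 0.05; only when all
gates pass is the two-sided t-test used, otherwise the two-sided Wilcoxon
rank-sum test (groups smaller than 3 force the Wilcoxon branch). Three-group
comparisons use the Kruskal–Wallis rank-sum test followed, when significant,
by Dunn's two-sided pairwise z-tests on tie-corrected pooled ranks with BH
adjustment across the three pairs. Multiplicity is controlled inside each
hypothesis family: BH across analytes within a comparison, data type and
correction route. A finding requires FDR < 0.05 *and* a median fold change
above 1.5 (computed as `2^(median(x) - median(y))` on log2 data), and — the
conservative rule — must hold under both age-correction routes
(`dual_method_intersect`). Pathway enrichment on user-supplied sets is an
upper-tail hypergeometric test with BH across pathways.

The clinical comparisons (I–Vb) encode the cohort's group definitions;
comparison Vb contrasts age-comparable controls, TSC without epilepsy and
TSC with epilepsy on enrollment samples, with a stringent variant that drops
presymptomatically treated subjects from the middle group and
abnormal-EEG-at-enrollment subjects from both TSC groups. Samples (not
subjects) are the unit of analysis where the design says so; comparison I
pools all qualifying samples of a subject, which overstates independence —
a documented limitation inherited from the design.

## Developmental trajectories

Age association is measured twice: Spearman rank correlation with age as a
continuous variable, and the Kruskal–Wallis test across the three age
tertiles (both BH-adjusted across analytes). Analytes significant in the
tertile screen are Z-scored over their own samples, collapsed to their three
tertile medians, and clustered by complete-linkage hierarchical clustering
on Euclidean distances; the tree is cut at a per-type `k` (defaults 6
protein, 6 metabolite, 8 RNA). Analytes are sorted by id before clustering
so results cannot depend on input order. `k` is a tuning choice, not an
estimate — the defaults reflect panel sizes at which those counts give
interpretable trajectory families.

## Classifier search

The predictive stage uses one enrollment sample per subject. Subjects are
excluded when (a) they had subclinical seizures at study entry, (b) they
received pre-symptomatic vigabatrin and never developed seizures (treatment
may have changed their outcome), or (c) no comparable enrollment sample
exists; exclusions are applied as a union. Under the default generator this
yields 65 of 93 subjects, 54 who developed seizures by 24 months and 11 who
did not.

RNA is prefiltered on raw counts (> 3 reads in ≥ 75% of samples, then a
2-fold median CPM change between outcome classes). Features must be
observed in ≥ 50% of cohort samples and non-constant; each is scored by its
oriented univariate AUC (`max(AUC, 1-AUC)`, Mann–Whitney with midrank
ties), and per data type the top 30 with AUC > 0.6 form the pool.

Every subset of 1–3 pool variables defines a logistic model
`logit(p) = b0 + b1 x1 + b2 x2 + b3 x3`. With a 126-variable pool that is
333,501 models. Each model is scored by Monte-Carlo cross-validation: 100
stratified 2/3–1/3 splits of its complete cases; per split the model is
fitted by penalised maximum likelihood (ridge 1e-4 on slopes only — enough
to keep complete separation finite, far too small to bias coefficients) on
training data standardised by training statistics; the probability threshold
is tuned on the training set to maximise training MCC (the class imbalance
makes 0.5 useless); the held-out third yields confusion counts. The ranking
metric is the mean test Matthews correlation coefficient; mean
misclassification error, PPV and NPV are reported alongside, the latter two
averaged over the splits where they are defined (with 3–4 negatives in a
test set, all-positive predictions happen and leave NPV undefined). Models
with complete cases below half the cohort are left unscored — a perfect CV
score over four samples is noise, not evidence.

The inner loop is compiled (Rcpp); each (model, subsample) pair draws its
own splitmix64-derived seed from the master seed, so the entire search is
deterministic and independent of enumeration order or parallel chunking.
Standardisation is refit within each training split by default (leak-free);
a variant standardising once on all data is available to mirror
preprocess-first protocols.

## Permutation significance

Because no independent validation cohort exists, significance comes from
repeating the *whole* experiment — AUC-based pooling included — on
outcome-permuted labels (default 30 permutations, 50 subsamples per
permuted model). All permuted models' mean test MCCs form one pooled null;
a real model's p-value is the fraction of pooled null values at least as
large, and the significance threshold is the null's 95th percentile.

This pooled convention reproduces the study design it models, and its
granularity (one value per permuted model) is what makes p-values like 0.02
possible from 30 permutations. But it is *anti-conservative for the
top-ranked model*: a maximum over a hundred thousand models is being
compared against the full distribution rather than against other maxima. In
null simulations the best model's pooled p-value falls below 0.05 in well
over half of replicates. `null_stat = "max"` switches to the
per-permutation-maximum null (a max-T familywise test), which is calibrated
for the best model but has granularity `1/n_perm`. Interpret pooled
p-values of top-ranked models as a ranking diagnostic, not familywise
evidence; the package keeps the pooled convention as the default because it
is the convention the reported thresholds come from.

## The synthetic cohort generator

`generate_cohort()` emulates the study structure end to end: 93 TSC
subjects with 2–5 protocol-driven draws (enrollment at a median of ~4.7
weeks, optional EEG/seizure event samples, a 26/52-week routine sample, and
a 104-week endpoint) plus 58 single-sample controls with ages weighted
toward the enrollment window; subject roles reproduce the exclusion
arithmetic (54 + 11 eligible, 7 entry-seizure, 14 presymptomatic-treated
seizure-free, 7 without an enrollment sample).

Analyte values are built on the log2 scale as baseline + age trajectory +
subject random intercept (SD 0.5) + batch offset (metabolites, 4 batches,
SD 0.6) + vigabatrin effect + group effect + residual noise (SD 0.2). RNA
becomes negative-binomial counts (size 8) around the latent mean with
lognormal library-size variation. Choices the source design left open, made
once:

* **Trajectory archetypes** — monotone up, monotone down, early peak, late
  plateau — all saturate past ~40 weeks, concentrating developmental change
  in the first year; this is also what makes the > 40-week window usable
  for the drug comparison. Amplitudes are |N(1.5, 0.5)| log2 units for the
  age-affected fraction of each type (defaults 0.84 protein, 0.69
  metabolite, 0.51 RNA).
* **Vigabatrin effects** are multiplicative on 28 metabolites, one at
  52-fold and the rest log-spaced 1.5–4.5.
* **Group gradients** (control < TSC-no-epilepsy < TSC-epilepsy, default
  0.45 log2 per level) are planted on enrollment-stage samples (age ≤ 17
  weeks). A lifelong subject-constant gradient would be absorbed by the
  mixed model's subject intercept and subtracted away, making the
  dual-route intersection empty by construction; an early-window effect is
  both the biologically interesting case and the one the pipeline can see.
* **Planted predictors** shift enrollment samples of future-seizure
  subjects by `sqrt(2) * qnorm(AUC)` total SDs — the closed-form
  normal-theory mapping, verified by simulation to hit the target AUC
  within 0.05 on average. Planted predictors carry no age trajectory and
  are never masked, so the mapping stays exact.
* **Missingness** is missing-not-at-random: values below a per-type
  detection-limit quantile (5% protein, 3% metabolite, 2% miRNA) are
  masked.

What the generator does *not* emulate: correlated analyte blocks within a
data type (beyond shared trajectories), linkage disequilibrium between
SNPs, cell-composition structure in blood RNA, assay drift within batches,
and informative dropout of subjects. Passing tests on this cohort therefore
demonstrate that the machinery recovers what was planted under the stated
noise model — not that real cohorts of this size will yield biomarkers of
similar strength.

## Numerical choices and degenerate inputs

Z/un-Z skips analyte/groups with < 2 observed values or SD < 1e-12.
Logistic fitting caps the linear predictor at ±30 and damps Newton steps;
threshold tuning scans the sorted unique training probabilities plus an
above-maximum sentinel, breaking ties toward the smaller threshold. MCC
with any zero denominator factor is 0 by convention (and equals the phi
coefficient everywhere else; the suite verifies all ~10^4 confusion tables
up to n = 20). Dunn's z-tests use tie-corrected pooled ranks. Dendrogram
determinism comes from sorting analytes by id; distinct heights make
complete linkage order-invariant.

Problem sizes in the shipped analysis scripts (340 proteins, 249
metabolites, 1000 RNAs, 45 miRNA, 86 SNPs; 100-subsample search over ~125k
models; 30 permutations at 50 subsamples) are the package's default
desk-scale configuration; every one of them is a config parameter, and the
RNA panel in particular is a down-scaled stand-in for a ~20k-gene
transcriptome.

## Known limitations

* The pooled permutation p-value is anti-conservative for top-ranked models
  (discussed above).
* The dual-route intersection cannot see subject-constant group effects, by
  construction of the mixed-model correction.
* Sample-level pooling in comparison I treats repeated draws of a subject
  as independent.
* The feature pool is selected on the same labels the models are
  cross-validated on; mean test MCCs are optimistic in absolute terms, which
  is exactly why the permutation null repeats the selection step.
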