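---
title: "Multimodal early response prediction from ctDNA and whole-blood RNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal early response prediction from ctDNA and whole-blood RNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patients with metastatic urothelial cancer (mUC) treated with immune
checkpoint inhibitors (ICIs) respond heterogeneously: a minority derive
durable benefit while the rest progress early. The clinically useful
question two to six weeks into therapy is whether a patient will reach
*clinical benefit* (CB), defined as progression-free survival (PFS) of at
least 6 months. `erpredict` implements a blood-only early-response
workflow that answers it from two complementary liquid-biopsy modalities
sampled at baseline (BL) and early on-treatment (OT):

* **ctDNA kinetics** — the change in circulating tumor DNA concentration,
  a proxy for tumor burden;
* **whole-blood immunotranscriptome kinetics** — early shifts in
  peripheral immune gene expression (T-cell activation, proliferation,
  interferon signaling) that accompany a productive anti-tumor response;

and an **arbitration layer** that consults the second modality exactly
when the first sits too close to its decision cutoff.

Throughout, the positive class for sensitivity/specificity is *absence*
of benefit (N-CB): the intended clinical use is to identify early, with
high specificity, the patients for whom the treatment is failing.

## ctDNA quantification

Input is a table of tracked somatic variant observations (reads, depth)
in cfDNA, the matched white-blood-cell (WBC) sample, a panel of control
cfDNA samples, CNV segments, and the total cfDNA plasma concentration.

1. **Independent calling** keeps variants with at least 5 supporting
   reads and VAF above 0.1%.
2. **Dependent calling** re-examines tracked variants at the other
   timepoint under a relaxed read threshold (3 reads) — relaxation
   applies *only* to the read/VAF thresholds. Every call, independent or
   dependent, must clear the background screens: VAF at least 20 times
   the mean VAF of the control panel for that nucleotide change
   (floored at 1e-5 so an empty panel is never vacuous) and at least 3
   times the matched WBC VAF, which rejects clonal-hematopoiesis
   artifacts.
3. **CNV classification**: loss when relative coverage is at most −0.3,
   or at most −0.1 with major-allele fraction (MAF) at least 0.6; gain
   mirrored at +0.3 / +0.1; neutral otherwise. The three clauses
   partition the plane.
4. **Tumor fraction (TF)** comes from allele-dosage algebra on the called
   variant with the highest VAF outside gain regions: a clonal
   heterozygous variant in a copy-neutral region has VAF `v = TF/2`
   (so `TF = 2v`), and on the retained copy of a single-copy loss
   `v = TF/(2−TF)` (so `TF = 2v/(1+v)`). When no somatic variant
   qualifies, the germline fallback uses the major-allele fraction `m`
   of SNPs in a single-copy-loss region, `m = 1/(2−TF)`, hence
   `TF = 2 − 1/m`. The three routes agree exactly on noiseless mixtures,
   which is how they are tested.
5. **Copies per mL** = TF × cfDNA concentration (ng/mL) × 303, the
   genome-equivalent content of one nanogram of human DNA.
6. **Uncertainty limits** propagate an exact 95% Clopper–Pearson interval
   on the defining variant's VAF through the same TF formula and the
   ×303 conversion. Any interval monotone in depth would do; the exact
   binomial one is reproducible and assumption-light.
7. **Dichotomization**: the ratio of OT to BL copies/mL is classified as
   increase-or-stable (ratio ≥ 1 → predicted N-CB) versus decrease
   (ratio < 1 → predicted CB). Undetectable ctDNA at both timepoints is
   "no increase"/predicted CB (ratio recorded as 0); an undetectable
   baseline with detectable OT ctDNA is an increase (ratio +Inf). A
   ratio of exactly 1 counts as stable, i.e. N-CB.

## RNA differential expression

Counts are filtered (genes below 1 CPM in every sample removed; genes
whose percent coefficient of variation of CPM exceeds 100 in *every*
condition group removed), TMM-normalized (`edgeR::calcNormFactors`,
which is exactly the published trim-and-weight recipe — 30% trim on
M-values, 5% on A-values, precision weighting, factors multiplying
to 1), and stabilized as `log2(CPM + 0.5)`. The stabilizing transform is
a deliberate, fully deterministic stand-in for dispersion-model-based
transforms: it is monotone, finite everywhere, and the downstream
classifier standardizes its features, so only ranks and relative spacing
matter.

Three differential expression analyses (DEAs) mirror the study design:
paired BL→OT within CB patients, paired BL→OT within N-CB patients, and
CB vs N-CB at OT. Each uses limma's moderated t: gene-wise variances are
shrunk toward a common prior, posterior variance
`(d0·s0² + d·s²)/(d0 + d)` with `d0`, `s0²` estimated by method of
moments on the log sample variances, then Benjamini–Hochberg adjustment.
Genes at adjusted p ≤ 0.05 are DEGs in all three DEAs (the study states
this threshold explicitly only for enrichment; we apply it uniformly for
definiteness). The intersection utilities report all 7 Venn regions; the
discriminative signature defaults to (CB ∩ OT) \ N-CB — whether the
published 49-gene set excluded the N-CB overlap is not documented, so
both are available (`exclude_ncb`). Signature scoring averages
normalized expression over the set per patient and compares groups by
rank-sum test. Enrichment is a generic one-sided hypergeometric test
against user-supplied gene sets (GMT), BH-adjusted.

## The sparse PLS classifier

Features are per-patient OT − BL changes of normalized expression at
candidate genes (the discovery-cohort CB-DEA DEGs, topped up to at least
100 genes by p-value rank when the DEG list is short). Change features
are the natural representation for DEGs discovered by a longitudinal
contrast; OT-only values are a configuration away since the feature
matrix is an argument, not a fixture.

The classifier is NIPALS partial least squares on standardized features
with a hard sparsity constraint: the first component's weight vector
`X'y` is truncated to its `k` largest-magnitude entries and subsequent
components are restricted to the same support, so every fitted model has
exactly `k` nonzero-loading genes — matching the "k-gene model" framing
with `k ∈ {10, 15, 20}`. Two components are used, the customary default
for discriminant PLS at n ≈ 30. The component scores are mapped to a CB
probability by logistic calibration on the training data; the published
cutoff of 55% converts probability to label. With a single centred
response, each NIPALS component has a closed form, so the fit is exactly
reproducible without iteration-order concerns.

Model selection follows the two-cohort protocol: repeated stratified
cross-validation (10 repeats × 3 folds) on the discovery cohort
produces per-`k` candidates; each candidate, refit on the full discovery
cohort, is then ranked on the *test* cohort by ROC AUC and by the
absolute difference in Kaplan–Meier median PFS between its predicted
groups (an unreached median is replaced by the largest observed time so
the ranking stays total — flagged in reports). The winner minimizes the
rank sum, ties broken toward the higher AUC.

## Multimodal arbitration

Each patient carries a ctDNA ratio and an RNA probability. The bands are
closed intervals around the two cutoffs: `[2^−d_ct, 2^d_ct]` around
ratio 1 (symmetric on the log2 scale, because a ratio is multiplicative)
and `[0.55 − d_rna, 0.55 + d_rna]` around the probability cutoff.
Precedence: ctDNA-in-band → RNA label; RNA-in-band (only) → ctDNA label;
both in band → RNA label; neither → ctDNA label (the ctDNA prediction is
the base being adjusted). Written out, the label reduces to *RNA if the
ratio is in its band, ctDNA otherwise* — the probability band cannot
change a label under this precedence, a property worth knowing when
reading grid reports: the tie-break (smaller `d_ct + d_rna`, then
smaller `d_ct`) therefore pins `d_rna` at 0 in practice.

Band widths are tuned by exhaustive grid search on the test cohort
(defaults `d_ct ∈ {0, 0.25, 0.5, 0.75, 1}` log2 units,
`d_rna ∈ {0, 0.05, 0.1, 0.15, 0.2}`), maximizing the gain in
sensitivity + specificity over the standalone RNA model. The frozen
configuration is then applied once to the validation cohort. Validation
truth is not an argument to any training or tuning function; the
leakage tests poison validation labels after data generation and verify
that nothing upstream of the frozen evaluation changes.

## The synthetic cohort generator

Because the patient-level study data are access-restricted, the package
ships a generator that reproduces the *statistical structure* the
analysis assumes, so that every stage is exercised end-to-end:

* a latent responder status drives PFS (responders: 6 months plus an
  exponential tail of mean 12; non-responders: exponential of mean 3
  truncated below 6; administrative censoring at 24 months), the ctDNA
  trajectory, and the RNA shift — so both modalities correlate with
  outcome but with independent noise;
* baseline tumor fraction is log-uniform over `10^[−2.5, −0.5]`; the OT
  fraction multiplies it by a log-normal factor with median 0.25 (CB) or
  2.0 (N-CB) and log-sd 0.5; 12.5% of patients have zero tumor fraction
  at both timepoints (the undetectable scenario, 11/88 in the study);
  variant reads are binomial in Poisson depth at VAF = TF·ccf/2; 10% of
  tracked variants are clonal-hematopoiesis artifacts present in the WBC
  sample at matching VAF;
* counts are negative binomial (dispersion 0.1) with log-normal gene
  means, a shared patient×gene random effect inducing the paired
  structure, and library sizes near 2×10⁶ over 2,000 genes (the
  per-gene coverage of a 30M-read whole-blood library scaled to desk
  size); in CB patients the OT sample shifts 50 signal genes by a log2
  fold change drawn from (0.4, 1.4), one fifth of them downward
  (the myeloid-gene analogue);
* discordance is injected deliberately, since the arbitration layer is
  only meaningful when the modalities disagree (the study observed
  12/27 discordant test-cohort predictions): 15% of patients have their
  ctDNA ratio pinned near 1, and 30% of CB patients have their RNA
  signal muted.

Where the study does not state a value (effect sizes, TF distributions,
discordance rates), the defaults were calibrated once so that the
synthetic cohorts reproduce the study's *reported* operating points —
median RNA test AUC ≈ 0.85 (reported 0.84), full-cohort ctDNA
sensitivity/specificity ≈ 0.65/0.88 (reported 0.59/0.92), ≈ 34%
test-cohort discordance — and were not revisited. The fixed-composition
`simulate_study_cohort()` fixture reproduces the printed cohort exactly:
93 patients, 42 with CB, split 29/29/21 into discovery/test/validation
with the remaining 14 carrying ctDNA data only.

What passing tests on these cohorts do *not* show: robustness to batch
effects, globin/library artifacts, non-binomial sequencing error,
subclonal copy-number complexity, or covariate shift between cohorts —
none of which the generator emulates. Results on synthetic cohorts
validate the machinery, not clinical performance.

## Numerical choices and edge cases

* Zero-depth variant records are rejected with a logged reason, never an
  exception; an all-zero count sample or library is a named error.
* A ratio of exactly 1 is "stable" → N-CB; bands are closed, so boundary
  values fall inside.
* Degenerate DEA inputs (all variances zero) yield p = 1 rather than
  NaN; single-gene zero variance is handled by the shrunk variance.
* KM medians that are not reached are `NA` everywhere except inside the
  model-selection separation metric, where the largest observed time is
  substituted to keep the ranking total.
* The log-rank hazard ratio is the O/E ratio with
  `se(log HR) = sqrt(1/E_A + 1/E_B)` — the Mantel–Haenszel-style
  estimator, chosen over an iterative proportional-hazards fit.
* Wilcoxon tests are exact up to 25 observations without ties, normal
  approximation with tie/continuity correction otherwise.
* One user seed fans out to per-stage child seeds (all below 2³¹)
  through a fixed affine map, so toggling a stage does not shift the
  randomness of the others.

## Problem sizes used in the shipped tests

The test suite exercises the full pipeline at the study scale (93
patients, 2,000 genes, 10 tracked variants at depth 5,000) across 10
seeds, the null-calibration study at 20 pairs × 2,000 genes × 20 seeds,
and unit fixtures of a few hundred genes. These sizes were chosen as the
smallest at which the cohort-level metrics are stable enough to assert
on medians.

## Limitations

The DEA is a generic moderated-t pipeline, not the study's proprietary
one; DEG *counts* are therefore not comparable to the published 395/53/551
and are not asserted anywhere. The published 10-gene panel cannot be
recovered without the restricted data, and no attempt is made. The
arbitration precedence renders the RNA uncertainty band inert for
labeling (see above); alternative precedences (e.g. RNA as base when
neither value is in band) are a one-line change in `arbitrate()` but are
not the documented behavior.
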