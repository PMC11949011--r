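#' Independent variant filtering for cfDNA observations
#'
#' Keeps cfDNA variant observations with at least 5 supporting reads and a
#' variant allele fraction above 0.1%. Records with zero depth are rejected
#' (with their reasons attached), never raised as an error.
#'
#' @param obs data.frame with columns `reads` and `depth` (plus any locus
#'   columns, carried through).
#' @param min_reads,min_vaf Selection thresholds (defaults 5 reads, VAF
#'   strictly above 0.001).
#' @return The passing subset, with attribute `"rejected"` holding a
#'   data.frame of zero-depth records and reasons.
#' @export
filter_independent_variants <- function(obs, min_reads = 5L, min_vaf = 0.001) {
  stopifnot(is.data.frame(obs), all(c("reads", "depth") %in% names(obs)))
  bad <- obs$depth == 0
  rejected <- obs[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "zero depth"
  obs <- obs[!bad, , drop = FALSE]
  vaf <- obs$reads / obs$depth
  keep <- obs$reads >= min_reads & vaf > min_vaf
  out <- obs[keep, , drop = FALSE]
  out$vaf <- vaf[keep]
  attr(out, "rejected") <- rejected
  out
}

#' Dependent calling of a tracked variant
#'
#' Re-evaluates, at one timepoint, a variant already detected at the other
#' timepoint (or in tumor tissue) under relaxed thresholds: at least 3
#' supporting reads, a VAF at least 20-fold above the mean VAF of the control
#' cfDNA panel for that nucleotide change, and (when a matched white-blood-cell
#' sample is available) at least 3-fold above the WBC VAF. The control mean
#' defaults to 0 when the locus is absent from all controls and is floored at
#' `control_floor` to avoid a vacuous 20-fold test.
#'
#' @param reads,vaf Candidate supporting reads and VAF.
#' @param control_vafs Numeric vector of control-panel VAFs for this
#'   nucleotide change (may be empty).
#' @param wbc_vaf Matched WBC VAF, or `NULL` when unavailable.
#' @param control_floor Lower floor for the control mean (default `1e-5`).
#' @return `TRUE` if the variant is called.
#' @export
dependent_call <- function(reads, vaf, control_vafs, wbc_vaf = NULL,
                           control_floor = 1e-5) {
  if (vaf < 0 || any(control_vafs < 0) ||
      (!is.null(wbc_vaf) && wbc_vaf < 0)) {
    stop("VAFs must be nonnegative")
  }
  ctrl_mean <- if (length(control_vafs)) mean(control_vafs) else 0
  ctrl_mean <- max(ctrl_mean, control_floor)
  reads >= 3L &&
    vaf >= 20 * ctrl_mean &&
    (is.null(wbc_vaf) || vaf >= 3 * wbc_vaf)
}

#' Classify a copy-number segment
#'
#' Loss: relative coverage <= -0.3, or <= -0.1 with major-allele fraction
#' >= 0.6. Gain: relative coverage >= 0.3, or >= 0.1 with MAF >= 0.6.
#' Everything else is neutral. The three calls partition the whole
#' (coverage, MAF) plane.
#'
#' @param relative_coverage Log-scale coverage ratio(s).
#' @param maf Major-allele fraction(s) in `[0.5, 1]`.
#' @return Character vector: `"loss"`, `"gain"` or `"neutral"`.
#' @export
classify_cnv <- function(relative_coverage, maf) {
  stopifnot(all(maf >= 0.5 - 1e-12), all(maf <= 1 + 1e-12))
  out <- rep("neutral", length(relative_coverage))
  out[relative_coverage <= -0.3 |
        (relative_coverage <= -0.1 & maf >= 0.6)] <- "loss"
  out[relative_coverage >= 0.3 |
        (relative_coverage >= 0.1 & maf >= 0.6)] <- "gain"
  out
}

#' Estimate the tumor fraction of a cfDNA sample
#'
#' Primary route: the called somatic variant with the highest VAF in a region
#' not classified as a gain. For a copy-neutral region a heterozygous somatic
#' variant at cancer cell fraction 1 has VAF = TF/2, so TF = 2v (capped at 1);
#' in a single-copy-loss region the variant sits on the retained copy, VAF =
#' TF/(2 - TF), so TF = 2v/(1 + v). Fallback when no somatic variant
#' qualifies: the major-allele fraction m of germline SNPs in a
#' single-copy-loss region satisfies m = 1/(2 - TF), so TF = 2 - 1/m
#' (clamped to `[0, 1]`; the median across informative SNPs is used).
#'
#' @param called data.frame of called somatic variants with columns `vaf` and
#'   `region_call` (`"loss"`, `"gain"`, `"neutral"`); may have zero rows.
#' @param germline_loss_mafs Numeric vector of germline SNP major-allele
#'   fractions in single-copy-loss regions (optional fallback).
#' @return List with `tumor_fraction`, `source`
#'   (`"somatic_vaf"`, `"germline_maf"` or `"none"`), and for the somatic
#'   route `vaf`, `region_call` of the defining variant.
#' @export
estimate_tumor_fraction <- function(called, germline_loss_mafs = numeric(0)) {
  if (!is.null(called) && nrow(called)) {
    usable <- called[called$region_call != "gain", , drop = FALSE]
    if (nrow(usable)) {
      i <- which.max(usable$vaf)
      v <- usable$vaf[i]
      rc <- usable$region_call[i]
      tf <- if (rc == "loss") 2 * v / (1 + v) else min(2 * v, 1)
      return(list(tumor_fraction = tf, source = "somatic_vaf",
                  vaf = v, region_call = rc))
    }
  }
  if (length(germline_loss_mafs)) {
    m <- stats::median(germline_loss_mafs)
    tf <- min(max(2 - 1 / m, 0), 1)
    return(list(tumor_fraction = tf, source = "germline_maf"))
  }
  list(tumor_fraction = 0, source = "none")
}

#' Convert a tumor fraction to ctDNA copies per mL plasma
#'
#' `copies/mL = tumor_fraction x cfDNA concentration (ng/mL) x 303`.
#'
#' @param tumor_fraction Fraction of cfDNA of tumor origin.
#' @param cfdna_conc_ng_per_ml Total cfDNA plasma concentration.
#' @return Copies per mL of plasma.
#' @export
to_copies_per_ml <- function(tumor_fraction, cfdna_conc_ng_per_ml) {
  if (any(tumor_fraction < 0) || any(cfdna_conc_ng_per_ml < 0)) {
    stop("inputs must be nonnegative")
  }
  tumor_fraction * cfdna_conc_ng_per_ml * 303
}

#' Uncertainty limits for a ctDNA quantification
#'
#' Exact 95% Clopper-Pearson interval on the VAF of the tumor-fraction
#' defining variant, propagated through the same TF formula (copy-neutral
#' `TF = 2v`, loss `TF = 2v/(1+v)`) and the copies-per-mL conversion.
#' Intervals shrink monotonically with depth at fixed VAF.
#'
#' @param reads,depth Supporting reads and depth of the defining variant.
#' @param cfdna_conc Total cfDNA concentration (ng/mL).
#' @param region_call Region class of the defining variant (`"neutral"` or
#'   `"loss"`).
#' @param conf Confidence level (default 0.95).
#' @return List: `vaf_lower`, `vaf_upper`, `tf_lower`, `tf_upper`,
#'   `copies_lower`, `copies_upper`.
#' @export
quant_uncertainty <- function(reads, depth, cfdna_conc,
                              region_call = "neutral", conf = 0.95) {
  stopifnot(depth >= reads, reads >= 0)
  a <- (1 - conf) / 2
  vl <- if (reads == 0) 0 else stats::qbeta(a, reads, depth - reads + 1)
  vu <- if (reads == depth) 1 else stats::qbeta(1 - a, reads + 1, depth - reads)
  to_tf <- function(v) {
    if (region_call == "loss") 2 * v / (1 + v) else min(2 * v, 1)
  }
  tfl <- to_tf(vl); tfu <- to_tf(vu)
  list(vaf_lower = vl, vaf_upper = vu, tf_lower = tfl, tf_upper = tfu,
       copies_lower = to_copies_per_ml(tfl, cfdna_conc),
       copies_upper = to_copies_per_ml(tfu, cfdna_conc))
}

#' Quantify ctDNA for one sample (patient x timepoint)
#'
#' Runs the full quantification chain on raw evidence tables: independent
#' filtering of the cfDNA observations, dependent calling of tracked variants
#' against the control panel and matched WBC sample, CNV classification,
#' tumor-fraction estimation (somatic route with germline fallback), and the
#' copies-per-mL conversion with exact binomial uncertainty limits. A sample
#' is detectable when at least one somatic variant passes independent or
#' dependent calling.
#'
#' @param cfdna data.frame of cfDNA variant observations for this sample:
#'   columns `chrom`, `pos`, `ref`, `alt`, `reads`, `depth`, `region_id`.
#' @param controls Control-panel observations at the same loci (`chrom`,
#'   `pos`, `ref`, `alt`, `reads`, `depth`).
#' @param wbc Matched WBC observations, or `NULL`.
#' @param cnv CNV segment table for this sample: `region_id`,
#'   `relative_coverage`, `maf`.
#' @param germline Germline SNP table (`region_id`, `maf`), or `NULL`.
#' @param cfdna_conc Total cfDNA concentration (ng/mL).
#' @param control_floor Floor for the control mean VAF, see
#'   [dependent_call()].
#' @return List of class `"ctdna_quant"`: `tumor_fraction`, `tf_lower`,
#'   `tf_upper`, `cfdna_conc_ng_per_ml`, `copies_per_ml`, `copies_lower`,
#'   `copies_upper`, `detectable`, `source`, `n_called`.
#' @export
quantify_ctdna <- function(cfdna, controls, wbc = NULL, cnv = NULL,
                           germline = NULL, cfdna_conc,
                           control_floor = 1e-5) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  cfdna$vaf <- ifelse(cfdna$depth > 0, cfdna$reads / cfdna$depth, 0)

  # region classification
  if (!is.null(cnv) && nrow(cnv)) {
    cnv$call <- classify_cnv(cnv$relative_coverage, cnv$maf)
    cfdna$region_call <- cnv$call[match(cfdna$region_id, cnv$region_id)]
    cfdna$region_call[is.na(cfdna$region_call)] <- "neutral"
  } else {
    cfdna$region_call <- "neutral"
  }

  indep <- filter_independent_variants(cfdna)
  indep_keys <- key(indep)

  ctrl_key <- key(controls)
  controls$vaf <- ifelse(controls$depth > 0, controls$reads / controls$depth, 0)
  wbc_key <- if (!is.null(wbc)) key(wbc) else character(0)
  if (!is.null(wbc)) {
    wbc$vaf <- ifelse(wbc$depth > 0, wbc$reads / wbc$depth, 0)
  }

  # Control-panel and matched-WBC screens apply to every call; the dependent
  # route only relaxes the read/VAF thresholds, never these checks.
  screen_ok <- function(k, vaf) {
    ctrl <- controls$vaf[ctrl_key == k]
    ctrl_mean <- max(if (length(ctrl)) mean(ctrl) else 0, control_floor)
    wv <- if (k %in% wbc_key) wbc$vaf[match(k, wbc_key)] else NULL
    vaf >= 20 * ctrl_mean && (is.null(wv) || vaf >= 3 * wv)
  }

  keys <- key(cfdna)
  pass <- vapply(seq_len(nrow(cfdna)), function(i) {
    indep_i <- keys[i] %in% indep_keys
    dep_i <- cfdna$depth[i] > 0 && cfdna$reads[i] >= 3L
    (indep_i || dep_i) && screen_ok(keys[i], cfdna$vaf[i])
  }, logical(1))

  called <- cfdna[pass, , drop = FALSE]
  detectable <- nrow(called) > 0

  germ_mafs <- numeric(0)
  if (!is.null(germline) && nrow(germline) && !is.null(cnv)) {
    loss_regions <- cnv$region_id[cnv$call == "loss"]
    germ_mafs <- germline$maf[germline$region_id %in% loss_regions &
                                germline$maf > 0.5]
  }

  est <- estimate_tumor_fraction(called, germ_mafs)
  tf <- est$tumor_fraction
  copies <- to_copies_per_ml(tf, cfdna_conc)

  if (identical(est$source, "somatic_vaf")) {
    usable <- called[called$region_call != "gain", , drop = FALSE]
    i <- which.max(usable$vaf)
    unc <- quant_uncertainty(usable$reads[i], usable$depth[i], cfdna_conc,
                             usable$region_call[i])
  } else {
    unc <- list(tf_lower = 0, tf_upper = if (detectable || tf > 0) 1 else 0,
                copies_lower = 0,
                copies_upper = to_copies_per_ml(
                  if (detectable || tf > 0) 1 else 0, cfdna_conc))
  }

  structure(list(
    tumor_fraction = tf,
    tf_lower = min(unc$tf_lower, tf), tf_upper = max(unc$tf_upper, tf),
    cfdna_conc_ng_per_ml = cfdna_conc,
    copies_per_ml = copies,
    copies_lower = min(unc$copies_lower, copies),
    copies_upper = max(unc$copies_upper, copies),
    detectable = detectable, source = est$source,
    n_called = nrow(called)
  ), class = "ctdna_quant")
}

#' Dichotomize longitudinal ctDNA dynamics
#'
#' Classifies the BL to OT change in ctDNA copies/mL into increase-or-stable
#' (predicted N-CB) versus decrease (predicted CB). Patients with
#' undetectable ctDNA at both timepoints are categorized as no
#' increase / predicted CB with the ratio defined as 0. An undetectable
#' baseline with detectable OT ctDNA is an increase (ratio `Inf`).
#' The boundary ratio of exactly 1 ("stable") maps to N-CB.
#'
#' @param bl,ot `"ctdna_quant"` objects (or lists with `copies_per_ml` and
#'   `detectable`).
#' @return List of class `"ctdna_dynamics"`: `bl`, `ot`, `ratio`, `category`
#'   (`"increase_or_stable"`, `"decrease"`, `"undetectable_both"`), and
#'   `predicted_label` (`"CB"` / `"N-CB"`).
#' @export
dichotomize_dynamics <- function(bl, ot) {
  if (!bl$detectable && !ot$detectable) {
    ratio <- 0
    category <- "undetectable_both"
    label <- "CB"
  } else {
    ratio <- if (bl$copies_per_ml == 0) {
      if (ot$copies_per_ml > 0) Inf else 0
    } else {
      ot$copies_per_ml / bl$copies_per_ml
    }
    if (ratio >= 1) {
      category <- "increase_or_stable"; label <- "N-CB"
    } else {
      category <- "decrease"; label <- "CB"
    }
  }
  structure(list(bl = bl, ot = ot, ratio = ratio, category = category,
                 predicted_label = label), class = "ctdna_dynamics")
}

#' Quantify and dichotomize ctDNA for a whole cohort
#'
#' Applies [quantify_ctdna()] to the BL and OT samples of every patient in a
#' simulated (or equivalently structured) assay and [dichotomize_dynamics()]
#' to the pair.
#'
#' @param assay List as returned by [simulate_ctdna_assay()] (tables
#'   `variants`, `controls`, `cnv`, `germline`, `plasma`).
#' @return data.frame with one row per patient: copies and detectability at
#'   both timepoints, `ratio`, `category`, `predicted_label`.
#' @export
quantify_cohort_ctdna <- function(assay) {
  pids <- unique(assay$plasma$patient_id)
  rows <- lapply(pids, function(pid) {
    v <- assay$variants[assay$variants$patient_id == pid, , drop = FALSE]
    ctrl <- assay$controls[assay$controls$patient_id == pid, , drop = FALSE]
    wbc <- v[v$sample_role == "wbc", , drop = FALSE]
    quants <- lapply(c("BL", "OT"), function(tp) {
      cf <- v[v$sample_role == paste0("cfdna_", tolower(tp)), , drop = FALSE]
      cnv <- assay$cnv[assay$cnv$patient_id == pid &
                         assay$cnv$timepoint == tp, , drop = FALSE]
      germ <- assay$germline[assay$germline$patient_id == pid &
                               assay$germline$timepoint == tp, , drop = FALSE]
      conc <- assay$plasma$cfdna_conc[assay$plasma$patient_id == pid &
                                        assay$plasma$timepoint == tp]
      quantify_ctdna(cf, ctrl, wbc, cnv, germ, conc)
    })
    dyn <- dichotomize_dynamics(quants[[1]], quants[[2]])
    data.frame(patient_id = pid,
               tf_bl = quants[[1]]$tumor_fraction,
               tf_ot = quants[[2]]$tumor_fraction,
               copies_bl = quants[[1]]$copies_per_ml,
               copies_ot = quants[[2]]$copies_per_ml,
               detectable_bl = quants[[1]]$detectable,
               detectable_ot = quants[[2]]$detectable,
               ratio = dyn$ratio, category = dyn$category,
               ctdna_label = dyn$predicted_label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
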