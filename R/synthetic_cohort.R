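#' Simulation configuration for synthetic multimodal cohorts
#'
#' Builds and validates the parameter set used by the three generators
#' ([simulate_cohort()], [simulate_ctdna_assay()], [simulate_expression()]).
#' The defaults describe a desk-scale cohort with the paired study design the
#' downstream analysis assumes: clinical benefit (CB) defined as
#' progression-free survival (PFS) of at least 6 months, a CB-dependent decline
#' in circulating tumor DNA (ctDNA) from baseline (BL) to on-treatment (OT),
#' and CB-specific on-treatment upregulation of a block of signal genes.
#'
#' @param n_patients Number of patients in the cohort.
#' @param cb_fraction Probability that a patient is a latent responder
#'   (experiences CB). Default `42/93`, the observed CB prevalence.
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_genes,n_signal_genes Size of the simulated transcriptome and of the
#'   CB-responsive signal block.
#' @param signal_log2fc_range Ordered pair; per-gene absolute log2 fold change
#'   of signal genes at OT in CB patients is drawn uniformly from this range.
#' @param signal_down_fraction Fraction of signal genes shifted downward at OT
#'   (emulating on-treatment myeloid-gene downregulation).
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`).
#' @param library_size Target library size (total counts per sample).
#' @param n_tracked_variants Somatic variants tracked per patient.
#' @param mean_depth Mean sequencing depth at tracked loci (Poisson).
#' @param n_controls Number of control cfDNA samples in the panel.
#' @param bl_tf_log10_range Ordered pair; baseline tumor fraction is
#'   `10^u` with `u` uniform on this range.
#' @param ot_tf_multiplier_cb,ot_tf_multiplier_ncb Median multiplicative change
#'   in tumor fraction from BL to OT for CB and non-CB patients.
#' @param ot_tf_sdlog Log-scale spread of the OT multiplier.
#' @param control_noise_vaf Background variant allele fraction in control and
#'   white-blood-cell samples.
#' @param chip_fraction Fraction of tracked variants that are clonal
#'   hematopoiesis artifacts (present in the matched WBC sample at comparable
#'   VAF, to exercise dependent-calling rejection).
#' @param cfdna_conc_lognormal_params `c(meanlog, sdlog)` of the total cfDNA
#'   plasma concentration (ng/mL).
#' @param censor_months Administrative censoring time for PFS.
#' @param cohort_sizes Named vector `c(discovery=, test=, validation=)`;
#'   remaining patients get cohort `"none"` (ctDNA-only).
#' @param tf_zero_fraction Fraction of patients with tumor fraction 0 at both
#'   timepoints (ctDNA undetectable in both samples).
#' @param discordant_ctdna_fraction Fraction of patients whose ctDNA ratio is
#'   forced close to 1 (uninformative ctDNA, clean RNA).
#' @param discordant_rna_fraction Fraction of CB patients whose RNA signal is
#'   muted (uninformative RNA, clean ctDNA).
#' @param ccf_range Range of per-variant cancer cell fractions; the first
#'   tracked variant per patient is always clonal (ccf = 1).
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 93L,
                       cb_fraction = 42 / 93,
                       seed = 1L,
                       n_genes = 2000L,
                       n_signal_genes = 50L,
                       signal_log2fc_range = c(0.4, 1.4),
                       signal_down_fraction = 0.2,
                       nb_dispersion = 0.1,
                       library_size = 2e6,
                       n_tracked_variants = 10L,
                       mean_depth = 5000,
                       n_controls = 22L,
                       bl_tf_log10_range = c(-2.5, -0.5),
                       ot_tf_multiplier_cb = 0.25,
                       ot_tf_multiplier_ncb = 2,
                       ot_tf_sdlog = 0.5,
                       control_noise_vaf = 1e-4,
                       chip_fraction = 0.1,
                       cfdna_conc_lognormal_params = c(log(10), 0.6),
                       censor_months = 24,
                       cohort_sizes = c(discovery = 29L, test = 29L, validation = 21L),
                       tf_zero_fraction = 0.125,
                       discordant_ctdna_fraction = 0.15,
                       discordant_rna_fraction = 0.3,
                       ccf_range = c(0.5, 1)) {
  cfg <- list(
    n_patients = as.integer(n_patients), cb_fraction = cb_fraction,
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_signal_genes = as.integer(n_signal_genes),
    signal_log2fc_range = signal_log2fc_range,
    signal_down_fraction = signal_down_fraction,
    nb_dispersion = nb_dispersion, library_size = library_size,
    n_tracked_variants = as.integer(n_tracked_variants),
    mean_depth = mean_depth, n_controls = as.integer(n_controls),
    bl_tf_log10_range = bl_tf_log10_range,
    ot_tf_multiplier_cb = ot_tf_multiplier_cb,
    ot_tf_multiplier_ncb = ot_tf_multiplier_ncb,
    ot_tf_sdlog = ot_tf_sdlog,
    control_noise_vaf = control_noise_vaf, chip_fraction = chip_fraction,
    cfdna_conc_lognormal_params = cfdna_conc_lognormal_params,
    censor_months = censor_months, cohort_sizes = cohort_sizes,
    tf_zero_fraction = tf_zero_fraction,
    discordant_ctdna_fraction = discordant_ctdna_fraction,
    discordant_rna_fraction = discordant_rna_fraction,
    ccf_range = ccf_range
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  props <- c("cb_fraction", "control_noise_vaf", "chip_fraction",
             "tf_zero_fraction", "discordant_ctdna_fraction",
             "discordant_rna_fraction", "signal_down_fraction")
  for (p in props) {
    stop_if(cfg[[p]] < 0 || cfg[[p]] > 1,
            sprintf("'%s' must lie in [0, 1]", p))
  }
  counts <- c("n_patients", "n_genes", "n_signal_genes", "n_tracked_variants",
              "n_controls")
  for (p in counts) stop_if(cfg[[p]] < 1L, sprintf("'%s' must be >= 1", p))
  for (p in c("signal_log2fc_range", "bl_tf_log10_range", "ccf_range")) {
    stop_if(length(cfg[[p]]) != 2L || cfg[[p]][1] > cfg[[p]][2],
            sprintf("'%s' must be an ordered pair (low <= high)", p))
  }
  stop_if(cfg$n_signal_genes > cfg$n_genes,
          "'n_signal_genes' cannot exceed 'n_genes'")
  stop_if(cfg$mean_depth <= 0, "'mean_depth' must be positive")
  stop_if(cfg$library_size <= 0, "'library_size' must be positive")
  stop_if(cfg$nb_dispersion <= 0, "'nb_dispersion' must be positive")
  stop_if(cfg$censor_months <= 0, "'censor_months' must be positive")
  stop_if(sum(cfg$cohort_sizes) > cfg$n_patients,
          "cohort sizes exceed 'n_patients'")
  stop_if(!all(c("discovery", "test", "validation") %in% names(cfg$cohort_sizes)),
          "'cohort_sizes' needs names discovery, test, validation")
  invisible(cfg)
}

# Deterministic per-stage child seeds from the single user seed, kept < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 101L, ctdna = 211L, rna = 307L, cv = 401L,
               multimodal = 503L, pipeline = 601L)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

#' Simulate a patient cohort with clinical ground truth
#'
#' Draws a latent responder status per patient and generates PFS consistent
#' with the CB definition: responders have PFS of 6 months plus an exponential
#' tail (mean 12 months), non-responders have exponential PFS (mean 3 months)
#' truncated below 6 months, and everyone is administratively censored at
#' `censor_months`. CB is true exactly when PFS reaches 6 months (event or
#' censoring at or beyond 6). Patients are randomly assigned to the discovery,
#' test and validation cohorts per `cfg$cohort_sizes`; the remainder are
#' `"none"` (ctDNA-only). Latent assay attributes used by the other two
#' generators (undetectable ctDNA, discordance flags) are drawn here so that
#' the three generators stay mutually consistent.
#'
#' @param cfg A [sim_config()].
#' @param n_cb Optional exact number of CB patients; when supplied, exactly
#'   `n_cb` responders are placed at random positions instead of Bernoulli
#'   draws (used by the fixed-composition study fixture).
#' @return A data.frame with one row per patient: `patient_id`, `cohort`,
#'   `cb`, `pfs_months`, `event`, plus latent columns `tf_zero`,
#'   `ctdna_flat`, `rna_mute`.
#' @export
simulate_cohort <- function(cfg, n_cb = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "cohort"))
  n <- cfg$n_patients

  if (is.null(n_cb)) {
    responder <- stats::rbinom(n, 1L, cfg$cb_fraction) == 1L
  } else {
    stopifnot(n_cb >= 0, n_cb <= n)
    responder <- rep(FALSE, n)
    responder[sample.int(n, n_cb)] <- TRUE
  }

  pfs <- numeric(n)
  pfs[responder] <- 6 + stats::rexp(sum(responder), rate = 1 / 12)
  # non-responders: exponential(mean 3) conditioned on < 6 months
  nr <- sum(!responder)
  u <- stats::runif(nr) * stats::pexp(6, rate = 1 / 3)
  pfs[!responder] <- stats::qexp(u, rate = 1 / 3)

  event <- pfs < cfg$censor_months
  pfs <- pmin(pfs, cfg$censor_months)

  cohort <- rep("none", n)
  ord <- sample.int(n)
  sizes <- cfg$cohort_sizes[c("discovery", "test", "validation")]
  idx <- split(ord[seq_len(sum(sizes))],
               rep(names(sizes), times = sizes))
  for (nm in names(idx)) cohort[idx[[nm]]] <- nm

  draw_flag <- function(p) stats::runif(n) < p
  tf_zero <- draw_flag(cfg$tf_zero_fraction)
  ctdna_flat <- draw_flag(cfg$discordant_ctdna_fraction) & !tf_zero
  rna_mute <- draw_flag(cfg$discordant_rna_fraction) & responder

  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    cohort = cohort,
    cb = responder,
    pfs_months = pfs,
    event = event,
    tf_zero = tf_zero,
    ctdna_flat = ctdna_flat,
    rna_mute = rna_mute,
    stringsAsFactors = FALSE
  )
}

#' Fixed-composition study cohort ("study-93")
#'
#' The default study-scale fixture: 93 patients of whom exactly 42 experience
#' clinical benefit, split 29/29/21 into discovery/test/validation with the
#' remaining 14 patients carrying ctDNA data only.
#'
#' @param seed Integer seed.
#' @param cfg Optional [sim_config()]; its `n_patients` must be 93.
#' @return As [simulate_cohort()].
#' @export
simulate_study_cohort <- function(seed = 1L, cfg = sim_config(seed = seed)) {
  stopifnot(cfg$n_patients == 93L)
  simulate_cohort(cfg, n_cb = 42L)
}

#' Simulate a longitudinal ctDNA assay
#'
#' Generates, per patient and timepoint, the evidence tables the ctDNA
#' quantification stage consumes: tracked somatic variant observations in
#' cfDNA (reads binomial in depth at VAF = TF x ccf / 2 in copy-neutral
#' regions), matched white-blood-cell observations (background noise, except
#' for clonal-hematopoiesis variants present at comparable VAF), a control
#' cfDNA panel, CNV segments (one neutral, one single-copy loss, one gain,
#' with coverage and major-allele fraction consistent with the tumor
#' fraction), germline SNP major-allele fractions in the loss region, and the
#' total cfDNA plasma concentration.
#'
#' Baseline tumor fraction is `10^u`, `u` uniform on `bl_tf_log10_range`; the
#' OT fraction multiplies it by a log-normal factor centred at the
#' CB-dependent multiplier. Patients flagged `tf_zero` have TF = 0 at both
#' timepoints; patients flagged `ctdna_flat` get a multiplier pinned near 1.
#'
#' @param patients Output of [simulate_cohort()].
#' @param cfg The same [sim_config()].
#' @return A list of data.frames: `variants` (cfDNA and WBC observations),
#'   `controls`, `cnv`, `germline`, `plasma`, and `truth` (latent tumor
#'   fractions, for diagnostics only).
#' @export
simulate_ctdna_assay <- function(patients, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "ctdna"))
  n <- nrow(patients)

  tf_bl <- ifelse(patients$tf_zero, 0,
                  10^stats::runif(n, cfg$bl_tf_log10_range[1],
                                  cfg$bl_tf_log10_range[2]))
  med_mult <- ifelse(patients$cb, cfg$ot_tf_multiplier_cb,
                     cfg$ot_tf_multiplier_ncb)
  mult <- exp(stats::rnorm(n, log(med_mult), cfg$ot_tf_sdlog))
  mult[patients$ctdna_flat] <-
    exp(stats::rnorm(sum(patients$ctdna_flat), 0, 0.03))
  tf_ot <- pmin(tf_bl * mult, 0.95)
  tf_ot[patients$tf_zero] <- 0

  nv <- cfg$n_tracked_variants
  bases <- c("A", "C", "G", "T")
  variants <- vector("list", n)
  controls <- vector("list", n)
  cnv <- vector("list", n)
  germline <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- patients$patient_id[i]
    chrom <- paste0("chr", sample(1:22, nv, replace = TRUE))
    pos <- sample.int(1e8, nv)
    ref <- sample(bases, nv, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    ccf <- c(1, stats::runif(nv - 1L, cfg$ccf_range[1], cfg$ccf_range[2]))
    chip <- stats::runif(nv) < cfg$chip_fraction
    chip_vaf <- ifelse(chip, stats::runif(nv, 0.001, 0.01), 0)

    per_tp <- function(tp, tf) {
      depth <- stats::rpois(nv, cfg$mean_depth)
      vaf_true <- pmin(tf * ccf / 2 + chip_vaf, 1)
      reads <- stats::rbinom(nv, depth, vaf_true)
      data.frame(patient_id = pid, timepoint = tp, chrom = chrom, pos = pos,
                 ref = ref, alt = alt, reads = reads, depth = depth,
                 sample_role = paste0("cfdna_", tolower(tp)),
                 region_id = "seg_neutral", stringsAsFactors = FALSE)
    }
    wbc_depth <- stats::rpois(nv, cfg$mean_depth)
    wbc_vaf <- pmin(chip_vaf + cfg$control_noise_vaf, 1)
    wbc <- data.frame(patient_id = pid, timepoint = NA_character_,
                      chrom = chrom, pos = pos, ref = ref, alt = alt,
                      reads = stats::rbinom(nv, wbc_depth, wbc_vaf),
                      depth = wbc_depth, sample_role = "wbc",
                      region_id = "seg_neutral", stringsAsFactors = FALSE)
    variants[[i]] <- rbind(per_tp("BL", tf_bl[i]), per_tp("OT", tf_ot[i]), wbc)

    ctrl_depth <- stats::rpois(nv * cfg$n_controls, cfg$mean_depth)
    controls[[i]] <- data.frame(
      patient_id = pid,
      control_id = rep(sprintf("C%02d", seq_len(cfg$n_controls)), each = nv),
      chrom = rep(chrom, cfg$n_controls), pos = rep(pos, cfg$n_controls),
      ref = rep(ref, cfg$n_controls), alt = rep(alt, cfg$n_controls),
      reads = stats::rbinom(nv * cfg$n_controls, ctrl_depth,
                            cfg$control_noise_vaf),
      depth = ctrl_depth, sample_role = "control", stringsAsFactors = FALSE)

    seg <- function(tp, tf) {
      rc_noise <- stats::rnorm(3, 0, 0.02)
      maf_loss <- pmin(pmax(1 / (2 - tf) + stats::rnorm(1, 0, 0.005), 0.5), 1)
      maf_gain <- pmin(pmax((1 + tf) / (2 + tf) + stats::rnorm(1, 0, 0.005), 0.5), 1)
      data.frame(
        patient_id = pid, timepoint = tp,
        region_id = c("seg_neutral", "seg_loss", "seg_gain"),
        relative_coverage = c(0, log2((2 - tf) / 2), log2((2 + tf) / 2)) + rc_noise,
        maf = c(0.5 + abs(stats::rnorm(1, 0, 0.005)), maf_loss, maf_gain),
        stringsAsFactors = FALSE)
    }
    cnv[[i]] <- rbind(seg("BL", tf_bl[i]), seg("OT", tf_ot[i]))

    germ <- function(tp, tf) {
      data.frame(patient_id = pid, timepoint = tp, region_id = "seg_loss",
                 maf = pmin(pmax(1 / (2 - tf) + stats::rnorm(3, 0, 0.005), 0.5), 1),
                 stringsAsFactors = FALSE)
    }
    germline[[i]] <- rbind(germ("BL", tf_bl[i]), germ("OT", tf_ot[i]))
  }

  plasma <- data.frame(
    patient_id = rep(patients$patient_id, each = 2L),
    timepoint = rep(c("BL", "OT"), times = n),
    cfdna_conc = stats::rlnorm(2L * n, cfg$cfdna_conc_lognormal_params[1],
                               cfg$cfdna_conc_lognormal_params[2]),
    stringsAsFactors = FALSE)

  list(variants = do.call(rbind, variants),
       controls = do.call(rbind, controls),
       cnv = do.call(rbind, cnv),
       germline = do.call(rbind, germline),
       plasma = plasma,
       truth = data.frame(patient_id = patients$patient_id,
                          tf_bl = tf_bl, tf_ot = tf_ot,
                          stringsAsFactors = FALSE))
}

#' Simulate paired whole-blood RNA counts
#'
#' Negative-binomial counts for `n_genes` genes in paired BL/OT samples of
#' every patient assigned to an RNA cohort. Gene baseline means are
#' log-normal; a per-patient-per-gene random effect shared between the two
#' timepoints induces the paired structure; sample library sizes vary
#' log-normally around `library_size`. In CB patients (unless `rna_mute`),
#' the OT sample shifts the signal genes by a per-gene log2 fold change drawn
#' from `signal_log2fc_range`, a `signal_down_fraction` minority of them
#' downward. Non-CB patients have no systematic shift.
#'
#' @param patients Output of [simulate_cohort()].
#' @param cfg The same [sim_config()].
#' @return A list: `counts` (gene x sample integer matrix), `samples`
#'   (metadata data.frame: `sample_id`, `patient_id`, `timepoint`, `group`,
#'   `cohort`), and `signal_genes` (character vector with the per-gene
#'   log2 fold changes as names' attribute `lfc`).
#' @export
simulate_expression <- function(patients, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "rna"))
  pts <- patients[patients$cohort != "none", , drop = FALSE]
  np <- nrow(pts)
  if (np == 0L) stop("no patients assigned to an RNA cohort")
  G <- cfg$n_genes

  genes <- sprintf("G%04d", seq_len(G))
  base_mu <- stats::rlnorm(G, meanlog = 0, sdlog = 1)
  base_mu <- base_mu / sum(base_mu) * cfg$library_size

  sig_idx <- sample.int(G, cfg$n_signal_genes)
  lfc <- stats::runif(cfg$n_signal_genes, cfg$signal_log2fc_range[1],
                      cfg$signal_log2fc_range[2])
  down <- stats::runif(cfg$n_signal_genes) < cfg$signal_down_fraction
  lfc[down] <- -lfc[down]

  sample_id <- c(rbind(paste0(pts$patient_id, "_BL"),
                       paste0(pts$patient_id, "_OT")))
  samples <- data.frame(
    sample_id = sample_id,
    patient_id = rep(pts$patient_id, each = 2L),
    timepoint = rep(c("BL", "OT"), times = np),
    group = rep(ifelse(pts$cb, "CB", "N-CB"), each = 2L),
    cohort = rep(pts$cohort, each = 2L),
    stringsAsFactors = FALSE)

  counts <- matrix(0L, nrow = G, ncol = 2L * np,
                   dimnames = list(genes, sample_id))
  for (j in seq_len(np)) {
    pat_eff <- 2^stats::rnorm(G, 0, 0.15)     # shared BL/OT
    for (tp in c("BL", "OT")) {
      lib_eff <- stats::rlnorm(1, 0, 0.15)
      mu <- base_mu * pat_eff * lib_eff
      if (tp == "OT" && pts$cb[j] && !pts$rna_mute[j]) {
        mu[sig_idx] <- mu[sig_idx] * 2^lfc
      }
      col <- paste0(pts$patient_id[j], "_", tp)
      counts[, col] <- stats::rnbinom(G, mu = mu, size = 1 / cfg$nb_dispersion)
    }
  }

  sig <- genes[sig_idx]
  attr(sig, "lfc") <- stats::setNames(lfc, sig)
  list(counts = counts, samples = samples, signal_genes = sig)
}

#' Write a simulated multimodal cohort to tab-separated files
#'
#' Materializes the generator outputs under `dir`: clinical table, variant /
#' control / CNV / germline / plasma tables, the gene x sample count matrix,
#' sample metadata, and the configuration as YAML.
#'
#' @param patients,assay,expr Outputs of the three generators (any may be
#'   `NULL` to skip).
#' @param cfg The [sim_config()] used.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort_tables <- function(patients, assay = NULL, expr = NULL,
                                cfg = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  wr(patients[c("patient_id", "cohort", "cb", "pfs_months", "event")],
     "clinical.tsv")
  if (!is.null(assay)) {
    wr(assay$variants, "variants.tsv")
    wr(assay$controls, "controls.tsv")
    wr(assay$cnv, "cnv_segments.tsv")
    wr(assay$germline, "germline_snps.tsv")
    wr(assay$plasma, "plasma.tsv")
  }
  if (!is.null(expr)) {
    cm <- data.frame(gene = rownames(expr$counts), expr$counts,
                     check.names = FALSE)
    wr(cm, "counts.tsv")
    wr(expr$samples, "samples.tsv")
  }
  if (!is.null(cfg)) {
    path <- file.path(dir, "sim_config.yaml")
    yaml::write_yaml(unclass(cfg), path)
    written <- c(written, path)
  }
  invisible(written)
}
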