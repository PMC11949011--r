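test_that("independent filtering applies both read and VAF thresholds", {
  obs <- data.frame(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
    reads = c(5L, 4L, 10L, 8L),
    depth = c(1000L, 100L, 20000L, 1000L))
  kept <- filter_independent_variants(obs)
  # reads=5/vaf=0.005 kept; reads=4 fails read rule; vaf=5e-4 fails VAF rule
  expect_equal(kept$pos, c(1L, 4L))
  expect_equal(kept$vaf, c(0.005, 0.008))
})

test_that("zero-depth records are rejected with a reason, not an error", {
  obs <- data.frame(chrom = "chr1", pos = 1:2, ref = "A", alt = "T",
                    reads = c(0L, 10L), depth = c(0L, 1000L))
  kept <- filter_independent_variants(obs)
  expect_equal(nrow(kept), 1L)
  rej <- attr(kept, "rejected")
  expect_equal(rej$pos, 1L)
  expect_equal(rej$reason, "zero depth")
})

test_that("dependent calling enforces read, control and WBC rules", {
  # all three rules satisfied: 30x control, 6x WBC
  expect_true(dependent_call(3, 0.003, rep(1e-4, 22), 5e-4))
  # read rule
  expect_false(dependent_call(2, 0.01, rep(1e-4, 22), NULL))
  # control rule: 15x < 20x
  expect_false(dependent_call(5, 0.003, rep(2e-4, 22), NULL))
  # WBC rule
  expect_false(dependent_call(10, 0.003, rep(1e-5, 22), 0.0015))
  # absent WBC sample skips that rule
  expect_true(dependent_call(10, 0.003, rep(1e-5, 22), NULL))
  # control floor: empty controls do not make the 20x rule vacuous
  expect_true(dependent_call(3, 0.001, numeric(0), NULL))
  expect_false(dependent_call(3, 1e-4, numeric(0), NULL))
  expect_error(dependent_call(3, -0.1, rep(1e-4, 3), NULL), "nonnegative")
})

test_that("dependent calling below 3 reads never accepts", {
  set.seed(1)
  for (i in 1:50) {
    expect_false(dependent_call(sample(0:2, 1), stats::runif(1),
                                stats::runif(5, 0, 1e-4), NULL))
  }
})

test_that("CNV classification matches the threshold clauses and partitions", {
  expect_equal(classify_cnv(-0.35, 0.55), "loss")
  expect_equal(classify_cnv(-0.15, 0.65), "loss")
  expect_equal(classify_cnv(0.12, 0.55), "neutral")
  expect_equal(classify_cnv(0.30, 0.50), "gain")   # boundary inclusive
  expect_equal(classify_cnv(-0.30, 0.50), "loss")  # boundary inclusive
  expect_equal(classify_cnv(0.12, 0.60), "gain")
  expect_equal(classify_cnv(0, 1), "neutral")
  # partition: every point of the plane gets exactly one of the three calls
  grid <- expand.grid(rc = seq(-1, 1, by = 0.05), maf = seq(0.5, 1, by = 0.025))
  calls <- classify_cnv(grid$rc, grid$maf)
  expect_true(all(calls %in% c("loss", "gain", "neutral")))
})

test_that("the three tumor-fraction routes agree on noiseless mixtures", {
  for (tf in c(0.1, 0.3, 0.5)) {
    # clonal het variant in a copy-neutral region: VAF = TF/2
    tf_neutral <- estimate_tumor_fraction(
      data.frame(vaf = tf / 2, region_call = "neutral"))
    # same variant on the retained copy of a single-copy loss: VAF = TF/(2-TF)
    tf_loss <- estimate_tumor_fraction(
      data.frame(vaf = tf / (2 - tf), region_call = "loss"))
    # germline SNP major-allele fraction in the loss region: m = 1/(2-TF)
    tf_germ <- estimate_tumor_fraction(
      data.frame(vaf = numeric(0), region_call = character(0)),
      germline_loss_mafs = 1 / (2 - tf))
    expect_equal(tf_neutral$tumor_fraction, tf, tolerance = 1e-12)
    expect_equal(tf_loss$tumor_fraction, tf, tolerance = 1e-12)
    expect_equal(tf_germ$tumor_fraction, tf, tolerance = 1e-12)
    expect_equal(tf_neutral$source, "somatic_vaf")
    expect_equal(tf_germ$source, "germline_maf")
  }
  # worked values: v = 0.25 neutral -> 0.5; v = 1/3 in loss -> 0.5; m = 2/3 -> 0.5
  expect_equal(estimate_tumor_fraction(
    data.frame(vaf = 0.25, region_call = "neutral"))$tumor_fraction, 0.5)
  expect_equal(estimate_tumor_fraction(
    data.frame(vaf = 1 / 3, region_call = "loss"))$tumor_fraction, 0.5)
  expect_equal(estimate_tumor_fraction(
    data.frame(vaf = numeric(0), region_call = character(0)),
    2 / 3)$tumor_fraction, 0.5)
})

test_that("gain-region variants are excluded; absent evidence yields source none", {
  res <- estimate_tumor_fraction(
    data.frame(vaf = c(0.4, 0.1), region_call = c("gain", "neutral")))
  expect_equal(res$tumor_fraction, 0.2)  # the gain variant is skipped
  none <- estimate_tumor_fraction(
    data.frame(vaf = 0.4, region_call = "gain"))
  expect_equal(none$source, "none")
  expect_equal(none$tumor_fraction, 0)
})

test_that("copies-per-mL conversion is the x303 product and is bilinear", {
  expect_identical(to_copies_per_ml(1, 1), 303)
  expect_identical(to_copies_per_ml(0, 17.3), 0)
  expect_equal(to_copies_per_ml(0.1, 10), 303)
  expect_equal(to_copies_per_ml(0.2, 5), 2 * to_copies_per_ml(0.1, 5))
  expect_equal(to_copies_per_ml(0.2, 10), 2 * to_copies_per_ml(0.2, 5))
  expect_error(to_copies_per_ml(-0.1, 1), "nonnegative")
})

test_that("uncertainty limits equal the exact binomial interval and shrink with depth", {
  u <- quant_uncertainty(50, 1000, cfdna_conc = 1, region_call = "neutral")
  oracle <- stats::binom.test(50, 1000)$conf.int
  expect_equal(u$vaf_lower, oracle[1], tolerance = 1e-10)
  expect_equal(u$vaf_upper, oracle[2], tolerance = 1e-10)
  expect_equal(u$tf_lower, 2 * oracle[1])
  expect_equal(u$tf_upper, 2 * oracle[2])
  expect_equal(u$copies_lower, 2 * oracle[1] * 303)

  expect_equal(quant_uncertainty(0, 1000, 1)$tf_lower, 0)

  widths <- vapply(c(100, 1000, 10000, 100000), function(d) {
    q <- quant_uncertainty(round(0.05 * d), d, 1)
    q$tf_upper - q$tf_lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("dichotomization follows the increase versus no-increase rule", {
  d <- dichotomize_dynamics(quant_stub(100), quant_stub(150))
  expect_equal(d$category, "increase_or_stable")
  expect_equal(d$predicted_label, "N-CB")

  d <- dichotomize_dynamics(quant_stub(0, FALSE), quant_stub(0, FALSE))
  expect_equal(d$category, "undetectable_both")
  expect_equal(d$predicted_label, "CB")
  expect_equal(d$ratio, 0)

  expect_equal(dichotomize_dynamics(quant_stub(100),
                                    quant_stub(100))$predicted_label, "N-CB")
  expect_equal(dichotomize_dynamics(quant_stub(100),
                                    quant_stub(99.9))$predicted_label, "CB")

  # undetectable baseline, detectable on-treatment: an increase
  d <- dichotomize_dynamics(quant_stub(0, FALSE), quant_stub(50, TRUE))
  expect_equal(d$ratio, Inf)
  expect_equal(d$predicted_label, "N-CB")
})

test_that("dichotomization is invariant to rescaling both timepoints", {
  set.seed(4)
  for (i in 1:25) {
    bl <- stats::runif(1, 1, 500)
    ot <- stats::runif(1, 1, 500)
    k <- stats::runif(1, 0.01, 100)
    a <- dichotomize_dynamics(quant_stub(bl), quant_stub(ot))
    b <- dichotomize_dynamics(quant_stub(k * bl), quant_stub(k * ot))
    expect_equal(a$predicted_label, b$predicted_label)
    expect_equal(a$ratio, b$ratio)
  }
})

test_that("sample-level quantification integrates calling, CNV and conversion", {
  mk <- function(reads, depth, pos = seq_along(reads)) {
    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
               reads = reads, depth = depth, region_id = "seg_neutral")
  }
  ctrl <- do.call(rbind, lapply(1:22, function(i) mk(0L, 5000L, pos = 1:2)))

  # clean somatic variant at VAF 0.03 in a neutral region: TF = 0.06
  q <- quantify_ctdna(mk(c(150L, 0L), 5000L), ctrl,
                      wbc = mk(c(0L, 0L), 5000L),
                      cnv = data.frame(region_id = "seg_neutral",
                                       relative_coverage = 0, maf = 0.5),
                      cfdna_conc = 10)
  expect_true(q$detectable)
  expect_equal(q$source, "somatic_vaf")
  expect_equal(q$tumor_fraction, 0.06)
  expect_equal(q$copies_per_ml, 0.06 * 10 * 303)
  expect_true(q$tf_lower <= q$tumor_fraction &
                q$tumor_fraction <= q$tf_upper)

  # clonal-hematopoiesis artifact: comparable WBC VAF blocks the call
  chip <- quantify_ctdna(mk(c(150L, 0L), 5000L), ctrl,
                         wbc = mk(c(145L, 0L), 5000L),
                         cnv = NULL, cfdna_conc = 10)
  expect_false(chip$detectable)
  expect_equal(chip$source, "none")

  # dependent route: 4 reads (< 5) but clean control/WBC background
  dep <- quantify_ctdna(mk(c(4L, 0L), 5000L), ctrl,
                        wbc = mk(c(0L, 0L), 5000L),
                        cnv = NULL, cfdna_conc = 10)
  expect_true(dep$detectable)
  expect_equal(dep$tumor_fraction, 2 * 4 / 5000)
})

test_that("cohort quantification labels dynamics consistently with truth", {
  cfg <- sim_config(seed = 13)
  pts <- simulate_cohort(cfg, n_cb = 42L)
  assay <- simulate_ctdna_assay(pts, cfg)
  ct <- quantify_cohort_ctdna(assay)
  expect_equal(nrow(ct), 93L)
  expect_true(all(ct$category %in%
                    c("increase_or_stable", "decrease", "undetectable_both")))
  # undetectable-both patients are exactly labeled CB via that category
  expect_true(all(ct$ctdna_label[ct$category == "undetectable_both"] == "CB"))
  # the dichotomization separates true CB from true N-CB far above chance
  truth <- ifelse(pts$cb[match(ct$patient_id, pts$patient_id)], "CB", "N-CB")
  cm <- confusion_metrics(ct$ctdna_label, truth)
  expect_gt(cm$sensitivity + cm$specificity, 1.2)
})
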