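test_that("CPM filter keeps genes with any sample at or above 1 CPM", {
  # toy CPMs: gene a {0.5, 0.5}, gene b {2, 2}, gene c {0.9, 1.1}
  counts <- rbind(a = c(5, 5), b = c(20, 20), c = c(9, 11))
  filler <- 1e7 - colSums(counts)
  counts <- rbind(counts, filler = filler)
  colnames(counts) <- c("s1", "s2")
  kept <- filter_genes(counts)
  expect_true(all(c("b", "c") %in% rownames(kept)))
  expect_false("a" %in% rownames(kept))
  expect_equal(unname(attr(kept, "removed")["low_cpm"]), 1)
})

test_that("all-zero genes are removed and zero-library samples are named", {
  m <- toy_counts()
  m[1, ] <- 0
  expect_false(rownames(m)[1] %in% rownames(filter_genes(m)))
  m[, 2] <- 0
  expect_error(filter_genes(m), "s2")
})

test_that("the CV filter removes genes noisy in every group", {
  set.seed(8)
  m <- toy_counts(n_genes = 30, lambda = 500)
  # spiky gene: zero in most samples, huge in one per group -> percent CV > 100
  m["g001", ] <- c(0, 0, 6000, 0, 0, 6000)
  groups <- rep(c("A", "B"), each = 3)
  kept <- filter_genes(m, groups = groups)
  expect_false("g001" %in% rownames(kept))
  expect_equal(unname(attr(kept, "removed")["high_cv"]), 1)
  # the same gene stable in group A survives
  m["g001", 1:3] <- 500
  expect_true("g001" %in% rownames(filter_genes(m, groups = groups)))
})

test_that("stabilized transform has its closed form and monotonicity", {
  m <- rbind(a = c(0, 0), b = c(1e6, 1e6))
  colnames(m) <- c("s1", "s2")
  tr <- transform_counts(m)
  expect_equal(unname(tr["a", ]), c(-1, -1))      # log2(0 + 0.5)
  expect_equal(tr[, "s1"], tr[, "s2"])            # equal counts, equal libraries
  expect_true(all(is.finite(tr)))

  set.seed(2)
  m <- toy_counts(n_genes = 100)
  tr <- transform_counts(m)
  for (i in 1:20) {
    g <- sample(nrow(m), 1); s <- sample(ncol(m), 1)
    m2 <- m
    m2[g, s] <- 2 * m[g, s]
    # fixed library: transform with the original library sizes
    tr2 <- log2(sweep(m2, 2, colSums(m), "/") * 1e6 + 0.5)
    gain <- tr2[g, s] - tr[g, s]
    expect_true(gain >= 0 && gain <= 1)
  }
})

test_that("TMM factors are 1 for identical or purely depth-scaled columns", {
  m <- toy_counts(n_genes = 200, n_samples = 3, lambda = 200)
  m[, 2] <- m[, 1]
  m[, 3] <- m[, 1] * 2L   # pure depth change
  f <- tmm_factors(m)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-9)
  expect_equal(prod(f), 1, tolerance = 1e-12)
  m0 <- m; m0[, 1] <- 0
  expect_error(tmm_factors(m0), "all-zero")
})

test_that("TMM factors match an independent trim-and-weight computation", {
  set.seed(31)
  m <- toy_counts(n_genes = 300, n_samples = 4, lambda = 150)
  m[1:10, 2] <- m[1:10, 2] * 40L   # inflate a few genes in one sample
  f <- tmm_factors(m)
  expect_equal(unname(f), unname(brute_force_tmm(m)), tolerance = 1e-8)
  expect_equal(prod(f), 1, tolerance = 1e-12)
})

test_that("paired DEA handles degenerate and spiked inputs", {
  set.seed(5)
  n_pairs <- 8
  samples <- data.frame(
    sample_id = c(rbind(paste0("P", 1:n_pairs, "_BL"),
                        paste0("P", 1:n_pairs, "_OT"))),
    patient_id = rep(paste0("P", 1:n_pairs), each = 2),
    timepoint = rep(c("BL", "OT"), n_pairs),
    group = "CB")
  # identical BL and OT -> no signal anywhere
  base <- matrix(stats::rpois(100 * n_pairs, 300), 100, n_pairs)
  m <- base[, rep(1:n_pairs, each = 2)]
  dimnames(m) <- list(sprintf("g%03d", 1:100), samples$sample_id)
  expect_warning(dea <- paired_dea(m, samples, "CB"),
                 "residual variances")   # limma flags the degenerate input
  expect_true(all(dea$log2fc == 0))
  expect_false(any(dea$deg))
  expect_true(all(is.finite(dea$p_value)))

  # one gene shifted up in every pair ranks first
  m2 <- matrix(stats::rpois(100 * 2 * n_pairs, 300), 100, 2 * n_pairs,
               dimnames = list(sprintf("g%03d", 1:100), samples$sample_id))
  ot_cols <- samples$sample_id[samples$timepoint == "OT"]
  m2["g007", ot_cols] <- m2["g007", ot_cols] * 4L
  dea2 <- paired_dea(m2, samples, "CB")
  expect_equal(dea2$gene[1], "g007")
  expect_equal(dea2$direction[1], "up")
  expect_true(all(dea2$adj_p >= dea2$p_value - 1e-15))
  expect_error(paired_dea(m2[, 1:4], samples[1:4, ], "CB"), "3 complete pairs")
})

test_that("moderated variance equals the stated empirical-Bayes pooling", {
  set.seed(6)
  gene_sd <- sqrt(stats::rchisq(200, df = 4) / 4)   # heterogeneous variances
  d <- matrix(stats::rnorm(200 * 10), 200, 10) * gene_sd
  fit <- limma::eBayes(limma::lmFit(d, matrix(1, 10, 1)))
  d0 <- fit$df.prior
  expect_true(is.finite(d0))
  s0sq <- fit$s2.prior
  manual <- (d0 * s0sq + fit$df.residual * fit$sigma^2) / (d0 + fit$df.residual)
  expect_equal(unname(fit$s2.post), unname(manual), tolerance = 1e-12)
})

test_that("group DEA detects a group-specific shift and respects ordering", {
  set.seed(7)
  n <- 8
  samples <- data.frame(
    sample_id = paste0("S", 1:(2 * n)),
    patient_id = paste0("P", 1:(2 * n)),
    timepoint = "OT",
    group = rep(c("CB", "N-CB"), each = n))
  m <- matrix(stats::rpois(150 * 2 * n, 300), 150, 2 * n,
              dimnames = list(sprintf("g%03d", 1:150), samples$sample_id))
  m["g010", samples$group == "CB"] <- m["g010", samples$group == "CB"] * 4L
  dea <- group_dea(m, samples)
  expect_equal(dea$gene[1], "g010")
  expect_gt(dea$log2fc[1], 1)  # CB minus N-CB
  expect_error(group_dea(m[, c(1, 2, 9, 10)], samples[c(1, 2, 9, 10), ]),
               "3 samples per group")
})

test_that("DEG set intersection produces the 7-region partition and signature", {
  r <- intersect_deg_sets(c("a", "b", "c"), c("c"), c("b", "c", "d"))
  expect_equal(r$signature, "b")
  expect_equal(unname(r$counts["all_three"]), 1)   # c
  expect_equal(unname(r$counts["cb_ot"]), 1)       # b
  expect_equal(unname(r$counts["ot_only"]), 1)     # d
  expect_equal(unname(r$counts["cb_only"]), 1)     # a
  expect_equal(sum(r$counts), 4)

  with_ncb <- intersect_deg_sets(c("a", "b", "c"), c("c"), c("b", "c", "d"),
                                 exclude_ncb = FALSE)
  expect_setequal(with_ncb$signature, c("b", "c"))

  d <- intersect_deg_sets(c("a"), c("b"), c("c"))
  expect_equal(unname(d$counts[c("cb_ncb", "cb_ot", "ncb_ot", "all_three")]),
               rep(0L, 4))

  set.seed(9)
  pool <- sprintf("g%02d", 1:40)
  s1 <- sample(pool, 15); s2 <- sample(pool, 10); s3 <- sample(pool, 20)
  r2 <- intersect_deg_sets(s1, s2, s3)
  expect_setequal(r2$signature, setdiff(intersect(s1, s3), s2))
  expect_equal(sum(r2$counts), length(unique(c(s1, s2, s3))))
})

test_that("signature scores are means with exact linearity", {
  set.seed(10)
  vals <- matrix(stats::rnorm(20 * 6), 20, 6,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("S", 1:6)))
  samples <- data.frame(sample_id = paste0("S", 1:6),
                        patient_id = paste0("P", 1:6), timepoint = "OT",
                        group = rep(c("CB", "N-CB"), 3))
  one <- signature_score(NULL, samples, "g03", values = vals)
  expect_equal(one$scores$score, unname(vals["g03", ]))

  set_ <- c("g01", "g05", "g09")
  base <- signature_score(NULL, samples, set_, values = vals)
  shifted <- vals
  shifted[set_, ] <- shifted[set_, ] + 2.5
  up <- signature_score(NULL, samples, set_, values = shifted)
  expect_equal(up$scores$score, base$scores$score + 2.5)
  expect_error(signature_score(NULL, samples, character(0), values = vals),
               "empty")
})

test_that("a CB-upshifted signature separates the groups by rank-sum", {
  cfg <- sim_config(seed = 14, n_genes = 400, n_signal_genes = 30,
                    discordant_rna_fraction = 0,
                    cohort_sizes = c(discovery = 40, test = 0, validation = 0),
                    n_patients = 40)
  pts <- simulate_cohort(cfg, n_cb = 20L)
  ex <- simulate_expression(pts, cfg)
  up_genes <- ex$signal_genes[attr(ex$signal_genes, "lfc") > 0]
  res <- signature_score(ex$counts, ex$samples, up_genes)
  expect_lt(res$test$p_value, 0.01)
  med <- tapply(res$scores$score, res$scores$group, stats::median)
  expect_gt(med["CB"], med["N-CB"])
})

test_that("hypergeometric enrichment reproduces exact combinatorial p-values", {
  universe <- sprintf("u%02d", 1:20)
  pathway <- universe[1:5]
  degs <- c(universe[1:3], universe[10])   # overlap 3 of 4
  res <- enrich_hypergeometric(degs, universe, list(pw = pathway))
  # (C(5,3)C(15,1) + C(5,4)C(15,0)) / C(20,4) = 155/4845
  expect_equal(res$p_value, 155 / 4845, tolerance = 1e-12)

  # a pathway equal to the DEG set is the most enriched among equal sizes
  pws <- list(hit = degs, miss = universe[11:14], other = universe[5:8])
  res2 <- enrich_hypergeometric(degs, universe, pws)
  expect_equal(res2$pathway[1], "hit")
  expect_true(all(res2$adj_p >= res2$p_value - 1e-15))
  expect_error(enrich_hypergeometric(degs, character(0), pws), "empty")
})

test_that("GMT gene sets parse by name", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg9"), f)
  sets <- read_gmt(f)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
})
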