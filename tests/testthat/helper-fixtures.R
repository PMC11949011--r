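# Shared builders for small in-code fixtures.

quant_stub <- function(copies, detectable = copies > 0) {
  structure(list(copies_per_ml = copies, detectable = detectable,
                 tumor_fraction = NA_real_),
            class = "ctdna_quant")
}

# Minimal sparse-PLS model with one feature and identity calibration,
# so predicted probability = plogis(x).
manual_spls_model <- function(cutoff = 0.55) {
  structure(list(
    selected_genes = "g1",
    weights = matrix(c(1, 0), 1, 2, dimnames = list("g1", c("comp1", "comp2"))),
    loadings = matrix(c(1, 0), 1, 2, dimnames = list("g1", c("comp1", "comp2"))),
    center = c(g1 = 0), scale = c(g1 = 1),
    calibration = c("(Intercept)" = 0, comp1 = 1),
    used_components = 1L, cutoff = cutoff, k = 1L, n_components = 2L
  ), class = "spls_model")
}

# Independent TMM implementation following the published trim-and-weight
# recipe (reference by upper-quartile CPM closest to the mean, 30% trim on
# M, 5% on A, precision weights, factors rescaled to multiply to 1).
brute_force_tmm <- function(counts) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  xr <- counts[, ref] / lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    xo <- counts[, j] / lib[j]
    ok <- xo > 0 & xr > 0
    m <- log2(xo[ok] / xr[ok])
    a <- (log2(xo[ok]) + log2(xr[ok])) / 2
    v <- (lib[j] - counts[ok, j]) / (lib[j] * counts[ok, j]) +
      (lib[ref] - counts[ok, ref]) / (lib[ref] * counts[ok, ref])
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Brute-force AUC: all positive-negative pairs, half credit for ties.
brute_force_auc <- function(scores, truth, positive = "N-CB") {
  sp <- scores[truth == positive]
  sn <- scores[truth != positive]
  conc <- 0
  for (a in sp) for (b in sn) {
    conc <- conc + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  conc / (length(sp) * length(sn))
}

# Independent log-rank computation: vectorized 2x2 summation over strata.
brute_force_logrank <- function(ta, ea, tb, eb) {
  times <- c(ta, tb); events <- c(ea, eb)
  ga <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  ut <- sort(unique(times[events]))
  n <- vapply(ut, function(t) sum(times >= t), numeric(1))
  na <- vapply(ut, function(t) sum(times >= t & ga), numeric(1))
  d <- vapply(ut, function(t) sum(times == t & events), numeric(1))
  da <- vapply(ut, function(t) sum(times == t & events & ga), numeric(1))
  oa <- sum(da)
  ea_ <- sum(d * na / n)
  v <- sum(ifelse(n > 1, d * (na / n) * (1 - na / n) * (n - d) / (n - 1), 0))
  (oa - ea_)^2 / v
}

# Benjamini-Hochberg by the step-up definition.
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Small deterministic count matrix with Poisson-ish structure.
toy_counts <- function(n_genes = 50, n_samples = 6, seed = 42, lambda = 100) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_genes * n_samples, lambda), n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  m
}
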