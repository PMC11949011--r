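#' Counts per million
#'
#' @param counts gene x sample matrix of nonnegative counts.
#' @param lib_sizes Optional library sizes (defaults to column sums); may be
#'   TMM-effective library sizes.
#' @return Matrix of CPM values.
#' @export
cpm_matrix <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes == 0)) {
    stop("zero-library sample(s): ",
         paste(colnames(counts)[lib_sizes == 0], collapse = ", "))
  }
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Expression filter: minimum CPM and coefficient of variation
#'
#' Removes genes whose CPM is below 1 in every sample, and genes whose
#' percent coefficient of variation of CPM exceeds `cv_max` within every
#' condition group (a gene is kept if at least one group expresses it with
#' CV at or below the threshold).
#'
#' @param counts gene x sample count matrix.
#' @param groups Optional factor/character of condition groups per sample;
#'   when missing all samples form one group.
#' @param cpm_min,cv_max Filter thresholds (defaults 1 CPM, 100 percent CV).
#' @return Filtered count matrix with attribute `"removed"` giving counts
#'   removed by each rule.
#' @export
filter_genes <- function(counts, groups = NULL, cpm_min = 1, cv_max = 100) {
  stopifnot(ncol(counts) >= 2)
  cpm <- cpm_matrix(counts)
  low <- rowSums(cpm >= cpm_min) == 0

  if (is.null(groups)) groups <- rep("all", ncol(counts))
  cv_ok_somewhere <- rep(FALSE, nrow(counts))
  for (g in unique(groups)) {
    sub <- cpm[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1, stats::sd)
    cv <- ifelse(m > 0, 100 * s / m, Inf)
    cv_ok_somewhere <- cv_ok_somewhere | (cv <= cv_max)
  }
  noisy <- !cv_ok_somewhere & !low

  keep <- !low & !noisy
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- c(low_cpm = sum(low), high_cv = sum(noisy))
  out
}

#' Stabilized expression values
#'
#' `log2(CPM + 0.5)`: a deterministic, monotone transform that flattens the
#' count-variance relationship enough for the moderated-t machinery and the
#' classifier (which standardizes its features anyway).
#'
#' @param counts Filtered gene x sample count matrix.
#' @param norm_factors Optional per-sample normalization factors (e.g. from
#'   [tmm_factors()]); effective library = column sum x factor.
#' @return Matrix of transformed values, finite everywhere.
#' @export
transform_counts <- function(counts, norm_factors = NULL) {
  lib <- colSums(counts)
  if (!is.null(norm_factors)) lib <- lib * norm_factors
  log2(cpm_matrix(counts, lib) + 0.5)
}

#' Trimmed mean of M-values normalization factors
#'
#' Per-sample scaling factors computed by the TMM method: the reference
#' sample is the one whose upper-quartile CPM is closest to the mean upper
#' quartile; each sample's factor is 2 to the weighted mean of gene-wise
#' log-ratios (M-values) after trimming 30% of M and 5% of A values;
#' factors are rescaled to multiply to 1. Delegates to
#' \code{edgeR::calcNormFactors}, which implements exactly this recipe.
#'
#' @param counts Filtered gene x sample count matrix (at least 2 samples).
#' @return Named numeric vector of factors multiplying to 1.
#' @export
tmm_factors <- function(counts) {
  stopifnot(ncol(counts) >= 2)
  if (any(colSums(counts) == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(f, colnames(counts))
}

#' Paired differential expression (BL vs OT within a group)
#'
#' Computes per-patient paired differences (OT minus BL) of TMM-normalized
#' stabilized expression values and tests each gene with a moderated paired
#' t statistic: gene-wise variances are shrunk toward a common prior by
#' empirical Bayes (posterior variance `(d0*s0^2 + d*s^2) / (d0 + d)` with
#' the prior estimated by method of moments on the log sample variances),
#' two-sided p values, Benjamini-Hochberg adjustment. Genes with zero
#' variance across pairs still receive finite statistics through the shrunk
#' variance.
#'
#' @param counts Filtered gene x sample count matrix.
#' @param samples Sample metadata (`sample_id`, `patient_id`, `timepoint`,
#'   `group`).
#' @param group Group whose paired samples are contrasted (e.g. `"CB"`).
#' @param deg_alpha Adjusted-p threshold flagging differentially expressed
#'   genes (default 0.05).
#' @return data.frame: `gene`, `log2fc` (mean OT - BL difference),
#'   `p_value`, `adj_p`, `direction`, `deg`.
#' @export
paired_dea <- function(counts, samples, group, deg_alpha = 0.05) {
  sel <- samples[samples$group == group, , drop = FALSE]
  pats <- intersect(sel$patient_id[sel$timepoint == "BL"],
                    sel$patient_id[sel$timepoint == "OT"])
  if (length(pats) < 3) stop("need at least 3 complete pairs in group ", group)

  nf <- tmm_factors(counts)
  expr <- transform_counts(counts, nf)
  bl_cols <- sel$sample_id[match(paste(pats, "BL"),
                                 paste(sel$patient_id, sel$timepoint))]
  ot_cols <- sel$sample_id[match(paste(pats, "OT"),
                                 paste(sel$patient_id, sel$timepoint))]
  diffs <- expr[, ot_cols, drop = FALSE] - expr[, bl_cols, drop = FALSE]

  fit <- limma::lmFit(diffs, design = matrix(1, ncol(diffs), 1,
                                             dimnames = list(NULL, "delta")))
  fit <- limma::eBayes(fit)
  finish_dea(rownames(diffs), fit$coefficients[, 1], fit$p.value[, 1],
             deg_alpha)
}

#' Group differential expression at one timepoint (CB vs N-CB)
#'
#' Two-sample moderated t on TMM-normalized stabilized values of the OT (or
#' BL) samples, contrasting CB minus N-CB, with the same empirical-Bayes
#' variance shrinkage and BH adjustment as [paired_dea()].
#'
#' @inheritParams paired_dea
#' @param timepoint Which timepoint to compare groups at (default `"OT"`).
#' @return As [paired_dea()]; `log2fc` is the CB minus N-CB difference.
#' @export
group_dea <- function(counts, samples, timepoint = "OT", deg_alpha = 0.05) {
  sel <- samples[samples$timepoint == timepoint, , drop = FALSE]
  if (min(table(sel$group)) < 3) stop("need at least 3 samples per group")

  nf <- tmm_factors(counts)
  expr <- transform_counts(counts, nf)[, sel$sample_id, drop = FALSE]
  grp <- factor(sel$group, levels = c("N-CB", "CB"))
  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(expr, design))
  finish_dea(rownames(expr), fit$coefficients[, 2], fit$p.value[, 2],
             deg_alpha)
}

finish_dea <- function(genes, log2fc, p, deg_alpha) {
  # degenerate all-zero-variance input: no evidence against the null
  p[!is.finite(p)] <- 1
  adj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = genes, log2fc = log2fc, p_value = p, adj_p = adj,
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    deg = adj <= deg_alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value), ]
}

#' Venn partition of three DEG sets and the discriminative signature
#'
#' Counts all 7 regions of the Venn diagram of the longitudinal CB, the
#' longitudinal N-CB and the on-treatment group DEG sets, and extracts the
#' signature set used for scoring: genes shared between the longitudinal CB
#' and the OT DEA. By default genes also differentially expressed in the
#' N-CB longitudinal DEA are excluded from the signature.
#'
#' @param deg_cb,deg_ncb,deg_ot Character vectors of DEG identifiers.
#' @param exclude_ncb Drop the N-CB overlap from the signature (default
#'   `TRUE`).
#' @return List: `counts` (named 7-region vector), `signature`, and the
#'   input sets.
#' @export
intersect_deg_sets <- function(deg_cb, deg_ncb, deg_ot, exclude_ncb = TRUE) {
  inx <- function(g, a, b, c) (g %in% a) & (g %in% b) & (g %in% c)
  all_genes <- unique(c(deg_cb, deg_ncb, deg_ot))
  a <- all_genes %in% deg_cb
  b <- all_genes %in% deg_ncb
  c_ <- all_genes %in% deg_ot
  counts <- c(
    cb_only = sum(a & !b & !c_),
    ncb_only = sum(!a & b & !c_),
    ot_only = sum(!a & !b & c_),
    cb_ncb = sum(a & b & !c_),
    cb_ot = sum(a & !b & c_),
    ncb_ot = sum(!a & b & c_),
    all_three = sum(a & b & c_)
  )
  signature <- intersect(deg_cb, deg_ot)
  if (exclude_ncb) signature <- setdiff(signature, deg_ncb)
  list(counts = counts, signature = signature,
       sets = list(cb = deg_cb, ncb = deg_ncb, ot = deg_ot))
}

#' Mean signature expression per patient
#'
#' Per-patient mean of TMM-normalized stabilized expression over a gene set
#' at one timepoint, with a rank-sum (Wilcoxon) comparison of the CB and
#' N-CB groups.
#'
#' @inheritParams paired_dea
#' @param gene_set Nonempty character vector of genes (must be present in
#'   `counts`).
#' @param timepoint Timepoint to score (default `"OT"`).
#' @param values Optional precomputed expression matrix (e.g. from
#'   [transform_counts()]); when supplied, normalization is skipped and
#'   `counts` may be `NULL`.
#' @return List: `scores` (data.frame `patient_id`, `group`, `score`) and
#'   `test` (the [wilcoxon_test()] result for CB vs N-CB).
#' @export
signature_score <- function(counts, samples, gene_set, timepoint = "OT",
                            values = NULL) {
  if (length(gene_set) == 0) stop("empty gene set")
  expr <- if (is.null(values)) {
    missing <- setdiff(gene_set, rownames(counts))
    if (length(missing)) {
      stop("gene set members absent from counts: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    transform_counts(counts, tmm_factors(counts))
  } else {
    values
  }
  sel <- samples[samples$timepoint == timepoint, , drop = FALSE]
  sc <- colMeans(expr[gene_set, sel$sample_id, drop = FALSE])
  scores <- data.frame(patient_id = sel$patient_id, group = sel$group,
                       score = unname(sc), stringsAsFactors = FALSE)
  tst <- wilcoxon_test(scores$score[scores$group == "CB"],
                       scores$score[scores$group == "N-CB"], paired = FALSE)
  list(scores = scores, test = tst)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of each pathway set against a
#' DEG set within a gene universe, with Benjamini-Hochberg adjustment
#' across pathways.
#'
#' @param deg_set Character vector of differentially expressed genes (subset
#'   of the universe).
#' @param universe Character vector: all genes tested.
#' @param pathways Named list of character vectors (subsets of the
#'   universe).
#' @param alpha Adjusted-p threshold flagging enrichment (default 0.05).
#' @return data.frame: `pathway`, `overlap`, `pathway_size`, `deg_size`,
#'   `universe_size`, `p_value`, `adj_p`, `enriched`.
#' @export
enrich_hypergeometric <- function(deg_set, universe, pathways, alpha = 0.05) {
  if (length(universe) == 0) stop("empty gene universe")
  deg_set <- intersect(deg_set, universe)
  N <- length(unique(universe))
  n <- length(unique(deg_set))
  res <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    K <- length(unique(pw))
    k <- length(intersect(deg_set, pw))
    # P(X >= k), X ~ Hypergeom(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, overlap = k, pathway_size = K, deg_size = n,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$adj_p <= alpha
  out[order(out$p_value), ]
}

#' Read a gene x sample count matrix
#'
#' Accepts a tab-separated matrix with gene identifiers in the first column,
#' or a MatrixMarket triplet file (`.mtx`) with companion `*_genes.txt` and
#' `*_samples.txt` files of row and column names.
#'
#' @param path Path to the `.tsv` or `.mtx` file.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("the Matrix package is required to read .mtx files")
    }
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, "_genes.txt"))
    colnames(m) <- readLines(paste0(stem, "_samples.txt"))
    return(m)
  }
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (name, description, then member genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "", USE.NAMES = FALSE)
  sets
}
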