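#' Multimodal arbitration configuration
#'
#' Uncertainty bands around the two standalone decision cutoffs: the ctDNA
#' ratio band is symmetric on the log2 scale around ratio 1,
#' `[2^-d_ct, 2^d_ct]`; the RNA probability band is
#' `[0.55 - d_rna, 0.55 + d_rna]`. Both are closed intervals.
#'
#' @param ratio_band_halfwidth Nonnegative `d_ct` (log2 units).
#' @param prob_band_halfwidth `d_rna` in `[0, 0.55]`.
#' @param prob_cutoff RNA probability cutoff the band is centred on
#'   (default 0.55).
#' @return List of class `"multimodal_config"`.
#' @export
multimodal_config <- function(ratio_band_halfwidth = 0.25,
                              prob_band_halfwidth = 0.05,
                              prob_cutoff = 0.55) {
  stopifnot(ratio_band_halfwidth >= 0,
            prob_band_halfwidth >= 0, prob_band_halfwidth <= prob_cutoff)
  structure(list(ratio_band_halfwidth = ratio_band_halfwidth,
                 prob_band_halfwidth = prob_band_halfwidth,
                 prob_cutoff = prob_cutoff),
            class = "multimodal_config")
}

#' Arbitrate between the ctDNA and RNA predictions for one patient
#'
#' Precedence: (i) ctDNA ratio inside its uncertainty band, RNA probability
#' outside its band: use the RNA label; (ii) probability inside its band,
#' ratio outside: use the ctDNA label; (iii) both inside: the RNA model is
#' prioritized; (iv) neither inside: the ctDNA label (the ctDNA prediction
#' is the base being adjusted). A missing modality falls back to the other
#' one.
#'
#' @param ratio ctDNA copies ratio OT/BL (0 for undetectable-at-both
#'   patients, may be `Inf`); `NA` when ctDNA is unavailable.
#' @param rna_prob RNA-model CB probability; `NA` when RNA is unavailable.
#' @param rna_label,ctdna_label Standalone `"CB"`/`"N-CB"` labels (`NA`
#'   allowed for a missing modality).
#' @param config A [multimodal_config()].
#' @return `"CB"` or `"N-CB"`.
#' @export
arbitrate <- function(ratio, rna_prob, rna_label, ctdna_label, config) {
  if (is.na(ratio) || is.na(ctdna_label)) return(rna_label)
  if (is.na(rna_prob) || is.na(rna_label)) return(ctdna_label)
  d_ct <- config$ratio_band_halfwidth
  d_rna <- config$prob_band_halfwidth
  in_ct <- ratio >= 2^(-d_ct) && ratio <= 2^d_ct
  in_rna <- rna_prob >= config$prob_cutoff - d_rna &&
    rna_prob <= config$prob_cutoff + d_rna
  if (in_ct && !in_rna) return(rna_label)       # ctDNA uncertain
  if (in_rna && !in_ct) return(ctdna_label)     # RNA uncertain
  if (in_ct && in_rna) return(rna_label)        # both uncertain: RNA wins
  ctdna_label                                   # both confident: ctDNA base
}

#' Evaluate one band configuration on a prediction table
#'
#' @param predictions data.frame with columns `ratio`, `rna_prob`,
#'   `rna_label`, `ctdna_label`.
#' @param config A [multimodal_config()].
#' @return Character vector of multimodal labels.
#' @export
apply_arbitration <- function(predictions, config) {
  vapply(seq_len(nrow(predictions)), function(i) {
    arbitrate(predictions$ratio[i], predictions$rna_prob[i],
              predictions$rna_label[i], predictions$ctdna_label[i], config)
  }, "")
}

#' Grid search for the uncertainty-band widths on the test cohort
#'
#' Evaluates every band pair on the grid, scoring each by the gain in
#' sensitivity plus specificity (N-CB positive) of the multimodal labels
#' over the standalone RNA model on the same patients. The winner maximizes
#' the gain; ties prefer the smaller total band `d_ct + d_rna`, then the
#' smaller `d_ct`. The function sees only the test cohort: validation truth
#' never enters band selection.
#'
#' @param predictions Test-cohort data.frame: `ratio`, `rna_prob`,
#'   `rna_label`, `ctdna_label`.
#' @param truth Test-cohort `"CB"`/`"N-CB"` truth labels.
#' @param ratio_grid,prob_grid Candidate half-widths (defaults
#'   `c(0, 0.25, 0.5, 0.75, 1)` log2 units and `c(0, 0.05, 0.1, 0.15, 0.2)`).
#' @param prob_cutoff RNA probability cutoff (default 0.55).
#' @return List: `config` (winning [multimodal_config()]), `grid`
#'   (data.frame `d_ct`, `d_rna`, `sensitivity`, `specificity`,
#'   `objective`), `rna_baseline` (standalone RNA SN/SP).
#' @export
grid_search_bands <- function(predictions, truth,
                              ratio_grid = c(0, 0.25, 0.5, 0.75, 1),
                              prob_grid = c(0, 0.05, 0.1, 0.15, 0.2),
                              prob_cutoff = 0.55) {
  if (length(ratio_grid) == 0 || length(prob_grid) == 0) {
    stop("empty band grid")
  }
  rna_cm <- confusion_metrics(predictions$rna_label, truth)
  rna_sum <- rna_cm$sensitivity + rna_cm$specificity

  grid <- expand.grid(d_ct = ratio_grid, d_rna = prob_grid,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- multimodal_config(grid$d_ct[i], grid$d_rna[i], prob_cutoff)
    cm <- confusion_metrics(apply_arbitration(predictions, cfg), truth)
    data.frame(d_ct = grid$d_ct[i], d_rna = grid$d_rna[i],
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               objective = cm$sensitivity + cm$specificity - rna_sum)
  })
  report <- do.call(rbind, res)
  ord <- order(-report$objective, report$d_ct + report$d_rna, report$d_ct)
  best <- report[ord[1], ]
  list(config = multimodal_config(best$d_ct, best$d_rna, prob_cutoff),
       grid = report,
       rna_baseline = list(sensitivity = rna_cm$sensitivity,
                           specificity = rna_cm$specificity))
}

#' Apply a frozen multimodal configuration to a cohort
#'
#' Labels every patient via [arbitrate()] and reports classification and
#' survival performance. Intended for the blinded validation cohort after
#' the bands were frozen on the test cohort.
#'
#' @param config A [multimodal_config()].
#' @param predictions data.frame: `ratio`, `rna_prob`, `rna_label`,
#'   `ctdna_label`.
#' @param truth Optional truth labels (`NULL` to only produce labels).
#' @param pfs,event Optional survival columns for stratification.
#' @return List: `labels`, `performance` ([confusion_metrics()] or `NULL`),
#'   `survival` ([stratify_survival()] or `NULL`).
#' @export
apply_multimodal <- function(config, predictions, truth = NULL,
                             pfs = NULL, event = NULL) {
  labels <- apply_arbitration(predictions, config)
  perf <- if (!is.null(truth)) confusion_metrics(labels, truth) else NULL
  surv <- if (!is.null(pfs) && !is.null(event)) {
    stratify_survival(labels, pfs, event)
  } else NULL
  list(labels = labels, performance = perf, survival = surv)
}
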