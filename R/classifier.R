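#' Fit a sparse PLS discriminant classifier
#'
#' NIPALS-style partial least squares on standardized features with a
#' sparsity constraint: the first component's loading vector is
#' soft-thresholded to its `k` largest-magnitude entries and later
#' components are restricted to the same support, so every fitted model
#' carries exactly `k` genes with nonzero loadings. The class is encoded as
#' a centred indicator; the discriminant score (the component scores) is
#' mapped to a CB probability by logistic calibration on the training data.
#' The fit is deterministic: NIPALS on a single response has a closed-form
#' weight vector per component, so `seed` only tags the model.
#'
#' @param X Patient x feature numeric matrix (no missing values). Features
#'   are typically per-patient on-treatment minus baseline expression
#'   changes of candidate genes.
#' @param y Logical (or `"CB"`/`"N-CB"`) class labels; `TRUE`/`"CB"` is the
#'   modelled positive probability.
#' @param k Number of features to retain (paper grid: 10, 15 or 20).
#' @param n_components Number of PLS components (default 2).
#' @param cutoff Probability cutoff for [classify()] (default 0.55).
#' @param seed Optional integer recorded in the model.
#' @return Object of class `"spls_model"`: `selected_genes`, `weights` and
#'   `loadings` (k x n_components), `center`, `scale`, `calibration`
#'   (logistic coefficients), `cutoff`, `k`, `n_components`.
#' @export
fit_spls <- function(X, y, k, n_components = 2L, cutoff = 0.55, seed = NULL) {
  y <- as_cb_logical(y)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (k > ncol(X)) stop("k exceeds the number of features")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (anyNA(X)) stop("X contains missing values")

  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sd_, "/")
  yc <- as.numeric(y) - mean(y)

  # component 1: weight = X'y, keep top-k magnitudes
  w1 <- drop(crossprod(Xs, yc))
  support <- order(abs(w1), decreasing = TRUE)[seq_len(k)]
  support <- sort(support)
  genes <- colnames(X)[support]

  Xk <- Xs[, support, drop = FALSE]
  W <- P <- matrix(0, k, n_components,
                   dimnames = list(genes, paste0("comp", seq_len(n_components))))
  Tm <- matrix(0, nrow(X), n_components)
  Xd <- Xk
  yd <- yc
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_ <- drop(Xd %*% w)
    tt <- sum(t_^2)
    p <- drop(crossprod(Xd, t_)) / tt
    c_ <- sum(yd * t_) / tt
    W[, h] <- w
    P[, h] <- p
    Tm[, h] <- t_
    Xd <- Xd - tcrossprod(t_, p)
    yd <- yd - c_ * t_
  }

  used <- which(colSums(Tm^2) > 0)
  cal_df <- data.frame(y = as.numeric(y), Tm[, used, drop = FALSE])
  cal <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = cal_df))

  structure(list(
    selected_genes = genes,
    weights = W, loadings = P,
    center = mu[support], scale = sd_[support],
    calibration = stats::coef(cal), used_components = used,
    cutoff = cutoff, k = k, n_components = n_components, seed = seed
  ), class = "spls_model")
}

as_cb_logical <- function(y) {
  if (is.logical(y)) return(y)
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    stopifnot(all(y %in% c("CB", "N-CB")))
    return(y == "CB")
  }
  as.logical(y)
}

spls_scores <- function(model, X) {
  missing <- setdiff(model$selected_genes, colnames(X))
  if (length(missing)) {
    stop("missing selected gene(s): ", paste(missing, collapse = ", "))
  }
  Xk <- as.matrix(X[, model$selected_genes, drop = FALSE])
  Xk <- sweep(sweep(Xk, 2, model$center, "-"), 2, model$scale, "/")
  nc <- model$n_components
  Tm <- matrix(0, nrow(Xk), nc)
  Xd <- Xk
  for (h in seq_len(nc)) {
    t_ <- drop(Xd %*% model$weights[, h])
    Tm[, h] <- t_
    Xd <- Xd - tcrossprod(t_, model$loadings[, h])
  }
  Tm
}

#' Predict CB probabilities from a sparse PLS model
#'
#' @param model A fitted [fit_spls()] model.
#' @param X Patient x feature matrix containing at least the model's
#'   selected genes (extra columns are ignored).
#' @return Numeric vector of CB probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, X) {
  Tm <- spls_scores(model, X)[, model$used_components, drop = FALSE]
  eta <- model$calibration[1] + drop(Tm %*% model$calibration[-1])
  stats::plogis(eta)
}

#' Classify patients as CB or N-CB
#'
#' Label is CB when the predicted CB probability reaches the model cutoff
#' (default 55%), N-CB otherwise.
#'
#' @inheritParams predict_proba
#' @return Character vector of `"CB"` / `"N-CB"` labels.
#' @export
classify <- function(model, X) {
  p <- predict_proba(model, X)
  ifelse(p >= model$cutoff, "CB", "N-CB")
}

#' Cross-validation plan
#'
#' @param n_repeats Number of repeated cross-validation iterations
#'   (default 10).
#' @param n_folds Folds per repeat (default 3), stratified by class.
#' @param seed Integer seed controlling fold assignment.
#' @param feature_grid Candidate feature counts (default `c(10, 15, 20)`).
#' @return List of class `"cv_plan"`.
#' @export
cv_plan <- function(n_repeats = 10L, n_folds = 3L, seed = 1L,
                    feature_grid = c(10L, 15L, 20L)) {
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 feature_grid = as.integer(feature_grid)),
            class = "cv_plan")
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation over the feature grid
#'
#' For every candidate feature count and every repeat, splits the samples
#' into stratified folds, fits on the in-fold data and pools the
#' out-of-fold CB probabilities into one cross-validated AUC. Out-of-fold
#' predictions never see the held-out labels. All candidates (one full-data
#' refit per feature count) are retained for test-cohort selection.
#'
#' @param X,y As in [fit_spls()].
#' @param plan A [cv_plan()].
#' @return List: `cv` (data.frame `k`, `repeat_id`, `auc`), `summary`
#'   (mean CV AUC per `k`), `candidates` (named list of full-data
#'   `spls_model`s, one per `k`), `folds` (fold assignments, for
#'   reproducibility checks).
#' @export
cross_validate <- function(X, y, plan = cv_plan()) {
  y <- as_cb_logical(y)
  if (min(table(y)) < plan$n_folds) {
    stop("each class needs at least n_folds members")
  }
  set.seed(plan$seed)
  folds <- replicate(plan$n_repeats, stratified_folds(y, plan$n_folds))

  rows <- list()
  for (k in plan$feature_grid) {
    for (r in seq_len(plan$n_repeats)) {
      fold <- folds[, r]
      oof <- rep(NA_real_, length(y))
      for (f in seq_len(plan$n_folds)) {
        tr <- fold != f
        m <- fit_spls(X[tr, , drop = FALSE], y[tr], k = k)
        oof[!tr] <- predict_proba(m, X[!tr, , drop = FALSE])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, repeat_id = r,
        auc = roc_auc(oof, ifelse(y, "CB", "N-CB"), positive = "CB")$auc)
    }
  }
  cv <- do.call(rbind, rows)
  summary <- stats::aggregate(auc ~ k, cv, mean)
  candidates <- lapply(plan$feature_grid, function(k) fit_spls(X, y, k = k))
  names(candidates) <- paste0("k", plan$feature_grid)
  list(cv = cv, summary = summary, candidates = candidates, folds = folds)
}

#' Select the best candidate model on an independent test cohort
#'
#' Scores every candidate on the test cohort by (a) ROC AUC and (b) the
#' absolute difference in Kaplan-Meier median PFS between the predicted CB
#' and predicted N-CB groups (an unreached median is replaced by the
#' largest observed time so the ranking stays total). Candidates are ranked
#' on both criteria; the winner minimizes the rank sum, ties broken by the
#' higher AUC.
#'
#' @param candidates Named list of `spls_model`s (e.g. from
#'   [cross_validate()]).
#' @param test_X Test-cohort feature matrix.
#' @param test_y Test-cohort CB labels.
#' @param test_pfs,test_event Test-cohort PFS (months) and event flags.
#' @return List: `model` (the winner), `scores` (per-candidate AUC, PFS
#'   separation and ranks).
#' @export
select_best_model <- function(candidates, test_X, test_y, test_pfs,
                              test_event) {
  test_y <- as_cb_logical(test_y)
  scores <- lapply(names(candidates), function(nm) {
    m <- candidates[[nm]]
    p <- predict_proba(m, test_X)
    auc <- roc_auc(p, ifelse(test_y, "CB", "N-CB"), positive = "CB")$auc
    lab <- ifelse(p >= m$cutoff, "CB", "N-CB")
    sep <- km_median_separation(lab, test_pfs, test_event)
    data.frame(candidate = nm, auc = auc, pfs_separation = sep,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, scores)
  if (all(!is.finite(scores$auc))) stop("no candidate with a finite AUC")
  scores$rank_auc <- rank(-scores$auc, ties.method = "min")
  scores$rank_sep <- rank(-scores$pfs_separation, ties.method = "min")
  scores$rank_sum <- scores$rank_auc + scores$rank_sep
  ord <- order(scores$rank_sum, -scores$auc)
  winner <- scores$candidate[ord[1]]
  list(model = candidates[[winner]], scores = scores, winner = winner)
}

km_median_separation <- function(labels, pfs, event) {
  if (length(unique(labels)) < 2) return(0)
  med <- vapply(c("CB", "N-CB"), function(g) {
    km <- km_estimate(pfs[labels == g], event[labels == g])
    if (is.na(km$median)) max(pfs) else km$median
  }, numeric(1))
  abs(med[1] - med[2])
}

#' Serialize a sparse PLS model to JSON
#'
#' @param model A fitted [fit_spls()] model.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spls_model <- function(model, path) {
  obj <- list(
    selected_genes = model$selected_genes,
    weights = as.data.frame(model$weights),
    loadings = as.data.frame(model$loadings),
    center = as.list(model$center), scale = as.list(model$scale),
    calibration = as.list(model$calibration),
    used_components = model$used_components,
    cutoff = model$cutoff, k = model$k, n_components = model$n_components)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
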