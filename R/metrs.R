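# Metabolic risk score (MetRS).
#
# A gradient-boosted decision-tree classifier (histogram-based, logistic
# loss, implemented in the package's C++ backend) is trained on all
# metabolites; features are ranked by total split information gain; the
# top-30 panel is refitted with a small hyperparameter grid and
# calibrated by isotonic regression fitted on inner out-of-sample
# predictions. Evaluation uses geography-blocked 10-fold
# cross-validation (whole assessment centres per fold), rank-based AUC
# with percentile bootstrap CIs, and DeLong tests for paired AUC
# comparisons.

# ---- boosted-tree wrapper ---------------------------------------------------

# quantile binning shared by fit and predict
gbt_bins <- function(X, n_bins = 64L) {
  lapply(seq_len(ncol(X)), function(j) {
    cuts <- unique(quantile(X[, j], probs = seq_len(n_bins - 1L) / n_bins,
                            type = 7, names = FALSE, na.rm = TRUE))
    cuts[is.finite(cuts)]
  })
}

gbt_apply_bins <- function(X, cuts) {
  out <- matrix(0L, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- findInterval(X[, j], cuts[[j]])
    v[is.na(v)] <- 0L  # missing values routed to the lowest bin
    out[, j] <- v
  }
  out
}

#' Fit a gradient-boosted tree classifier
#'
#' Histogram-based boosting with logistic loss and second-order split
#' gain; deterministic given the data. Used for feature ranking and the
#' MetRS classifier itself.
#'
#' @param X numeric feature matrix.
#' @param y binary 0/1 outcome vector with both classes present.
#' @param n_trees,learning_rate,max_depth,min_leaf,lambda,n_bins
#'   boosting hyperparameters.
#' @return a `gbt_model` with `importance` (per-feature total gain).
#' @export
gbt_fit <- function(X, y, n_trees = 150L, learning_rate = 0.1, max_depth = 3L,
                    min_leaf = 20L, lambda = 1, n_bins = 64L) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("training labels are single-class")
  cuts <- gbt_bins(X, n_bins)
  Xb <- gbt_apply_bins(X, cuts)
  fit <- gbt_fit_cpp(Xb, as.numeric(y), n_bins, as.integer(n_trees),
                     learning_rate, as.integer(max_depth),
                     as.integer(min_leaf), lambda, 1e-12)
  structure(list(trees = fit$trees, init = fit$init,
                 importance = setNames(fit$importance,
                                       colnames(X) %||% paste0("f", seq_len(ncol(X)))),
                 cuts = cuts, n_features = ncol(X),
                 feature_names = colnames(X),
                 params = list(n_trees = n_trees, learning_rate = learning_rate,
                               max_depth = max_depth, min_leaf = min_leaf,
                               lambda = lambda, n_bins = n_bins)),
            class = "gbt_model")
}

#' Predict from a boosted-tree model
#'
#' @param object a `gbt_model`.
#' @param newdata feature matrix with the training columns.
#' @param type `"response"` (probability), `"margin"` (raw log-odds) or
#'   `"contrib"` (per-feature additive path contributions; columns are
#'   features plus a final bias column, rows sum to the raw margin).
#' @param ... unused.
#' @export
predict.gbt_model <- function(object, newdata, type = c("response", "margin", "contrib"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) stop("feature count mismatch")
  Xb <- gbt_apply_bins(X, object$cuts)
  if (type == "contrib") {
    out <- gbt_contrib_cpp(object[c("trees", "init")], Xb)
    colnames(out) <- c(object$feature_names %||% paste0("f", seq_len(object$n_features)),
                       "bias")
    return(out)
  }
  m <- gbt_margin_cpp(object[c("trees", "init")], Xb)
  if (type == "margin") m else 1 / (1 + exp(-m))
}

# ---- folds and panel selection ---------------------------------------------

#' Geography-blocked fold assignment
#'
#' Assessment centres (not individuals) are partitioned into `k` folds
#' by greedy largest-first size balancing: centres are sorted by size
#' descending (ties shuffled under `seed`) and each centre joins the
#' currently smallest fold, so all members of a centre always share a
#' fold.
#'
#' @param centres character vector, one assessment centre per participant.
#' @param k number of folds (default 10).
#' @param seed integer seed (tie-breaking only).
#' @return integer fold id (1..k) per participant.
#' @export
assign_geographic_folds <- function(centres, k = 10L, seed = 1L) {
  if (anyNA(centres)) stop("every participant needs a centre")
  sizes <- table(centres)
  if (length(sizes) < k) stop("fewer centres than folds")
  set.seed(substream_seed(seed, "folds"))
  ord <- sample(names(sizes))                       # shuffle, then stable sort
  ord <- ord[order(-as.vector(sizes[ord]))]
  fold_of <- setNames(integer(length(sizes)), names(sizes))
  load <- numeric(k)
  for (cn in ord) {
    f <- which.min(load)
    fold_of[cn] <- f
    load[f] <- load[f] + sizes[cn]
  }
  unname(fold_of[centres])
}

#' Rank metabolites by boosted-tree information gain and select a panel
#'
#' Fits the boosted classifier on all features and ranks them by total
#' split gain (descending; ties broken by column order). The panel is
#' the `top_k` head of the ranking.
#'
#' @param X training feature matrix (all metabolites).
#' @param y binary labels.
#' @param top_k panel size (default 30).
#' @param seed integer seed (recorded; the fit itself is deterministic).
#' @param ... boosting hyperparameters passed to [gbt_fit()].
#' @return list with `ranking` (feature names, best first), `ranks`
#'   (named rank vector), `panel` (top_k names), `importance`.
#' @export
rank_and_select <- function(X, y, top_k = 30L, seed = 1L, ...) {
  fit <- gbt_fit(X, y, ...)
  imp <- fit$importance
  ord <- order(-imp, seq_along(imp))
  ranking <- names(imp)[ord]
  ranks <- setNames(match(names(imp), ranking), names(imp))
  list(ranking = ranking, ranks = ranks,
       panel = head(ranking, top_k), importance = imp, seed = seed)
}

#' Cross-validated panel: average feature ranks over training folds
#'
#' @param X full feature matrix; `y` labels; `folds` integer fold ids.
#' @param top_k panel size.
#' @param ... passed to [gbt_fit()].
#' @return list with `panel` (top_k by mean rank), `mean_rank`,
#'   `per_fold` rankings.
#' @export
select_panel_cv <- function(X, y, folds, top_k = 30L, ...) {
  per_fold <- lapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    rank_and_select(X[tr, , drop = FALSE], y[tr], top_k = top_k, ...)$ranks
  })
  mr <- rowMeans(do.call(cbind, per_fold))
  ord <- order(mr, seq_along(mr))
  list(panel = names(mr)[ord][seq_len(top_k)], mean_rank = sort(mr),
       per_fold = per_fold)
}

# ---- calibration ------------------------------------------------------------

iso_fit <- function(scores, y) {
  o <- order(scores, y)
  fit <- isoreg(scores[o], y[o])
  x <- fit$x; yf <- fit$yf
  keep <- !duplicated(x, fromLast = TRUE)
  sf <- stats::approxfun(x[keep], yf[keep], method = "linear", rule = 2, ties = "ordered")
  structure(list(fun = sf), class = "iso_calibrator")
}

predict_iso <- function(cal, scores) pmin(pmax(cal$fun(scores), 0), 1)

#' Train a calibrated MetRS fold model
#'
#' Trains the boosted classifier on the selected metabolite panel (plus
#' demographics when supplied), choosing hyperparameters by a small grid
#' on an inner 80/20 split of the training data, then fits an isotonic
#' calibrator on the inner held-out predictions (never the boosting rows
#' themselves) and refits the chosen configuration on all training rows.
#' The calibrated probability is the MetRS.
#'
#' @param X training metabolite matrix (ids x all metabolites).
#' @param y binary training labels.
#' @param panel metabolite names to use (fixed before this call; the
#'   caller guarantees the panel was selected on training data only).
#' @param demographics optional data.frame/matrix of demographic columns
#'   (already numeric/dummy-coded) appended to the panel.
#' @param seed integer seed for the inner split.
#' @param grid list of hyperparameter lists to try; default a small
#'   learning-rate/size grid.
#' @return `metrs_fold` list: `model`, `calibrator`, `panel`,
#'   `chosen_params`, `inner_auc`.
#' @export
train_calibrated <- function(X, y, panel, demographics = NULL, seed = 1L,
                             grid = NULL) {
  missing_panel <- setdiff(panel, colnames(X))
  if (length(missing_panel))
    stop("panel references unknown metabolite(s): ",
         paste(missing_panel, collapse = ", "))
  Xp <- X[, panel, drop = FALSE]
  if (!is.null(demographics)) Xp <- cbind(Xp, as.matrix(demographics))
  grid <- grid %||% list(
    list(n_trees = 150L, learning_rate = 0.1, max_depth = 3L),
    list(n_trees = 300L, learning_rate = 0.05, max_depth = 3L))
  set.seed(substream_seed(seed, "inner_split"))
  n <- nrow(Xp)
  inner_val <- sample.int(n) <= ceiling(0.2 * n)
  if (length(unique(y[!inner_val])) < 2L || length(unique(y[inner_val])) < 2L)
    stop("inner split lost a class; too few cases")
  best <- NULL; best_auc <- -Inf; best_val_pred <- NULL
  for (g in grid) {
    fit <- do.call(gbt_fit, c(list(X = Xp[!inner_val, , drop = FALSE],
                                   y = y[!inner_val]), g))
    pv <- predict(fit, Xp[inner_val, , drop = FALSE], type = "margin")
    a <- auc_rank(pv, y[inner_val])
    if (a > best_auc) { best_auc <- a; best <- g; best_val_pred <- pv }
  }
  calibrator <- iso_fit(best_val_pred, y[inner_val])
  final <- do.call(gbt_fit, c(list(X = Xp, y = y), best))
  structure(list(model = final, calibrator = calibrator, panel = panel,
                 has_demographics = !is.null(demographics),
                 demo_names = if (is.null(demographics)) NULL else colnames(demographics),
                 chosen_params = best, inner_auc = best_auc, seed = seed),
            class = "metrs_fold")
}

#' @export
predict.metrs_fold <- function(object, newdata, demographics = NULL, ...) {
  Xp <- newdata[, object$panel, drop = FALSE]
  if (object$has_demographics) {
    if (is.null(demographics)) stop("model was trained with demographics")
    Xp <- cbind(Xp, as.matrix(demographics))
  }
  m <- predict(object$model, Xp, type = "margin")
  predict_iso(object$calibrator, m)
}

# ---- evaluation -------------------------------------------------------------

#' Rank-statistic AUC
#'
#' Mann-Whitney form: mean pairwise concordance of case vs control
#' scores, ties counted 1/2.
#'
#' @param scores numeric scores; `labels` binary 0/1.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("labels are single-class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong covariance machinery for paired AUC comparison
delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  rall <- rank(c(pos, neg), ties.method = "average")
  rpos <- rank(pos, ties.method = "average")
  rneg <- rank(neg, ties.method = "average")
  v10 <- (rall[seq_len(m)] - rpos) / n
  v01 <- 1 - (rall[m + seq_len(n)] - rneg) / m
  list(auc = (sum(rall[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided nonparametric comparison of the AUCs of two score vectors
#' on the same labels. Comparing a score vector with itself returns
#' `p = 1` by convention.
#'
#' @param scores1,scores2 score vectors on identical observations.
#' @param labels binary 0/1 labels.
#' @return list with `auc1`, `auc2`, `z`, `p`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  labels <- as.integer(labels)
  c1 <- delong_components(scores1, labels)
  c2 <- delong_components(scores2, labels)
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  S <- s10 / m + s01 / n
  vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- c1$auc - c2$auc
  if (vd <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc1 = c1$auc, auc2 = c2$auc, z = z, p = p)
}

#' Evaluate pooled out-of-fold scores
#'
#' AUC point estimate with a percentile bootstrap CI over participants,
#' plus optional DeLong comparisons against alternative score vectors on
#' the same labels.
#'
#' @param scores pooled held-out scores.
#' @param labels binary 0/1 labels.
#' @param B bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param compare optional named list of score vectors to compare via
#'   [delong_test()].
#' @return `evaluation_report` list: `auc`, `ci` (2.5/97.5 percentiles),
#'   `boot_median`, `delong` (named list), `B`.
#' @export
evaluate_scores <- function(scores, labels, B = 1000L, seed = 1L, compare = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels are single-class")
  point <- auc_rank(scores, labels)
  set.seed(substream_seed(seed, "bootstrap"))
  n <- length(scores)
  boot <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) < 2L) return(NA_real_)
    auc_rank(scores[idx], labels[idx])
  }, numeric(1))
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  delong <- NULL
  if (!is.null(compare))
    delong <- lapply(compare, function(s2) delong_test(scores, s2, labels))
  structure(list(auc = point, ci = ci,
                 boot_median = median(boot, na.rm = TRUE),
                 delong = delong, B = B),
            class = "evaluation_report")
}

#' Per-feature additive attributions
#'
#' Exact tree-path attribution from the boosted ensemble: per
#' individual, contributions plus the bias column sum to the raw margin.
#' For reporting, each feature's contributions are also normalized to
#' zero mean and unit SD across individuals (constant features keep 0).
#'
#' @param model a `gbt_model` or `metrs_fold`.
#' @param X feature matrix (panel plus demographics for a `metrs_fold`).
#' @return list with `contributions` (n x features+bias), `normalized`,
#'   and `mean_abs` (per-feature mean absolute contribution).
#' @export
attribute <- function(model, X) {
  gm <- if (inherits(model, "metrs_fold")) model$model else model
  if (!inherits(gm, "gbt_model")) stop("attribution requires a tree model")
  contrib <- predict(gm, X, type = "contrib")
  feat <- contrib[, -ncol(contrib), drop = FALSE]
  nrm <- apply(feat, 2L, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  list(contributions = contrib, normalized = nrm,
       mean_abs = colMeans(abs(feat)))
}

#' Full geography-blocked MetRS cross-validation
#'
#' Runs the paper-style pipeline for one disease: per fold, rank and
#' select the panel on the training folds, train the calibrated
#' classifier, and score the held-out fold; pooled out-of-fold scores
#' are evaluated with bootstrap CIs. Optionally fits demographic-only
#' and metabolite+demographic variants for DeLong comparison.
#'
#' @param X metabolite matrix (ids x metabolites).
#' @param y binary labels.
#' @param centres assessment centre per participant.
#' @param demographics optional numeric/dummy demographic matrix.
#' @param k folds (default 10); `top_k` panel size (default 30).
#' @param B bootstrap iterations; `seed` global seed.
#' @param ... passed to [gbt_fit()] during ranking.
#' @return list with `scores` (out-of-fold MetRS), `folds`, `panel`
#'   (mean-rank top_k across folds), `report`, and when demographics are
#'   given `scores_demo`, `scores_combined`, `delong`.
#' @export
metrs_cv <- function(X, y, centres, demographics = NULL, k = 10L, top_k = 30L,
                     B = 1000L, seed = 1L, ...) {
  folds <- assign_geographic_folds(centres, k = k, seed = seed)
  n <- nrow(X)
  scores <- rep(NA_real_, n)
  scores_demo <- if (!is.null(demographics)) rep(NA_real_, n) else NULL
  scores_comb <- if (!is.null(demographics)) rep(NA_real_, n) else NULL
  fold_ranks <- list()
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    rs <- rank_and_select(X[tr, , drop = FALSE], y[tr], top_k = top_k,
                          seed = substream_seed(seed, paste0("rank", f)), ...)
    fold_ranks[[as.character(f)]] <- rs$ranks
    fm <- train_calibrated(X[tr, , drop = FALSE], y[tr], rs$panel,
                           seed = substream_seed(seed, paste0("fold", f)))
    scores[te] <- predict(fm, X[te, , drop = FALSE])
    if (!is.null(demographics)) {
      fd <- train_calibrated(demographics[tr, , drop = FALSE], y[tr],
                             colnames(demographics),
                             seed = substream_seed(seed, paste0("demo", f)))
      scores_demo[te] <- predict(fd, demographics[te, , drop = FALSE])
      fc <- train_calibrated(X[tr, , drop = FALSE], y[tr], rs$panel,
                             demographics = demographics[tr, , drop = FALSE],
                             seed = substream_seed(seed, paste0("comb", f)))
      scores_comb[te] <- predict(fc, X[te, , drop = FALSE],
                                 demographics = demographics[te, , drop = FALSE])
    }
  }
  mr <- rowMeans(do.call(cbind, fold_ranks))
  panel <- names(sort(mr))[seq_len(top_k)]
  compare <- NULL
  if (!is.null(demographics))
    compare <- list(demographic = scores_demo, combined = scores_comb)
  report <- evaluate_scores(scores, y, B = B, seed = seed, compare = compare)
  out <- list(scores = scores, folds = folds, panel = panel,
              mean_rank = sort(mr), report = report)
  if (!is.null(demographics)) {
    out$scores_demo <- scores_demo
    out$scores_combined <- scores_comb
    out$delong <- list(
      metrs_vs_demo = delong_test(scores, scores_demo, y),
      combined_vs_demo = delong_test(scores_comb, scores_demo, y))
  }
  out
}
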