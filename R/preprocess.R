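# Metabolite QC and transformation.
#
# The transform chain mirrors standard NMR-metabolomics practice:
# outliers are removed on the raw concentration scale (anything beyond
# four interquartile ranges from the median), then values are
# natural-log transformed and z-standardized. Outlier detection precedes
# the log transform because concentrations are right-skewed and the
# IQR rule is defined on the measured scale.

#' QC-transform a metabolite matrix
#'
#' Per metabolite: flag values outside `median +/- iqr_mult * IQR`
#' (computed on the raw scale with the stated quantile convention) as
#' missing, natural-log transform the remainder, and z-standardize to
#' mean 0, SD 1 over retained values. Missing values propagate.
#'
#' @param raw numeric matrix (participants x metabolites) or vector; all
#'   non-missing values must be strictly positive.
#' @param iqr_mult IQR multiplier for the outlier fence (default 4).
#' @param qtype quantile algorithm passed to [stats::quantile()];
#'   default 7 (linear interpolation between order statistics). The
#'   outlier mask depends on this convention, hence it is configurable.
#' @param outlier_step set `FALSE` to skip the outlier fence (used e.g.
#'   for idempotence checks and pre-cleaned input).
#' @return list with `z` (transformed matrix) and `report`
#'   (`transform_report`: per-metabolite outlier ids, median, IQR, and
#'   post-transform mean/SD).
#' @export
qc_transform <- function(raw, iqr_mult = 4, qtype = 7, outlier_step = TRUE) {
  vec_in <- is.null(dim(raw))
  m <- as.matrix(raw)
  if (is.null(colnames(m))) colnames(m) <- sprintf("met_%03d", seq_len(ncol(m)))
  z <- m * NA_real_
  rep_rows <- vector("list", ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    if (sum(ok) < 10L)
      stop("metabolite ", colnames(m)[j], ": fewer than 10 non-missing values")
    if (any(x[ok] <= 0))
      stop("metabolite ", colnames(m)[j],
           ": non-positive value encountered; log transform requires > 0")
    med <- median(x[ok])
    iqr <- diff(quantile(x[ok], c(0.25, 0.75), type = qtype, names = FALSE))
    out_mask <- rep(FALSE, length(x))
    if (outlier_step) {
      out_mask <- ok & (x < med - iqr_mult * iqr | x > med + iqr_mult * iqr)
    }
    keep <- ok & !out_mask
    lx <- log(x[keep])
    s <- sd(lx)
    if (!is.finite(s) || s == 0)
      stop("metabolite ", colnames(m)[j],
           ": zero variance after outlier removal; cannot z-standardize")
    z[keep, j] <- (lx - mean(lx)) / s
    rep_rows[[j]] <- list(metabolite = colnames(m)[j],
                          n_outliers = sum(out_mask),
                          outlier_rows = which(out_mask),
                          median = med, iqr = iqr,
                          post_mean = mean(z[keep, j]), post_sd = sd(z[keep, j]))
  }
  report <- structure(list(metabolites = setNames(rep_rows, colnames(m)),
                           iqr_mult = iqr_mult, qtype = qtype,
                           covariates = list()),
                      class = "transform_report")
  list(z = if (vec_in) z[, 1L] else z, report = report)
}

#' Impute covariates by within-sex mode / median
#'
#' Discrete covariates are filled with the within-sex mode (ties broken
#' by the lexicographically smallest category, logged), continuous ones
#' with the within-sex median. A sex stratum with no observed values for
#' a covariate falls back to the overall mode/median. Non-missing entries
#' are preserved bit-exactly. Covariates missing in more than
#' `warn_frac` of rows trigger a warning but are imputed anyway.
#'
#' @param covariates data.frame including a complete `sex` column.
#' @param sex_col name of the sex column.
#' @param skip columns never imputed (identifiers etc.).
#' @param warn_frac missingness fraction above which a warning is issued.
#' @return list with `covariates` (no missing values remain) and
#'   `report` (fill values and counts per covariate x stratum).
#' @export
impute_covariates <- function(covariates, sex_col = "sex",
                              skip = c("id", "centre"), warn_frac = 0.05) {
  stopifnot(sex_col %in% names(covariates))
  if (anyNA(covariates[[sex_col]])) stop("sex column must be complete")
  log <- list()
  for (cv in setdiff(names(covariates), c(sex_col, skip))) {
    x <- covariates[[cv]]
    n_miss <- sum(is.na(x))
    if (n_miss == 0L) next
    if (n_miss / length(x) > warn_frac)
      warning(sprintf("covariate %s is %.1f%% missing; imputing anyway",
                      cv, 100 * n_miss / length(x)))
    discrete <- is.character(x) || is.factor(x) || is.logical(x) ||
      (is.numeric(x) && all(x[!is.na(x)] %in% c(0, 1)))  # 0/1 indicators
    for (s in unique(covariates[[sex_col]])) {
      in_s <- covariates[[sex_col]] == s
      miss <- in_s & is.na(x)
      if (!any(miss)) next
      src <- x[in_s & !is.na(x)]
      fallback <- FALSE
      if (length(src) == 0L) { src <- x[!is.na(x)]; fallback <- TRUE }
      fill <- if (discrete) {
        f <- stat_mode(src)
        if (is.numeric(x)) as.numeric(f) else f
      } else median(src)
      x[miss] <- fill
      log[[paste(cv, s, sep = ".")]] <- list(covariate = cv, stratum = s,
                                             fill = fill, n_filled = sum(miss),
                                             overall_fallback = fallback)
    }
    covariates[[cv]] <- x
  }
  list(covariates = covariates,
       report = structure(list(covariates = log, metabolites = list()),
                          class = "transform_report"))
}

#' Pairwise Spearman correlation matrix of the metabolite panel
#'
#' Rank correlations with pairwise-complete handling of missing values.
#' Columns with zero rank variance yield `NA` correlations with a
#' warning rather than an error.
#'
#' @param z numeric matrix (participants x metabolites).
#' @param min_pairs minimum complete pairs required per metabolite pair.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(z, min_pairs = 3L) {
  z <- as.matrix(z)
  cc <- crossprod(!is.na(z))
  if (any(cc[upper.tri(cc)] < min_pairs))
    stop("fewer than ", min_pairs, " complete pairs for some metabolite pair")
  zero_var <- apply(z, 2L, function(x) {
    x <- x[!is.na(x)]; length(unique(x)) <= 1L
  })
  if (any(zero_var))
    warning("zero rank variance in: ",
            paste(colnames(z)[zero_var], collapse = ", "),
            "; correlations set to NA")
  suppressWarnings(r <- stats::cor(z, method = "spearman",
                                   use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}
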