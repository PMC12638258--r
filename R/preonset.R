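# Nested case-control pre-onset divergence profiling.
#
# Incident cases are matched to never-diagnosed controls on a propensity
# score (logistic model of case status on sex, age, ethnicity, BMI and
# TDI), nearest neighbour without replacement; each control inherits its
# case's time-to-onset as a proxy time. Case-control metabolite
# differences are then profiled within one-year time-to-onset bins, and
# a backward screen walking from onset outward calls the bin at which
# divergence emerged.

#' Propensity-score matching of incident cases to controls
#'
#' Fits a logistic propensity model of case status on the matching
#' covariates over cases plus pool, then greedily assigns each case its
#' `ratio` nearest unused pool members by absolute distance on the
#' propensity (linear-predictor) scale, without replacement, processing
#' cases in randomized order under `seed` to break greedy-order
#' dependence.
#'
#' @param cases data.frame of cases: `id`, the matching covariates, and
#'   `time_to_onset` (years from baseline to diagnosis).
#' @param pool data.frame of eligible (never-diagnosed) controls: `id`
#'   plus the matching covariates; must be disjoint from `cases`.
#' @param covariates matching covariate names (default sex, age,
#'   ethnicity, BMI, TDI); must be complete (post-imputation).
#' @param ratio controls per case (default 5).
#' @param seed integer seed for the case processing order.
#' @return data.frame of matched pairs (`case_id`, `control_id`,
#'   `proxy_time`, `distance`); attribute `deficit` counts unfilled
#'   control slots when the pool ran short.
#' @export
propensity_match <- function(cases, pool,
                             covariates = c("sex", "age", "ethnicity", "bmi", "tdi"),
                             ratio = 5L, seed = 1L) {
  stopifnot(nrow(cases) > 0L, nrow(pool) > 0L)
  if (length(intersect(cases$id, pool$id))) stop("cases present in control pool")
  if (!"time_to_onset" %in% names(cases)) stop("cases need a time_to_onset column")
  if (any(cases$time_to_onset <= 0)) stop("time_to_onset must be > 0")
  both <- rbind(cbind(cases[, c("id", covariates)], .case = 1L),
                cbind(pool[, c("id", covariates)], .case = 0L))
  use_cv <- covariates
  for (cv in covariates) {
    if (anyNA(both[[cv]])) stop("matching covariate ", cv, " has missing values")
    if (is.character(both[[cv]])) both[[cv]] <- factor(both[[cv]])
    if (is.factor(both[[cv]]) && nlevels(droplevels(both[[cv]])) < 2L)
      use_cv <- setdiff(use_cv, cv)  # constant: uninformative for the score
  }
  X <- model.matrix(~ ., data = both[, use_cv, drop = FALSE])
  fit <- suppressWarnings(glm.fit(X, both$.case, family = binomial()))
  score <- as.vector(X %*% fit$coefficients)
  cs <- score[both$.case == 1L]
  ps <- score[both$.case == 0L]
  o <- order(ps)
  set.seed(seed)
  case_order <- sample.int(nrow(cases))
  picks <- nn_match_cpp(cs[case_order], ps[o], as.integer(ratio))
  ci <- rep(case_order, each = ratio)       # case row per slot
  pk <- as.vector(t(picks))                 # pool slot per case, 0 = unfilled
  filled <- pk > 0L
  res <- data.frame(case_id = cases$id[ci[filled]],
                    control_id = pool$id[o][pk[filled]],
                    proxy_time = cases$time_to_onset[ci[filled]],
                    distance = abs(ps[o][pk[filled]] - cs[ci[filled]]),
                    stringsAsFactors = FALSE)
  res <- res[order(match(res$case_id, cases$id)), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "deficit") <- sum(!filled)
  attr(res, "propensity_coef") <- fit$coefficients
  res
}

#' Standardized mean differences of matching covariates
#'
#' Balance diagnostic: for each covariate (dummy-coded if categorical),
#' the absolute difference of case and matched-control means divided by
#' the pooled SD.
#'
#' @param matched matched pairs from [propensity_match()].
#' @param covariates covariate data.frame with `id`.
#' @param covariate_names which columns to assess.
#' @return named numeric vector of absolute SMDs.
#' @export
matching_balance <- function(matched, covariates,
                             covariate_names = c("sex", "age", "ethnicity", "bmi", "tdi")) {
  df <- covariates[match(c(matched$case_id, matched$control_id), covariates$id),
                   covariate_names, drop = FALSE]
  for (nm in names(df)) if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  mm <- model.matrix(~ . - 1, data = df)
  grp <- rep(c(1L, 0L), c(nrow(matched), nrow(matched)))
  apply(mm, 2L, function(x) {
    s <- sqrt((var(x[grp == 1L]) + var(x[grp == 0L])) / 2)
    if (!is.finite(s) || s == 0) return(0)
    abs(mean(x[grp == 1L]) - mean(x[grp == 0L])) / s
  })
}

#' Per-timeframe case-control divergence profile
#'
#' Cases are assigned to one-year time-to-onset bins `b = (b-1, b]`
#' (i.e. `ceiling(time_to_onset)`); matched controls join the same bin
#' via their proxy time. Within each bin, metabolite values are adjusted
#' by regressing out smoking, statin use and fasting time (model fitted
#' on that bin's controls, residuals applied to all, so the case-control
#' contrast is not absorbed), and the bin summary is
#' `z_b = (case mean - control mean) / control spread` with a two-sided
#' Welch t-test p-value on the adjusted values.
#'
#' @param matched matched pairs from [propensity_match()].
#' @param z QC-transformed metabolite matrix, participant ids as rownames.
#' @param covariates covariate data.frame with `id` (post-imputation).
#' @param disease_id label stored on the profile rows.
#' @param bins number of one-year bins (default 15).
#' @param min_cases_per_bin bins with fewer cases are marked unavailable.
#' @param adjust covariates regressed out within bins.
#' @param denominator `"sd"` (default) or `"variance"` of the adjusted
#'   control values.
#' @return long data.frame: `disease_id`, `metabolite_id`, `bin`, `z`,
#'   `p`, `n_cases`, `n_controls`, `available`.
#' @export
timeframe_profile <- function(matched, z, covariates, disease_id = "disease",
                              bins = 15L, min_cases_per_bin = 10L,
                              adjust = c("smoking", "statin", "fasting"),
                              denominator = c("sd", "variance")) {
  denominator <- match.arg(denominator)
  cs <- unique(matched[, c("case_id", "proxy_time")])
  over <- cs$proxy_time > bins
  if (any(over)) {
    message(sum(over), " case(s) with time-to-onset beyond ", bins,
            " years excluded from profiling")
    keep_cases <- cs$case_id[!over]
    matched <- matched[matched$case_id %in% keep_cases, , drop = FALSE]
  }
  case_bin <- ceiling(matched$proxy_time)
  mets <- colnames(z)
  out <- vector("list", bins)
  X_adj <- covariate_design(covariates, adjust)
  for (b in seq_len(bins)) {
    in_b <- case_bin == b
    cids <- unique(matched$case_id[in_b])
    kids <- matched$control_id[in_b]
    nc <- length(cids); nk <- length(kids)
    if (nc < min_cases_per_bin || nk < 2L) {
      out[[b]] <- data.frame(disease_id = disease_id, metabolite_id = mets,
                             bin = b, z = NA_real_, p = NA_real_,
                             n_cases = nc, n_controls = nk, available = FALSE)
      next
    }
    ids <- c(cids, kids)
    grp <- rep(c(TRUE, FALSE), c(nc, nk))
    Xb <- X_adj[ids, , drop = FALSE]
    Y <- z[ids, , drop = FALSE]
    # fit adjustment on controls only, residualize everyone; metabolite
    # values masked at QC stay missing and are dropped per metabolite
    nm <- length(mets)
    zval <- pval <- rep(NA_real_, nm)
    nc_eff <- nk_eff <- integer(nm)
    for (jm in seq_len(nm)) {
      yj <- Y[, jm]
      okj <- !is.na(yj)
      ctrl <- okj & !grp
      if (sum(grp & okj) < min_cases_per_bin || sum(ctrl) < 2L) next
      cf <- lm.fit(Xb[ctrl, , drop = FALSE], yj[ctrl])$coefficients
      res_j <- yj - as.vector(Xb %*% cf)
      rc <- res_j[grp & okj]; rk <- res_j[ctrl]
      vk <- var(rk); vc <- var(rc)
      den <- if (denominator == "sd") sqrt(vk) else vk
      zval[jm] <- (mean(rc) - mean(rk)) / den
      n1 <- length(rc); n0 <- length(rk)
      sed2 <- vc / n1 + vk / n0
      dfw <- sed2^2 / ((vc / n1)^2 / (n1 - 1) + (vk / n0)^2 / (n0 - 1))
      pval[jm] <- 2 * stats::pt(-abs((mean(rc) - mean(rk)) / sqrt(sed2)), dfw)
      nc_eff[jm] <- n1; nk_eff[jm] <- n0
    }
    out[[b]] <- data.frame(disease_id = disease_id, metabolite_id = mets,
                           bin = b, z = zval, p = pval,
                           n_cases = nc_eff, n_controls = nk_eff,
                           available = !is.na(zval))
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(res$metabolite_id, res$bin), , drop = FALSE]
}

#' Backward screening for the emergence timeframe
#'
#' Walks bins from disease onset outward (b = 1, 2, ...). Unavailable
#' bins count as non-significant. The walk stops at the smallest `b*`
#' whose p-value and the next bin's p-value both exceed `alpha`; the
#' emergence bin is `b*` under the default `stopping_bin` convention or
#' `b* - 1` under `last_significant`. If no such pair exists through bin
#' B the emergence bin is B (divergence present throughout); if the walk
#' stops at the very first pair the call is "none".
#'
#' @param profile long profile rows for one disease x metabolite (from
#'   [timeframe_profile()]), or a numeric p-vector.
#' @param alpha significance level (default 0.05).
#' @param convention `"stopping_bin"` (default) or `"last_significant"`.
#' @return list `emergence_call`: `emergence_bin` (integer or NA for
#'   none), `convention`, `p_sequence`.
#' @export
backward_screen <- function(profile, alpha = 0.05,
                            convention = c("stopping_bin", "last_significant")) {
  convention <- match.arg(convention)
  if (is.data.frame(profile)) {
    profile <- profile[order(profile$bin), , drop = FALSE]
    p <- profile$p
    p[!profile$available] <- NA_real_
  } else p <- as.numeric(profile)
  B <- length(p)
  if (all(is.na(p))) stop("all bins unavailable")
  if (B < 2L) stop("need at least 2 bins")
  nonsig <- is.na(p) | p > alpha
  bstar <- NA_integer_
  for (b in seq_len(B - 1L)) {
    if (nonsig[b] && nonsig[b + 1L]) { bstar <- b; break }
  }
  emergence <- if (is.na(bstar)) B
               else if (bstar == 1L) NA_integer_
               else if (convention == "stopping_bin") bstar
               else bstar - 1L
  structure(list(emergence_bin = emergence, convention = convention,
                 p_sequence = p, alpha = alpha),
            class = "emergence_call")
}

# loess-smooth each row of a metabolite x bin matrix over bin index
smooth_trajectories <- function(mat, span = 0.75) {
  bins <- seq_len(ncol(mat))
  t(apply(mat, 1L, function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 4L) { y[!ok] <- 0; return(y) }
    fit <- suppressWarnings(loess(y[ok] ~ bins[ok], span = span, degree = 1))
    predict(fit, newdata = data.frame(bins = bins))
  }))
}

#' Cluster disease trajectory matrices
#'
#' Each disease's metabolite x timeframe z matrix is smoothed per
#' metabolite by locally weighted regression over bin index (unavailable
#' bins imputed as 0, logged), flattened, and clustered by Ward-linkage
#' agglomerative clustering on Euclidean distances. The number of
#' clusters maximizes the mean silhouette width over `k_range`.
#'
#' @param profiles named list of metabolite x bin z matrices (or a long
#'   profile data.frame covering several diseases).
#' @param k_range candidate cluster counts; default
#'   `2:min(60, n_diseases - 1)`.
#' @param span loess span for trajectory smoothing.
#' @return list `trajectory_clusters`: `labels`, `k`, `silhouette`
#'   (named by k), `tree` (hclust), `flat` (smoothed flattened matrix).
#' @export
cluster_trajectories <- function(profiles, k_range = NULL, span = 0.75) {
  if (is.data.frame(profiles)) {
    profiles <- lapply(split(profiles, profiles$disease_id), function(d) {
      mets <- sort(unique(d$metabolite_id)); bb <- sort(unique(d$bin))
      m <- matrix(NA_real_, length(mets), length(bb),
                  dimnames = list(mets, bb))
      m[cbind(match(d$metabolite_id, mets), match(d$bin, bb))] <- d$z
      m
    })
  }
  nd <- length(profiles)
  if (nd < 3L) stop("need at least 3 diseases to cluster")
  n_imputed <- 0L
  flat <- t(vapply(profiles, function(m) {
    m <- as.matrix(m)
    n_imputed <<- n_imputed + sum(!is.finite(m))
    m[!is.finite(m)] <- 0
    as.vector(smooth_trajectories(m, span = span))
  }, numeric(length(profiles[[1L]]))))
  rownames(flat) <- names(profiles)
  if (n_imputed > 0L)
    message(n_imputed, " unavailable cells imputed as 0 before clustering")
  cl <- ward_silhouette_cluster(flat, k_range %||% (2:min(60L, nd - 1L)))
  structure(c(cl, list(flat = flat)), class = "trajectory_clusters")
}

# shared Ward + silhouette machinery (also used for age-curve clustering)
ward_silhouette_cluster <- function(mat, k_range) {
  d <- dist(mat)
  tree <- hclust(d, method = "ward.D2")
  k_range <- k_range[k_range >= 2L & k_range <= nrow(mat) - 1L]
  if (length(k_range) == 0L) k_range <- 2L
  sil <- vapply(k_range, function(k) {
    lab <- cutree(tree, k = k)
    if (length(unique(lab)) < 2L) return(NA_real_)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  k_best <- k_range[which.max(sil)]
  list(labels = cutree(tree, k = k_best), k = k_best,
       silhouette = sil, tree = tree)
}
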