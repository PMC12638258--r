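# Metabolite ageing patterns and sliding-window wave quantification.
#
# Age trends are estimated on covariate-residualized, re-standardized
# metabolite levels with locally weighted regression over baseline age,
# and clustered by Ward linkage with silhouette-chosen k. The
# sliding-window scan (DE-SWAN style) slides a centre age in 1-year
# increments, compares individuals in the age parcels just below and
# just above the centre with the linear model
#   metabolite ~ intercept + age-group + sex + ethnic background,
# applies Benjamini-Hochberg within each window across metabolites, and
# tracks the per-centre count of significant metabolites; interior peaks
# of that count series locate waves of metabolomic change.

#' Covariate-adjusted metabolite age curves
#'
#' Each metabolite is residualized on the adjustment covariates (age
#' excluded), re-standardized to unit SD, then smoothed against baseline
#' age by local-linear loess and evaluated on an integer age grid.
#'
#' @param z QC-transformed metabolite matrix, ids as rownames.
#' @param covariates covariate data.frame with `id` and `age`.
#' @param adjust covariates regressed out (default sex, ethnicity, TDI,
#'   BMI, smoking, statin, fasting).
#' @param grid evaluation ages (default 40:70); participants outside the
#'   grid range are dropped.
#' @param span loess span (default 0.75).
#' @return list `age_curves`: `curves` (metabolite x grid matrix),
#'   `grid`, `span`, `residuals` (participant x metabolite matrix) and
#'   `ages` for downstream use.
#' @export
age_adjusted_curves <- function(z, covariates,
                                adjust = c("sex", "ethnicity", "tdi", "bmi",
                                           "smoking", "statin", "fasting"),
                                grid = 40:70, span = 0.75) {
  stopifnot(all(diff(grid) > 0))
  keep <- covariates$age >= min(grid) & covariates$age <= max(grid)
  ids <- intersect(covariates$id[keep], rownames(z))
  if (length(ids) < 100L) stop("fewer than 100 participants in the age range")
  cv <- covariates[match(ids, covariates$id), , drop = FALSE]
  X <- covariate_design(cv, adjust)
  Y <- z[ids, , drop = FALSE]
  res <- Y
  complete <- colSums(is.na(Y)) == 0L
  if (any(complete))
    res[, complete] <- qr.resid(qr(X), Y[, complete, drop = FALSE])
  for (jm in which(!complete)) {  # QC-masked values stay missing
    okr <- !is.na(Y[, jm])
    res[okr, jm] <- lm.fit(X[okr, , drop = FALSE], Y[okr, jm])$residuals
  }
  res <- scale(res, center = TRUE, scale = TRUE)
  ages <- cv$age
  # loess cost grows steeply with n; aggregate to fine age bins (0.1 y)
  # and fit a count-weighted local-linear smoother on the bin means.
  # A line through the raw data is preserved exactly; within-bin age
  # variation (< 0.1 y) is negligible against the 30-year range.
  abin <- round(ages, 1L)
  curves <- t(apply(res, 2L, function(y) {
    ok <- !is.na(y)
    mw <- tapply(y[ok], abin[ok], mean)
    ww <- tapply(y[ok], abin[ok], length)
    ax <- as.vector(tapply(ages[ok], abin[ok], mean))  # true bin-mean age
    lf <- suppressWarnings(loess(mw ~ ax, weights = as.vector(ww),
                                 span = span, degree = 1,
                                 control = stats::loess.control(surface = "direct")))
    predict(lf, newdata = data.frame(ax = grid))
  }))
  colnames(curves) <- grid
  structure(list(curves = curves, grid = grid, span = span,
                 residuals = res, ages = ages),
            class = "age_curves")
}

#' Cluster metabolite age curves
#'
#' Ward-linkage hierarchical clustering on Euclidean distances between
#' grid-evaluated curves; the number of clusters maximizes the mean
#' silhouette width over `k_range`.
#'
#' @param curves an `age_curves` object or a metabolite x grid matrix.
#' @param k_range candidate cluster counts (default 2:12).
#' @return list with `labels`, `k`, `silhouette`, `tree`.
#' @export
cluster_age_curves <- function(curves, k_range = 2:12) {
  m <- if (inherits(curves, "age_curves")) curves$curves else as.matrix(curves)
  if (nrow(m) < 3L) stop("need at least 3 curves")
  ward_silhouette_cluster(m, k_range)
}

#' Sliding-window scan for waves of metabolite change
#'
#' For each centre age c the low parcel is ages in `[c - w, c)` and the
#' high parcel ages in `[c, c + w)` (half-open convention, configurable
#' via `closed_high`). On the pooled parcels the model
#' `metabolite ~ intercept + I(age >= c) + sex + ethnicity` is fitted
#' for every metabolite; the age-group coefficient, its p-value and the
#' signed score `sign(beta1) * (-log10 p)` are recorded.
#' Benjamini-Hochberg is applied within each centre across metabolites
#' (each window is one multiple-testing family), and metabolite counts
#' below each q threshold are tracked per centre.
#'
#' @param z QC-transformed metabolite matrix, ids as rownames.
#' @param covariates covariate data.frame with `id`, `age`, `sex`,
#'   `ethnicity`.
#' @param width parcel width in years, one of 2:5 (default 3).
#' @param centres centre ages (default every integer age for which both
#'   parcels fit inside the observed range).
#' @param q_thresholds q-value thresholds for the count series.
#' @param min_parcel minimum individuals per parcel, else the centre is
#'   skipped (default 30).
#' @param closed_high if `TRUE` (default) the centre age itself belongs
#'   to the high parcel.
#' @return `deswan_result` list: `long` (centre x metabolite rows with
#'   beta1, p, q, signed_score), `counts` (centre x threshold matrix),
#'   `width`, `centres`, `skipped`.
#' @export
deswan_scan <- function(z, covariates, width = 3,
                        centres = NULL,
                        q_thresholds = c(1e-4, 1e-3, 1e-2, 5e-2),
                        min_parcel = 30L, closed_high = TRUE) {
  ids <- intersect(covariates$id, rownames(z))
  cv <- covariates[match(ids, covariates$id), , drop = FALSE]
  Y <- z[ids, , drop = FALSE]
  age <- cv$age
  if (is.null(centres)) {
    centres <- seq(ceiling(min(age) + width), floor(max(age) - width + 1), by = 1)
  }
  Xcov <- covariate_design(cv, c("sex", "ethnicity"))
  p_met <- ncol(Y)
  long <- list(); skipped <- character(0)
  counts <- matrix(0L, length(centres), length(q_thresholds),
                   dimnames = list(centres, q_thresholds))
  for (ci in seq_along(centres)) {
    cc <- centres[ci]
    lo <- if (closed_high) age >= cc - width & age < cc
          else age > cc - width & age <= cc
    hi <- if (closed_high) age >= cc & age < cc + width
          else age > cc & age <= cc + width
    if (sum(lo) < min_parcel || sum(hi) < min_parcel) {
      skipped <- c(skipped, as.character(cc))
      counts[ci, ] <- NA_integer_
      next
    }
    sel <- lo | hi
    X <- cbind(Xcov[sel, 1L, drop = FALSE], group = as.numeric(hi[sel]),
               Xcov[sel, -1L, drop = FALSE])
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep_cols <- qrX$pivot[seq_len(qrX$rank)]
      if (!2L %in% keep_cols) {  # age-group column itself aliased
        skipped <- c(skipped, as.character(cc))
        counts[ci, ] <- NA_integer_
        next
      }
      X <- X[, sort(keep_cols), drop = FALSE]
      qrX <- qr(X)
    }
    gi <- which(colnames(X) == "group")
    Yc <- Y[sel, , drop = FALSE]
    b1 <- se <- pv <- rep(NA_real_, p_met)
    complete <- colSums(is.na(Yc)) == 0L
    if (any(complete)) {
      Ycc <- Yc[, complete, drop = FALSE]
      beta <- qr.coef(qrX, Ycc)
      resid <- qr.resid(qrX, Ycc)
      dfres <- nrow(X) - qrX$rank
      sig2 <- colSums(resid^2) / dfres
      gvar <- chol2inv(qr.R(qrX))[gi, gi]
      b1[complete] <- beta[gi, ]
      se[complete] <- sqrt(gvar * sig2)
      pv[complete] <- 2 * stats::pt(-abs(b1[complete] / se[complete]), dfres)
    }
    for (jm in which(!complete)) {  # metabolites with QC-masked values
      okr <- !is.na(Yc[, jm])
      if (sum(okr) <= ncol(X) + 1L) next
      ft <- lm.fit(X[okr, , drop = FALSE], Yc[okr, jm])
      dfj <- sum(okr) - ft$rank
      Vj <- chol2inv(qr.R(ft$qr)) * sum(ft$residuals^2) / dfj
      b1[jm] <- ft$coefficients[gi]
      se[jm] <- sqrt(Vj[gi, gi])
      pv[jm] <- 2 * stats::pt(-abs(b1[jm] / se[jm]), dfj)
    }
    qv <- bh_adjust(pv)
    long[[as.character(cc)]] <- data.frame(
      centre = cc, metabolite_id = colnames(Y), beta1 = b1, se = se,
      p = pv, q = qv, signed_score = sign(b1) * (-log10(pmax(pv, 1e-300))),
      n_low = sum(lo), n_high = sum(hi), stringsAsFactors = FALSE)
    counts[ci, ] <- vapply(q_thresholds, function(th) sum(qv < th, na.rm = TRUE),
                           integer(1))
  }
  structure(list(long = do.call(rbind, c(long, make.row.names = FALSE)),
                 counts = counts, width = width, centres = centres,
                 q_thresholds = q_thresholds, skipped = skipped),
            class = "deswan_result")
}

#' Detect wave peaks in a sliding-window count series
#'
#' Merges plateaus (runs of equal counts) and returns interior strict
#' local maxima of the per-centre significant-metabolite counts, sorted
#' by count descending. A plateau peak is reported at its (rounded)
#' middle centre age.
#'
#' @param result a `deswan_result`, or a numeric count vector named by
#'   centre age.
#' @param q_threshold which threshold's count series to use (default
#'   0.05); ignored when a plain vector is given.
#' @return data.frame with `centre` and `count`, one row per peak
#'   (empty for flat or monotone series).
#' @export
detect_wave_peaks <- function(result, q_threshold = 0.05) {
  if (inherits(result, "deswan_result")) {
    col <- which(abs(result$q_thresholds - q_threshold) < 1e-12)
    if (length(col) != 1L) stop("q_threshold not among the scanned thresholds")
    counts <- result$counts[, col]
    centres <- result$centres
  } else {
    counts <- as.numeric(result)
    centres <- as.numeric(names(result)) %||% seq_along(counts)
    if (anyNA(centres)) centres <- seq_along(counts)
  }
  ok <- !is.na(counts)
  counts <- counts[ok]; centres <- centres[ok]
  if (length(counts) < 5L) stop("need a count series over at least 5 centres")
  if (all(counts == 0)) return(data.frame(centre = numeric(), count = numeric()))
  r <- rle(counts)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- list()
  for (i in seq_along(vals)) {
    if (i == 1L || i == length(vals)) next  # interior only
    if (vals[i] > vals[i - 1L] && vals[i] > vals[i + 1L]) {
      mid <- (centres[starts[i]] + centres[ends[i]]) / 2
      peaks[[length(peaks) + 1L]] <- data.frame(centre = mid, count = vals[i])
    }
  }
  if (!length(peaks)) return(data.frame(centre = numeric(), count = numeric()))
  out <- do.call(rbind, peaks)
  out[order(-out$count, out$centre), , drop = FALSE]
}
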