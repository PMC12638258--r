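# Phenome-wide association scans.
#
# Metabolites enter one at a time (marginal scans) with a fixed covariate
# adjustment set: logistic regression for prevalent disease, Cox
# proportional hazards (Efron ties) for incident disease, linear models
# for continuous traits (inverse-normal transformed, trait as outcome),
# linear models with the metabolite as outcome for binary traits, and
# proportional-odds logistic regression for ordered traits. Multiplicity
# is controlled family-wise by Bonferroni within each phenotype family,
# and replication uses Benjamini-Hochberg FDR.

DEFAULT_COVARIATES <- c("age", "sex", "tdi", "bmi", "smoking", "statin", "fasting")

#' Bonferroni significance threshold for a metabolite x phenotype family
#'
#' @param alpha family-wise error level in (0, 1).
#' @param n_metabolites number of metabolites tested.
#' @param n_phenotypes number of phenotypes tested.
#' @return `alpha / (n_metabolites * n_phenotypes)`, exact.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_metabolites, n_phenotypes) {
  assert_prob(alpha, "alpha")
  if (n_metabolites < 1 || n_phenotypes < 1) stop("counts must be >= 1")
  alpha / (n_metabolites * n_phenotypes)
}

#' Build eligible case/control analysis sets
#'
#' For incident analysis of a disease, participants with a prevalent
#' record of that disease are excluded; for prevalent analysis,
#' participants who develop it during follow-up are excluded. Controls
#' are participants who never acquire the disease. Diseases with fewer
#' than `min_cases` eligible cases are excluded with the reason recorded;
#' traits with fewer than `trait_min_n` observations, or binary traits
#' with fewer than `binary_min_cell` cases or controls, likewise.
#'
#' @param registry long disease registry (`id`, `disease_id`, `status`,
#'   `onset_time`, `censor_time`).
#' @param participant_ids full vector of cohort participant ids (defines
#'   the "never" controls).
#' @param kind `"prevalent"` or `"incident"`.
#' @param traits optional trait data.frame (first column `id`) when
#'   building trait analysis sets with `kind = "traits"`.
#' @param trait_kinds named character vector mapping trait columns to
#'   `"continuous"`, `"ordinal"` or `"binary"` (required for traits).
#' @param min_cases minimum case count for diseases (default 300).
#' @param trait_min_n minimum sample size for traits (default 10000).
#' @param binary_min_cell minimum cases and controls for binary traits
#'   (default 50).
#' @return list of `analysis_set` objects (one per phenotype), each with
#'   `included` flag and exclusion reasons.
#' @export
build_analysis_sets <- function(registry = NULL, participant_ids = NULL,
                                kind = c("prevalent", "incident", "traits"),
                                traits = NULL, trait_kinds = NULL,
                                min_cases = 300L, trait_min_n = 10000L,
                                binary_min_cell = 50L) {
  kind <- match.arg(kind)
  if (kind == "traits") {
    stopifnot(!is.null(traits), !is.null(trait_kinds))
    sets <- lapply(setdiff(names(traits), "id"), function(tr) {
      if (!tr %in% names(trait_kinds)) stop("unknown phenotype id: ", tr)
      x <- traits[[tr]]
      ok <- !is.na(x)
      s <- list(id = tr, kind = "trait", trait_kind = trait_kinds[[tr]],
                ids = traits$id[ok], included = TRUE, reason = NA_character_)
      if (sum(ok) < trait_min_n) {
        s$included <- FALSE
        s$reason <- sprintf("n=%d < %d", sum(ok), trait_min_n)
      } else if (trait_kinds[[tr]] == "binary") {
        cells <- table(factor(x[ok], levels = sort(unique(x[ok]))))
        if (length(cells) < 2L || min(cells) < binary_min_cell) {
          s$included <- FALSE
          s$reason <- sprintf("binary cell < %d", binary_min_cell)
        }
      }
      structure(s, class = "analysis_set")
    })
    names(sets) <- setdiff(names(traits), "id")
    return(sets)
  }
  stopifnot(!is.null(registry), !is.null(participant_ids))
  diseases <- sort(unique(registry$disease_id))
  sets <- lapply(diseases, function(d) {
    sub <- registry[registry$disease_id == d, , drop = FALSE]
    prev_ids <- sub$id[sub$status == "prevalent"]
    inc_ids <- sub$id[sub$status == "incident"]
    if (kind == "incident") {
      cases <- inc_ids
      excluded <- data.frame(id = prev_ids,
                             reason = rep("prevalent diagnosis", length(prev_ids)))
    } else {
      cases <- prev_ids
      excluded <- data.frame(id = inc_ids,
                             reason = rep("developed during follow-up", length(inc_ids)))
    }
    controls <- setdiff(participant_ids, c(prev_ids, inc_ids))
    s <- list(id = d, kind = kind, cases = cases, controls = controls,
              excluded = excluded, included = TRUE, reason = NA_character_)
    if (length(cases) < min_cases) {
      s$included <- FALSE
      s$reason <- sprintf("<%d cases", min_cases)
    }
    structure(s, class = "analysis_set")
  })
  names(sets) <- diseases
  sets
}

# covariate design matrix (intercept + numeric/dummy columns), complete rows only
covariate_design <- function(covariates, covariate_names) {
  miss <- setdiff(covariate_names, names(covariates))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  df <- covariates[, covariate_names, drop = FALSE]
  for (nm in names(df)) {
    if (is.character(df[[nm]])) df[[nm]] <- factor(df[[nm]])
    if (is.factor(df[[nm]]) && nlevels(droplevels(df[[nm]])) < 2L)
      df[[nm]] <- NULL  # constant factor carries no information
  }
  mm <- if (ncol(df)) model.matrix(~ ., data = df)
        else matrix(1, nrow(covariates), 1L,
                    dimnames = list(NULL, "(Intercept)"))
  rownames(mm) <- covariates$id
  mm
}

# marginal fits of one model kind over all metabolite columns; returns
# effect, se, p, converged per metabolite. X = covariate design incl intercept.
fit_marginal <- function(zmat, X, outcome, model_kind, trait = NULL) {
  p <- ncol(zmat)
  eff <- se <- pv <- rep(NA_real_, p)
  conv <- rep(TRUE, p)
  note <- rep(NA_character_, p)
  for (j in seq_len(p)) {
    okj <- !is.na(zmat[, j])
    if (!is.null(trait)) okj <- okj & !is.na(trait)
    if (model_kind %in% c("logistic", "linear", "ordinal_logistic"))
      okj <- okj & !is.na(outcome)
    res <- tryCatch({
      switch(model_kind,
        logistic = {
          Xj <- cbind(X, met = zmat[, j])[okj, , drop = FALSE]
          yy <- outcome[okj]
          fit <- suppressWarnings(glm.fit(Xj, yy, family = binomial()))
          if (!fit$converged) stop("IRLS did not converge")
          if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10))
            note[j] <- "possible separation"
          k <- ncol(Xj)
          V <- chol2inv(qr.R(structure(fit$qr, class = "qr")))
          c(fit$coefficients[k], sqrt(V[k, k]))
        },
        cox = {
          Xj <- cbind(met = zmat[, j], X[, -1L, drop = FALSE])[okj, , drop = FALSE]
          fit <- survival::coxph(outcome[okj] ~ Xj, ties = "efron")
          c(coef(fit)[1L], sqrt(vcov(fit)[1L, 1L]))
        },
        linear = {
          Xj <- cbind(X, met = zmat[, j])[okj, , drop = FALSE]
          yy <- outcome[okj]
          fit <- lm.fit(Xj, yy)
          k <- ncol(Xj)
          V <- chol2inv(qr.R(fit$qr)) * sum(fit$residuals^2) /
            (length(yy) - fit$rank)
          c(fit$coefficients[k], sqrt(V[k, k]))
        },
        linear_reversed = {
          # binary trait as predictor, metabolite as outcome
          Xj <- cbind(X, trt = trait)[okj, , drop = FALSE]
          yy <- zmat[okj, j]
          fit <- lm.fit(Xj, yy)
          k <- ncol(Xj)
          V <- chol2inv(qr.R(fit$qr)) * sum(fit$residuals^2) /
            (length(yy) - fit$rank)
          c(fit$coefficients[k], sqrt(V[k, k]))
        },
        ordinal_logistic = {
          df <- data.frame(y = factor(outcome[okj], ordered = TRUE),
                           met = zmat[okj, j],
                           as.data.frame(X[okj, -1L, drop = FALSE]))
          fit <- MASS::polr(y ~ ., data = df, Hess = TRUE)
          sm <- sqrt(diag(vcov(fit)))
          c(coef(fit)["met"], sm["met"])
        })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      conv[j] <- FALSE
      note[j] <- conditionMessage(res)
    } else {
      eff[j] <- res[1L]; se[j] <- res[2L]
      pv[j] <- 2 * pnorm(-abs(res[1L] / res[2L]))
    }
  }
  data.frame(metabolite_id = colnames(zmat), effect = eff, se = se,
             p_value = pv, converged = conv, note = note,
             stringsAsFactors = FALSE)
}

#' Marginal metabolite-phenotype association scan
#'
#' One model per metabolite x phenotype, adjusted for the configured
#' covariates. Prevalent disease uses logistic regression; incident
#' disease uses Cox proportional hazards on time-on-study (follow-up
#' from baseline to `min(onset, censor)`); continuous traits are
#' inverse-normal transformed and modelled as the outcome; binary traits
#' enter as predictors of the metabolite; ordered traits use
#' proportional-odds logistic regression. Non-converging fits are
#' reported with `converged = FALSE`, never dropped, so multiplicity
#' denominators stay explicit.
#'
#' @param z QC-transformed metabolite matrix with participant ids as
#'   rownames.
#' @param sets list of `analysis_set`s from [build_analysis_sets()].
#' @param covariates covariate data.frame (with `id`), post-imputation.
#' @param registry disease registry (required for incident scans).
#' @param traits trait data.frame (required for trait scans).
#' @param covariate_names adjustment set; default age, sex, TDI, BMI,
#'   smoking, statin, fasting time. Add `"egfr"` for sensitivity runs.
#' @param alpha family-wise error level for the Bonferroni flag.
#' @param n_phenotypes_family family size used in the Bonferroni
#'   denominator; defaults to the number of included sets.
#' @param stratum label stored on each record (default "all").
#' @return data.frame of association records (one row per metabolite x
#'   included phenotype) with effect, se, 95% CI, p, counts and
#'   `passes_bonferroni`.
#' @export
scan_associations <- function(z, sets, covariates, registry = NULL, traits = NULL,
                              covariate_names = DEFAULT_COVARIATES,
                              alpha = 0.05, n_phenotypes_family = NULL,
                              stratum = "all") {
  sets <- Filter(function(s) isTRUE(s$included), sets)
  if (length(sets) == 0L) return(empty_records())
  n_fam <- n_phenotypes_family %||% length(sets)
  thr <- bonferroni_threshold(alpha, ncol(z), n_fam)
  X_all <- covariate_design(covariates, covariate_names)
  out <- list()
  for (s in sets) {
    if (s$kind %in% c("prevalent", "incident")) {
      ids <- c(s$cases, s$controls)
      ids <- ids[ids %in% rownames(z) & ids %in% rownames(X_all)]
      y <- as.integer(ids %in% s$cases)
      X <- X_all[ids, , drop = FALSE]
      zz <- z[ids, , drop = FALSE]
      if (s$kind == "prevalent") {
        rec <- fit_marginal(zz, X, y, "logistic")
        mk <- "logistic"
      } else {
        sub <- registry[registry$disease_id == s$id & registry$status == "incident", ]
        tt <- setNames(rep(NA_real_, length(ids)), ids)
        cens <- setNames(rep(NA_real_, length(ids)), ids)
        cens[] <- max(sub$censor_time %||% 15)
        cens[sub$id] <- sub$censor_time
        tt[] <- cens
        tt[sub$id] <- sub$onset_time
        surv <- survival::Surv(pmin(tt, cens), y)
        rec <- fit_marginal(zz, X, surv, "cox")
        mk <- "cox"
      }
      rec$model_kind <- mk
      rec$n <- length(ids); rec$n_cases <- sum(y)
    } else {
      x <- traits[[s$id]]
      names(x) <- traits$id
      ids <- s$ids[s$ids %in% rownames(z) & s$ids %in% rownames(X_all)]
      X <- X_all[ids, , drop = FALSE]
      zz <- z[ids, , drop = FALSE]
      tv <- x[ids]
      rec <- switch(s$trait_kind,
        continuous = {
          r <- fit_marginal(zz, X, inverse_normal_transform(tv), "linear")
          r$model_kind <- "linear"; r
        },
        binary = {
          r <- fit_marginal(zz, X, NULL, "linear_reversed", trait = tv)
          r$model_kind <- "linear"
          r$note <- ifelse(is.na(r$note), "metabolite~trait", r$note)
          r
        },
        ordinal = {
          r <- fit_marginal(zz, X, tv, "ordinal_logistic")
          r$model_kind <- "ordinal_logistic"; r
        })
      rec$n <- length(ids)
      rec$n_cases <- if (s$trait_kind == "binary") sum(tv == max(tv)) else NA_integer_
    }
    rec$phenotype_id <- s$id
    rec$stratum <- stratum
    out[[s$id]] <- rec
  }
  rec <- do.call(rbind, c(out, make.row.names = FALSE))
  rec$ci_lo <- rec$effect - 1.96 * rec$se
  rec$ci_hi <- rec$effect + 1.96 * rec$se
  rec$passes_bonferroni <- !is.na(rec$p_value) & rec$p_value < thr
  rec$bonferroni_threshold <- thr
  rec[, c("metabolite_id", "phenotype_id", "model_kind", "stratum", "effect",
          "se", "ci_lo", "ci_hi", "p_value", "n", "n_cases", "converged",
          "note", "passes_bonferroni", "bonferroni_threshold")]
}

empty_records <- function() {
  data.frame(metabolite_id = character(), phenotype_id = character(),
             model_kind = character(), stratum = character(),
             effect = numeric(), se = numeric(), ci_lo = numeric(),
             ci_hi = numeric(), p_value = numeric(), n = integer(),
             n_cases = integer(), converged = logical(), note = character(),
             passes_bonferroni = logical(), bonferroni_threshold = numeric())
}

#' Subgroup and interaction analysis
#'
#' Re-runs the scan within strata of sex and of age (cut at 60 years),
#' dropping the stratifying covariate from the adjustment set, and fits
#' full-sample interaction models adding a metabolite x stratum term.
#' Metabolite-phenotype pairs Bonferroni-significant in both strata of a
#' variable with opposite effect signs are flagged divergent.
#'
#' @inheritParams scan_associations
#' @param strata named list of stratum definitions; default sex
#'   (Female/Male) and age (`<60` / `>=60`).
#' @param min_cases strata with fewer cases are skipped (logged).
#' @return list with `records` (stratified scan records), `interactions`
#'   (interaction-term p per metabolite x phenotype x variable), and
#'   `divergent` (flagged pairs).
#' @export
subgroup_and_interaction <- function(z, sets, covariates, registry = NULL,
                                     covariate_names = DEFAULT_COVARIATES,
                                     alpha = 0.05, min_cases = 100L,
                                     strata = NULL) {
  strata <- strata %||% list(
    sex = list(covariate = "sex",
               groups = list(female = function(cv) cv$sex == "Female",
                             male = function(cv) cv$sex == "Male")),
    age = list(covariate = "age",
               groups = list(`age<60` = function(cv) cv$age < 60,
                             `age>=60` = function(cv) cv$age >= 60)))
  records <- list(); inters <- list(); skipped <- list()
  for (vn in names(strata)) {
    st <- strata[[vn]]
    cn <- setdiff(covariate_names, st$covariate)
    for (gn in names(st$groups)) {
      keep <- st$groups[[gn]](covariates)
      cv_g <- covariates[keep, , drop = FALSE]
      sets_g <- lapply(sets, function(s) {
        if (!isTRUE(s$included)) return(s)
        s$cases <- intersect(s$cases, cv_g$id)
        s$controls <- intersect(s$controls, cv_g$id)
        if (length(s$cases) < min_cases) {
          s$included <- FALSE
          s$reason <- sprintf("stratum %s: <%d cases", gn, min_cases)
        }
        s
      })
      skipped[[paste(vn, gn)]] <-
        names(Filter(function(s) !isTRUE(s$included), sets_g))
      records[[paste(vn, gn)]] <-
        scan_associations(z, sets_g, cv_g, registry = registry,
                          covariate_names = cn, alpha = alpha, stratum = gn)
    }
    # interaction model on the full sample
    X <- covariate_design(covariates, covariate_names)
    svar <- if (vn == "sex") as.numeric(covariates$sex == "Male")
            else as.numeric(covariates$age >= 60)
    names(svar) <- covariates$id
    for (s in Filter(function(s) isTRUE(s$included), sets)) {
      if (!s$kind %in% c("prevalent", "incident")) next
      ids <- intersect(c(s$cases, s$controls), rownames(X))
      y <- as.integer(ids %in% s$cases)
      Xi <- X[ids, , drop = FALSE]
      sv <- svar[ids]
      pv <- vapply(seq_len(ncol(z)), function(j) {
        okj <- !is.na(z[ids, j])
        Xj <- cbind(Xi, met = z[ids, j], int = z[ids, j] * sv)[okj, , drop = FALSE]
        fit <- tryCatch(suppressWarnings(glm.fit(Xj, y[okj], family = binomial())),
                        error = function(e) NULL)
        if (is.null(fit) || !fit$converged) return(NA_real_)
        k <- ncol(Xj)
        V <- chol2inv(qr.R(structure(fit$qr, class = "qr")))
        2 * pnorm(-abs(fit$coefficients[k] / sqrt(V[k, k])))
      }, numeric(1))
      inters[[paste(s$id, vn)]] <-
        data.frame(phenotype_id = s$id, variable = vn,
                   metabolite_id = colnames(z), interaction_p = pv,
                   stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, c(records, make.row.names = FALSE))
  divergent <- list()
  if (nrow(rec)) {
    for (vn in names(strata)) {
      gns <- names(strata[[vn]]$groups)
      a <- rec[rec$stratum == gns[1L] & rec$passes_bonferroni, ]
      b <- rec[rec$stratum == gns[2L] & rec$passes_bonferroni, ]
      key <- function(d) paste(d$metabolite_id, d$phenotype_id)
      common <- intersect(key(a), key(b))
      if (length(common)) {
        ea <- a$effect[match(common, key(a))]
        eb <- b$effect[match(common, key(b))]
        opp <- sign(ea) != sign(eb)
        if (any(opp)) divergent[[vn]] <-
          data.frame(pair = common[opp], variable = vn,
                     effect_1 = ea[opp], effect_2 = eb[opp])
      }
    }
  }
  list(records = rec,
       interactions = do.call(rbind, c(inters, make.row.names = FALSE)),
       divergent = if (length(divergent))
         do.call(rbind, c(divergent, make.row.names = FALSE)) else NULL,
       skipped = skipped)
}

#' Replication with FDR control
#'
#' Refits each Bonferroni-significant derivation pair in a replication
#' cohort and applies Benjamini-Hochberg at `level` across the
#' replication p-values. Pairs untestable in replication are marked
#' unavailable and excluded from the FDR family.
#'
#' @param derivation_records records from [scan_associations()], already
#'   filtered or flagged by `passes_bonferroni`.
#' @param z_rep,sets_rep,covariates_rep,registry_rep,traits_rep the
#'   replication cohort pieces, as for [scan_associations()].
#' @param covariate_names adjustment set.
#' @param level FDR level (default 0.05).
#' @return derivation records augmented with `replication_p`,
#'   `replication_q` and `passes_fdr`.
#' @export
replicate_fdr <- function(derivation_records, z_rep, sets_rep, covariates_rep,
                          registry_rep = NULL, traits_rep = NULL,
                          covariate_names = DEFAULT_COVARIATES, level = 0.05) {
  der <- derivation_records[derivation_records$passes_bonferroni %in% TRUE, ,
                            drop = FALSE]
  rep_rec <- scan_associations(z_rep, sets_rep, covariates_rep,
                               registry = registry_rep, traits = traits_rep,
                               covariate_names = covariate_names)
  key <- function(d) paste(d$metabolite_id, d$phenotype_id)
  idx <- match(key(der), key(rep_rec))
  der$replication_p <- rep_rec$p_value[idx]
  der$replication_q <- bh_adjust(der$replication_p)
  der$passes_fdr <- !is.na(der$replication_q) & der$replication_q < level
  der$replication_available <- !is.na(der$replication_p)
  der
}
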