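test_that("bonferroni_threshold is exact and monotone", {
  expect_equal(signif(bonferroni_threshold(0.05, 313, 527), 3), 3.03e-7)
  expect_equal(signif(bonferroni_threshold(0.05, 313, 859), 3), 1.86e-7)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)
  expect_identical(bonferroni_threshold(0.05, 10, 20), 0.05 / 200)
  expect_lt(bonferroni_threshold(0.05, 11, 20), bonferroni_threshold(0.05, 10, 20))
  expect_lt(bonferroni_threshold(0.05, 10, 21), bonferroni_threshold(0.05, 10, 20))
  expect_error(bonferroni_threshold(0.05, 0, 10), "counts")
  expect_error(bonferroni_threshold(1.2, 10, 10), "alpha")
})

test_that("analysis sets enforce case thresholds and exclusions", {
  reg <- data.frame(
    id = c(sprintf("P%03d", 1:299), "P500", "P501"),
    disease_id = "D1",
    status = c(rep("incident", 299), "prevalent", "prevalent"),
    onset_time = c(runif(299, 0, 15), NA, NA),
    censor_time = 15)
  ids <- c(sprintf("P%03d", 1:299), sprintf("P%03d", 300:450), "P500", "P501")
  sets <- build_analysis_sets(reg, ids, "incident")
  expect_false(sets$D1$included)
  expect_equal(sets$D1$reason, "<300 cases")
  # prevalent participants appear in neither cases nor controls
  expect_false(any(c("P500", "P501") %in% c(sets$D1$cases, sets$D1$controls)))
  expect_true(all(sets$D1$excluded$reason == "prevalent diagnosis"))
  # for the prevalent analysis, incident cases are excluded instead
  psets <- build_analysis_sets(reg, ids, "prevalent", min_cases = 2)
  expect_true(psets$D1$included)
  expect_length(intersect(psets$D1$cases, psets$D1$controls), 0)
  expect_false(any(sprintf("P%03d", 1:299) %in% psets$D1$controls))
})

test_that("trait sets apply sample-size and binary cell filters", {
  traits <- data.frame(id = sprintf("P%04d", 1:2000),
                       small = c(rnorm(900), rep(NA, 1100)),
                       rare = c(rep(1, 49), rep(0, 1951)),
                       ok = rbinom(2000, 1, 0.4))
  tk <- c(small = "continuous", rare = "binary", ok = "binary")
  sets <- build_analysis_sets(kind = "traits", traits = traits, trait_kinds = tk,
                              trait_min_n = 1000, binary_min_cell = 50)
  expect_false(sets$small$included)
  expect_match(sets$small$reason, "< 1000")
  expect_false(sets$rare$included)
  expect_match(sets$rare$reason, "cell")
  expect_true(sets$ok$included)
  expect_error(build_analysis_sets(kind = "traits", traits = traits,
                                   trait_kinds = c(small = "continuous")),
               "unknown phenotype")
})

test_that("planted effects are recovered by the scan with valid CIs", {
  ds <- list(disease_spec("prev", "hazard_driven", 0.10, 1e-6,
                          effect_metabolites = data.frame(metabolite = 1,
                                                          effect = 0.5)),
             disease_spec("inc", "hazard_driven", 0.001, 0.01,
                          effect_metabolites = data.frame(metabolite = 2,
                                                          effect = 0.4)))
  b <- make_test_bundle(n = 12000, p = 4, seed = 17, diseases = ds)
  qc <- qc_transform(b$metabolites)
  imp <- impute_covariates(b$participants)
  psets <- build_analysis_sets(b$registry, b$participants$id, "prevalent",
                               min_cases = 100)
  prec <- scan_associations(qc$z, psets, imp$covariates)
  r <- prec[prec$phenotype_id == "prev" & prec$metabolite_id == "met_001", ]
  expect_equal(r$model_kind, "logistic")
  expect_true(r$ci_lo < 0.5 && 0.5 < r$ci_hi)
  expect_lt(r$p_value, 1e-6)
  isets <- build_analysis_sets(b$registry, b$participants$id, "incident",
                               min_cases = 100)
  irec <- scan_associations(qc$z, isets, imp$covariates, registry = b$registry)
  r2 <- irec[irec$phenotype_id == "inc" & irec$metabolite_id == "met_002", ]
  expect_equal(r2$model_kind, "cox")
  expect_true(r2$ci_lo < 0.4 && 0.4 < r2$ci_hi)
  # every CI reproduces from effect +/- 1.96 se on the link scale
  all_rec <- rbind(prec, irec)
  expect_lt(max(abs(all_rec$ci_lo - (all_rec$effect - 1.96 * all_rec$se)),
                na.rm = TRUE), 1e-6)
  expect_true(all(all_rec$p_value > 0 & all_rec$p_value <= 1, na.rm = TRUE))
})

test_that("binary traits run reversed and ordinal traits use proportional odds", {
  tr <- list(trait_spec("tb", "binary", intercept = qlogis(0.3),
                        effect_metabolites = data.frame(metabolite = 3, effect = 1.0)),
             trait_spec("to", "ordinal", n_ordinal_levels = 4,
                        effect_metabolites = data.frame(metabolite = 1, effect = 0.5)))
  b <- make_test_bundle(n = 6000, p = 4, seed = 19, traits = tr)
  qc <- qc_transform(b$metabolites)
  imp <- impute_covariates(b$participants)
  tk <- c(tb = "binary", to = "ordinal")
  sets <- build_analysis_sets(kind = "traits", traits = b$traits, trait_kinds = tk,
                              trait_min_n = 1000)
  rec <- scan_associations(qc$z, sets, imp$covariates, traits = b$traits)
  rb <- rec[rec$phenotype_id == "tb" & rec$metabolite_id == "met_003", ]
  expect_equal(rb$model_kind, "linear")
  expect_equal(rb$note, "metabolite~trait")
  expect_gt(rb$effect, 0)
  expect_lt(rb$p_value, 1e-4)
  ro <- rec[rec$phenotype_id == "to" & rec$metabolite_id == "met_001", ]
  expect_equal(ro$model_kind, "ordinal_logistic")
  expect_gt(ro$effect, 0)
  expect_lt(ro$p_value, 1e-4)
})

test_that("scan results are invariant to participant row order", {
  ds <- list(disease_spec("d", "hazard_driven", 0.08, 1e-6,
                          effect_metabolites = data.frame(metabolite = 1, effect = 0.3)))
  b <- make_test_bundle(n = 2000, p = 3, seed = 23, diseases = ds,
                        missingness = 0)
  qc <- qc_transform(b$metabolites)
  imp <- impute_covariates(b$participants)
  sets <- build_analysis_sets(b$registry, b$participants$id, "prevalent",
                              min_cases = 50)
  r1 <- scan_associations(qc$z, sets, imp$covariates)
  set.seed(9); perm <- sample.int(2000)
  r2 <- scan_associations(qc$z[perm, ], sets, imp$covariates[perm, ])
  expect_lt(max(abs(r1$effect - r2$effect)), 1e-8)
  expect_lt(max(abs(r1$p_value - r2$p_value)), 1e-8)
})

test_that("Cox scan matches closed-form exponential regression without censoring", {
  set.seed(29)
  n <- 5000
  x <- rnorm(n)
  beta <- 0.5
  tt <- rexp(n, rate = 0.1 * exp(beta * x))
  fit <- survival::coxph(survival::Surv(tt, rep(1, n)) ~ x, ties = "efron")
  # closed-form MLE of exponential (log-linear) regression
  loglik <- function(b) -sum(b * x - log(mean(tt * exp(b * x))))
  bhat_exp <- optimize(loglik, c(-2, 2))$minimum
  expect_lt(abs(coef(fit) - bhat_exp), 3 * sqrt(vcov(fit)[1, 1]))
  expect_lt(abs(coef(fit) - beta), 3 * sqrt(vcov(fit)[1, 1]))
})

test_that("inverse normal transform uses Blom offsets and averaged ties", {
  x <- c(3, 1, 2)
  expect_equal(inverse_normal_transform(x),
               qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4)))
  xt <- c(1, 1, 2)
  r <- rank(xt)  # 1.5 1.5 3
  expect_equal(inverse_normal_transform(xt), qnorm((r - 3 / 8) / (3 + 1 / 4)))
  xna <- c(5, NA, 1)
  out <- inverse_normal_transform(xna)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], qnorm((c(2, 1) - 3 / 8) / (2 + 1 / 4)))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  set.seed(31)
  for (i in 1:1000) {
    p <- runif(sample(2:12, 1))
    expect_equal(bh_adjust(p), oracle_bh_q(p), tolerance = 1e-12)
  }
  # decisions match p.adjust as well
  p <- runif(100)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
})

test_that("replicate_fdr refits significant pairs and applies BH", {
  ds <- list(disease_spec("d", "hazard_driven", 0.12, 1e-6,
                          effect_metabolites = data.frame(metabolite = 1,
                                                          effect = 0.7)))
  b1 <- make_test_bundle(n = 6000, p = 4, seed = 41, diseases = ds)
  b2 <- make_test_bundle(n = 6000, p = 4, seed = 43, diseases = ds)
  prep <- function(b) {
    qc <- qc_transform(b$metabolites)
    imp <- impute_covariates(b$participants)
    sets <- build_analysis_sets(b$registry, b$participants$id, "prevalent",
                                min_cases = 100)
    list(z = qc$z, cv = imp$covariates, sets = sets)
  }
  d1 <- prep(b1); d2 <- prep(b2)
  der <- scan_associations(d1$z, d1$sets, d1$cv)
  expect_true(any(der$passes_bonferroni))
  rep_rec <- replicate_fdr(der, d2$z, d2$sets, d2$cv)
  expect_true(all(rep_rec$passes_bonferroni))
  r <- rep_rec[rep_rec$metabolite_id == "met_001", ]
  expect_true(r$replication_available)
  expect_true(r$passes_fdr)
  # BH at level 0.05: step-up examples
  expect_true(all(bh_adjust(c(0.01, 0.02, 0.03, 0.04)) < 0.05))
  expect_true(all(bh_adjust(rep(1, 4)) == 1))
})

test_that("sex-stratified scans drop sex and flag planted divergent effects", {
  # plant opposite log-OR by sex on metabolite 1
  cfg <- simulation_config(20000, n_metabolites = 2, missingness = 0, seed = 37)
  b <- simulate_cohort(cfg)
  lat_z <- scale(log(b$metabolites))
  male <- b$participants$sex == "Male"
  lp <- qlogis(0.10) + ifelse(male, 0.6, -0.6) * lat_z[, 1]
  set.seed(37)
  prev <- runif(20000) < plogis(lp)
  b$registry <- data.frame(id = b$participants$id[prev], disease_id = "dx",
                           status = "prevalent", onset_time = NA_real_,
                           censor_time = 15)
  qc <- qc_transform(b$metabolites)
  imp <- impute_covariates(b$participants)
  sets <- build_analysis_sets(b$registry, b$participants$id, "prevalent",
                              min_cases = 100)
  res <- subgroup_and_interaction(qc$z, sets, imp$covariates,
                                  alpha = 0.05, min_cases = 100)
  expect_true(!is.null(res$divergent))
  expect_true("met_001 dx" %in% res$divergent$pair)
  # stratified records exist for all four strata
  expect_setequal(unique(res$records$stratum),
                  c("female", "male", "age<60", "age>=60"))
  # interaction p is small for the planted metabolite, sex variable
  ip <- res$interactions
  expect_lt(ip$interaction_p[ip$variable == "sex" &
                             ip$metabolite_id == "met_001"], 1e-6)
})
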