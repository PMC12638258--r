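make_match_inputs <- function(n = 8000, seed = 47, rate = 0.005, divergence = NULL,
                              p = 3) {
  mode <- if (is.null(divergence)) "null" else "divergence_driven"
  ds <- list(disease_spec("d", mode, 0.01, rate, divergence = divergence))
  b <- make_test_bundle(n = n, p = p, seed = seed, diseases = ds)
  qc <- qc_transform(b$metabolites)
  imp <- impute_covariates(b$participants)
  s <- build_analysis_sets(b$registry, b$participants$id, "incident",
                           min_cases = 50)[["d"]]
  inc <- b$registry[b$registry$status == "incident", ]
  cases <- imp$covariates[match(inc$id, imp$covariates$id), ]
  cases$time_to_onset <- inc$onset_time
  pool <- imp$covariates[match(s$controls, imp$covariates$id), ]
  list(bundle = b, z = qc$z, cv = imp$covariates, cases = cases, pool = pool)
}

test_that("matching honours ratio, uniqueness and proxy times", {
  mi <- make_match_inputs()
  m <- propensity_match(mi$cases, mi$pool, ratio = 5, seed = 3)
  tab <- table(m$case_id)
  expect_true(all(tab == 5))                      # ample pool: full sets
  expect_equal(anyDuplicated(m$control_id), 0L)   # without replacement
  expect_false(any(m$control_id %in% mi$cases$id))
  expect_equal(unname(m$proxy_time[match(mi$cases$id, m$case_id)]),
               mi$cases$time_to_onset)
  expect_true(all(m$proxy_time > 0))
})

test_that("an identical-covariate pool member is picked at distance zero", {
  cv <- data.frame(id = c("case1", paste0("ctl", 1:50)),
                   sex = c("F", rep(c("F", "M"), 25)),
                   age = c(50, seq(40, 69.4, length.out = 50)),
                   ethnicity = "a",
                   bmi = c(27, rnorm(50, 27, 4)),
                   tdi = c(0, rnorm(50, 0, 3)))
  cv$sex[2] <- "F"; cv$age[2] <- 50; cv$bmi[2] <- 27; cv$tdi[2] <- 0  # clone
  cases <- cv[1, ]; cases$time_to_onset <- 4
  m <- propensity_match(cases, cv[-1, ], ratio = 1, seed = 1)
  expect_equal(m$control_id, "ctl1")
  expect_equal(m$distance, 0)
})

test_that("matching balances a confounded cohort to SMD < 0.1", {
  # cases strongly skewed in age and bmi relative to the pool
  set.seed(51)
  n <- 20000
  cv <- data.frame(id = sprintf("P%05d", 1:n),
                   sex = sample(c("F", "M"), n, TRUE),
                   age = runif(n, 40, 70),
                   ethnicity = sample(c("a", "b"), n, TRUE, c(0.9, 0.1)),
                   bmi = rnorm(n, 27, 4), tdi = rnorm(n, 0, 3))
  p_case <- plogis(-3.3 + 0.06 * (cv$age - 55) + 0.10 * (cv$bmi - 27))
  is_case <- runif(n) < p_case
  cases <- cv[is_case, ]; cases$time_to_onset <- runif(nrow(cases), 0, 15)
  pre <- matching_balance(data.frame(case_id = cases$id,
                                     control_id = sample(cv$id[!is_case], nrow(cases))),
                          cv)
  m <- propensity_match(cases, cv[!is_case, ], ratio = 5, seed = 5)
  post <- matching_balance(m, cv)
  expect_gt(max(pre[c("age", "bmi")]), 0.2)   # confounding was real
  expect_lt(max(post), 0.1)
})

test_that("deficits are logged when the pool runs short", {
  mi <- make_match_inputs(n = 2000, rate = 0.12)
  m <- propensity_match(mi$cases, mi$pool, ratio = 5, seed = 1)
  expect_gt(attr(m, "deficit"), 0)
  expect_lt(nrow(m), 5 * nrow(mi$cases))
  expect_equal(anyDuplicated(m$control_id), 0L)
})

test_that("cases land in ceiling(time-to-onset) bins with matched controls", {
  mi <- make_match_inputs()
  m <- propensity_match(mi$cases, mi$pool, ratio = 5, seed = 7)
  m45 <- m[m$proxy_time > 4 & m$proxy_time <= 5, ]
  prof <- timeframe_profile(m, mi$z, mi$cv, disease_id = "d",
                            min_cases_per_bin = 2)
  p5 <- prof[prof$bin == 5 & prof$metabolite_id == "met_001", ]
  cases5 <- unique(m45$case_id)
  expect_equal(p5$n_cases, sum(!is.na(mi$z[cases5, "met_001"])))
  # profile rows cover every metabolite x bin
  expect_equal(nrow(prof), 3 * 15)
})

test_that("null profiles are centred with uniform p-values", {
  mi <- make_match_inputs(n = 20000, rate = 0.006, seed = 53)
  m <- propensity_match(mi$cases, mi$pool, ratio = 5, seed = 9)
  prof <- timeframe_profile(m, mi$z, mi$cv, disease_id = "d")
  av <- prof[prof$available, ]
  expect_lt(abs(mean(av$z)), 0.05)
  expect_gt(stats::ks.test(av$p, "punif")$p.value, 0.01)
})

test_that("a planted step shift is recovered bin-exactly", {
  dv <- list(metabolite = 2, emergence_time = 3, shift = 1, ramp = "step")
  mi <- make_match_inputs(n = 30000, rate = 0.008, divergence = dv, seed = 59)
  m <- propensity_match(mi$cases, mi$pool, ratio = 5, seed = 11)
  prof <- timeframe_profile(m, mi$z, mi$cv, disease_id = "d")
  pm <- prof[prof$metabolite_id == "met_002" & prof$available, ]
  zin <- pm$z[pm$bin <= 3]
  zout <- pm$z[pm$bin > 3]
  expect_true(all(abs(zin - 1) < 0.2))
  expect_true(all(abs(zout) < 0.2))
})

test_that("profiles are invariant to matched-set order", {
  mi <- make_match_inputs(n = 5000, rate = 0.012)
  m <- propensity_match(mi$cases, mi$pool, ratio = 5, seed = 13)
  set.seed(2); m2 <- m[sample.int(nrow(m)), ]
  p1 <- timeframe_profile(m, mi$z, mi$cv, disease_id = "d")
  p2 <- timeframe_profile(m2, mi$z, mi$cv, disease_id = "d")
  expect_equal(p1$z, p2$z, tolerance = 1e-12)
})

test_that("backward screening applies the two-consecutive rule literally", {
  # all bins strongly significant: emergence at the last bin
  ec <- backward_screen(rep(0.001, 15))
  expect_equal(ec$emergence_bin, 15L)
  # worked sequence: bins 4 and 5 are the first non-significant pair
  p <- c(0.001, 0.3, 0.001, 0.4, 0.6, 0.5, rep(0.7, 9))
  expect_equal(backward_screen(p)$emergence_bin, 4L)
  expect_equal(backward_screen(p, convention = "last_significant")$emergence_bin, 3L)
  # immediately non-significant: no emergence
  expect_true(is.na(backward_screen(c(0.2, 0.3, rep(0.5, 13)))$emergence_bin))
  # unavailable bins count as non-significant
  pna <- c(0.001, NA, NA, rep(0.001, 12))
  expect_equal(backward_screen(pna)$emergence_bin, 2L)
  expect_error(backward_screen(rep(NA_real_, 15)), "unavailable")
  expect_error(backward_screen(0.01), "2 bins")
})

test_that("trajectory clustering recovers construction and matches the oracle", {
  set.seed(61)
  base1 <- matrix(rnorm(20 * 15), 20, 15)
  base2 <- base1 + 5
  mats <- c(lapply(1:4, function(i) base1 + rnorm(300, sd = 0.1)),
            lapply(1:4, function(i) base2 + rnorm(300, sd = 0.1)))
  names(mats) <- paste0("d", 1:8)
  mats$d9 <- mats$d1  # exact duplicate
  res <- cluster_trajectories(mats, k_range = 2:6, span = 0.9)
  expect_equal(res$k, 2L)
  expect_equal(res$labels[["d9"]], res$labels[["d1"]])
  truth <- c(rep(1, 4), rep(2, 4), 1)
  tab <- table(res$labels, truth)
  expect_equal(sum(apply(tab, 1, max)), 9)  # Rand index 1: pure clusters
  # chosen k equals brute-force silhouette argmax over the same labels
  sil_oracle <- vapply(2:6, function(k) {
    oracle_silhouette_mean(res$flat, cutree(res$tree, k))
  }, numeric(1))
  expect_equal(res$k, (2:6)[which.max(sil_oracle)])
  expect_equal(unname(res$silhouette), sil_oracle, tolerance = 1e-10)
  expect_error(cluster_trajectories(mats[1:2]), "at least 3")
})
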