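sim_xy <- function(n, p, informative = integer(0), beta = 0.8,
                   prevalence = 0.1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("met_%03d", 1:p)))
  lp <- qlogis(prevalence)
  if (length(informative)) lp <- lp + X[, informative, drop = FALSE] %*% rep(beta, length(informative))
  y <- rbinom(n, 1, plogis(lp))
  list(X = X, y = y)
}

test_that("geographic folds keep centres intact and balance sizes", {
  centres <- rep(sprintf("c%02d", 1:10), each = 100)
  f <- assign_geographic_folds(centres, k = 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 100))
  # all members of a centre share a fold, always
  expect_true(all(tapply(f, centres, function(x) length(unique(x))) == 1))
  # 22 unequal centres: greedy largest-first keeps folds within 1.5x
  set.seed(2)
  sizes <- as.integer(exp(runif(22, 4, 7)))
  centres2 <- rep(sprintf("c%02d", 1:22), times = sizes)
  f2 <- assign_geographic_folds(centres2, k = 10, seed = 3)
  tab <- table(f2)
  expect_lte(max(tab) / min(tab), 1.5)
  expect_error(assign_geographic_folds(rep("c1", 50), k = 10), "fewer centres")
})

test_that("ranking recovers planted features, keeps panel size and is deterministic", {
  d <- sim_xy(6000, 50, informative = c(3, 10, 20), beta = 0.8, seed = 5)
  rs <- rank_and_select(d$X, d$y, top_k = 30)
  expect_length(rs$panel, 30)
  expect_true(all(sprintf("met_%03d", c(3, 10, 20)) %in% rs$panel[1:5]))
  rs2 <- rank_and_select(d$X, d$y, top_k = 30)
  expect_identical(rs$panel, rs2$panel)
  # pure noise: panel still length 30 and deterministic
  dn <- sim_xy(2000, 50, seed = 6)
  rn1 <- rank_and_select(dn$X, dn$y, top_k = 30)
  rn2 <- rank_and_select(dn$X, dn$y, top_k = 30)
  expect_length(rn1$panel, 30)
  expect_identical(rn1$panel, rn2$panel)
  expect_error(rank_and_select(dn$X, rep(1, 2000)), "single-class")
})

test_that("a linearly separable outcome is classified almost perfectly", {
  set.seed(7)
  n <- 3000
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("met_", 1:5)))
  y <- as.integer(X[, 1] > 0)
  tr <- seq_len(n) <= 2000
  fm <- train_calibrated(X[tr, ], y[tr], panel = colnames(X), seed = 1)
  sc <- predict(fm, X[!tr, ])
  expect_gte(auc_rank(sc, y[!tr]), 0.99)
})

test_that("isotonic calibration matches prevalence and stays monotone", {
  d <- sim_xy(20000, 20, informative = 1:3, beta = 0.6, prevalence = 0.05, seed = 9)
  tr <- seq_len(20000) <= 12000
  fm <- train_calibrated(d$X[tr, ], d$y[tr], panel = colnames(d$X), seed = 2)
  sc <- predict(fm, d$X[!tr, ])
  expect_true(all(sc >= 0 & sc <= 1))
  prev <- mean(d$y[!tr])
  expect_lt(abs(mean(sc) - prev) / prev, 0.10)
  # calibrator applied to sorted raw margins is non-decreasing
  raw <- sort(predict(fm$model, d$X[!tr, colnames(d$X)], type = "margin"))
  cal <- metaphenome:::predict_iso(fm$calibrator, raw)
  expect_true(all(diff(cal) >= -1e-12))
  expect_error(train_calibrated(d$X[tr, ], d$y[tr], panel = c("nope"), seed = 1),
               "unknown metabolite")
})

test_that("AUC machinery matches brute force, bootstrap and DeLong conventions", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(50:300, 1)
    sc <- sample(rnorm(n))  # with replacement sampling introduces ties below
    sc[sample(n, 10)] <- sc[sample(n, 10)]
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(auc_rank(sc, lb), oracle_auc_pairwise(sc, lb), tolerance = 1e-12)
  }
  # perfect ranking
  expect_equal(auc_rank(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  # random scores: AUC near 0.5 and CI covers it
  set.seed(12)
  sc <- rnorm(10000); lb <- rbinom(10000, 1, 0.3)
  ev <- evaluate_scores(sc, lb, B = 300, seed = 4)
  expect_equal(ev$auc, 0.5, tolerance = 0.02)
  expect_true(ev$ci[1] <= 0.5 && 0.5 <= ev$ci[2])
  expect_true(ev$ci[1] <= ev$auc && ev$auc <= ev$ci[2])
  # DeLong of a vector against itself: p = 1 by convention
  dl <- delong_test(sc, sc, lb)
  expect_equal(dl$p, 1)
  # DeLong detects a real difference
  d <- sim_xy(4000, 3, informative = 1, beta = 1.2, prevalence = 0.3, seed = 13)
  good <- d$X[, 1]; noise <- rnorm(4000)
  expect_lt(delong_test(good, noise, d$y)$p, 1e-6)
  expect_error(evaluate_scores(rnorm(10), rep(1, 10)), "single-class")
})

test_that("bootstrap CI width shrinks with sample size", {
  d <- sim_xy(16000, 3, informative = 1, beta = 0.5, prevalence = 0.3, seed = 15)
  sc <- d$X[, 1]
  w <- vapply(c(1000, 4000, 16000), function(n) {
    ev <- evaluate_scores(sc[1:n], d$y[1:n], B = 300, seed = 5)
    diff(ev$ci)
  }, numeric(1))
  expect_true(w[1] > w[2] && w[2] > w[3])
})

test_that("path attributions are exactly additive and ignore unused features", {
  d <- sim_xy(3000, 10, informative = 2, beta = 1.5, prevalence = 0.3, seed = 17)
  X <- d$X
  X[, 5] <- 0  # constant: can never be split on
  fit <- gbt_fit(X, d$y, n_trees = 60)
  at <- attribute(fit, X)
  marg <- predict(fit, X, type = "margin")
  expect_lt(max(abs(rowSums(at$contributions) - marg)), 1e-6)
  expect_true(all(at$contributions[, "met_005"] == 0))
  expect_equal(names(which.max(at$mean_abs)), "met_002")
})

test_that("cross-validation has no test-fold leakage", {
  d <- sim_xy(3000, 15, informative = c(1, 2), beta = 0.8, prevalence = 0.2, seed = 19)
  centres <- sample(sprintf("c%02d", 1:8), 3000, TRUE)
  folds <- assign_geographic_folds(centres, k = 4, seed = 7)
  # corrupting the held-out fold's rows must not change the fold-1 model:
  # everything the fold model sees comes from training rows only
  te <- folds == 1L
  Xc <- d$X
  Xc[te, ] <- matrix(rnorm(sum(te) * 15), sum(te), 15)
  rs1 <- rank_and_select(d$X[!te, ], d$y[!te], top_k = 10)
  rs2 <- rank_and_select(Xc[!te, ], d$y[!te], top_k = 10)
  expect_identical(rs1$panel, rs2$panel)
  f1 <- train_calibrated(d$X[!te, ], d$y[!te], rs1$panel, seed = 3)
  f2 <- train_calibrated(Xc[!te, ], d$y[!te], rs2$panel, seed = 3)
  expect_identical(predict(f1, d$X[te, ]), predict(f2, d$X[te, ]))
})

test_that("noise demographics cannot inflate held-out AUC materially", {
  d <- sim_xy(6000, 20, informative = c(1, 3), beta = 0.7, prevalence = 0.15, seed = 21)
  centres <- sample(sprintf("c%02d", 1:12), 6000, TRUE)
  demo <- matrix(rnorm(6000 * 4), 6000, 4,
                 dimnames = list(NULL, paste0("noise", 1:4)))
  r1 <- metrs_cv(d$X, d$y, centres, k = 4, top_k = 10, B = 100, seed = 9)
  r2 <- metrs_cv(d$X, d$y, centres, demographics = demo, k = 4, top_k = 10,
                 B = 100, seed = 9)
  a_only <- r1$report$auc
  a_comb <- auc_rank(r2$scores_combined, d$y)
  expect_lte(a_comb, a_only + 0.02)
})
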