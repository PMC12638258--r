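# Brute-force oracles, independent of the package implementations they check.

# BH step-up by direct enumeration of the definition: reject the largest k
# with p_(k) <= k*alpha/m; q_i = min over j >= rank(i) of p_(j)*m/j.
oracle_bh_q <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p[i]
    cand <- vapply(r:m, function(j) p[o[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# silhouette by definition: s(i) = (b_i - a_i) / max(a_i, b_i)
oracle_silhouette_mean <- function(mat, labels) {
  D <- as.matrix(dist(mat))
  n <- nrow(mat)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# AUC by exhaustive pairwise comparison
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) tot <- tot + sum(x > neg) + 0.5 * sum(x == neg)
  tot / (length(pos) * length(neg))
}

# 4*IQR outlier rule recomputed from scratch with type-7 quantiles
oracle_outlier_mask <- function(x, mult = 4) {
  med <- median(x)
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  x < med - mult * iqr | x > med + mult * iqr
}

# small standard cohort used across tests
make_test_bundle <- function(n = 4000, p = 8, seed = 42, diseases = NULL,
                             traits = NULL, waves = list(), missingness = 0.02,
                             blocks = list()) {
  cfg <- simulation_config(n, n_metabolites = p, blocks = blocks,
                           diseases = diseases %||% list(),
                           traits = traits %||% list(),
                           waves = waves, missingness = missingness,
                           seed = seed)
  simulate_cohort(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
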