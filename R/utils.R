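#' @useDynLib metaphenome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.formula binomial coef cutree dist glm.fit hclust
#'   isoreg lm lm.fit loess median model.matrix pnorm predict qlogis qnorm
#'   quantile rbinom resid rexp rgamma rnorm runif sd setNames var vcov
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named per-stage random seed from a global seed
#'
#' All stochastic stages draw their seed from one global integer so that
#' toggling a stage on or off does not shift the random draws of any other
#' stage. The derived seed is kept below 2^31.
#'
#' @param seed global integer seed.
#' @param stream stage name, e.g. `"simulate"` or `"metrs"`.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483579)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; equivalent to `p.adjust(p, "BH")` but written
#' against the explicit step-up definition so it can be cross-checked by a
#' brute-force oracle. `NA` entries are excluded from the family and
#' returned as `NA`.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
  out[ok] <- q
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their (averaged-tie) ranks using
#' Blom offsets, \eqn{\Phi^{-1}((r - 3/8) / (n + 1/4))}. Missing values
#' stay missing and are excluded from `n`.
#'
#' @param x numeric vector.
#' @param offset rank offset; 3/8 gives Blom scores.
#' @return transformed vector.
#' @export
inverse_normal_transform <- function(x, offset = 3 / 8) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0L) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

# mode with deterministic lexicographic tie-break (documented contract)
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  tab <- table(x)
  cand <- names(tab)[tab == max(tab)]
  sort(cand)[1L]
}

assert_prob <- function(x, name) {
  if (any(x <= 0 | x >= 1)) stop(name, " must lie strictly in (0, 1)", call. = FALSE)
  invisible(x)
}
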