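#' Percent seizure reduction from pre/post monthly frequencies
#'
#' `max(0, 100 * (pre - post) / pre)`: a worsening (post above pre) clamps
#' to 0 rather than reporting a negative reduction.
#'
#' @param pre,post seizures per month before and after; `pre > 0`.
#' @return Reduction percent in `[0, 100]` (vectorized).
#' @export
seizure_reduction <- function(pre, post) {
  if (any(!is.finite(pre)) || any(pre <= 0))
    stop("preoperative frequency must be positive")
  if (any(!is.finite(post)) || any(post < 0))
    stop("postoperative frequency must be non-negative")
  pmax(0, 100 * (pre - post) / pre)
}

#' Response category from percent seizure reduction
#'
#' Responder above 50%, partial responder from 25% to 50% inclusive,
#' nonresponder below 25%.
#'
#' @param reduction percent in `[0, 100]` (vectorized).
#' @return Character vector in {"responder", "partial", "nonresponder"}.
#' @export
classify_response <- function(reduction) {
  if (any(!is.finite(reduction)) || any(reduction < 0 | reduction > 100))
    stop("reduction must lie in [0, 100]")
  ifelse(reduction > 50, "responder",
         ifelse(reduction >= 25, "partial", "nonresponder"))
}

#' Spearman rank correlation with a two-sided p value
#'
#' Ranks use average ties; rho is the Pearson correlation of the rank
#' vectors. The two-sided p value comes from the t approximation with n - 2
#' degrees of freedom, or from exhaustive permutation of one variable when
#' `exact = TRUE` (feasible for n <= 8).
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @param exact exhaustive-permutation p value instead of the t
#'   approximation.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("Spearman rho is undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8) stop("exact permutation p only supported for n <= 8")
    perms <- permutations_of(n)
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      r <- stats::cor(rx[perms[i, ]], ry)
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(1, p)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mann-Whitney U test with exact two-sided p for small samples
#'
#' U is computed from rank sums with average-rank ties. For combined sizes
#' up to 20 the two-sided p value is exact, by enumerating all
#' choose(na + nb, na) group assignments of the pooled values (792 for 7 vs
#' 5); larger samples fall back to the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b nonempty numeric vectors.
#' @param exact_max largest na + nb for which the exact enumeration runs.
#' @return List with `U` (for group `a`), `p`, `method`.
#' @export
mann_whitney_test <- function(a, b, exact_max = 20L) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1L, nb >= 1L)
  pooled <- c(a, b)
  U <- u_statistic(pooled, na)
  n <- na + nb
  mu <- na * nb / 2
  if (n <= exact_max) {
    r <- rank(pooled)
    combs <- utils::combn(n, na)
    offs <- na * (na + 1) / 2
    Uall <- colSums(matrix(r[combs], nrow = na)) - offs
    dev_obs <- abs(U - mu)
    p <- mean(abs(Uall - mu) >= dev_obs - 1e-9)
    method <- "exact enumeration"
  } else {
    r <- rank(pooled)
    ties <- table(r)
    tiecor <- sum(ties^3 - ties) / (n * (n - 1))
    sdU <- sqrt(na * nb / 12 * ((n + 1) - tiecor))
    z <- (abs(U - mu) - 0.5) / sdU
    p <- min(1, 2 * stats::pnorm(-max(0, z)))
    method <- "normal approximation"
  }
  list(U = U, p = p, na = na, nb = nb, method = method)
}

u_statistic <- function(pooled, na) {
  r <- rank(pooled)
  sum(r[seq_len(na)]) - na * (na + 1) / 2
}

#' Quantiles with the linear-interpolation (inclusive) convention
#'
#' Fixes the percentile convention used for the interquartile ranges:
#' `stats::quantile` type 7.
#'
#' @param x numeric vector.
#' @param probs probabilities.
#' @return Quantiles.
#' @export
iqr_quantiles <- function(x, probs = c(0.25, 0.75)) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

#' Group comparison of peak connection probability between response groups
#'
#' Pools partial responders with nonresponders (the cohort's grouping for
#' its first analysis) and compares the peak probability of connectivity
#' between the pooled group and responders with the Mann-Whitney U test;
#' reports per-group medians and IQRs.
#'
#' @param cohort data frame with columns `peak_probability` and `reduction`
#'   (or a precomputed `response` column).
#' @return List with group summaries and the test result.
#' @export
run_group_comparison <- function(cohort) {
  resp <- if ("response" %in% names(cohort)) cohort$response
          else classify_response(cohort$reduction)
  g_resp <- cohort$peak_probability[resp == "responder"]
  g_other <- cohort$peak_probability[resp != "responder"]
  if (length(g_resp) == 0L || length(g_other) == 0L)
    stop("both response groups must be nonempty")
  mw <- mann_whitney_test(g_resp, g_other)
  summ <- function(x) list(n = length(x), median = stats::median(x),
                           iqr = iqr_quantiles(x))
  list(responders = summ(g_resp),
       partial_nonresponders = summ(g_other),
       U = mw$U, p = mw$p, method = mw$method)
}
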