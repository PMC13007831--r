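test_that("seizure reduction is the clamped percent change from baseline", {
  expect_equal(seizure_reduction(0.17, 0), 100)
  expect_equal(seizure_reduction(4, 3), 25)
  expect_equal(seizure_reduction(5, 6), 0)      # worsening clamps to 0
  expect_equal(seizure_reduction(2, 4), 0)
  expect_equal(seizure_reduction(12, 10), 16 + 2 / 3, tolerance = 1e-9)
  expect_error(seizure_reduction(0, 1), "positive")
  expect_error(seizure_reduction(-2, 1), "positive")
})

test_that("response categories split at >50 / 25-50 / <25", {
  expect_equal(classify_response(100), "responder")
  expect_equal(classify_response(50), "partial")
  expect_equal(classify_response(25), "partial")
  expect_equal(classify_response(16.67), "nonresponder")
  expect_equal(classify_response(c(60, 50.0001, 24.99)),
               c("responder", "responder", "nonresponder"))
  expect_error(classify_response(120), "0, 100")
})

test_that("Spearman rho matches rank correlation and its oracles", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_test(x, x + 100)$rho, 1.0)

  # against base R on tie-free data (t approximation on both sides)
  set.seed(5)
  for (rep in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    ours <- spearman_test(a, b)
    ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                            exact = FALSE))
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  }

  # exact permutation p against a brute-force oracle at n = 5
  perm_oracle <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    obs <- abs(cor(rx, ry))
    perms <- expand.grid(rep(list(1:5), 5))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
    mean(apply(perms, 1, function(pr) abs(cor(rx[pr], ry)) >= obs - 1e-12))
  }
  set.seed(8)
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(5)
    expect_equal(spearman_test(a, b, exact = TRUE)$p, perm_oracle(a, b))
  }
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
})

test_that("Mann-Whitney exact p matches full enumeration, ties included", {
  # independent oracle: count pairwise wins + half-ties over all C(n, na)
  # group assignments
  enum_oracle <- function(a, b) {
    pooled <- c(a, b); na <- length(a); n <- length(pooled)
    ustat <- function(g1) {
      g2 <- setdiff(seq_len(n), g1)
      sum(outer(pooled[g1], pooled[g2], ">")) +
        0.5 * sum(outer(pooled[g1], pooled[g2], "=="))
    }
    mu <- na * length(b) / 2
    obs <- abs(ustat(seq_len(na)) - mu)
    combs <- utils::combn(n, na)
    mean(vapply(seq_len(ncol(combs)),
                function(j) abs(ustat(combs[, j]) - mu) >= obs - 1e-9,
                logical(1)))
  }

  # complete separation at 7 vs 5: both extreme tails, p = 2/792
  a <- c(8, 9, 10, 11, 12, 13, 14); b <- c(1, 2, 3, 4, 5)
  res <- mann_whitney_test(a, b)
  expect_equal(res$p, 2 / choose(12, 7))
  expect_equal(res$U, 35)          # all 7x5 pairwise wins
  expect_equal(res$p, enum_oracle(a, b))

  expect_equal(mann_whitney_test(3, 3)$p, 1)

  set.seed(9)
  for (rep in 1:6) {
    a <- sample(1:10, 7, replace = TRUE)    # replacement forces ties
    b <- sample(1:10, 5, replace = TRUE)
    expect_equal(mann_whitney_test(a, b)$p, enum_oracle(a, b))
  }

  # tie-free case agrees with base R's exact test
  a <- c(1.2, 3.4, 2.2, 5.1, 0.4, 7.7, 6.1); b <- c(2.9, 4.4, 0.9, 8.2, 3.1)
  expect_equal(mann_whitney_test(a, b)$p,
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
  expect_equal(mann_whitney_test(a, b)$U,
               unname(stats::wilcox.test(a, b, exact = TRUE)$statistic))
})

test_that("the percentile convention is linear interpolation, inclusive", {
  expect_equal(iqr_quantiles(c(1, 2, 3, 4, 5)), c(2, 4))
  expect_equal(iqr_quantiles(c(10, 20, 30, 40)), c(17.5, 32.5))
})

test_that("group comparison pools partial with nonresponders", {
  cohort <- data.frame(
    peak_probability = c(0.30, 0.28, 0.25, 0.22, 0.21, 0.24, 0.27,
                         0.08, 0.06, 0.17, 0.05, 0.09),
    reduction = c(100, 100, 95, 60, 96.33, 75, 100, 25, 0, 16.67, 50, 0))
  res <- run_group_comparison(cohort)
  expect_equal(res$responders$n, 7)
  expect_equal(res$partial_nonresponders$n, 5)
  # complete separation: exact two-sided p = 2 / C(12, 7)
  expect_equal(res$p, 2 / choose(12, 7))
  expect_gt(res$responders$median, res$partial_nonresponders$median)

  flat <- data.frame(peak_probability = rep(0.2, 8),
                     reduction = c(90, 80, 70, 60, 40, 30, 10, 0))
  rf <- run_group_comparison(flat)
  expect_equal(rf$p, 1)
  expect_equal(rf$responders$median, rf$partial_nonresponders$median)
})

test_that("published-cohort sensitivity: rounded percents barely move rho", {
  img <- load_cohort_imaging()
  rho_ratio <- spearman_test(img$n_activated / img$n_streamlines,
                             img$reduction_pct)$rho
  rho_rounded <- spearman_test(img$percent_activated / 100,
                               img$reduction_pct)$rho
  expect_lt(abs(rho_ratio - rho_rounded), 0.02)
})
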