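test_that("degenerate outcomes give the boundary p-values", {
  g <- rep(0:1, each = 10)
  expect_warning(res <- adjustedPermutationTest(rep(2, 20), g, nPerm = 99),
                 "constant")
  expect_equal(res$p, 1)

  ## perfect separation attains the minimum attainable p
  y <- c(rnorm(20, 0, 0.1), rnorm(20, 50, 0.1))
  res <- adjustedPermutationTest(y, rep(0:1, each = 20), nPerm = 999,
                                 seed = 4)
  expect_equal(res$p, 1 / 1000)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration at n = 8", {
  set.seed(10)
  y <- rnorm(8) + rep(c(0, 1.2), each = 4)
  g <- rep(0:1, each = 4)

  tFor <- function(lab) {
    a <- y[lab == 1]; b <- y[lab == 0]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }
  tObs <- abs(tFor(g))
  combos <- combn(8, 4)
  tAll <- apply(combos, 2, function(ix) {
    lab <- integer(8); lab[ix] <- 1L
    abs(tFor(lab))
  })
  pExact <- mean(tAll >= tObs - 1e-12)

  res <- adjustedPermutationTest(y, g, nPerm = 4999, seed = 2)
  se <- sqrt(pExact * (1 - pExact) / 4999)
  expect_lt(abs(res$p - pExact), 3 * se + 1 / 5000)
  ## the regression t for a binary indicator is the two-sample t
  expect_equal(abs(res$statistic), tObs, tolerance = 1e-10)
})

test_that("permutation p-values are reproducible and seed-sensitive", {
  set.seed(5)
  y <- rnorm(30); g <- rep(0:1, 15); X <- cbind(rnorm(30))
  r1 <- adjustedPermutationTest(y, g, X, nPerm = 500, seed = 9)
  r2 <- adjustedPermutationTest(y, g, X, nPerm = 500, seed = 9)
  expect_identical(r1, r2)

  expect_error(adjustedPermutationTest(y, g, cbind(X, X), nPerm = 10),
               "rank deficient")
  expect_error(adjustedPermutationTest(y, rep(1, 30), nPerm = 10),
               "two levels")
})

test_that("covariate-adjusted test controls type-I error under the null", {
  n <- 50
  rej <- vapply(1:200, function(s) {
    set.seed(6000 + s)
    age <- rnorm(n); sex <- rbinom(n, 1, 0.5)
    y <- 0.8 * age + 0.5 * sex + rnorm(n)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) return(NA)
    adjustedPermutationTest(y, g, cbind(age, sex), nPerm = 299,
                            seed = s)$p < 0.05
  }, logical(1))
  rate <- mean(rej, na.rm = TRUE)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.105)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bhFDR(0.37), 0.37)
  expect_equal(bhFDR(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))

  set.seed(7)
  p <- runif(25)
  q <- bhFDR(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_equal(order(q[order(p)]), seq_len(25))  # order-preserving
  ## never more discoveries than unadjusted testing
  expect_lte(sum(q < 0.05), sum(p < 0.05))
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
})

test_that("chi-squared reproduces the printed sex-ratio p-values", {
  twoGroup <- rbind(HC = c(15, 12), MS = c(69, 33))
  res <- chiSquaredContingency(twoGroup)
  expect_equal(res$df, 1)
  expect_equal(round(res$p, 3), 0.241)

  threeGroup <- rbind(HC = c(15, 12), CPMS = c(36, 11), CIMS = c(33, 22))
  res3 <- chiSquaredContingency(threeGroup)
  expect_equal(res3$df, 2)
  expect_equal(round(res3$p, 3), 0.108)

  flat <- rbind(c(10, 20), c(5, 10))
  resF <- chiSquaredContingency(flat)
  expect_equal(resF$statistic, 0, tolerance = 1e-12)
  expect_equal(resF$p, 1)

  expect_error(chiSquaredContingency(rbind(c(0, 0), c(1, 2))), "marginal")
  expect_error(chiSquaredContingency(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("group comparison tables have coherent structure", {
  ch <- generateCohort(smallSpec(), seed = 31)
  profiles <- computeProfiles(ch)
  agg <- aggregateMetrics(profiles)
  comp <- runGroupComparisons(agg, ch@manifest, nPerm = 99, seed = 3,
                              contrasts = "HC_vs_MS")
  expect_equal(nrow(comp), 3 * (1 + 8 + 7))
  expect_true(all(comp$p_fdr >= comp$p_perm))
  expect_true(all(comp$p_perm >= 1 / 100))
  expect_true(all(comp$direction %in% c(-1, 0, 1)))
  expect_setequal(unique(comp$level), c("global", "network", "nucleus"))
  ## reproducible given the same seed
  comp2 <- runGroupComparisons(agg, ch@manifest, nPerm = 99, seed = 3,
                               contrasts = "HC_vs_MS")
  expect_identical(comp, comp2)
})
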