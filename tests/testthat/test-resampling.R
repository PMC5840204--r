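test_that("permutation ANOVA matches exhaustive enumeration on disjoint groups", {
  r <- permutation_anova(list(1:5, 11:15), exhaustive = TRUE)
  # only the observed assignment and its mirror reach the observed F
  expect_equal(r$p_value, 2 / 252)
  expect_equal(r$n_perm, 252)
})

test_that("permutation ANOVA is deterministic, valid on constants, and seeded", {
  expect_equal(permutation_anova(list(rep(2, 5), rep(2, 5)))$p_value, 1)
  g <- list(rnorm(6), rnorm(6), rnorm(6))
  a <- permutation_anova(g, n_perm = 500, seed = 9)
  b <- permutation_anova(g, n_perm = 500, seed = 9)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 1 / 501)
  expect_error(permutation_anova(list(1:3)), "2 groups")
})

test_that("permutation ANOVA agrees with classical ANOVA on well-separated data", {
  withr::with_seed(50, {
    g <- list(rnorm(10), rnorm(10, 3), rnorm(10, 6))
    r <- permutation_anova(g, n_perm = 2000, seed = 1)
    f_ref <- summary(aov(y ~ grp, data.frame(
      y = unlist(g), grp = factor(rep(1:3, each = 10)))))[[1]]$F[1]
    expect_equal(r$statistic, f_ref, tolerance = 1e-9)
    expect_lt(r$p_value, 0.01)
  })
})

test_that("interaction ANOVA finds a crossed effect and not an additive one", {
  withr::with_seed(51, {
    n <- 30
    geno <- rep(c("control", "opsin"), each = 2 * n)
    laser <- rep(rep(c("pre", "laser"), each = n), 2)
    # pure main effects
    y_add <- rnorm(4 * n) + (geno == "opsin") * 1 + (laser == "laser") * 2
    p_add <- interaction_anova(y_add, geno, laser)$p_value
    expect_gt(p_add, 0.01)
    # effect confined to the opsin x laser cell, 1 SD
    y_int <- rnorm(4 * n) + (geno == "opsin" & laser == "laser") * 1
    expect_lt(interaction_anova(y_int, geno, laser)$p_value, 0.01)
    # the interaction F is invariant to adding main effects
    f1 <- interaction_anova(y_int, geno, laser)$statistic
    f2 <- interaction_anova(y_int + 5 * (geno == "opsin") -
                              3 * (laser == "laser"), geno, laser)$statistic
    expect_equal(f1, f2, tolerance = 1e-8)
  })
})

test_that("interaction ANOVA handles degenerate input and empty cells", {
  geno <- rep(c("control", "opsin"), each = 4)
  laser <- rep(c("pre", "laser"), 4)
  expect_warning(r <- interaction_anova(rep(1, 8), geno, laser), "identical")
  expect_equal(r$p_value, 1)
  expect_error(interaction_anova(rnorm(4), rep("control", 4),
                                 rep(c("pre", "laser"), 2)), "cell")
})

test_that("the residual-permutation interaction test agrees with the analytic one", {
  withr::with_seed(52, {
    n <- 20
    geno <- rep(c("control", "opsin"), each = 2 * n)
    laser <- rep(rep(c("pre", "laser"), each = n), 2)
    y <- rnorm(4 * n) + (geno == "opsin" & laser == "laser") * 0.8
    p_perm <- interaction_anova(y, geno, laser, n_perm = 400, seed = 3)$p_value
    p_an <- interaction_anova(y, geno, laser)$p_value
    expect_lt(abs(p_perm - p_an), 0.05)
  })
})

test_that("chi-squared on two proportions matches the pooled-expected-count formula", {
  r <- chi2_proportions(90, 100, 50, 100)
  expect_equal(r$statistic, 400 * (2 / 70 + 2 / 30), tolerance = 1e-9)  # 38.095
  expect_lt(r$p_value, 1e-9)
  expect_equal(chi2_proportions(50, 100, 50, 100)$statistic, 0)
  expect_equal(chi2_proportions(50, 100, 50, 100)$p_value, 1)
  expect_equal(chi2_proportions(0, 50, 0, 50)$p_value, 1)
  expect_error(chi2_proportions(5, 0, 1, 10), "> 0")
})

test_that("two-sample tests cover the rank-sum and paired-t contracts", {
  a <- rnorm(20)
  r0 <- two_sample_test(a, a, "paired_t")
  expect_equal(r0$statistic, 0); expect_equal(r0$p_value, 1)
  expect_lt(two_sample_test(rnorm(20, 10), rnorm(20), "ranksum")$p_value, 1e-6)
  expect_error(two_sample_test(1:3, 1:4, "paired_t"), "equal lengths")
  withr::with_seed(53, {
    x <- rnorm(25); y <- rnorm(25, 1)
    ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    expect_equal(two_sample_test(x, y, "ranksum")$p_value, ref)
  })
})

test_that("permutation p-values are super-uniform under the null", {
  withr::with_seed(54, {
    p <- replicate(60, permutation_anova(
      list(rnorm(6), rnorm(6)), n_perm = 199, seed = sample.int(1e6, 1))$p_value)
    # at alpha = 0.2 the rejection rate must not exceed alpha by much
    expect_lt(mean(p <= 0.2), 0.35)
    expect_gt(mean(p <= 0.5), 0.25)
  })
})
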