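# brute-force oracle: P(pos > neg) + 0.5 P(tie) - 0.5 over all pairs
auroc_pairs <- function(pos, neg) {
  g <- outer(pos, neg, ">"); t <- outer(pos, neg, "==")
  mean(g + 0.5 * t) - 0.5
}

test_that("recentered auROC matches exhaustive pair counting", {
  expect_equal(auroc_centered(c(3, 5), c(2, 4))$auroc, 0.25)
  expect_equal(auroc_centered(1:5, 1:5)$auroc, 0)
  expect_equal(auroc_centered(6:10, 1:5)$auroc, 0.5)
  withr::with_seed(42, {
    for (i in 1:50) {
      pos <- sample(1:6, sample(2:12, 1), replace = TRUE)
      neg <- sample(1:6, sample(2:12, 1), replace = TRUE)
      expect_equal(auroc_centered(pos, neg)$auroc, auroc_pairs(pos, neg))
    }
  })
})

test_that("auROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    for (i in 1:10) {
      pos <- rnorm(20, 1); neg <- rnorm(15)
      ref <- as.numeric(pROC::auc(pROC::roc(
        response = rep(c(1, 0), c(20, 15)), predictor = c(pos, neg),
        direction = "<", quiet = TRUE)))
      expect_equal(auroc_centered(pos, neg)$auroc, ref - 0.5, tolerance = 1e-12)
    }
  })
})

test_that("the ROC curve is a valid staircase whose area matches", {
  withr::with_seed(44, {
    pos <- rnorm(12, 0.5); neg <- rnorm(9)
    r <- auroc_centered(pos, neg)
    expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
    expect_equal(r$curve$fpr[nrow(r$curve)], 1)
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
    trap <- sum(diff(r$curve$fpr) *
                  (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
    expect_equal(trap - 0.5, r$auroc, tolerance = 1e-12)
  })
})

test_that("auROC properties: antisymmetry, range, monotone invariance", {
  withr::with_seed(45, {
    for (i in 1:20) {
      pos <- rnorm(10); neg <- rnorm(8)
      a <- auroc_centered(pos, neg)$auroc
      expect_identical(a, -auroc_centered(neg, pos)$auroc)
      expect_gte(a, -0.5); expect_lte(a, 0.5)
      expect_equal(auroc_centered(exp(pos), exp(neg))$auroc, a)
    }
  })
})

test_that("the z-test behaves at the edges and under the null", {
  expect_equal(auroc_centered(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_lt(auroc_centered(rnorm(30, 10), rnorm(30))$p_value, 1e-6)
  expect_warning(r <- auroc_centered(rep(1, 5), rep(1, 5)), "identical")
  expect_equal(r$p_value, 1)
  expect_error(auroc_centered(numeric(0), 1:3), "non-empty")
  # null calibration: rejection rate near alpha
  withr::with_seed(46, {
    p <- replicate(300, auroc_centered(rnorm(15), rnorm(15))$p_value)
    expect_gt(mean(p < 0.05), 0.01)
    expect_lt(mean(p < 0.05), 0.12)
  })
})

test_that("BH step-up matches the hand rule and p.adjust", {
  fr <- fdr_correct(c(0.001, 0.01, 0.02, 0.9), q = 0.05)
  expect_equal(fr$p_fdr, 0.02)
  expect_equal(fr$n_significant, 3)
  expect_identical(fr$significant, c(TRUE, TRUE, TRUE, FALSE))

  expect_equal(fdr_correct(c(0.3, 0.6, 0.9), 0.05)$n_significant, 0)
  expect_equal(fdr_correct(c(0.3, 0.6, 0.9), 0.05)$p_fdr, 0)
  expect_true(all(fdr_correct(rep(0, 5), 0.05)$significant))

  withr::with_seed(47, {
    for (i in 1:20) {
      p <- runif(30)^2
      fr <- fdr_correct(p, 0.05)
      expect_identical(fr$significant, p.adjust(p, "BH") <= 0.05)
    }
  })
})

test_that("enlarging q never shrinks the significant set", {
  withr::with_seed(48, {
    p <- runif(40)^3
    qs <- c(0.01, 0.05, 0.1, 0.2)
    ks <- vapply(qs, function(q) fdr_correct(p, q)$n_significant, numeric(1))
    expect_true(all(diff(ks) >= 0))
  })
})

test_that("d-prime normalization divides by the mean class SD and is scale-free", {
  withr::with_seed(49, {
    a <- rnorm(200, 0, 2); b <- rnorm(200, 2, 2)
    dp <- dprime_normalize(list(cr = a, hit = b))
    expect_equal(dp$divisor, mean(c(sd(a), sd(b))))
    expect_equal(mean(dp$values$hit) - mean(dp$values$cr),
                 (mean(b) - mean(a)) / dp$divisor)
    # class-mean d' difference ~ (2 - 0) / 2 = 1
    expect_equal(mean(dp$values$hit) - mean(dp$values$cr), 1, tolerance = 0.2)
    dp10 <- dprime_normalize(list(cr = 10 * a, hit = 10 * b))
    expect_equal(dp10$values$hit, dp$values$hit)
  })
  expect_error(dprime_normalize(list(a = c(1, 1), b = c(1, 1))), "zero pooled")
  expect_error(dprime_normalize(list(a = 1, b = c(1, 2))), ">= 2")
})

test_that("percent significant applies FDR within each group family", {
  tab <- data.frame(band = rep(c("theta", "beta"), each = 4),
                    p_value = c(rep(0, 4), rep(0.9, 4)))
  ps <- percent_significant(tab, by = "band", q = 0.05)
  expect_equal(ps$percent[ps$band == "theta"], 100)
  expect_equal(ps$percent[ps$band == "beta"], 0)
  expect_equal(ps$n, c(4, 4))
})
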