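stat_result <- function(method, statistic, p_value, n_perm = 0L, seed = NA_integer_,
                        group_sizes = integer(0), extra = list()) {
  structure(c(list(method = method, statistic = statistic, p_value = p_value,
                   n_perm = as.integer(n_perm), seed = seed,
                   group_sizes = group_sizes), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g%s\n",
              x$method, x$statistic, x$p_value,
              if (x$n_perm > 0) paste0(" (", x$n_perm, " permutations)") else ""))
  invisible(x)
}

# one-way F statistic; labels as integer group ids 1..k
f_statistic <- function(values, groups) {
  n <- length(values)
  k <- max(groups)
  gs <- rowsum(values, groups)
  gn <- tabulate(groups, k)
  gm <- gs / gn
  grand <- sum(gs) / n
  ss_between <- sum(gn * (gm - grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_within <- ss_total - ss_between
  if (ss_within <= .Machine$double.eps * ss_total) {
    if (ss_between <= .Machine$double.eps) return(0)
    return(Inf)
  }
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Permutation-based one-way ANOVA
#'
#' Compares the observed one-way F statistic with its distribution under
#' random relabelings of the observations. The p-value uses the add-one rule
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so it is never 0 and is
#' valid under exchangeability. For two groups an exhaustive mode enumerates
#' every assignment of observations to groups (then
#' `p = #{F >= F_obs} / #assignments`, observed included).
#'
#' @param groups List of numeric vectors (>= 2 groups, >= 2 values each).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Integer seed (the test is deterministic given the seed).
#' @param exhaustive Enumerate all assignments (two groups only).
#' @return A `stat_result` with `method = "perm_anova"`.
#' @export
permutation_anova <- function(groups, n_perm = 10000L, seed = 1L,
                              exhaustive = FALSE) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(seq_along(groups), lengths(groups))
  f_obs <- f_statistic(values, labels)
  if (f_obs == 0 && stats::var(values) == 0) {
    return(stat_result("perm_anova", 0, 1, 0L, seed, lengths(groups)))
  }
  if (exhaustive) {
    if (length(groups) != 2) {
      stop("exhaustive enumeration implemented for two groups", call. = FALSE)
    }
    n <- length(values); n1 <- length(groups[[1]])
    idx <- utils::combn(n, n1)
    fs <- apply(idx, 2, function(i) {
      g <- rep(2L, n); g[i] <- 1L
      f_statistic(values, g)
    })
    p <- mean(fs >= f_obs - 1e-12)
    return(stat_result("perm_anova", f_obs, p, ncol(idx), NA_integer_,
                       lengths(groups), list(exhaustive = TRUE)))
  }
  count <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      f_statistic(values[sample.int(length(values))], labels) >= f_obs - 1e-12
    }, logical(1)))
  })
  p <- (1 + count) / (1 + n_perm)
  stat_result("perm_anova", f_obs, p, n_perm, seed, lengths(groups))
}

#' Genotype-by-laser interaction ANOVA
#'
#' Two-way fixed-effects ANOVA returning the interaction term: does the
#' laser-induced change differ between genotypes? Analytic F test by default;
#' with `n_perm > 0` a permutation variant shuffles the residuals of the
#' additive (main-effects-only) model.
#'
#' @param values Numeric vector of observations (e.g. per-electrode auROC).
#' @param genotype Factor-like, two or more levels (e.g. control/opsin).
#' @param laser Factor-like (e.g. pre/laser).
#' @param n_perm 0 for the analytic test, else number of residual
#'   permutations.
#' @param seed Seed for the permutation variant.
#' @return A `stat_result` with `method = "interaction_anova"`; `extra`
#'   fields carry the main-effect rows of the ANOVA table.
#' @export
interaction_anova <- function(values, genotype, laser, n_perm = 0L, seed = 1L) {
  genotype <- factor(genotype); laser <- factor(laser)
  if (nlevels(genotype) < 2 || nlevels(laser) < 2 ||
      any(table(genotype, laser) == 0)) {
    stop("empty genotype x laser cell", call. = FALSE)
  }
  gs <- as.integer(table(interaction(genotype, laser)))
  if (stats::var(values) == 0) {
    warning("all values identical; interaction undefined, p = 1", call. = FALSE)
    return(stat_result("interaction_anova", 0, 1, 0L, seed, gs))
  }
  fit <- stats::lm(values ~ genotype * laser)
  tab <- stats::anova(fit)
  f_obs <- tab["genotype:laser", "F value"]
  if (!is.finite(f_obs)) {
    warning("interaction F undefined; p = 1", call. = FALSE)
    return(stat_result("interaction_anova", 0, 1, 0L, seed, gs))
  }
  if (n_perm <= 0) {
    p <- tab["genotype:laser", "Pr(>F)"]
    return(stat_result("interaction_anova", f_obs, p, 0L, seed, gs,
                       list(anova_table = tab)))
  }
  additive <- stats::lm(values ~ genotype + laser)
  fitted0 <- stats::fitted(additive)
  res0 <- stats::residuals(additive)
  count <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      y <- fitted0 + res0[sample.int(length(res0))]
      stats::anova(stats::lm(y ~ genotype * laser))["genotype:laser",
                                                    "F value"] >= f_obs - 1e-12
    }, logical(1)))
  })
  stat_result("interaction_anova", f_obs, (1 + count) / (1 + n_perm),
              n_perm, seed, gs)
}

#' Chi-squared test for two proportions
#'
#' Pearson chi-squared on the 2x2 table of significant/non-significant counts
#' (continuity correction off by default, matching the large-sample test on
#' percent-significant electrodes).
#'
#' @param k1,n1 Successes and total in condition 1.
#' @param k2,n2 Successes and total in condition 2.
#' @param correct Apply Yates continuity correction.
#' @return A `stat_result` with `method = "chi2_prop"`.
#' @export
chi2_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0) stop("group totals must be > 0", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("need 0 <= k <= n", call. = FALSE)
  }
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    return(stat_result("chi2_prop", 0, 1, group_sizes = c(n1, n2)))
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  stat_result("chi2_prop", unname(ct$statistic), ct$p.value,
              group_sizes = c(n1, n2))
}

#' Classical two-sample tests
#'
#' Wilcoxon rank-sum (normal approximation with tie correction) or paired t,
#' both two-sided.
#'
#' @param a,b Numeric samples; equal length required for `paired_t`.
#' @param method `"ranksum"` or `"paired_t"`.
#' @return A `stat_result`.
#' @export
two_sample_test <- function(a, b, method = c("ranksum", "paired_t")) {
  method <- match.arg(method)
  if (method == "ranksum") {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    stat_result("ranksum", unname(wt$statistic), wt$p.value,
                group_sizes = c(length(a), length(b)))
  } else {
    if (length(a) != length(b)) {
      stop("paired_t requires equal lengths", call. = FALSE)
    }
    d <- a - b
    if (stats::sd(d) == 0) {
      return(stat_result("paired_t", 0, if (all(d == 0)) 1 else NA_real_,
                         group_sizes = c(length(a), length(b))))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    stat_result("paired_t", unname(tt$statistic), tt$p.value,
                group_sizes = c(length(a), length(b)))
  }
}
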