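#' Recentered ROC analysis of two score distributions
#'
#' Computes the empirical ROC curve and the recentered area
#' `auroc = P(pos > neg) + 0.5 * P(tie) - 0.5`, so 0 means the scores carry
#' no class information and +/-0.5 perfect separation in either direction.
#' Ties receive half credit (midranks). Equals the trapezoidal area under the
#' empirical ROC minus 0.5. Significance is a two-sided z-test with the
#' Hanley--McNeil standard error of the (uncentered) area.
#'
#' @param scores_pos,scores_neg Numeric scores of the positive (e.g. S+ or
#'   Hit) and negative (S- or CR) class. Both non-empty.
#' @param label_pair Optional label for the contrast (e.g. `"Splus_Sminus"`).
#' @return Object of class `roc_result`: `auroc` in `[-0.5, 0.5]`,
#'   `p_value`, `n_pos`, `n_neg`, `curve` (data.frame `fpr`, `tpr`),
#'   `label_pair`.
#' @export
auroc_centered <- function(scores_pos, scores_neg, label_pair = NA_character_) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  n_pos <- length(scores_pos); n_neg <- length(scores_neg)
  if (length(unique(c(scores_pos, scores_neg))) == 1) {
    warning("all scores identical; auROC = 0, p = 1", call. = FALSE)
  }
  r <- rank(c(scores_pos, scores_neg))      # midranks handle ties
  u <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  # centered area computed directly from the U statistic so that
  # auroc(A, B) == -auroc(B, A) exactly (U swaps to n_pos*n_neg - U)
  centered <- (u - n_pos * n_neg / 2) / (n_pos * n_neg)

  # empirical ROC curve at descending thresholds
  th <- sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores_pos >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(scores_neg >= t), numeric(1)))

  res <- structure(list(auroc = centered, p_value = NA_real_,
                        n_pos = n_pos, n_neg = n_neg,
                        curve = data.frame(fpr = fpr, tpr = tpr),
                        label_pair = label_pair),
                   class = "roc_result")
  res$p_value <- auroc_significance(res)
  res
}

#' z-test significance of a recentered auROC
#'
#' Two-sided p-value for the null auROC = 0, using the Hanley--McNeil
#' variance of the uncentered area. Degenerate inputs (all scores identical,
#' zero variance) return p = 1 with a warning.
#'
#' @param result A `roc_result` from [auroc_centered()].
#' @return p-value in `[0, 1]`.
#' @export
auroc_significance <- function(result) {
  a <- result$auroc + 0.5
  n1 <- result$n_pos; n2 <- result$n_neg
  if (n1 < 2 || n2 < 2) stop("need >= 2 scores per class", call. = FALSE)
  if (result$auroc == 0) return(1)
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  v <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n2 - 1) * (q2 - a^2)) / (n1 * n2)
  if (v <= 0) {
    # perfect separation: variance formula degenerates; use the exact
    # Mann-Whitney tail instead of dividing by zero
    return(min(1, 2 / choose(n1 + n2, n1)))
  }
  z <- result$auroc / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> auROC = %+.3f (n+ = %d, n- = %d), p = %.3g%s\n",
              x$auroc, x$n_pos, x$n_neg, x$p_value,
              if (is.na(x$label_pair)) "" else paste0(" [", x$label_pair, "]")))
  invisible(x)
}

#' Benjamini--Hochberg false-discovery-rate correction
#'
#' Step-up procedure: `p_fdr` is the largest sorted p-value `p(i)` with
#' `p(i) <= (i/m) * q` (0 when none qualifies); all p-values at or below
#' `p_fdr` are declared significant.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.05).
#' @return Object of class `fdr_result`: `q`, `p_fdr`, `significant`
#'   (logical mask in input order), `m` (family size), `n_significant`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (!length(p_values)) stop("empty p-value family", call. = FALSE)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values outside [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= (seq_len(m) / m) * q)
  p_fdr <- if (length(ok)) ps[max(ok)] else 0
  significant <- if (length(ok)) p_values <= p_fdr else rep(FALSE, m)
  structure(list(q = q, p_fdr = p_fdr, significant = significant, m = m,
                 n_significant = sum(significant)),
            class = "fdr_result")
}

#' Normalize delta power to d-prime by class spread
#'
#' Divides every value by the unweighted mean of the per-class standard
#' deviations, yielding a dimensionless effect size whose class-mean
#' difference is the classical d'.
#'
#' @param values_by_class Named list: one numeric vector of delta power per
#'   class (each with >= 2 values).
#' @return Object of class `dprime_table`: `values` (same shape, divided),
#'   `divisor` (mean class SD), `class_sd` (per class).
#' @export
dprime_normalize <- function(values_by_class) {
  if (any(vapply(values_by_class, length, integer(1)) < 2)) {
    stop("need >= 2 values per class", call. = FALSE)
  }
  sds <- vapply(values_by_class, stats::sd, numeric(1))
  divisor <- mean(sds)
  if (!is.finite(divisor) || divisor <= 0) {
    stop("zero pooled standard deviation", call. = FALSE)
  }
  structure(list(values = lapply(values_by_class, function(v) v / divisor),
                 divisor = divisor, class_sd = sds),
            class = "dprime_table")
}

#' Percent of significant auROCs per group after FDR correction
#'
#' Applies [fdr_correct()] within each group (the family: all electrodes of
#' one condition) and reports the percent declared significant, with the
#' counts retained for chi-squared comparisons between conditions.
#'
#' @param roc_table Data.frame with at least a `p_value` column and the
#'   grouping column(s) named by `by`.
#' @param by Character vector of grouping column names (default `"band"`).
#' @param q Target FDR.
#' @return Data.frame: grouping columns, `n`, `k` (significant), `percent`,
#'   `p_fdr`.
#' @export
percent_significant <- function(roc_table, by = "band", q = 0.05) {
  key <- interaction(roc_table[, by, drop = FALSE], drop = TRUE, sep = ":")
  parts <- split(seq_len(nrow(roc_table)), key)
  do.call(rbind, lapply(names(parts), function(k) {
    i <- parts[[k]]
    fr <- fdr_correct(roc_table$p_value[i], q)
    cbind(roc_table[i[1], by, drop = FALSE],
          data.frame(n = length(i), k = fr$n_significant,
                     percent = 100 * fr$n_significant / length(i),
                     p_fdr = fr$p_fdr, row.names = NULL))
  }))
}

#' Per-electrode auROC from a delta power table
#'
#' For each electrode and band, contrasts delta power between two trial
#' classes and returns the recentered auROC with its z-test p-value.
#'
#' @param dpt Output of [delta_power_table()].
#' @param contrast `"splus_sminus"` (valence), `"hit_cr"` or `"fa_cr"`
#'   (outcome-based).
#' @return Data.frame `electrode`, `band`, `auroc`, `p_value`, `n_pos`,
#'   `n_neg`.
#' @export
roc_by_electrode <- function(dpt, contrast = c("splus_sminus", "hit_cr",
                                               "fa_cr")) {
  contrast <- match.arg(contrast)
  cls <- switch(contrast,
    splus_sminus = list(pos = dpt$odorant_valence == "Splus",
                        neg = dpt$odorant_valence == "Sminus"),
    hit_cr = list(pos = dpt$outcome == "Hit", neg = dpt$outcome == "CR"),
    fa_cr = list(pos = dpt$outcome == "FA", neg = dpt$outcome == "CR"))
  combos <- unique(dpt[, c("electrode", "band")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- dpt$electrode == combos$electrode[i] & dpt$band == combos$band[i]
    pos <- dpt$delta_db[sel & cls$pos & !is.na(dpt$delta_db)]
    neg <- dpt$delta_db[sel & cls$neg & !is.na(dpt$delta_db)]
    if (length(pos) < 2 || length(neg) < 2) return(NULL)
    r <- auroc_centered(pos, neg, label_pair = contrast)
    data.frame(electrode = combos$electrode[i], band = combos$band[i],
               auroc = r$auroc, p_value = r$p_value,
               n_pos = r$n_pos, n_neg = r$n_neg, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no electrode/band had >= 2 trials per class",
                         call. = FALSE)
  rownames(res) <- NULL
  res
}
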