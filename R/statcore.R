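# Shared inferential statistics: t-tests with effect sizes, Fisher
# transform, correlation comparison, BH-FDR, balanced factorial ANOVA.
# Conventions: two-tailed p values throughout; Cohen's d with pooled SD for
# independent samples, dz = mean/SD for paired differences; partial eta^2 =
# SS_effect / (SS_effect + SS_error).

#' Welch two-sample t-test with Cohen's d
#'
#' Unequal-variance t-test (Satterthwaite degrees of freedom) comparing two
#' independent samples, reported with Cohen's d computed from the pooled
#' standard deviation.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `effect_size`
#'   (Cohen's d), `method`.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    abort("Each sample needs n >= 2 for a Welch t-test.")
  }
  if (var(a) == 0 && var(b) == 0) {
    abort("Zero variance in both samples; t-statistic undefined.")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    effect_size = (mean(a) - mean(b)) / sp,
    method = "welch_t"
  )
}

#' Paired t-test on differences with Cohen's dz
#'
#' One-sample t-test of paired differences against zero, with the paired
#' effect size dz = mean(diffs) / sd(diffs).
#'
#' @param diffs Numeric vector of within-subject differences, length >= 2.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `effect_size` (dz),
#'   `method`.
#' @export
paired_t <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) abort("Need >= 2 paired differences.")
  if (sd(diffs) == 0) {
    if (all(diffs == 0)) {
      return(tibble(
        statistic = 0, df = length(diffs) - 1, p_value = 1,
        effect_size = 0, method = "paired_t"
      ))
    }
    abort("Zero variance in nonzero differences; t-statistic undefined.")
  }
  ht <- t.test(diffs, mu = 0)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    effect_size = mean(diffs) / sd(diffs),
    method = "paired_t"
  )
}

#' Fisher r-to-z transform
#'
#' @param r Correlation(s) strictly inside (-1, 1).
#' @return atanh(r), same length as `r`.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("fisher_z() is unbounded at |r| >= 1; correlations must lie in (-1, 1).")
  }
  atanh(r)
}

#' Compare two independent correlations (Fisher z test)
#'
#' Tests the difference between two correlation coefficients estimated in
#' independent samples: z = (atanh(r1) - atanh(r2)) /
#' sqrt(1/(n1 - 3) + 1/(n2 - 3)), with a two-tailed normal p value.
#'
#' @param r1,r2 Correlations in (-1, 1).
#' @param n1,n2 Sample sizes (> 3) behind each correlation.
#' @return One-row tibble: `statistic` (z), `p_value`, `method`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) abort("Fisher z comparison needs n > 3 in each sample.")
  z <- (fisher_z(r1) - fisher_z(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(
    statistic = z,
    p_value = 2 * pnorm(-abs(z)),
    method = "fisher_z_comparison"
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control; a thin wrapper around
#' [stats::p.adjust()] kept for a stable in-package interface.
#'
#' @param pvals Numeric vector of p values in (0, 1].
#' @return Adjusted p values, same order as input.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Balanced two-way factorial ANOVA with partial eta-squared
#'
#' Fits a fully crossed two-factor ANOVA on a balanced design (all cells
#' equally replicated) and reports F, p and partial eta^2 =
#' SS_effect / (SS_effect + SS_error) for the two main effects and their
#' interaction. Unbalanced designs are rejected: with unequal cell counts the
#' sums-of-squares partition is no longer unique.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or vectors coercible to factors) of the
#'   same length as `values`.
#' @return Tibble with one row per effect (`A`, `B`, `A:B`) plus residuals:
#'   `term`, `df`, `sum_sq`, `statistic`, `p_value`, `partial_eta_sq`.
#' @export
factorial_anova <- function(values, factor_a, factor_b) {
  values <- as.numeric(values)
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  if (length(values) != length(fa) || length(values) != length(fb)) {
    abort("`values`, `factor_a` and `factor_b` must have equal length.")
  }
  counts <- table(fa, fb)
  if (any(counts == 0) || length(unique(as.vector(counts))) != 1L) {
    abort("Design is unbalanced: every factor_a x factor_b cell must have the same count.")
  }
  if (all(counts == 1)) {
    abort("Need replication within cells (>= 2 observations per cell) to estimate the interaction.")
  }
  fit <- aov(values ~ fa * fb)
  ss <- summary(fit)[[1]]
  terms_map <- c("fa" = "A", "fb" = "B", "fa:fb" = "A:B", "Residuals" = "residuals")
  term <- terms_map[trimws(rownames(ss))]
  sum_sq <- ss[["Sum Sq"]]
  df <- ss[["Df"]]
  ss_err <- sum_sq[term == "residuals"]
  df_err <- df[term == "residuals"]
  out <- tibble(
    term = unname(term), df = df, sum_sq = sum_sq,
    statistic = NA_real_, p_value = NA_real_, partial_eta_sq = NA_real_
  )
  eff <- out$term != "residuals"
  ms_err <- if (df_err > 0) ss_err / df_err else 0
  f_val <- ifelse(out$sum_sq[eff] <= .Machine$double.eps * max(1, sum(sum_sq)),
    0,
    (out$sum_sq[eff] / out$df[eff]) / ms_err
  )
  out$statistic[eff] <- f_val
  out$p_value[eff] <- ifelse(
    f_val == 0, 1,
    ifelse(is.finite(f_val), pf_upper(f_val, out$df[eff], df_err), 0)
  )
  out$partial_eta_sq[eff] <- ifelse(
    out$sum_sq[eff] + ss_err == 0, 0,
    out$sum_sq[eff] / (out$sum_sq[eff] + ss_err)
  )
  out
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)
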