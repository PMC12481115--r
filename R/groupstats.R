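#' Mann-Whitney U test for two independent samples
#'
#' Rank-sum test with midrank tie handling. The U statistic is the
#' number of (A, B) pairs with A > B (ties counted 1/2). The p-value is
#' two-sided: exact (from the null U distribution) when both samples
#' have at most 10 observations and there are no ties, otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param sample_A,sample_B Numeric vectors.
#' @return List with `U` (for sample A), `p_value`, `method`
#'   (`"exact"` or `"normal"`), `n_A`, `n_B`.
#' @export
mann_whitney <- function(sample_A, sample_B) {
  a <- as.numeric(sample_A); b <- as.numeric(sample_B)
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  nA <- length(a); nB <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && nA <= 10 && nB <= 10) {
    # exact two-sided p from the null distribution of U
    lower <- pwilcox(U, nA, nB)
    upper <- pwilcox(U - 1, nA, nB, lower.tail = FALSE)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- nA * nB / 2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab) / ((nA + nB) * (nA + nB - 1))
    sigma2 <- nA * nB / 12 * ((nA + nB + 1) - tie_term)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(U = U, p_value = p, method = method, n_A = nA, n_B = nB)
}

#' Cohen's d effect size for two samples
#'
#' Magnitude of the standardized mean difference,
#' `|mean_A - mean_B| / s_pooled`, with the pooled standard deviation
#' using n-1 denominators. The direction of the difference is reported
#' separately.
#'
#' @param sample_A,sample_B Numeric vectors with at least 2 values
#'   each.
#' @return List with `d` (magnitude), `direction` (`"A>B"`, `"B>A"` or
#'   `"equal"`).
#' @export
cohens_d <- function(sample_A, sample_B) {
  a <- as.numeric(sample_A); b <- as.numeric(sample_B)
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 values")
  }
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("effect size undefined: zero pooled standard deviation")
  diff <- mean(a) - mean(b)
  list(d = abs(diff) / sqrt(sp2),
       direction = if (diff > 0) "A>B" else if (diff < 0) "B>A" else "equal")
}

#' Between-group comparison summary for one outcome variable
#'
#' Assembles the group-comparison row used for outcome tables: medians
#' and ranges per group, Mann-Whitney U and two-sided p, and Cohen's d.
#' No rounding is applied; formatting belongs to the presentation
#' layer.
#'
#' @param variable Name of the outcome.
#' @param values Numeric vector of per-subject values.
#' @param groups Factor/character vector of group membership, exactly
#'   two levels; the first level (alphabetically, or by factor order)
#'   is reported as group A.
#' @return One-row data.frame: `variable`, `median_A`, `min_A`,
#'   `max_A`, `median_B`, `min_B`, `max_B`, `u_statistic`, `p_value`,
#'   `effect_size_d`.
#' @export
summarize_comparison <- function(variable, values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) {
    stop("exactly two groups required, got ", nlevels(groups))
  }
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  mw <- mann_whitney(a, b)
  es <- cohens_d(a, b)
  data.frame(variable = variable,
             median_A = median(a), min_A = min(a), max_A = max(a),
             median_B = median(b), min_B = min(b), max_B = max(b),
             u_statistic = mw$U, p_value = mw$p_value,
             effect_size_d = es$d)
}
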