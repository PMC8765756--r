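#' Bootstrap percentile confidence interval for a median
#'
#' Resamples the values with replacement `n_boot` times and returns the
#' percentile interval of the median, the interval style used for every
#' across-unit and across-pair summary in this package.
#'
#' @param values Numeric vector, length at least 2 (`NA`s dropped).
#' @param n_boot Number of resamples (default 1000).
#' @param alpha Two-sided error level (default 0.05 for a 95% interval).
#' @param seed Optional integer seed.
#' @return One-row tibble: `estimate` (sample median), `lower`, `upper`,
#'   `n`, `n_boot`, `alpha`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 1000, alpha = 0.05, seed = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) rlang::abort("need at least 2 values")
  run <- function() {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    meds <- apply(idx, 2, function(i) stats::median(values[i]))
    qs <- stats::quantile(meds, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    tibble::tibble(estimate = stats::median(values),
                   lower = qs[1], upper = qs[2],
                   n = n, n_boot = n_boot, alpha = alpha)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

test_result <- function(method, statistic, p_value, n, two_sided = TRUE) {
  tibble::tibble(method = method, statistic = unname(statistic),
                 p_value = p_value, n = list(n), two_sided = two_sided)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided test of H0: the median difference is zero. Exact when there are
#' at most 25 nonzero differences and no ties in their absolute values;
#' normal approximation otherwise. Zero differences are dropped (at least 5
#' nonzero required); all-zero input is an error.
#'
#' @param differences Numeric vector of paired differences.
#' @return One-row tibble: `method`, `statistic` (V), `p_value`, `n`
#'   (nonzero differences used), `two_sided`.
#' @export
signrank_test <- function(differences) {
  d <- differences[!is.na(differences) & differences != 0]
  if (length(d) == 0) rlang::abort("all differences are zero")
  if (length(d) < 5) rlang::abort("need at least 5 nonzero differences")
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  test_result("wilcoxon signed-rank", ht$statistic, ht$p.value, length(d))
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided; exact for small samples without ties, normal approximation
#' with tie correction otherwise (the `stats::wilcox.test` rules).
#'
#' @param a,b Numeric vectors, each with at least 3 values.
#' @return One-row tibble, `n` holding both group sizes.
#' @export
ranksum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) rlang::abort("each group needs >= 3 values")
  ht <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  test_result("wilcoxon rank-sum", ht$statistic, ht$p.value,
              c(length(a), length(b)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided test of H0: both sets of values come from the same
#' distribution; used to compare the LC-linked and region-swapped
#' difference distributions.
#'
#' @param a,b Numeric vectors, each with at least 3 values.
#' @return One-row tibble with the D statistic.
#' @export
ks_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) rlang::abort("each group needs >= 3 values")
  ht <- suppressWarnings(stats::ks.test(a, b))
  test_result("two-sample KS", ht$statistic, ht$p.value, c(length(a), length(b)))
}

#' One-way ANOVA across groups
#'
#' Fixed-effects F test for a group effect (e.g., an effect of partner
#' firing-rate group, or of counting-window size).
#'
#' @param groups Named or unnamed list of numeric vectors, at least 2 groups
#'   with at least 2 values each.
#' @return One-row tibble with the F statistic.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(x) x[!is.na(x)])
  if (any(lengths(groups) < 2)) rlang::abort("each group needs >= 2 values")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(seq_along(groups), lengths(groups)))
  )
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  test_result("one-way ANOVA", tab[["F value"]][1], tab[["Pr(>F)"]][1],
              lengths(groups))
}

#' Two-factor fixed-effects ANOVA with interaction
#'
#' Used for the evoked-pupil analysis: tests effects of trial group, a
#' second factor (e.g., pupil measure), and their interaction.
#'
#' @param values Numeric response vector.
#' @param f1,f2 Factors (or coercible) of the same length as `values`.
#' @return Tibble with one row per term: `term`, `statistic` (F), `p_value`.
#' @export
anova_twoway <- function(values, f1, f2) {
  df <- data.frame(value = values, f1 = factor(f1), f2 = factor(f2))
  df <- df[stats::complete.cases(df), ]
  fit <- stats::aov(value ~ f1 * f2, data = df)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  tibble::tibble(term = terms[keep],
                 statistic = tab[["F value"]][keep],
                 p_value = tab[["Pr(>F)"]][keep],
                 method = "two-way ANOVA")
}
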