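new_test_result <- function(test_name, statistic, p_value, n,
                            chosen_branch = NA_character_, post_hoc = NULL) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n = n,
                 chosen_branch = chosen_branch, post_hoc = post_hoc),
            class = "mito_test")
}

#' @export
print.mito_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n", x$test_name,
              x$statistic, x$p_value, paste(x$n, collapse = ", "),
              if (!is.na(x$chosen_branch)) paste0("; ", x$chosen_branch) else ""))
  if (!is.null(x$post_hoc)) {
    cat("post-hoc pairwise comparisons:\n")
    print(as.data.frame(x$post_hoc))
  }
  invisible(x)
}

#' D'Agostino's K-squared normality test
#'
#' Omnibus test combining the transformed sample skewness (D'Agostino 1970)
#' and kurtosis (Anscombe-Glynn 1983) z-scores: `K2 = Z1^2 + Z2^2`,
#' compared against a chi-square distribution with 2 degrees of freedom.
#' Requires n >= 8 for the kurtosis transform to be defined.
#'
#' @param sample Numeric vector, n >= 8.
#' @return A `mito_test` result with the K-squared statistic and p-value.
#' @export
normality_test <- function(sample) {
  n <- length(sample)
  if (n < 8) abort("D'Agostino's K-squared requires n >= 8")
  x <- sample - mean(sample)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)
  if (m2 == 0) abort("sample is constant; normality test undefined")
  # skewness z-score (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis z-score (Anscombe-Glynn 1983)
  g2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  new_test_result("D'Agostino K-squared", k2, pchisq(k2, df = 2,
                  lower.tail = FALSE), n)
}

#' Compare two independent samples
#'
#' Both samples are first tested for normality with [normality_test()] (at
#' `alpha`); if both pass, an independent two-sample t-test is used,
#' otherwise the Mann-Whitney U test. Samples too small for the normality
#' test (n < 8) fall back to the nonparametric branch. The branch actually
#' taken is recorded in the result.
#'
#' @param sample_a,sample_b Numeric vectors, each n >= 3.
#' @param alpha Normality gate level (default 0.05).
#' @return A `mito_test` result (`statistic` is t or U for `sample_a`).
#' @export
compare_two <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    abort("compare_two requires n >= 3 per sample")
  }
  normal <- length(sample_a) >= 8 && length(sample_b) >= 8 &&
    var(sample_a) > 0 && var(sample_b) > 0 &&
    normality_test(sample_a)$p_value > alpha &&
    normality_test(sample_b)$p_value > alpha
  n <- c(length(sample_a), length(sample_b))
  if (normal) {
    tt <- t.test(sample_a, sample_b)
    new_test_result("independent two-sample t-test", tt$statistic,
                    tt$p.value, n, chosen_branch = "parametric")
  } else {
    wt <- suppressWarnings(wilcox.test(sample_a, sample_b, exact = FALSE,
                                       correct = TRUE))
    new_test_result("Mann-Whitney U", wt$statistic, wt$p.value, n,
                    chosen_branch = "nonparametric")
  }
}

# Dunn's pairwise z-tests on global ranks with tie correction
dunn_posthoc <- function(values, groups, p_adjust_method = "bonferroni") {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- unique(groups)
  mean_r <- tapply(r, groups, mean)[lv]
  n_g <- tapply(r, groups, length)[lv]
  combs <- utils::combn(seq_along(lv), 2)
  rows <- purrr::map(seq_len(ncol(combs)), function(k) {
    i <- combs[1, k]; j <- combs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[i] + 1 / n_g[j]))
    z <- (mean_r[i] - mean_r[j]) / se
    tibble::tibble(group_a = as.character(lv[i]), group_b = as.character(lv[j]),
                   z = unname(z), p = unname(2 * pnorm(-abs(z))))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(p.adjust(out$p, method = p_adjust_method), 1)
  out
}

#' Compare three or more groups (Kruskal-Wallis + Dunn's post hoc)
#'
#' Kruskal-Wallis H (tie-corrected, chi-square p-value with k - 1 degrees
#' of freedom); if significant at `alpha`, Dunn's pairwise z-statistics on
#' the global ranks with multiplicity adjustment are attached as the
#' post-hoc table.
#'
#' @param samples List of >= 3 numeric vectors, each n >= 3 (names are used
#'   as group labels).
#' @param alpha Significance gate for running the post hoc (default 0.05).
#' @param p_adjust_method Multiplicity adjustment for Dunn's test
#'   (default `"bonferroni"`; any [stats::p.adjust] method).
#' @return A `mito_test` result with the H statistic; `post_hoc` is a
#'   tibble (`group_a`, `group_b`, `z`, `p`, `p_adjusted`) or `NULL`.
#' @export
compare_multi <- function(samples, alpha = 0.05,
                          p_adjust_method = "bonferroni") {
  if (length(samples) < 3) abort("compare_multi requires >= 3 groups")
  if (any(lengths(samples) < 3)) abort("each group needs n >= 3")
  if (is.null(names(samples))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  values <- unlist(samples, use.names = FALSE)
  groups <- rep(names(samples), lengths(samples))
  kw <- kruskal.test(values, factor(groups))
  post <- NULL
  if (is.finite(kw$p.value) && kw$p.value < alpha) {
    post <- dunn_posthoc(values, groups, p_adjust_method)
  }
  new_test_result("Kruskal-Wallis", kw$statistic, kw$p.value,
                  lengths(samples), chosen_branch = "nonparametric",
                  post_hoc = post)
}

#' Correlation matrix over feature columns
#'
#' Pairwise-complete Pearson or Spearman correlations between feature
#' columns of a per-image summary table. Constant features give missing
#' entries, never 0 or 1.
#'
#' @param feature_table Data frame with >= 3 rows; non-numeric columns are
#'   dropped.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix.
#' @export
correlate_features <- function(feature_table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  num <- feature_table[purrr::map_lgl(feature_table, is.numeric)]
  if (nrow(num) < 3) abort("need >= 3 observations")
  if (ncol(num) < 2) abort("need >= 2 numeric features")
  suppressWarnings(cor(as.matrix(num), use = "pairwise.complete.obs",
                       method = method))
}

#' @export
tidy.mito_test <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p_value = x$p_value, branch = x$chosen_branch,
                 n = paste(x$n, collapse = "/"))
}

#' @export
glance.mito_test <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p_value = x$p_value,
                 n_groups = length(x$n),
                 post_hoc_pairs = if (is.null(x$post_hoc)) 0L else nrow(x$post_hoc))
}
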