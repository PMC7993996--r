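# Statistical tests used to compare read-frequency distributions: the
# two-sample Kolmogorov-Smirnov statistic with sample-size correction,
# one-sided Welch t-tests and one-way ANOVA with Tukey HSD.

#' Two-sample Kolmogorov-Smirnov statistic with sample-size correction
#'
#' `D` is the supremum distance between the two empirical CDFs;
#' the size-corrected statistic is `Z = D * sqrt(n * m / (n + m))`.
#'
#' @param a,b Numeric samples.
#' @return A list of class `KsResult` with `D`, `Z`, `n`, `m`.
#' @export
ks_z <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  fail_unless(length(a) >= 1 && length(b) >= 1, "empty sample")
  n <- length(a); m <- length(b)
  pooled <- sort(unique(c(a, b)))
  ecdf_a <- stats::ecdf(a)(pooled)
  ecdf_b <- stats::ecdf(b)(pooled)
  # the sup over R of |F_a - F_b| is attained at a pooled data point,
  # approaching it from the right (step functions are right-continuous)
  # or the left; evaluate both one-sided limits
  left_a <- c(0, ecdf_a[-length(pooled)])
  left_b <- c(0, ecdf_b[-length(pooled)])
  D <- max(abs(ecdf_a - ecdf_b), abs(left_a - left_b))
  structure(list(D = D, Z = D * sqrt(n * m / (n + m)), n = n, m = m),
            class = "KsResult")
}

#' @export
print.KsResult <- function(x, ...) {
  cat(sprintf("Two-sample KS: D = %.4f, Z = %.4f (n = %d, m = %d)\n",
              x$D, x$Z, x$n, x$m))
  invisible(x)
}

#' One-sided Welch t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom and a one-sided
#' p-value in the stated direction. When both groups have zero variance
#' and equal means the test is undefined; by convention p = 0.5 and the
#' statistic is 0.
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param alternative `"greater"` (mean of `a` greater) or `"less"`.
#' @return A list with `statistic`, `df`, `p`, `conf_int` (95%,
#'   one-sided), `alternative`.
#' @export
welch_t_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  fail_unless(length(a) >= 2 && length(b) >= 2, "need n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, df = NA_real_, p = 0.5,
                  conf_int = c(NA_real_, NA_real_),
                  alternative = alternative))
    }
    # complete separation with no variance: direction decides
    hit <- (mean(a) > mean(b)) == (alternative == "greater")
    return(list(statistic = if (hit) Inf else -Inf, df = NA_real_,
                p = if (hit) 0 else 1,
                conf_int = c(NA_real_, NA_real_),
                alternative = alternative))
  }
  tt <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE,
                      conf.level = 0.95)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, conf_int = unname(tt$conf.int),
       alternative = alternative)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Standard one-way ANOVA F test followed by Tukey's multiple comparisons
#' of means with 95% family-wise confidence level.
#'
#' @param groups Named list of numeric samples (each n >= 2).
#' @return A list with `F`, `p` (omnibus), `tukey` (data frame with
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
anova_tukey <- function(groups) {
  fail_unless(length(groups) >= 2, "need at least two groups")
  fail_unless(all(vapply(groups, length, integer(1)) >= 2),
              "every group needs n >= 2")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  fit <- stats::aov(y ~ g, data = df)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$g
  list(F = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"], lwr = tk[, "lwr"],
                          upr = tk[, "upr"], p_adj = tk[, "p adj"],
                          row.names = NULL))
}
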