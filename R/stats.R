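#' Two-by-two within-subject repeated-measures ANOVA
#'
#' Classical sum-of-squares decomposition for two fully-crossed 2-level
#' within-subject factors: each effect (A, B, A:B) is tested against its own
#' subject-by-effect interaction error term, with effect size reported as
#' partial eta squared, `SS_effect / (SS_effect + SS_error)`. Subjects with
#' any undefined cell are dropped listwise and counted. Both factors have two
#' levels, so sphericity holds trivially and no correction is applied.
#'
#' @param data A data frame in long format: one value per subject x A x B
#'   cell.
#' @param value,subject,a,b Column names (tidy-eval) of the response, the
#'   subject identifier, and the two within-subject factors.
#'
#' @return An object of class `rm_anova_2x2` with a `table` tibble (one row
#'   per effect: `effect`, `ss_effect`, `ss_error`, `df_effect`, `df_error`,
#'   `statistic`, `p.value`, `partial_eta_sq`), `n_used` and `n_dropped`.
#'   Use [generics::tidy()] / [generics::glance()] to extract results.
#' @export
#' @examples
#' d <- tidyr::expand_grid(s = 1:8, a = c("x", "y"), b = c("u", "v"))
#' d$v <- rnorm(nrow(d)) + (d$a == "x" & d$b == "u")
#' tidy(rm_anova_2x2(d, v, s, a, b))
rm_anova_2x2 <- function(data, value, subject, a, b) {
  df <- dplyr::transmute(
    tibble::as_tibble(data),
    value = {{ value }},
    subject = factor({{ subject }}),
    a = factor({{ a }}),
    b = factor({{ b }})
  )
  if (nlevels(df$a) != 2L || nlevels(df$b) != 2L)
    stop("both within-subject factors must have exactly 2 levels",
         call. = FALSE)
  wide <- tidyr::pivot_wider(df, names_from = c("a", "b"),
                             values_from = "value")
  complete <- stats::complete.cases(wide)
  n_dropped <- sum(!complete)
  keep <- wide$subject[complete]
  df <- dplyr::filter(df, .data$subject %in% keep, !is.na(.data$value))
  df$subject <- droplevels(df$subject)
  n <- nlevels(df$subject)
  if (n < 2L)
    stop("insufficient data: fewer than 2 subjects with complete cells",
         call. = FALSE)

  fit <- stats::aov(value ~ a * b + Error(subject / (a * b)), data = df)
  sm <- summary(fit)
  pull_stratum <- function(name, effect) {
    tab <- sm[[paste0("Error: ", name)]][[1]]
    rn <- trimws(rownames(tab))
    list(ss_effect = tab[rn == effect, "Sum Sq"],
         ss_error = tab[rn == "Residuals", "Sum Sq"],
         df_effect = tab[rn == effect, "Df"],
         df_error = tab[rn == "Residuals", "Df"])
  }
  effects <- list(A = pull_stratum("subject:a", "a"),
                  B = pull_stratum("subject:b", "b"),
                  `A:B` = pull_stratum("subject:a:b", "a:b"))
  table <- purrr::imap(effects, function(e, nm) {
    ms_e <- e$ss_effect / e$df_effect
    ms_r <- e$ss_error / e$df_error
    f <- if (ms_r > 0) ms_e / ms_r else if (ms_e == 0) 0 else Inf
    tibble::tibble(
      effect = nm,
      ss_effect = e$ss_effect, ss_error = e$ss_error,
      df_effect = e$df_effect, df_error = e$df_error,
      statistic = f,
      p.value = stats::pf(f, e$df_effect, e$df_error, lower.tail = FALSE),
      partial_eta_sq = if (e$ss_effect + e$ss_error > 0)
        e$ss_effect / (e$ss_effect + e$ss_error) else 0
    )
  })
  structure(
    list(table = dplyr::bind_rows(table),
         n_used = n, n_dropped = n_dropped,
         factors = c(a = levels(df$a), b = levels(df$b))),
    class = "rm_anova_2x2")
}

#' @export
print.rm_anova_2x2 <- function(x, ...) {
  cat("2x2 within-subject RM-ANOVA (n =", x$n_used,
      "subjects,", x$n_dropped, "dropped)\n")
  print(x$table)
  invisible(x)
}

#' @rdname rm_anova_2x2
#' @param x An `rm_anova_2x2` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rm_anova_2x2 <- function(x, ...) x$table

#' @rdname rm_anova_2x2
#' @exportS3Method generics::glance
glance.rm_anova_2x2 <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_used, n_dropped = x$n_dropped)
}

#' Paired (one-sample) t-test on per-subject differences
#'
#' Two-sided one-sample t-test of the mean of per-subject differences against
#' zero, with the paired effect size Cohen's dz = mean(diffs) / sd(diffs)
#' (sample SD, denominator n - 1), which equals t / sqrt(n).
#'
#' @param diffs Numeric vector of per-subject differences (NAs dropped).
#'
#' @return An object of class `paired_t` with fields `statistic`, `df`,
#'   `p.value`, `cohens_dz`, `estimate` (mean difference), `n`. Use
#'   [generics::tidy()] to get a one-row tibble.
#' @export
#' @examples
#' tidy(paired_t(c(1, 2, 3)))
paired_t <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) < 2L)
    stop("insufficient data: need at least 2 paired differences",
         call. = FALSE)
  if (stats::sd(diffs) == 0)
    stop("degenerate variance: all differences identical", call. = FALSE)
  tt <- stats::t.test(diffs)
  structure(
    list(statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p.value = tt$p.value,
         cohens_dz = mean(diffs) / stats::sd(diffs),
         estimate = mean(diffs),
         n = length(diffs)),
    class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g, dz = %.3f (n = %d)\n",
              x$df, x$statistic, x$p.value, x$cohens_dz, x$n))
  invisible(x)
}

#' @rdname paired_t
#' @param x A `paired_t` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.paired_t <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, statistic = x$statistic,
                 df = x$df, p.value = x$p.value, cohens_dz = x$cohens_dz,
                 n = x$n)
}

#' @rdname paired_t
#' @exportS3Method generics::glance
glance.paired_t <- function(x, ...) tidy(x)

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a family of p-values; output order matches input
#' order and adjusted values are monotone in the input ranking and capped at
#' 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#'
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

# Exact power of a two-sided (or one-sided) paired t-test at effect size dz,
# from the noncentral t distribution.
paired_t_power <- function(n, dz, alpha = 0.05,
                           tails = c("two", "one")) {
  tails <- match.arg(tails)
  df <- n - 1
  ncp <- dz * sqrt(n)
  if (tails == "two") {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  }
}

#' Minimum sample size for a paired t-test
#'
#' Smallest n >= 2 at which a paired t-test with effect size dz reaches the
#' target power, computed exactly from the noncentral t distribution
#' (noncentrality dz * sqrt(n), df = n - 1).
#'
#' @param dz Paired effect size Cohen's dz (> 0).
#' @param power Target power in (0, 1).
#' @param alpha Significance level in (0, 1).
#' @param tails `"two"` (default) or `"one"`.
#'
#' @return The minimal integer n.
#' @export
#' @examples
#' required_n_paired_t(dz = 1.69, power = 0.95) # 7
required_n_paired_t <- function(dz, power = 0.95, alpha = 0.05,
                                tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(dz > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  n <- 2L
  while (paired_t_power(n, dz, alpha, tails) < power) {
    n <- n + 1L
    if (n > 1e7) stop("sample size search did not converge", call. = FALSE)
  }
  n
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param data A data frame of paired observations.
#' @param x,y Column names (tidy-eval) of the two variables.
#'
#' @return A one-row tibble with `r`, `statistic` (t), `df`, `p.value`, `n`.
#' @export
#' @examples
#' pearson_corr(data.frame(u = 1:5, v = c(2, 1, 4, 3, 5)), u, v)
pearson_corr <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L)
    stop("insufficient data: need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("degenerate variance: a variable is constant", call. = FALSE)
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(r = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p.value = ct$p.value,
                 n = length(xv))
}
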