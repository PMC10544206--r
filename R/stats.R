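#' One-way ANOVA with Tukey post hoc comparisons
#'
#' The group-comparison workhorse for per-animal measurement tables: a
#' one-way ANOVA F test with (k - 1, N - k) degrees of freedom, followed by
#' Tukey honest-significant-difference adjusted p-values for all group
#' pairs (studentized-range distribution). Missing values are dropped
#' listwise with a logged count.
#'
#' @param table data.frame with columns `group` and `value` (as produced by
#'   [simulate_group_table()]); at least 2 groups with n >= 2 each.
#' @param tukey compute the pairwise Tukey table (default TRUE; skip for
#'   speed in simulation loops).
#' @param alpha significance level recorded in the report (default 0.05).
#' @return list of class `test_report`: `test`, `statistic` (F), `df`,
#'   `p_value`, `pairwise` data.frame (`group_i`, `group_j`, `diff`,
#'   `adjusted_p`, `significant`), `alpha`, `n_dropped`.
#' @export
one_way_anova_tukey <- function(table, tukey = TRUE, alpha = 0.05) {
  tab <- check_group_table(table)
  k <- nlevels(tab$group)
  if (k < 2) stop("at least 2 groups are required")
  n_per <- table(tab$group)
  if (any(n_per < 2)) {
    stop("every group needs n >= 2 (got ",
         paste(sprintf("%s: %d", names(n_per), n_per), collapse = ", "), ")")
  }
  fit <- aov(value ~ group, data = tab)
  s <- summary(fit)[[1]]
  fstat <- s[["F value"]][1]
  df <- c(s[["Df"]][1], s[["Df"]][2])
  p <- s[["Pr(>F)"]][1]
  # degenerate case: identical group means give SSB = 0, hence F = 0 and
  # p = 1 (aov returns 0/0 when the residuals are also all zero)
  gmeans <- tapply(tab$value, tab$group, mean)
  flat_means <- max(gmeans) - min(gmeans) < 1e-12
  zero_var <- stats::var(tab$value) < 1e-24
  if (flat_means) {
    fstat <- 0; p <- 1
  }
  pairwise <- NULL
  if (tukey && flat_means && zero_var) {
    nm <- utils::combn(levels(tab$group), 2)
    pairwise <- data.frame(group_i = nm[2, ], group_j = nm[1, ], diff = 0,
                           adjusted_p = 1, significant = FALSE)
    tukey <- FALSE
  }
  if (tukey) {
    tk <- TukeyHSD(fit)$group
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    pairwise <- data.frame(
      group_i = vapply(nm, `[`, "", 1),
      group_j = vapply(nm, `[`, "", 2),
      diff = tk[, "diff"],
      adjusted_p = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha,
      row.names = NULL
    )
  }
  structure(list(test = "one_way_anova_tukey", statistic = fstat, df = df,
                 p_value = p, pairwise = pairwise, alpha = alpha,
                 significant = p < alpha,
                 n_dropped = attr(tab, "n_dropped")),
            class = "test_report")
}

#' Two-sample Student's t test
#'
#' Pooled-variance (Student's) two-sided t test on a two-group table:
#' t with df = n1 + n2 - 2. Exactly two groups must be supplied.
#'
#' @inheritParams one_way_anova_tukey
#' @return A `test_report` with `statistic` (t), `df`, `p_value`.
#' @export
two_sample_t <- function(table, alpha = 0.05) {
  tab <- check_group_table(table)
  if (nlevels(tab$group) != 2) {
    stop("exactly 2 groups are required (got ", nlevels(tab$group), ")")
  }
  n_per <- table(tab$group)
  if (any(n_per < 2)) stop("every group needs n >= 2")
  gmeans <- tapply(tab$value, tab$group, mean)
  if (stats::var(tab$value) < 1e-24 && max(gmeans) - min(gmeans) < 1e-12) {
    # identical constant groups: zero effect, zero variance -> t = 0, p = 1
    tstat <- 0; df <- sum(n_per) - 2; p <- 1
  } else {
    tt <- t.test(value ~ group, data = tab, var.equal = TRUE)
    tstat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(test = "two_sample_t",
                 statistic = tstat, df = df,
                 p_value = p, pairwise = NULL, alpha = alpha,
                 significant = p < alpha,
                 n_dropped = attr(tab, "n_dropped")),
            class = "test_report")
}

#' Pearson's chi-squared test on two proportions
#'
#' Compares positive/total counts between two groups (e.g., the proportion
#' of marker-positive nuclei) with a 2 x 2 Pearson chi-squared test,
#' df = 1, without continuity correction by default (the correction is
#' available behind a flag).
#'
#' @param positives_a,total_a,positives_b,total_b counts; totals > 0 and
#'   positives <= totals.
#' @param correct apply Yates continuity correction (default FALSE).
#' @param alpha significance level recorded in the report.
#' @return A `test_report` with `statistic` (X-squared), `df`, `p_value`.
#' @export
chi2_proportions <- function(positives_a, total_a, positives_b, total_b,
                             correct = FALSE, alpha = 0.05) {
  counts <- c(positives_a, total_a, positives_b, total_b)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (total_a <= 0 || total_b <= 0) stop("totals must be > 0")
  if (positives_a > total_a || positives_b > total_b) {
    stop("positives cannot exceed totals")
  }
  m <- matrix(c(positives_a, total_a - positives_a,
                positives_b, total_b - positives_b), nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  structure(list(test = "chi2_proportions",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value, pairwise = NULL, alpha = alpha,
                 significant = ct$p.value < alpha, n_dropped = 0L),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> %s: statistic %.4g, df %s, p = %.4g%s\n",
              x$test, x$statistic, paste(x$df, collapse = ", "), x$p_value,
              if (isTRUE(x$significant)) " *" else ""))
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("  %s vs %s: adj p = %.4g%s\n", x$pairwise$group_i[i],
                  x$pairwise$group_j[i], x$pairwise$adjusted_p[i],
                  if (x$pairwise$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}

# validate + listwise-drop missing values, recording the count
check_group_table <- function(table) {
  if (!is.data.frame(table) || !all(c("group", "value") %in% names(table))) {
    stop("`table` must be a data.frame with columns `group` and `value`")
  }
  tab <- table
  tab$group <- factor(tab$group)
  ok <- !is.na(tab$value) & !is.na(tab$group)
  out <- droplevels(tab[ok, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!ok)
  out
}
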