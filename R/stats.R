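# One tidy row per test result; group tests fill group1/group2.
assoc_row <- function(test, variables, statistic_name, statistic, p_value, n,
                      method, group1 = NA_character_, group2 = NA_character_,
                      adjusted_p = NA_real_) {
  data.frame(test = test, variables = variables, group1 = group1,
             group2 = group2, statistic_name = statistic_name,
             statistic = statistic, p_value = p_value, n = n,
             adjusted_p = adjusted_p, alternative = "two.sided",
             method = method, stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Used as a logged gate before the nonparametric battery: when normality is
#' rejected for the metric, time, or covariate distributions, rank-based
#' tests are used. The gate logs its conclusion (via a message) rather than
#' branching silently.
#'
#' @param values numeric vector, 3 <= n <= 5000, finite, not all identical.
#' @param variable label used in the output row.
#' @param alpha significance level used for the logged conclusion only.
#' @return one-row data.frame with W statistic and p-value.
#' @export
shapiro_wilk <- function(values, variable = "values", alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    segsim_stop("Shapiro-Wilk requires 3 <= n <= 5000 finite values",
                "segsim_precondition_error")
  if (diff(range(values)) == 0)
    segsim_stop("Shapiro-Wilk is undefined for a constant vector",
                "segsim_degenerate_error")
  ht <- shapiro.test(values)
  message(sprintf(
    "shapiro_wilk[%s]: W = %.4f, p = %.3g -> %s normality at alpha = %g%s",
    variable, ht$statistic, ht$p.value,
    if (ht$p.value < alpha) "reject" else "do not reject", alpha,
    if (ht$p.value < alpha) "; nonparametric tests indicated" else ""))
  assoc_row("shapiro_wilk", variable, "W", unname(ht$statistic), ht$p.value,
            n, "shapiro.test")
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of the average-ranked data (ties get mean
#' ranks). The two-sided p-value is an exact permutation enumeration over
#' all n! orderings for n <= 10, and the t approximation
#' t = rho * sqrt((n-2) / (1-rho^2)) on n-2 df otherwise; the switch point
#' is fixed so p-values are reproducible.
#'
#' @param x,y numeric vectors of equal length n >= 3, finite.
#' @param variables label for the output row.
#' @return one-row data.frame with `statistic` = rho.
#' @export
spearman <- function(x, y, variables = "x~y") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n)
    segsim_stop("spearman requires equal-length finite vectors, n >= 3",
                "segsim_precondition_error")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    segsim_stop("correlation undefined for a constant input",
                "segsim_degenerate_error")
  rx <- rank(x); ry <- rank(y)
  if (n <= 10L) {
    res <- spearman_exact_perm_cpp(rx, ry)
    assoc_row("spearman", variables, "rho", res$rho, res$p_value, n,
              "exact permutation")
  } else {
    rho <- cor(rx, ry)
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    assoc_row("spearman", variables, "rho", rho, min(1, p), n,
              "t approximation")
  }
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for a difference between two independent groups.
#' The exact null distribution is used when n1*n2 <= 400 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' corrections. The reported U is the smaller of the two directed U
#' statistics.
#'
#' @param g1,g2 numeric vectors, both nonempty, combined n >= 4.
#' @param variables label for the output row.
#' @param group1,group2 group labels for the output row.
#' @return one-row data.frame with `statistic` = min(U1, U2).
#' @export
mann_whitney_u <- function(g1, g2, variables = "value~group",
                           group1 = "g1", group2 = "g2") {
  g1 <- g1[is.finite(g1)]; g2 <- g2[is.finite(g2)]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 == 0L || n2 == 0L)
    segsim_stop("both groups must be nonempty", "segsim_precondition_error")
  if (n1 + n2 < 4L)
    segsim_stop("Mann-Whitney U requires combined n >= 4",
                "segsim_precondition_error")
  ties <- anyDuplicated(c(g1, g2)) > 0L
  exact <- (n1 * n2 <= 400L) && !ties
  ht <- suppressWarnings(wilcox.test(g1, g2, exact = exact, correct = TRUE))
  r <- rank(c(g1, g2))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u <- min(u1, n1 * n2 - u1)
  assoc_row("mann_whitney_u", variables, "U", u, ht$p.value, n1 + n2,
            if (exact) "exact" else "normal approximation (tie + continuity corrected)",
            group1 = group1, group2 = group2)
}

#' Kruskal-Wallis test with Mann-Whitney post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value for three or
#' more groups. If (and only if) the omnibus p-value is below `alpha`, all
#' pairwise Mann-Whitney U tests are run with Bonferroni-adjusted p-values
#' (adjusted_p = min(1, p * m), m = number of pairwise comparisons); the
#' Bonferroni family is the set of pairwise comparisons of this one
#' variable. For two groups use [mann_whitney_u] instead.
#'
#' @param groups named list of >= 3 numeric vectors, each n >= 2.
#' @param alpha omnibus significance threshold gating the post-hoc tests.
#' @param variables label for the output rows.
#' @return data.frame: the omnibus row, plus one row per pairwise comparison
#'   when the omnibus is significant.
#' @export
kruskal_wallis_with_posthoc <- function(groups, alpha = 0.05,
                                        variables = "value~group") {
  if (!is.list(groups) || length(groups) < 3L)
    segsim_stop("need >= 3 groups; for 2 groups use mann_whitney_u",
                "segsim_routing_error")
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (any(vapply(groups, length, 1L) < 2L))
    segsim_stop("each group needs n >= 2", "segsim_precondition_error")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  ht <- kruskal.test(groups)
  out <- assoc_row("kruskal_wallis", variables, "H", unname(ht$statistic),
                   ht$p.value, sum(lengths(groups)), "chi-square approximation")
  if (ht$p.value < alpha) {
    pairs <- utils::combn(length(groups), 2)
    m <- ncol(pairs)
    ph <- lapply(seq_len(m), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      row <- mann_whitney_u(groups[[i]], groups[[j]], variables,
                            group1 = names(groups)[i], group2 = names(groups)[j])
      row$adjusted_p <- min(1, row$p_value * m)
      row
    })
    out <- rbind(out, do.call(rbind, ph))
  }
  rownames(out) <- NULL
  out
}

#' Correlate a metric panel with correction times
#'
#' Joins a per-case metric panel to a case table on `case_id` and computes
#' one Spearman correlation per metric column against `correction_time`,
#' ranked by |rho| descending. Sign conventions are preserved: similarity
#' metrics correlate negatively with time when time grows with error, error
#' metrics positively. Constant metric columns are undefined and are
#' excluded from the ranking (recorded in the `excluded` attribute). Missing
#' values are dropped pairwise per metric and the per-test n recorded.
#'
#' @param panel data.frame with `case_id` and numeric metric columns.
#' @param cases data.frame with `case_id` and `correction_time` (minutes).
#' @return data.frame with columns metric, rho, p_value, n, in decreasing
#'   |rho| order; attribute `excluded` lists constant/undefined metrics.
#' @export
metric_time_correlation_table <- function(panel, cases) {
  if (!"case_id" %in% names(panel) || !all(c("case_id", "correction_time") %in% names(cases)))
    segsim_stop("panel needs case_id; cases need case_id and correction_time",
                "segsim_schema_error")
  df <- merge(panel, cases[, c("case_id", "correction_time")], by = "case_id")
  if (nrow(df) < 3L)
    segsim_stop("fewer than 3 joinable cases with metrics and times",
                "segsim_insufficient_data_error")
  metric_cols <- setdiff(names(panel)[vapply(panel, is.numeric, TRUE)], "case_id")
  rows <- list(); excluded <- character()
  for (mcol in metric_cols) {
    ok <- is.finite(df[[mcol]]) & is.finite(df$correction_time)
    x <- df[[mcol]][ok]
    if (sum(ok) < 3L || diff(range(x)) == 0) {
      excluded <- c(excluded, mcol)
      next
    }
    r <- spearman(x, df$correction_time[ok],
                  variables = paste0(mcol, "~correction_time"))
    rows[[mcol]] <- data.frame(metric = mcol, rho = r$statistic,
                               p_value = r$p_value, n = r$n,
                               stringsAsFactors = FALSE)
  }
  if (!length(rows))
    segsim_stop("no usable metric columns", "segsim_insufficient_data_error")
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$rho)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
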