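#' Normality gate: Shapiro-Wilk plus Kolmogorov-Smirnov
#'
#' A sample is considered normally distributed when it passes either the
#' Shapiro-Wilk test or the Kolmogorov-Smirnov test at the 0.05 level
#' (passing = p > 0.05). Because the normal parameters are estimated from
#' the sample, the KS p-value uses the Lilliefors correction by default;
#' set `lilliefors = FALSE` to audit against the naive KS test.
#'
#' @param values numeric sample, n >= 3
#' @param lilliefors use the Lilliefors-corrected KS p (default TRUE)
#' @return list: `normal`, `shapiro_p`, `ks_p`, `degenerate` (TRUE for a
#'   zero-variance sample, which is reported as non-normal)
#' @export
normality_gate <- function(values, lilliefors = TRUE) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("normality gate undefined for n < 3")
  if (stats::sd(values) == 0) {
    return(list(normal = FALSE, shapiro_p = NA_real_, ks_p = NA_real_,
                degenerate = TRUE))
  }
  sw <- tryCatch(stats::shapiro.test(values)$p.value,
                 error = function(e) NA_real_)
  ks <- if (lilliefors) {
    tryCatch(nortest::lillie.test(values)$p.value, error = function(e) NA_real_)
  } else {
    tryCatch(suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values))$p.value),
      error = function(e) NA_real_)
  }
  normal <- isTRUE(sw > 0.05) || isTRUE(ks > 0.05)
  list(normal = normal, shapiro_p = sw, ks_p = ks, degenerate = FALSE)
}

#' Exact two-sided Mann-Whitney U test by enumeration
#'
#' Computes the permutation distribution of the U statistic by enumerating
#' all C(n1 + n2, n1) assignments of the pooled (mid)ranks, which remains
#' valid under ties. Two-sided p = min(1, 2 x min(P(U <= u), P(U >= u))).
#' Intended for small groups (both n <= 8).
#'
#' @param a,b numeric samples
#' @return list with `statistic` (U of group `a`) and `p_value`
#' @export
mann_whitney_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  p_lo <- mean(u_all <= u_obs + eps)
  p_hi <- mean(u_all >= u_obs - eps)
  list(statistic = u_obs, p_value = min(1, 2 * min(p_lo, p_hi)))
}

#' Mann-Whitney U with tie-corrected normal approximation
#'
#' Two-sided, with continuity correction; the tie correction subtracts
#' sum(t^3 - t) / (N (N - 1)) from the null variance.
#' @param a,b numeric samples
#' @return list with `statistic` (U of group `a`) and `p_value`
#' @export
mann_whitney_approx <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  N <- n1 + n2
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(list(statistic = u, p_value = 1))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Compare two groups with the normality-gated protocol
#'
#' Both groups are passed through [normality_gate()]; when both pass, a
#' two-sided pooled-variance Student's t-test is used (Welch available via
#' `welch = TRUE`); otherwise a two-sided Mann-Whitney U test, exact by
#' enumeration when both n <= 8 and tie-corrected normal approximation
#' otherwise. Significance is declared at p < 0.05.
#'
#' @param a,b numeric samples, each n >= 3
#' @param metric label carried into the result
#' @param labels group labels
#' @param lilliefors passed to [normality_gate()]
#' @param welch use Welch's t instead of pooled-variance Student's t
#' @return object of class `group_comparison`
#' @export
compare_groups <- function(a, b, metric = "", labels = c("a", "b"),
                           lilliefors = TRUE, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  ga <- normality_gate(a, lilliefors)
  gb <- normality_gate(b, lilliefors)
  both_normal <- ga$normal && gb$normal
  if (both_normal) {
    ht <- stats::t.test(a, b, var.equal = !welch)
    test_used <- "student_t"
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    test_used <- "mann_whitney"
    mw <- if (length(a) <= 8 && length(b) <= 8) mann_whitney_exact(a, b)
    else mann_whitney_approx(a, b)
    statistic <- mw$statistic
    p <- mw$p_value
  }
  structure(list(metric = metric, labels = labels,
                 n = c(length(a), length(b)),
                 shapiro_p = c(ga$shapiro_p, gb$shapiro_p),
                 ks_p = c(ga$ks_p, gb$ks_p),
                 normal = c(ga$normal, gb$normal),
                 test_used = test_used, statistic = statistic,
                 p_value = p, significant = p < 0.05),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s (n = %d, %d)\n",
              if (nzchar(x$metric)) x$metric else "comparison",
              x$labels[1], x$labels[2], x$n[1], x$n[2]))
  cat(sprintf("  normal: %s/%s -> %s; statistic = %.4g, p = %.4g%s\n",
              x$normal[1], x$normal[2], x$test_used, x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Five-number box-and-whisker summary
#'
#' Min, lower quartile, median, upper quartile, max (whiskers reach the
#' extremes, matching min-max box plots). Quartiles use the
#' linear-interpolation convention of `stats::quantile` type 7.
#'
#' @param values numeric sample, n >= 1
#' @return named numeric vector (min, q1, median, q3, max)
#' @export
summarize_box <- function(values) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

#' Gated comparisons of several metrics between two groups
#'
#' Applies [compare_groups()] to each named metric column of a per-plaque
#' (or per-plane) table split by a grouping column, and attaches box
#' summaries. No multiple-testing correction is applied; the number of
#' comparisons performed is recorded in the result.
#'
#' @param tab data.frame with metric columns and a grouping column
#' @param metrics character vector of metric column names
#' @param group_col grouping column (must have exactly two levels)
#' @param ... passed to [compare_groups()]
#' @return data.frame with one row per metric (test, statistic, p, box
#'   summaries per group); attribute `n_comparisons`
#' @export
compare_metric_table <- function(tab, metrics, group_col = "genotype", ...) {
  levs <- sort(unique(as.character(tab[[group_col]])))
  stopifnot(length(levs) == 2)
  rows <- lapply(metrics, function(m) {
    a <- tab[[m]][tab[[group_col]] == levs[1]]
    b <- tab[[m]][tab[[group_col]] == levs[2]]
    cmp <- compare_groups(a, b, metric = m, labels = levs, ...)
    ba <- summarize_box(a); bb <- summarize_box(b)
    data.frame(metric = m, group_a = levs[1], group_b = levs[2],
               n_a = cmp$n[1], n_b = cmp$n[2],
               normal_a = cmp$normal[1], normal_b = cmp$normal[2],
               test_used = cmp$test_used, statistic = cmp$statistic,
               p_value = cmp$p_value, significant = cmp$significant,
               median_a = ba["median"], median_b = bb["median"],
               min_a = ba["min"], max_a = ba["max"],
               min_b = bb["min"], max_b = bb["max"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_comparisons") <- length(metrics)
  out
}
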