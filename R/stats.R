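# Group-comparison and correlation statistics for cohort tables.
# Omnibus tests wrap the base R implementations; the post-hoc and
# summary-statistic reconstructions are computed explicitly.

stat_result <- function(test, statistic, df, p_value,
                        group_summaries = NULL, posthoc = NULL,
                        note = NULL) {
  structure(
    list(test = test, statistic = statistic, df = df, p_value = p_value,
         group_summaries = group_summaries, posthoc = posthoc, note = note),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(format(x$df, trim = TRUE), collapse = ", ")
  cat(sprintf("<%s: statistic = %.4g, df = %s, p = %.4g%s>\n",
              x$test, x$statistic, dfs, x$p_value,
              if (!is.null(x$note)) paste0("; ", x$note) else ""))
  if (!is.null(x$posthoc)) {
    print(x$posthoc)
  }
  invisible(x)
}

check_groups <- function(values_by_group, min_per_group = 2L) {
  stopifnot(is.list(values_by_group))
  if (length(values_by_group) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  ns <- vapply(values_by_group, function(v) sum(is.finite(v)), 0L)
  if (any(ns < min_per_group)) {
    stop("each group needs at least ", min_per_group, " finite values",
         call. = FALSE)
  }
  lapply(values_by_group, function(v) v[is.finite(v)])
}

group_summary_table <- function(values_by_group) {
  data.frame(
    group = names(values_by_group),
    n = vapply(values_by_group, length, 0L),
    mean = vapply(values_by_group, mean, 0),
    sd = vapply(values_by_group, stats::sd, 0),
    median = vapply(values_by_group, stats::median, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Kruskal-Wallis rank test across groups
#'
#' Rank-based one-way comparison (tie-corrected H statistic,
#' chi-squared reference on k - 1 degrees of freedom).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @return A `stat_result` with the H statistic, df and p-value.
#' @export
kruskal_wallis <- function(values_by_group) {
  values_by_group <- check_groups(values_by_group)
  if (length(unique(unlist(values_by_group))) == 1L) {
    # fully tied data: no rank variation, H = 0 by convention
    return(stat_result("Kruskal-Wallis", 0,
                       length(values_by_group) - 1L, 1,
                       group_summary_table(values_by_group)))
  }
  kt <- stats::kruskal.test(values_by_group)
  stat_result("Kruskal-Wallis", unname(kt$statistic), unname(kt$parameter),
              kt$p.value, group_summary_table(values_by_group))
}

#' One-way analysis of variance across groups
#'
#' Classical fixed-effects ANOVA: `F = MS_between / MS_within` on
#' `(k - 1, N - k)` degrees of freedom.
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @return A `stat_result`; when all observations are identical the F
#'   statistic is undefined and flagged via `note`.
#' @export
one_way_anova <- function(values_by_group) {
  values_by_group <- check_groups(values_by_group)
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, 0L)))
  k <- nlevels(g); N <- length(y)
  fit <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  Fv <- fit[["F value"]][1]
  p <- fit[["Pr(>F)"]][1]
  note <- NULL
  if (!is.finite(Fv)) {
    note <- "F undefined: zero within-group variance"
    p <- NA_real_
  }
  stat_result("one-way ANOVA", Fv, c(k - 1L, N - k), p,
              group_summary_table(values_by_group), note = note)
}

#' Reconstruct a one-way ANOVA F statistic from group summaries
#'
#' Computes the F statistic that a raw-data one-way ANOVA would give
#' for any dataset having exactly the stated per-group means, SDs and
#' sizes: the between-group sum of squares from the means and sizes,
#' the within-group sum of squares from the SDs. This reproduces the F
#' columns of published group-comparison tables from their printed
#' "mean (SD)" summaries.
#'
#' @param means,sds,ns Equal-length numeric vectors (one entry per
#'   group); all `sds > 0`, all `ns >= 2`.
#' @return A `stat_result` with the F statistic, `(k - 1, N - k)`
#'   degrees of freedom and p-value.
#' @export
anova_from_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(means) == length(ns))
  if (any(sds <= 0)) stop("all group SDs must be positive", call. = FALSE)
  if (any(ns < 2)) stop("all group sizes must be >= 2", call. = FALSE)
  k <- length(means)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand) ^ 2)
  ss_within <- sum((ns - 1) * sds ^ 2)
  Fv <- (ss_between / (k - 1)) / (ss_within / (N - k))
  stat_result("one-way ANOVA (from summaries)", Fv, c(k - 1, N - k),
              stats::pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-squared test of independence
#'
#' Applied without continuity correction, as is conventional for tables
#' larger than 2 x 2 (e.g. sex-by-group counts).
#'
#' @param table Matrix of non-negative counts.
#' @return A `stat_result` with the chi-squared statistic,
#'   `(r - 1)(c - 1)` df and p-value.
#' @export
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must hold non-negative integer counts", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat_result("chi-squared independence", unname(ct$statistic),
              unname(ct$parameter), ct$p.value)
}

#' Tukey HSD post-hoc comparisons
#'
#' Studentized-range pairwise comparisons after a one-way layout
#' (Tukey-Kramer under unequal group sizes). For rank-based omnibus
#' tests set `rank_transform = TRUE` to run the comparisons on the rank
#' scale.
#'
#' @param values_by_group Named list of numeric vectors.
#' @param alpha Significance level for the `significant` flag.
#' @param rank_transform Run on ranks (companion to [kruskal_wallis()]).
#' @return Data.frame of pairs with mean difference, adjusted p and
#'   significance flag; attribute `rank_transform` records the scale.
#' @export
tukey_posthoc <- function(values_by_group, alpha = 0.05,
                          rank_transform = FALSE) {
  values_by_group <- check_groups(values_by_group)
  y <- unlist(values_by_group, use.names = FALSE)
  if (rank_transform) y <- rank(y)
  g <- factor(rep(names(values_by_group),
                  vapply(values_by_group, length, 0L)),
              levels = names(values_by_group))
  tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
  out <- data.frame(
    pair = rownames(tk),
    diff = tk[, "diff"],
    p = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "rank_transform") <- rank_transform
  out
}

#' Fisher LSD post-hoc comparisons
#'
#' Protected pairwise t-tests using the pooled within-group mean
#' square: `t = (m_i - m_j) / sqrt(MSW (1/n_i + 1/n_j))` on `N - k`
#' degrees of freedom. Following the protected-LSD rule, pairwise
#' significance is only asserted when the omnibus ANOVA is itself
#' significant; otherwise the pairs are reported but flagged as
#' suppressed.
#'
#' @param values_by_group Named list of numeric vectors.
#' @param alpha Significance level.
#' @return Data.frame of pairs with difference, t, p and `significant`
#'   flag; attributes `omnibus` (the ANOVA `stat_result`) and
#'   `protected` (whether the omnibus gate was passed).
#' @export
fisher_lsd_posthoc <- function(values_by_group, alpha = 0.05) {
  values_by_group <- check_groups(values_by_group)
  omnibus <- one_way_anova(values_by_group)
  protected <- is.finite(omnibus$p_value) && omnibus$p_value < alpha
  ns <- vapply(values_by_group, length, 0L)
  ms <- vapply(values_by_group, mean, 0)
  N <- sum(ns); k <- length(ns)
  ssw <- sum(vapply(values_by_group, function(v) sum((v - mean(v)) ^ 2), 0))
  msw <- ssw / (N - k)
  pairs <- utils::combn(names(values_by_group), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(msw * (1 / ns[[i]] + 1 / ns[[j]]))
    tval <- if (se > 0) (ms[[i]] - ms[[j]]) / se else NaN
    p <- 2 * stats::pt(-abs(tval), N - k)
    c(diff = ms[[i]] - ms[[j]], t = tval, p = p)
  })
  out <- data.frame(
    pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
    diff = res["diff", ], t = res["t", ], p = res["p", ],
    significant = protected & res["p", ] < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "omnibus") <- omnibus
  attr(out, "protected") <- protected
  out
}

#' Per-group Pearson correlation tables
#'
#' Correlates each feature column with each score column within each
#' group, with two-sided p-values and the conventional significance
#' stars (`*` p < 0.05, `**` p < 0.01). Cells with fewer than three
#' complete pairs or a constant column are flagged `NA`.
#'
#' @param records Data.frame of participant records.
#' @param feature_names,score_names Column names to correlate.
#' @param group_col Grouping column (default `"group"`).
#' @return A named list (one per group) of data.frames with columns
#'   `feature`, `score`, `n`, `r`, `p`, `stars`.
#' @export
pearson_correlations <- function(records, feature_names, score_names,
                                 group_col = "group") {
  stopifnot(is.data.frame(records),
            all(feature_names %in% names(records)),
            all(score_names %in% names(records)),
            group_col %in% names(records))
  out <- list()
  for (gr in unique(records[[group_col]])) {
    sub <- records[records[[group_col]] == gr, ]
    rows <- list()
    for (f in feature_names) {
      for (s in score_names) {
        ok <- is.finite(sub[[f]]) & is.finite(sub[[s]])
        n <- sum(ok)
        if (n < 3 || stats::sd(sub[[f]][ok]) == 0 ||
            stats::sd(sub[[s]][ok]) == 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            feature = f, score = s, n = n, r = NA_real_, p = NA_real_,
            stars = "", stringsAsFactors = FALSE)
          next
        }
        ct <- stats::cor.test(sub[[f]][ok], sub[[s]][ok])
        stars <- if (ct$p.value < 0.01) "**"
                 else if (ct$p.value < 0.05) "*" else ""
        rows[[length(rows) + 1L]] <- data.frame(
          feature = f, score = s, n = n, r = unname(ct$estimate),
          p = ct$p.value, stars = stars, stringsAsFactors = FALSE)
      }
    }
    out[[as.character(gr)]] <- do.call(rbind, rows)
  }
  out
}

#' Split ASD records into high- and low-VIQ subgroups
#'
#' VIQ is the mean of the two language T-scores. The default cutoff is
#' the sample mean VIQ of the supplied records; values strictly above
#' the cutoff go to the high-VIQ subgroup, values at or below it to
#' the low-VIQ subgroup (ties assigned low, since "high" is defined as
#' strictly above the cutoff).
#'
#' @param records Data.frame with a `viq` column (typically the ASD
#'   subset of a cohort).
#' @param cutoff VIQ cutoff (default: `mean(records$viq)`).
#' @return A list with `hviq` and `lviq` data.frames and the `cutoff`
#'   used; empty subgroups trigger a warning.
#' @export
split_by_viq <- function(records, cutoff = NULL) {
  stopifnot(is.data.frame(records), "viq" %in% names(records))
  if (nrow(records) == 0) stop("no records to split", call. = FALSE)
  if (is.null(cutoff)) cutoff <- mean(records$viq)
  high <- records$viq > cutoff
  if (all(high) || !any(high)) {
    warning("VIQ split is degenerate: one subgroup is empty")
  }
  list(hviq = records[high, , drop = FALSE],
       lviq = records[!high, , drop = FALSE],
       cutoff = cutoff)
}

#' Descriptive statistics with a normality flag
#'
#' Mean, SD, standard error, t-based 95% confidence half-width, range
#' (max minus min) and a Shapiro-Wilk normality flag at alpha = 0.05.
#'
#' @param values Numeric vector, `n >= 2`.
#' @return A list: `n`, `mean`, `sd`, `sem`, `ci95_halfwidth`, `range`,
#'   `min`, `max`, `shapiro_p`, `normal` (logical; `NA` when the test
#'   is not applicable).
#' @export
descriptive_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least two finite values", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  sem <- s / sqrt(n)
  ci <- stats::qt(0.975, n - 1) * sem
  sp <- if (n >= 3 && s > 0) stats::shapiro.test(values)$p.value else NA_real_
  list(n = n, mean = m, sd = s, sem = sem, ci95_halfwidth = ci,
       range = max(values) - min(values), min = min(values),
       max = max(values), shapiro_p = sp,
       normal = if (is.na(sp)) NA else sp >= 0.05)
}

#' Percentage of participants exhibiting each band
#'
#' For each group, the percentage of participants whose contour has at
#' least one bin (presence) in each timescale band.
#'
#' @param records Data.frame with logical `presence_sr`, `presence_ft`,
#'   `presence_poa` columns and a group column.
#' @param group_col Grouping column name.
#' @return Data.frame: one row per group, columns `group`, `n`, `sr`,
#'   `ft`, `poa` (percentages).
#' @export
presence_percentages <- function(records, group_col = "group") {
  cols <- c("presence_sr", "presence_ft", "presence_poa")
  stopifnot(is.data.frame(records), all(cols %in% names(records)),
            group_col %in% names(records))
  groups <- unique(records[[group_col]])
  out <- do.call(rbind, lapply(groups, function(gr) {
    sub <- records[records[[group_col]] == gr, ]
    data.frame(group = gr, n = nrow(sub),
               sr = 100 * mean(sub$presence_sr, na.rm = TRUE),
               ft = 100 * mean(sub$presence_ft, na.rm = TRUE),
               poa = 100 * mean(sub$presence_poa, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
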