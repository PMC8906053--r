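# Group-comparison statistics for assay metrics: two-tailed Student t,
# one-way ANOVA, Fisher's exact test on 2x2 counts, Mann-Whitney
# rank-sum and paired Wilcoxon signed-rank, with mean +/- SEM summaries.

check_group_table <- function(table, metric) {
  table <- tibble::as_tibble(table)
  req <- c("group", "metric", "value")
  if (!all(req %in% names(table))) {
    stop_contract("group table needs columns: %s", paste(req, collapse = ", "))
  }
  tb <- table[table$metric == metric & is.finite(table$value), ]
  if (nrow(tb) == 0L) stop_contract("no finite values for metric '%s'", metric)
  tb$group <- as.character(tb$group)
  tb
}

#' Compare groups on one metric
#'
#' Tests mirror the study's statistical toolbox: `t_two_tailed`
#' (two-sided Student's t with pooled variance), `anova_oneway`
#' (ordinary one-way ANOVA), `fisher_exact` (2x2 counts, e.g. cells
#' with/without spontaneous events per group; values must be 0/1),
#' `mann_whitney` (rank-sum) and `wilcoxon` (paired signed-rank, groups
#' paired by row order). No multiple-testing correction is applied by
#' default, matching per-panel testing; `p_adjust = "holm"` is available.
#'
#' @param table Long tibble with columns `group`, `metric`, `value`
#'   (and optionally an id column).
#' @param metric Metric name to test.
#' @param test One of `"t_two_tailed"`, `"anova_oneway"`,
#'   `"fisher_exact"`, `"mann_whitney"`, `"wilcoxon"`.
#' @param p_adjust Optional p-adjustment method (passed to
#'   [stats::p.adjust()]) applied to pairwise p-values under ANOVA.
#' @return A one-row `test_result` tibble: `test`, `statistic`,
#'   `p_value`, plus per-group `n`, means and SEMs in a nested `groups`
#'   tibble.
#' @export
compare_groups <- function(table, metric,
                           test = c("t_two_tailed", "anova_oneway",
                                    "fisher_exact", "mann_whitney",
                                    "wilcoxon"),
                           p_adjust = NULL) {
  test <- match.arg(test)
  tb <- check_group_table(table, metric)
  groups <- unique(tb$group)
  if (length(groups) < 2L) stop_contract("need >= 2 groups (got %d)",
                                         length(groups))
  two_only <- c("t_two_tailed", "fisher_exact", "mann_whitney", "wilcoxon")
  if (test %in% two_only && length(groups) != 2L) {
    stop_contract("%s requires exactly 2 groups (got %d)", test, length(groups))
  }
  vals <- split(tb$value, factor(tb$group, levels = groups))
  gsum <- dplyr::summarise(
    dplyr::group_by(tb, .data$group),
    n = dplyr::n(), mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
  res <- switch(
    test,
    t_two_tailed = {
      if (any(lengths(vals) < 2L)) stop_contract("t-test needs n >= 2 per group")
      ht <- t.test(vals[[1]], vals[[2]], var.equal = TRUE,
                   alternative = "two.sided")
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    anova_oneway = {
      if (any(lengths(vals) < 2L)) stop_contract("ANOVA needs n >= 2 per group")
      fit <- aov(value ~ group, data = tb)
      s <- summary(fit)[[1]]
      list(statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1])
    },
    fisher_exact = {
      if (!all(tb$value %in% c(0, 1))) {
        stop_contract("fisher_exact needs 0/1 values (per-cell event indicator)")
      }
      counts <- vapply(vals, function(v) c(sum(v == 1), sum(v == 0)),
                       numeric(2))
      ht <- fisher.test(counts)
      list(statistic = unname(ht$estimate %||% NA_real_), p_value = ht$p.value)
    },
    mann_whitney = {
      ht <- suppressWarnings(wilcox.test(vals[[1]], vals[[2]], exact = NULL))
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    wilcoxon = {
      if (length(vals[[1]]) != length(vals[[2]])) {
        stop_contract("wilcoxon (paired) needs equal group sizes")
      }
      ht <- suppressWarnings(wilcox.test(vals[[1]], vals[[2]], paired = TRUE))
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    })
  out <- tibble::tibble(metric = metric, test = test,
                        statistic = res$statistic, p_value = res$p_value,
                        n_groups = length(groups),
                        groups = list(gsum))
  if (!is.null(p_adjust) && test == "anova_oneway") {
    pw <- utils::combn(groups, 2, simplify = FALSE)
    pp <- vapply(pw, function(g) {
      t.test(vals[[g[1]]], vals[[g[2]]], var.equal = TRUE)$p.value
    }, numeric(1))
    out$pairwise <- list(tibble::tibble(
      group1 = vapply(pw, `[`, "", 1), group2 = vapply(pw, `[`, "", 2),
      p_value = pp, p_adjusted = stats::p.adjust(pp, method = p_adjust)))
  }
  class(out) <- c("test_result", class(out))
  out
}

#' Per-group mean, SEM and relative-frequency histogram
#'
#' `SEM = SD / sqrt(n)`; a single-value group reports `NA` SEM with a
#' warning; an empty metric errors.
#'
#' @param table Long group table (see [compare_groups()]).
#' @param metric Metric name.
#' @param breaks Optional histogram bin edges; when given, a
#'   relative-frequency histogram per group is attached as a nested
#'   `histogram` column.
#' @return A tibble with one row per group.
#' @export
summarize_groups <- function(table, metric, breaks = NULL) {
  tb <- check_group_table(table, metric)
  out <- dplyr::summarise(
    dplyr::group_by(tb, .data$group),
    n = dplyr::n(),
    mean = mean(.data$value),
    sem = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n())
          else NA_real_,
    .groups = "drop")
  if (any(out$n == 1L)) cq_warn("group(s) with a single value: SEM undefined")
  if (!is.null(breaks)) {
    out$histogram <- lapply(out$group, function(g) {
      v <- tb$value[tb$group == g]
      h <- graphics::hist(v, breaks = breaks, plot = FALSE)
      tibble::tibble(bin_mid = h$mids, rel_freq = h$counts / length(v))
    })
  }
  out
}
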