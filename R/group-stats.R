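#' Effect size (Cohen's d) with maximal-SD denominator
#'
#' Effect size between two groups as `d = (mean_1 - mean_2) / (2 * s)`, where
#' `s` is the maximal sample standard deviation across all groups of the
#' complete dataset (not only the compared pair). With the large per-cell
#' sample sizes typical of this analysis, p-values alone overstate
#' significance, so comparisons with `|d| < 0.5` are considered not
#' significant.
#'
#' @param group_1,group_2 numeric vectors of per-cell statistics (n >= 2).
#' @param all_groups list of all groups in the dataset, used for the maximal
#'   SD; defaults to the compared pair.
#' @return list of class `effect_size_result`: `d`, `mean_1`, `mean_2`,
#'   `s_max`, `significant` (`|d| >= 0.5`).
#' @export
cohens_d <- function(group_1, group_2, all_groups = list(group_1, group_2)) {
  if (any(vapply(all_groups, length, 1L) < 2))
    ap_stop("every group needs n >= 2 for an SD", "too_few_values")
  s_max <- max(vapply(all_groups, stats::sd, numeric(1)))
  if (s_max == 0) ap_stop("all groups are constant; d undefined", "too_few_values")
  d <- (mean(group_1) - mean(group_2)) / (2 * s_max)
  structure(list(d = d, mean_1 = mean(group_1), mean_2 = mean(group_2),
                 s_max = s_max, significant = abs(d) >= 0.5),
            class = "effect_size_result")
}

#' Pooled-variance two-sample Student's t-test
#'
#' @param group_1,group_2 numeric vectors (n >= 2 each).
#' @return list with `statistic` (t), `df`, `p_value` (two-sided).
#' @export
two_sample_ttest <- function(group_1, group_2) {
  if (length(group_1) < 2 || length(group_2) < 2)
    ap_stop("each group needs n >= 2", "too_few_values")
  if (stats::sd(group_1) == 0 && stats::sd(group_2) == 0 &&
      mean(group_1) == mean(group_2))
    ap_stop("zero pooled variance with equal means: test degenerate", "degenerate")
  ht <- stats::t.test(group_1, group_2, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' One-way ANOVA with Tukey post hoc comparisons
#'
#' Standard between/within variance decomposition over two or more groups,
#' followed by Tukey's honestly-significant-difference pairwise comparisons
#' (Tukey-Kramer for unequal group sizes).
#'
#' @param groups named list of numeric vectors (>= 2 groups, n >= 2 each).
#' @param conf_level confidence level of the Tukey intervals.
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p_value`, and `tukey`, a data frame of pairwise mean differences with
#'   adjusted intervals and p-values.
#' @export
anova_oneway <- function(groups, conf_level = 0.95) {
  if (length(groups) < 2) ap_stop("need at least two groups", "too_few_values")
  if (any(vapply(groups, length, 1L) < 2)) ap_stop("each group needs n >= 2", "too_few_values")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  if (all(vapply(groups, stats::sd, numeric(1)) == 0) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1)
    ap_stop("all values identical: F undefined (0/0)", "degenerate")
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), vapply(groups, length, 1L))))
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tk <- as.data.frame(stats::TukeyHSD(fit, conf.level = conf_level)$group)
  tk$comparison <- rownames(tk)
  rownames(tk) <- NULL
  names(tk) <- c("diff", "lwr", "upr", "p_adj", "comparison")
  structure(list(F = tab[1, "F value"], df_between = tab[1, "Df"],
                 df_within = tab[2, "Df"], p_value = tab[1, "Pr(>F)"],
                 tukey = tk[, c("comparison", "diff", "lwr", "upr", "p_adj")]),
            class = "anova_result")
}

#' Fold change of a group mean relative to the control mean
#'
#' Normalizes a test-group mean rate to the control-group mean, yielding a
#' fold change (control = 1) and the corresponding percent change. Report
#' rounding follows the presentation convention for these quantities: folds
#' to one decimal, percent changes to the nearest integer.
#'
#' @param control_mean,test_mean group means (control must be positive).
#' @return list of class `fold_change_result`: `fold`, `percent_change`,
#'   `fold_rounded`, `percent_change_rounded`.
#' @examples
#' fold_change_rates(9.9, 7.5)$fold_rounded      # 0.8
#' fold_change_rates(3.2, 5.1)$fold_rounded      # 1.6
#' @export
fold_change_rates <- function(control_mean, test_mean) {
  if (control_mean <= 0) ap_stop("control mean must be positive", "invalid_control")
  fold <- test_mean / control_mean
  pc <- 100 * (fold - 1)
  structure(list(fold = fold, percent_change = pc,
                 fold_rounded = round(fold, 1),
                 percent_change_rounded = round(pc)),
            class = "fold_change_result")
}

#' Ratio of the magnitudes of two percent changes
#'
#' How many times larger the change in the expansion rate is than the change
#' in the constriction rate.
#'
#' @param percent_change_expansion,percent_change_constriction percent
#'   changes (the latter nonzero).
#' @return scalar `|expansion change| / |constriction change|`.
#' @examples
#' ratio_of_changes(60, -24)   # 2.5
#' @export
ratio_of_changes <- function(percent_change_expansion, percent_change_constriction) {
  if (percent_change_constriction == 0)
    ap_stop("constriction change is zero: ratio undefined", "undefined_ratio")
  abs(percent_change_expansion) / abs(percent_change_constriction)
}

#' Fractions of cells per contractile behaviour category
#'
#' @param categories a vector of labels, a factor, or a list of
#'   [categorize_cell()] results.
#' @return list with `fractions` and `counts`, both named over
#'   constricted/impaired/expanded.
#' @export
category_fractions <- function(categories) {
  if (is.list(categories) && length(categories) > 0 &&
      inherits(categories[[1]], "cell_category"))
    categories <- vapply(categories, function(x) as.character(x$label), "")
  if (length(categories) == 0) ap_stop("no categorized cells", "empty")
  f <- factor(as.character(categories), levels = c("constricted", "impaired", "expanded"))
  if (anyNA(f)) ap_stop("unknown category label", "invalid_parameters")
  counts <- table(f)
  list(fractions = stats::setNames(as.numeric(counts) / length(categories), names(counts)),
       counts = stats::setNames(as.integer(counts), names(counts)))
}
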