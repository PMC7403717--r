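test_that("Cohen's d follows the maximal-SD formula and the 0.5 rule", {
  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4)
  same <- cohens_d(g1, g1 + 0)
  expect_equal(same$d, 0)
  expect_false(same$significant)

  # means 1 and 0 with s_max forced to 0.5 through a third group
  r <- cohens_d(c(0.9, 1.0, 1.1), c(-0.1, 0, 0.1),
                all_groups = list(c(0.9, 1.0, 1.1), c(-0.1, 0, 0.1), c(0, 0.5, 1)))
  expect_equal(r$s_max, 0.5)
  expect_equal(r$d, 1)
  expect_true(r$significant)

  # antisymmetry and shift invariance
  set.seed(2)
  a <- rnorm(20, 5); b <- rnorm(20, 6)
  expect_equal(cohens_d(a, b)$d, -cohens_d(b, a)$d)
  expect_equal(cohens_d(a + 10, b + 10)$d, cohens_d(a, b)$d, tolerance = 1e-12)
  expect_error(cohens_d(1, c(1, 2)), class = "ap_too_few_values")
})

test_that("pooled t-test matches hand computation and the F = t^2 identity", {
  ident <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  ht <- two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ht$statistic, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(ht$df, 4)

  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    tt <- two_sample_ttest(x, y)
    av <- anova_oneway(list(a = x, b = y))
    expect_equal(av$F, tt$statistic^2, tolerance = 1e-9)
    expect_equal(av$p_value, tt$p_value, tolerance = 1e-9)
  }
  expect_error(two_sample_ttest(c(2, 2), c(2, 2)), class = "ap_degenerate")
})

test_that("one-way ANOVA matches a sum-of-squares oracle and Tukey covers all pairs", {
  groups <- list(a = c(6, 8, 4, 5, 3, 4), b = c(8, 12, 9, 11, 6, 8), c = c(13, 9, 11, 8, 7, 12))
  res <- anova_oneway(groups)
  # independent decomposition by hand
  all_v <- unlist(groups); gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 15)
  expect_equal(res$F, f_oracle, tolerance = 1e-12)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 15)
  expect_equal(nrow(res$tukey), 3)

  shifted <- anova_oneway(lapply(groups, `+`, 100))
  expect_equal(shifted$F, res$F, tolerance = 1e-9)
  expect_error(anova_oneway(list(a = c(2, 2), b = c(2, 2))), class = "ap_degenerate")
})

test_that("the printed fold-change chain reproduces end to end", {
  f_con <- fold_change_rates(9.9, 7.5)
  expect_equal(f_con$fold_rounded, 0.8)
  expect_equal(f_con$percent_change_rounded, -24)
  f_exp <- fold_change_rates(3.2, 5.1)
  expect_equal(f_exp$fold_rounded, 1.6)
  expect_equal(ratio_of_changes(60, -24), 2.5)
  expect_equal(ratio_of_changes(f_exp$percent_change, f_con$percent_change),
               2.449, tolerance = 1e-3)
  expect_equal(fold_change_rates(4.4, 4.4)$fold, 1)
  expect_equal(fold_change_rates(4.4, 4.4)$percent_change, 0)
  expect_error(fold_change_rates(0, 5), class = "ap_invalid_control")
  expect_error(ratio_of_changes(60, 0), class = "ap_undefined_ratio")
})

test_that("category fractions sum to one and are order invariant", {
  all_c <- category_fractions(rep("constricted", 9))
  expect_equal(unname(all_c$fractions), c(1, 0, 0))
  lab <- c(rep("constricted", 150), rep("impaired", 132), rep("expanded", 18))
  cf <- category_fractions(lab)
  expect_equal(unname(cf$fractions), c(0.50, 0.44, 0.06))
  expect_equal(sum(cf$fractions), 1)
  set.seed(3)
  expect_equal(category_fractions(sample(lab))$fractions, cf$fractions)
  expect_error(category_fractions(character(0)), class = "ap_empty")
})
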