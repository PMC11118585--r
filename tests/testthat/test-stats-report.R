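# Group-comparison battery and the ontogeny experiment report.

test_that("identical groups give non-significant tests near the null", {
  d <- data.frame(value = rep(c(1, 2, 3, 4, 5), 2),
                  g = rep(c("a", "b"), each = 5))
  r <- compare_groups(d, group_comparison_spec("ttest", factors = "g"))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  expect_false(r$significant)
  rk <- compare_groups(d, group_comparison_spec("ks", factors = "g"))
  expect_gt(rk$p_value, 0.9)
})

test_that("well-separated groups are detected by every design", {
  set.seed(31)
  d <- data.frame(value = c(rnorm(50, 0), rnorm(50, 2)),
                  g = rep(c("a", "b"), each = 50),
                  subject = c(paste0("s", 1:50), paste0("s", 1:50)))
  for (des in c("ttest", "paired_ttest", "anova1", "kruskal_wallis", "ks")) {
    r <- compare_groups(d, group_comparison_spec(des, factors = "g"))
    expect_lt(r$p_value, 1e-4)
  }
})

test_that("two-sample power at delta 2 SD, n 50 is essentially 1", {
  set.seed(17)
  hits <- mean(replicate(200, {
    d <- data.frame(value = c(rnorm(50), rnorm(50, 2)),
                    g = rep(c("a", "b"), each = 50))
    compare_groups(d, group_comparison_spec("ttest", factors = "g"))$p_value < 0.05
  }))
  expect_gte(hits, 0.99)
})

test_that("null one-way ANOVA rejects at about the nominal rate", {
  set.seed(23)
  rate <- mean(replicate(400, {
    d <- data.frame(value = rnorm(50), g = rep(letters[1:5], each = 10))
    compare_groups(d, group_comparison_spec("anova1", factors = "g"))$p_value < 0.05
  }))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("Tukey post-hoc appears only when requested and separates groups", {
  set.seed(41)
  d <- data.frame(value = c(rnorm(20, 0), rnorm(20, 0.1), rnorm(20, 3)),
                  g = rep(c("a", "b", "c"), each = 20))
  plain <- compare_groups(d, group_comparison_spec("anova1", factors = "g"))
  expect_null(plain$posthoc_table)
  r <- compare_groups(d, group_comparison_spec("anova1", factors = "g",
                                               posthoc = "tukey_hsd"))
  ph <- r$posthoc_table
  expect_equal(nrow(ph), 3)
  expect_gt(ph$p_adj[ph$contrast == "b-a"], 0.05)
  expect_lt(ph$p_adj[ph$contrast == "c-a"], 0.01)
})

test_that("repeated-measures two-way ANOVA detects a within-subject effect", {
  set.seed(51)
  d <- expand.grid(subject = paste0("s", 1:12), age = c("3", "5"),
                   geno = c("wt", "mut"))
  subj_off <- rnorm(12, 0, 2)[as.integer(factor(d$subject))]
  d$value <- subj_off + (d$age == "5") * 1.5 + rnorm(nrow(d), 0, 0.5)
  r <- compare_groups(d, group_comparison_spec("anova2_rm",
                                               factors = c("age", "geno"),
                                               posthoc = "tukey_hsd"))
  expect_lt(r$p_value, 0.01)
  expect_true(is.data.frame(r$posthoc_table))
  expect_true("age:geno" %in% sub("f1", "age", sub("f2", "geno", r$terms$term)) ||
              any(grepl(":", r$terms$term)))
})

test_that("Bonferroni correction divides alpha by the declared family size", {
  set.seed(61)
  d <- data.frame(value = c(rnorm(20), rnorm(20, 0.8)),
                  g = rep(c("a", "b"), each = 20))
  spec <- group_comparison_spec("ttest", factors = "g",
                                correction = "bonferroni", n_comparisons = 5)
  r <- compare_groups(d, spec)
  expect_equal(r$alpha_adjusted, 0.01)
  expect_identical(r$significant, r$p_value < 0.01)
})

test_that("invalid specs and malformed data error clearly", {
  d <- data.frame(value = rnorm(10), g = rep(c("a", "b"), each = 5))
  expect_error(compare_groups(d, group_comparison_spec("anova1", factors = "age")),
               "missing factor")
  expect_error(compare_groups(data.frame(g = d$g),
                              group_comparison_spec("anova1", factors = "g")),
               "value")
  expect_error(group_comparison_spec("zscore", factors = "g"))
  expect_error(group_comparison_spec("anova2_rm", factors = "g"), "two factors")
  d$value[d$g == "b"] <- d$value[d$g == "b"] - 2
  d3 <- rbind(d, data.frame(value = 1, g = "c"))
  expect_error(compare_groups(d3, group_comparison_spec("anova1", factors = "g")),
               ">= 2")
})

test_that("rank-based tests are identical on raw and log(dFF+1) data", {
  set.seed(71)
  d <- data.frame(value = rexp(60), g = rep(c("a", "b", "c"), each = 20))
  raw <- compare_groups(d, group_comparison_spec("kruskal_wallis", factors = "g"))
  logd <- compare_groups(d, group_comparison_spec("kruskal_wallis", factors = "g",
                                                  transform = "log_dff_plus_1"))
  expect_equal(raw$statistic, logd$statistic, tolerance = 1e-12)
  expect_equal(raw$p_value, logd$p_value, tolerance = 1e-12)
})

test_that("dual analysis runs both arms and flags only real disagreements", {
  set.seed(81)
  strong <- data.frame(value = c(rexp(30, 10), rexp(30, 10) + 1.5),
                       g = rep(c("a", "b"), each = 30))
  r <- dual_analysis(strong, group_comparison_spec("ttest", factors = "g",
                                                   transform = "log_dff_plus_1"))
  expect_true(r$parametric$significant)
  expect_true(r$nonparametric$significant)
  expect_false(r$disagreement)
  same <- data.frame(value = rep(rnorm(30), 2), g = rep(c("a", "b"), each = 30))
  r0 <- dual_analysis(same, group_comparison_spec("ttest", factors = "g"))
  expect_false(r0$parametric$significant)
  expect_false(r0$nonparametric$significant)
  expect_false(r0$disagreement)
  expect_identical(r0$disagreement,
                   r0$parametric$significant != r0$nonparametric$significant)
})

test_that("paired dual analysis uses the signed-rank counterpart", {
  set.seed(91)
  d <- data.frame(value = c(rnorm(20), rnorm(20, 1.5)),
                  g = rep(c("pre", "post"), each = 20),
                  subject = rep(paste0("s", 1:20), 2))
  r <- dual_analysis(d, group_comparison_spec("paired_ttest", factors = "g"))
  expect_equal(r$nonparametric$test, "Wilcoxon signed-rank")
  expect_true(r$parametric$significant)
})

test_that("ontogeny experiment detects the plateau shape", {
  rep1 <- run_ontogeny_experiment(seed = 19)
  expect_lt(rep1$gain_anova$p_value, 0.05)
  ph <- rep1$gain_anova$posthoc_table
  expect_gt(ph$p_adj[ph$contrast == "15-9"], 0.05)
  expect_lt(ph$p_adj[ph$contrast == "9-3"], 0.05)
  expect_lt(rep1$dff_pair_tests[["3-5"]]$p_value, 0.05)
  expect_gt(rep1$dff_pair_tests[["7-9"]]$p_value, 0.01)
  expect_lt(rep1$nmj_anova$p_value, 0.05)
})

test_that("ontogeny report files are reproducible byte for byte", {
  d1 <- file.path(tempdir(), "ont1"); d2 <- file.path(tempdir(), "ont2")
  run_ontogeny_experiment(seed = 5, out_dir = d1)
  run_ontogeny_experiment(seed = 5, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
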