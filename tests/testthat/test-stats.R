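test_that("the normality gate routes to the expected branch", {
  set.seed(11)
  norm2 <- list(rnorm(20), rnorm(20, 1))
  expect_identical(select_test(norm2, "two_indep"), "t_test")
  skew2 <- list(rlnorm(20, 0, 1.5), rlnorm(20, 0.5, 1.5))
  expect_identical(select_test(skew2, "two_indep"), "mann_whitney")
  norm3 <- list(rnorm(15), rnorm(15), rnorm(15, 2))
  expect_identical(select_test(norm3, "multi_indep"), "anova")
  skew3 <- list(rlnorm(15, 0, 2), rlnorm(15, 0, 2), rlnorm(15, 1, 2))
  expect_identical(select_test(skew3, "multi_indep"), "kruskal_wallis")
  # repeated, 4 timepoints, non-normal -> Friedman
  rep4 <- replicate(4, rlnorm(12, 0, 2), simplify = FALSE)
  expect_identical(select_test(rep4, "repeated"), "friedman")
  rep2 <- list(rnorm(12), rnorm(12, 0.3))
  expect_identical(select_test(rep2, "repeated"), "paired_t")
  expect_error(select_test(list(rnorm(2), rnorm(20)), "two_indep"),
               "insufficient sample")
})

test_that("branch selection is reproducible for the same p-values", {
  set.seed(5)
  s <- list(rnorm(18), rnorm(18))
  expect_identical(select_test(s, "two_indep"), select_test(s, "two_indep"))
})

test_that("identical samples give p = 1 under the rank branch", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  tab <- data.frame(subject = 1:16, group = rep(c("a", "b"), each = 8),
                    day = 0, y = c(x, x))
  r <- compare_groups(tab, "y", list(list(group = "a"), list(group = "b")),
                      test = "mann_whitney")
  expect_identical(r$test, "mann_whitney")
  expect_equal(r$p, 1)
  expect_false(r$significant)
})

test_that("group comparisons detect a strong simulated colitis effect", {
  # measurement-level simulation at the magnitudes of the longitudinal study
  set.seed(42)
  hits <- 0
  for (i in 1:60) {
    a <- rnorm(10, 60.9, 20.67)
    b <- rnorm(10, 127.3, 53.65)
    tab <- data.frame(subject = 1:20, group = rep(c("sham", "dss"), each = 10),
                      day = 9, y = c(a, b))
    r <- compare_groups(tab, "y",
                        list(list(group = "sham"), list(group = "dss")))
    if (r$significant) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.9)
  # permuted labels: roughly the nominal type-I rate
  set.seed(43)
  fp <- 0
  for (i in 1:200) {
    y <- c(rnorm(10, 60.9, 20.67), rnorm(10, 127.3, 53.65))
    g <- sample(rep(c("sham", "dss"), each = 10))
    tab <- data.frame(subject = 1:20, group = g, day = 9, y = y)
    r <- compare_groups(tab, "y",
                        list(list(group = "sham"), list(group = "dss")))
    if (r$significant) fp <- fp + 1
  }
  expect_lt(fp / 200, 0.12)
})

test_that("multi-group parametric branch reports Holm-adjusted pairwise p", {
  set.seed(7)
  tab <- data.frame(subject = 1:45,
                    group = rep(c("a", "b", "c"), each = 15),
                    day = 0,
                    y = c(rnorm(15), rnorm(15, 0.2), rnorm(15, 3)))
  r <- compare_groups(tab, "y", list(list(group = "a"), list(group = "b"),
                                     list(group = "c")))
  expect_true(r$test %in% c("anova", "kruskal_wallis"))
  expect_false(is.null(r$pairwise_p))
})

test_that("missing contrast cells are an error", {
  tab <- data.frame(subject = 1:4, group = "a", day = 0, y = rnorm(4))
  expect_error(compare_groups(tab, "y", list(list(group = "a"),
                                             list(group = "zz"))),
               "matches no rows")
})

test_that("spearman correlation handles monotone transforms, sign and ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  expect_equal(spearman_cor(x, exp(x))$r_s, 1)
  expect_equal(spearman_cor(x, -x^3)$r_s, -1)
  # average ranks on ties: agree with cor(..., method = "spearman")
  y <- c(1, 1, 2, 2, 3, 3, 4, 4)
  expect_equal(spearman_cor(x, y)$r_s, cor(x, y, method = "spearman"))
  expect_error(spearman_cor(rep(1, 8), x), "constant")
  expect_error(spearman_cor(x[1:3], x[1:3]), "n >= 4")
})

test_that("friedman branch runs on a repeated design", {
  set.seed(9)
  base <- rlnorm(8, 0, 1)
  samples <- list(base, base * 1.6 + rlnorm(8, 0, 0.4),
                  base * 2.4 + rlnorm(8, 0, 0.4))
  tab <- data.frame(subject = rep(1:8, 3),
                    group = "dss",
                    day = rep(c(0, 7, 28), each = 8),
                    y = unlist(samples))
  r <- compare_groups(tab, "y", list(list(day = 0), list(day = 7),
                                     list(day = 28)),
                      design = "repeated")
  expect_identical(r$test, "friedman")
  expect_lt(r$p, 0.05)
})
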