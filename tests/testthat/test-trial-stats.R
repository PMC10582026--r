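test_that("normality check wraps Shapiro-Wilk with input guards", {
  expect_error(check_normality(c(1, 2)), "3 values")
  expect_error(check_normality(rep(1, 10)), "constant")
  set.seed(31)
  p_norm <- replicate(100, check_normality(rnorm(50))$p)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_skew <- replicate(100, check_normality(exp(rnorm(50, sd = 1.5)))$p)
  expect_gte(mean(p_skew < 0.05), 0.90)
})

test_that("Greenhouse-Geisser epsilon is 1 for two levels, generic beyond", {
  expect_equal(gg_epsilon(diag(2) + 0.3), 1)
  set.seed(32)
  X <- matrix(rnorm(200 * 4), ncol = 4) %*% diag(c(3, 1, 1, 0.3))
  eps <- gg_epsilon(stats::cov(X))
  expect_gte(eps, 1 / 3)
  expect_lte(eps, 1)
  expect_lt(eps, 0.999)  # heteroscedastic levels violate sphericity
})

test_that("mixed ANOVA agrees with the design-matrix oracle and aov", {
  set.seed(33)
  for (i in 1:20) {
    tab <- random_trial_table(sample(3:9, 1), sample(3:9, 1))
    mine <- mixed_anova_2x2(tab, "y")$effects
    oracle <- anova22_oracle(tab)
    expect_equal(setNames(mine$F, mine$effect), oracle, tolerance = 1e-8)
    df <- as.data.frame(tab)
    a <- summary(stats::aov(y ~ group * timepoint +
                              Error(factor(subject_id)), data = df))
    expect_equal(mine$F[1],
                 a[["Error: factor(subject_id)"]][[1]]$`F value`[1],
                 tolerance = 1e-8)
    expect_equal(mine$F[2:3], a[["Error: Within"]][[1]]$`F value`[1:2],
                 tolerance = 1e-8)
  }
})

test_that("constructed effects land on the intended ANOVA terms", {
  n <- 200
  set.seed(34)
  base <- rnorm(2 * n)
  shift <- data.frame(
    subject_id = rep(sprintf("s%03d", 1:(2 * n)), each = 2),
    group = rep(rep(c("COMB", "MICT"), each = n), each = 2),
    timepoint = rep(c("W0", "W3"), 2 * n),
    y = rep(base, each = 2) + rep(c(0, 1), 2 * n) + rnorm(4 * n, sd = 0.2))
  a_shift <- mixed_anova_2x2(trial_table(shift, c(y = "u")), "y")
  p <- setNames(a_shift$effects$p, a_shift$effects$effect)
  expect_lt(p[["T"]], 1e-6)
  expect_gt(p[["G"]], 0.001)
  expect_gt(p[["GxT"]], 0.001)
  # interaction only: crossed cells with equal margins
  cross <- shift
  cross$y <- rep(base, each = 2) + rnorm(4 * n, sd = 0.2) +
    ifelse(cross$group == "COMB", 1, -1) *
    ifelse(cross$timepoint == "W0", 1, -1) * 0.5
  a_cross <- mixed_anova_2x2(trial_table(cross, c(y = "u")), "y")
  p2 <- setNames(a_cross$effects$p, a_cross$effects$effect)
  expect_lt(p2[["GxT"]], 1e-6)
  expect_gt(p2[["T"]], 0.001)
})

test_that("incomplete subjects are excluded and small groups rejected", {
  tab <- random_trial_table(4, 4)
  broken <- as.data.frame(tab)[-1, ]  # drop one timepoint of one subject
  tt <- trial_table(broken, c(y = "u"))
  expect_warning(res <- mixed_anova_2x2(tt, "y"), "excluded")
  expect_equal(sum(res$n_per_group), 7)
  tiny <- random_trial_table(2, 2)
  one <- trial_table(as.data.frame(tiny)[tiny$group == "COMB", ],
                     c(y = "u"))
  expect_error(mixed_anova_2x2(one, "y"), "2 groups")
})

test_that("post-hoc contrasts are the four Bonferroni-adjusted cells", {
  set.seed(35)
  tab <- random_trial_table(8, 8)
  res <- mixed_anova_2x2(tab, "y")
  expect_equal(nrow(res$posthoc), 4L)
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p))
  expect_true(all(res$posthoc$p_adj <= 1))
  expect_equal(res$posthoc$p_adj, pmin(1, 4 * res$posthoc$p))
})

test_that("Hedges g: closed-form correction, antisymmetry, labels", {
  a <- c(0, 1, 2, 3, 4)
  b <- a - sd(a)          # raw pooled d exactly 1, df = 8
  g <- hedges_g(a, b)
  expect_equal(g$correction, 1 - 3 / 31)
  expect_equal(g$g, 1 - 3 / 31)
  expect_equal(g$label, "large")
  same <- hedges_g(a, a)
  expect_equal(same$g, 0)
  expect_equal(same$label, "small")
  set.seed(36)
  x <- rnorm(30); y <- rnorm(30, 0.4)
  expect_equal(hedges_g(x, y)$g, -hedges_g(y, x)$g)
  flat <- hedges_g(c(1, 1, 1), c(1, 1, 1))
  expect_false(flat$defined)
  # large-sample recovery of a true standardized difference of 0.5
  set.seed(37)
  big <- hedges_g(rnorm(10000, 0.5), rnorm(10000))
  expect_equal(big$g, 0.5, tolerance = 0.03)
  expect_equal(big$label, "large")
})

test_that("the summary table reproduces hand-computed cells and errors", {
  df <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 2),
                   group = rep(c("COMB", "COMB", "MICT", "MICT"), each = 2),
                   timepoint = rep(c("W0", "W3"), 4),
                   BM = c(100, 95, 120, 114, 110, 101, 108, 100))
  tab <- trial_table(df, c(BM = "kg"))
  t1 <- build_table1(tab)
  expect_equal(t1$COMB_W0, sprintf("%s ± %s", 110, signif(sd(c(100, 120)), 2)))
  expect_true(all(c("p_G", "p_T", "p_GxT", "es") %in% names(t1)))
  one <- trial_table(df[df$group == "COMB", ], c(BM = "kg"))
  expect_error(build_table1(one), "both groups")
  expect_error(build_table1(tab[0, ]), "empty")
})

test_that("trial tables round-trip with their units sidecar", {
  set.seed(38)
  tab <- random_trial_table(3, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tab, path)
  back <- read_trial_table(path)
  expect_identical(back$y, tab$y)
  expect_identical(attr(back, "units"), attr(tab, "units"))
  expect_error(trial_table(as.data.frame(tab), units = c(z = "u")),
               "unit")
})
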