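test_that("rm_anova_gg matches the direct sums-of-squares oracle and aov", {
  set.seed(121)
  n <- 12; k <- 4
  Y <- matrix(rnorm(n * k, rep(c(0, 0.3, 0.5, 0.2), each = n)), n, k)
  res <- rm_anova_gg(Y)
  # oracle: explicit sums of squares
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_err <- sum((Y - grand)^2) - ss_cond - ss_subj
  F_o <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(res$F, F_o, tolerance = 1e-8)
  expect_equal(res$eta_p_sq, ss_cond / (ss_cond + ss_err), tolerance = 1e-8)
  expect_equal(res$df_num_raw, k - 1)
  expect_equal(res$df_den_raw, (n - 1) * (k - 1))
  # cross-check against aov's within-stratum F
  d <- data.frame(y = as.vector(Y),
                  subject = factor(rep(seq_len(n), k)),
                  condition = factor(rep(seq_len(k), each = n)))
  sm <- summary(aov(y ~ condition + Error(subject / condition), data = d))
  F_aov <- sm[["Error: subject:condition"]][[1]]["condition", "F value"]
  expect_equal(res$F, unname(F_aov), tolerance = 1e-8)
  # epsilon bounds and correction bookkeeping
  expect_gte(res$gg_epsilon, 1 / (k - 1)); expect_lte(res$gg_epsilon, 1)
  expect_equal(res$df_num, res$df_num_raw * res$gg_epsilon, tolerance = 1e-12)
})

test_that("rm_anova_gg handles edge designs", {
  # no condition effect at all: each subject constant across conditions
  Y0 <- matrix(rep(rnorm(6, 0, 1), 3), 6, 3)
  res0 <- rm_anova_gg(Y0)
  expect_equal(res0$F, 0); expect_equal(res0$p, 1)
  # two conditions: sphericity holds trivially, no correction
  set.seed(122)
  res2 <- rm_anova_gg(matrix(rnorm(20), 10, 2))
  expect_equal(res2$gg_epsilon, 1)
  expect_false(res2$corrected)
  # long input equals matrix input
  set.seed(123)
  Y <- matrix(rnorm(15), 5, 3, dimnames = list(1:5, c("a", "b", "c")))
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(Y), subject = 1:5),
    -subject, names_to = "condition", values_to = "value")
  expect_equal(rm_anova_gg(long), rm_anova_gg(Y))
  expect_error(rm_anova_gg(Y[, 1, drop = FALSE]),
               class = "metaown_validation_error")
  expect_error(rm_anova_gg(Y[1:2, ]), class = "metaown_validation_error")
})

test_that("rm_anova_mixed agrees with aov on a balanced design", {
  set.seed(124)
  d <- expand.grid(subject = 1:8, condition = c("c1", "c2", "c3"),
                   group = c("g1", "g2"))
  d$value <- rnorm(nrow(d)) + ifelse(d$group == "g1", 0, 0.4) +
    ifelse(d$condition == "c2", 0.3, 0)
  res <- rm_anova_mixed(d)
  d2 <- dplyr::mutate(d, subject = factor(paste(group, subject)),
                      group = factor(group), condition = factor(condition))
  sm <- summary(aov(value ~ group * condition + Error(subject / condition),
                    data = d2))
  F_grp <- sm[["Error: subject"]][[1]]["group", "F value"]
  within <- sm[["Error: subject:condition"]][[1]]
  expect_equal(res$F[res$effect == "group"], unname(F_grp), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "condition"],
               unname(within["condition", "F value"]), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "group:condition"],
               unname(within["group:condition", "F value"]), tolerance = 1e-8)
})

test_that("the JZS Bayes factor matches the g-space quadrature oracle", {
  for (cs in list(c(2.3, 24, 0.707), c(0.5, 12, 0.5), c(4, 40, 1),
                  c(-1.7, 30, 0.707))) {
    set.seed(125)
    x <- rnorm(cs[2])
    x <- (x - mean(x)) / sd(x) # force t exactly
    x <- x + cs[1] / sqrt(cs[2])
    res <- bayes_t_one_sample(x, rscale = cs[3])
    expect_equal(res$t, cs[1], tolerance = 1e-9)
    oracle <- jzs_gspace_oracle(cs[1], cs[2], cs[3])
    expect_lt(abs(res$bf10 - oracle) / oracle, 1e-4)
  }
})

test_that("Bayes-factor invariants hold", {
  set.seed(126)
  x <- rnorm(20, 0.4)
  res_pos <- bayes_t_one_sample(x, direction = "positive")
  res_neg <- bayes_t_one_sample(-x, direction = "positive")
  # the one-sided factors average to the two-sided one
  expect_equal((res_pos$bf_plus0 + res_neg$bf_plus0) / 2, res_pos$bf10,
               tolerance = 1e-6)
  expect_equal(res_pos$bf10, res_neg$bf10, tolerance = 1e-9)
  expect_equal(res_pos$cohens_d, mean(x) / sd(x), tolerance = 1e-12)
  # a vanishing prior width makes the alternative indistinguishable from null
  expect_equal(bayes_t_one_sample(x, rscale = 1e-4)$bf10, 1, tolerance = 1e-2)
  # t = 0 favours the null
  y <- c(-1, 1, -2, 2, -0.5, 0.5)
  expect_lt(bayes_t_one_sample(y)$bf10, 1)
  # robustness sweep is attached and consistent at the main width
  rb <- bayes_t_one_sample(x, rscale = 0.707, robustness = TRUE,
                           rscale_grid = c(0.5, 0.707, 1))
  expect_equal(rb$robustness[[1]]$bf[2], rb$bf10, tolerance = 1e-9)
  expect_error(bayes_t_one_sample(rep(1, 5)),
               class = "metaown_estimation_error")
  expect_error(bayes_t_one_sample(1), class = "metaown_validation_error")
})

test_that("bayes_t_sequential tracks accumulation", {
  set.seed(127)
  x <- rnorm(10, 1)
  seqbf <- bayes_t_sequential(x)
  expect_equal(seqbf$n, 2:10)
  expect_equal(seqbf$bf[9], bayes_t_one_sample(x)$bf, tolerance = 1e-9)
})

test_that("bf_oneway_rm separates null from strong-effect data", {
  set.seed(128)
  n <- 15; k <- 3
  null_Y <- matrix(rnorm(n * k), n, k) + rnorm(n) # subject effects only
  eff_Y <- null_Y + matrix(rep(c(0, 1.5, 3), each = n), n, k)
  bf_null <- bf_oneway_rm(null_Y, seed = 4)
  bf_eff <- bf_oneway_rm(eff_Y, seed = 4)
  expect_gt(bf_null, 1)   # data support the null
  expect_lt(bf_eff, 0.01) # strong condition effect demolishes the null
  expect_identical(bf_oneway_rm(null_Y, seed = 4), bf_null) # seeded MC
})

test_that("nonparametric tests behave on known configurations", {
  # identical value multisets across groups: H = 0
  v <- c(1, 2, 3, 4, 5)
  d0 <- data.frame(value = c(v, v), group = rep(c("a", "b"), each = 5))
  res0 <- nonparametric_tests(d0)
  expect_equal(res0$kruskal$H, 0, tolerance = 1e-12)
  expect_equal(res0$kruskal$df, 1)
  # hand-computed H on a small example without ties
  d1 <- data.frame(value = c(1, 3, 5, 2, 4, 6), group = rep(c("a", "b"), each = 3))
  r <- rank(d1$value); N <- 6
  H_o <- 12 / (N * (N + 1)) *
    sum(tapply(r, d1$group, function(z) length(z) * mean(z)^2)) - 3 * (N + 1)
  expect_equal(nonparametric_tests(d1)$kruskal$H, H_o, tolerance = 1e-10)
  expect_equal(nrow(res0$normality), 2)
  expect_true(all(res0$normality$ks_statistic >= 0))
  expect_error(nonparametric_tests(data.frame(value = 1:4, group = "a")),
               class = "metaown_validation_error")
})
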