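test_that("group summaries report mean and SEM with degenerate-n flagging", {
  d <- tibble::tibble(group = c("a", "a", "a", "b"), y = c(1, 2, 3, 5))
  s <- summarize_groups(d, y)
  a <- s[s$group == "a", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sem, 1 / sqrt(3), tolerance = 1e-6)   # SD 1, n 3 -> 0.577
  b <- s[s$group == "b", ]
  expect_equal(b$sem, 0)
  expect_true(b$degenerate)
  same <- summarize_groups(tibble::tibble(group = "a", y = c(4, 4, 4)), y)
  expect_equal(same$sem, 0)
  expect_error(summarize_groups(d[0, ], y), "empty group")
})

test_that("two-group Student's t matches hand computation and is symmetric", {
  # {1,2,3} vs {4,5,6}: pooled SD 1, t = -3 / sqrt(2/3) = -3.674, df 4
  r <- two_group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  r_same <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r_same$statistic, 0)
  expect_equal(r_same$p_value, 1)
  r_swap <- two_group_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r_swap$p_value, r$p_value)
  expect_equal(r_swap$statistic, -r$statistic)
  expect_error(two_group_test(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA matches the direct mean-square ratio and gates post hoc tests", {
  # 4 x 3 toy table, hand ANOVA oracle from between/within mean squares
  d <- tibble::tibble(
    group = rep(c("g1", "g2", "g3", "g4"), each = 3),
    y = c(1, 2, 3, 2, 3, 4, 5, 6, 7, 1, 1, 4)
  )
  gm <- tapply(d$y, d$group, mean)
  ss_b <- 3 * sum((gm - mean(d$y))^2)
  ss_w <- sum((d$y - gm[d$group])^2)
  f_hand <- (ss_b / 3) / (ss_w / 8)
  r <- anova_posthoc(d, y)
  expect_equal(r$anova$f, f_hand, tolerance = 1e-10)
  expect_equal(r$anova$df_between, 3)
  expect_equal(r$anova$df_within, 8)

  # identical groups: F ~ 0, no post hoc run
  d0 <- tibble::tibble(group = rep(c("g1", "g2", "g3", "g4"), each = 3),
                       y = rep(c(1, 2, 3), 4))
  r0 <- anova_posthoc(d0, y)
  expect_lt(r0$anova$f, 1e-10)
  expect_equal(nrow(r0$posthoc), 0)

  # one group shifted far away: significant, and exactly its 3 contrasts flagged
  set.seed(1)
  d1 <- tibble::tibble(
    group = rep(c("g1", "g2", "g3", "g4"), each = 5),
    y = rnorm(20, sd = 1) + rep(c(0, 0, 0, 10), each = 5)
  )
  r1 <- anova_posthoc(d1, y)
  expect_lt(r1$anova$p_value, 0.05)
  expect_equal(nrow(r1$posthoc), 6)
  sig <- r1$posthoc[r1$posthoc$p_value < 0.05, ]
  hits_g4 <- grepl("g4", sig$group_a) | grepl("g4", sig$group_b)
  expect_equal(sum(hits_g4), 3)

  expect_error(anova_posthoc(d1[d1$group != "g4", ], y), "4 groups")
})

test_that("ANOVA on two groups reduces to the squared t statistic", {
  a <- c(1.2, 2.4, 3.1, 2.2); b <- c(4.4, 5.1, 6.0, 5.2)
  tt <- two_group_test(a, b)
  d <- tibble::tibble(group = rep(c("a", "b"), each = 4), y = c(a, b))
  fit <- stats::aov(y ~ group, data = d)
  f <- summary(fit)[[1]]$`F value`[1]
  expect_equal(f, tt$statistic^2, tolerance = 1e-10)
})

test_that("Pearson correlations hit the exact limits and exclude missing pairs", {
  d <- tibble::tibble(modulus_kpa = 1:6,
                      lin = 2 * (1:6) + 1,
                      neg = -(1:6),
                      with_na = c(NA, 2, 4, 6, 8, 10))
  r <- modulus_correlations(d, vars = c("lin", "neg", "with_na"))
  expect_equal(r$r[r$variable == "lin"], 1, tolerance = 1e-12)
  expect_equal(r$r[r$variable == "neg"], -1, tolerance = 1e-12)
  expect_equal(r$n[r$variable == "with_na"], 5)
  # invariance to affine rescaling
  d2 <- dplyr::mutate(d, lin = 100 + 7 * lin)
  r2 <- modulus_correlations(d2, vars = "lin")
  expect_equal(r2$r, 1, tolerance = 1e-12)
  expect_error(
    modulus_correlations(tibble::tibble(modulus_kpa = 1:2, v = 1:2), vars = "v"),
    "fewer than 3")
})

test_that("a coupled synthetic cohort reproduces the published correlation signs", {
  # ligated-arm construction: modulus proportional to intima volume with
  # small noise; strain falls as modulus rises
  set.seed(42)
  n <- 10
  intima <- runif(n, 2e7, 12e7)
  modulus <- 10 + 4e-7 * intima + rnorm(n, sd = 2)
  strain <- 30 - 0.4 * modulus + rnorm(n, sd = 1)
  d <- tibble::tibble(modulus_kpa = modulus, intima_um3 = intima,
                      strain_pct = strain,
                      im_ratio = intima / 4e7)
  r <- modulus_correlations(d, vars = c("intima_um3", "im_ratio", "strain_pct"))
  expect_gt(r$r[r$variable == "intima_um3"], 0)
  expect_gt(r$r[r$variable == "im_ratio"], 0)
  expect_lt(r$r[r$variable == "strain_pct"], 0)
  expect_true(all(r$p_value[r$variable != "strain_pct"] < 0.05))
})
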