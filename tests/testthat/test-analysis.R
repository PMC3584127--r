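test_that("probit transform is boundary-safe and invertible", {
  expect_equal(probit_transform(20, 40), 0, tolerance = 1e-15)
  expect_equal(probit_transform(0, 40), qnorm(0.5 / 41), tolerance = 1e-12)
  expect_true(is.finite(probit_transform(40, 40)))
  set.seed(2)
  k <- sample(0:50, 20, replace = TRUE)
  expect_equal(pnorm(probit_transform(k, 50)), (k + 0.5) / 51,
               tolerance = 1e-12)
  expect_error(probit_transform(1, 0), "> 0")
  expect_error(probit_transform(5, 3), "0 <= k <= n")
})

test_that("observer-level summaries tally proportions and RTs", {
  trials <- data.frame(
    observer_id = rep(c("a", "b"), each = 4),
    sex_group = rep(c("female", "male"), each = 4),
    signed_fov = rep(c(-10, -10, 10, 10), 2),
    response = c("FTV", "FTV", "FA", "FTV", "FA", "FA", "FA", "FTV"),
    rt = c(1000, 1200, 2000, 2200, 900, 1100, 1500, 2500))
  s <- observer_level_summary(trials)
  expect_equal(nrow(s), 4)
  a_neg <- s[s$observer_id == "a" & s$signed_fov == -10, ]
  expect_equal(a_neg$prop_ftv, 1)
  expect_equal(a_neg$mean_rt, 1100)
  expect_equal(a_neg$median_rt, 1100)
  b_pos <- s[s$observer_id == "b" & s$signed_fov == 10, ]
  expect_equal(b_pos$k, 1)
  expect_equal(b_pos$z_ftv, qnorm(1.5 / 3))
})

test_that("mixed RM-ANOVA matches the brute-force decomposition", {
  s <- make_summary_fixture(n_per_group = 4, n_levels = 3, seed = 7)
  tab <- mixed_rm_anova(s, "z_ftv")
  orc <- aov_oracle(s, "z_ftv")
  get <- function(e) tab[tab$effect == e, ]
  expect_equal(get("between")$ss, orc$between$grp$ss, tolerance = 1e-9)
  expect_equal(get("subjects_error")$ss, orc$between$Residuals$ss,
               tolerance = 1e-9)
  expect_equal(get("within")$ss, orc$within$lev$ss, tolerance = 1e-9)
  expect_equal(get("interaction")$ss, orc$within$`grp:lev`$ss,
               tolerance = 1e-9)
  expect_equal(get("within_error")$ss, orc$within$Residuals$ss,
               tolerance = 1e-9)
  expect_equal(get("between")$f, orc$between$grp$f, tolerance = 1e-9)
  expect_equal(get("within")$f, orc$within$lev$f, tolerance = 1e-9)
  expect_equal(get("interaction")$f, orc$within$`grp:lev`$f,
               tolerance = 1e-9)
  expect_equal(get("between")$df, 1)
  expect_equal(get("within")$df, 2)
  expect_equal(get("interaction")$df, 2)
  # grand sums-of-squares partition
  expect_equal(sum(tab$ss), sum((s$z_ftv - mean(s$z_ftv))^2),
               tolerance = 1e-9)
})

test_that("the full design yields the canonical df pairs", {
  s <- make_summary_fixture(n_per_group = 11, n_levels = 13, seed = 13)
  tab <- mixed_rm_anova(s, "z_ftv")
  expect_equal(tab$df[tab$effect == "between"], 1)
  expect_equal(tab$df_error[tab$effect == "between"], 20)
  expect_equal(tab$df[tab$effect == "within"], 12)
  expect_equal(tab$df_error[tab$effect == "within"], 240)
  expect_equal(tab$df[tab$effect == "interaction"], 12)
  expect_equal(tab$df_error[tab$effect == "interaction"], 240)
})

test_that("incomplete or unbalanced designs are explicit errors", {
  s <- make_summary_fixture(4, 3, seed = 1)
  expect_error(mixed_rm_anova(s[-1, ], "z_ftv"), "not complete")
  s2 <- make_summary_fixture(4, 3, seed = 1)
  s2$sex_group[s2$observer_id == "f01"] <- "male"
  expect_error(mixed_rm_anova(s2, "z_ftv"), "equal numbers")
})

test_that("a constant dependent variable is reported as degenerate", {
  s <- make_summary_fixture(4, 3, seed = 1, dv_fun = function(g, i, l) 5)
  tab <- mixed_rm_anova(s, "z_ftv")
  expect_true(all(tab$ss == 0))
  expect_false(any(is.finite(tab$f)))   # 0/0 ratios, reported not hidden
  expect_true(all(is.na(tab$p)))
})

test_that("ANOVA effects reject at the nominal rate under the null", {
  reject <- matrix(FALSE, 300, 3)
  for (r in 1:300) {
    s <- make_summary_fixture(6, 5, seed = 1000 + r)
    tab <- mixed_rm_anova(s, "z_ftv")
    reject[r, ] <- tab$p[match(c("between", "within", "interaction"),
                               tab$effect)] < 0.05
  }
  rates <- colMeans(reject)
  expect_true(all(rates > 0.02 & rates < 0.09))
})

test_that("RT polynomial fits interpolate exact quadratic data", {
  fov <- default_levels()
  rt <- 1800 + 2.1 * fov - 0.015 * fov^2
  co <- fit_rt_polynomial(fov, rt)
  expect_equal(co$constant, 1800, tolerance = 1e-9)
  expect_equal(co$slope, 2.1, tolerance = 1e-9)
  expect_equal(co$curvature, -0.015, tolerance = 1e-9)

  flat <- fit_rt_polynomial(fov, rep(1500, 13))
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  expect_equal(flat$curvature, 0, tolerance = 1e-9)
  expect_error(fit_rt_polynomial(c(0, 10), c(1, 2)), ">= 3 distinct")
})

test_that("group t-tests report the paired-by-rank df of 10 at 11 + 11", {
  set.seed(5)
  fits <- data.frame(
    observer_id = sprintf("o%02d", 1:22),
    sex_group = rep(c("female", "male"), each = 11),
    constant = rnorm(22, 1800, 200),
    slope = rnorm(22, 1.5, 0.5),
    curvature = rnorm(22, -0.02, 0.01))
  tt <- group_ttests(fits)
  pr <- tt[tt$test == "paired_by_rank" & tt$coefficient == "constant", ]
  expect_equal(pr$df, 10)
  one <- tt[tt$test == "one_sample" & tt$coefficient == "slope", ]
  expect_equal(one$df, 21)
  # all-zero coefficients: degenerate one-sample t of 0 with p = 1
  zero <- fits; zero$slope <- 0
  tz <- group_ttests(zero)
  z1 <- tz[tz$test == "one_sample" & tz$coefficient == "slope", ]
  expect_equal(z1$t, 0)
  expect_equal(z1$p, 1)
})

test_that("two-sample t-tests detect a 2-SD group shift at n = 11", {
  hits <- 0L
  for (r in 1:400) {
    set.seed(3000 + r)
    fits <- data.frame(
      observer_id = sprintf("o%02d", 1:22),
      sex_group = rep(c("female", "male"), each = 11),
      constant = c(rnorm(11, 0, 1), rnorm(11, 2, 1)),
      slope = 1, curvature = 1)
    tt <- group_ttests(fits)
    p <- tt$p[tt$test == "two_sample" & tt$coefficient == "constant"]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / 400, 0.97)
})

test_that("Spearman correlation matches a rank-then-Pearson oracle", {
  # perfect monotone decrease
  s <- data.frame(z_ftv = seq(0.1, 2, length.out = 10),
                  mean_rt = seq(2000, 1000, length.out = 10))
  r <- spearman_rt_certainty(s)
  expect_equal(r$rho, -1, tolerance = 1e-12)
  expect_equal(r$df, 8)

  set.seed(11)
  s2 <- data.frame(z_ftv = round(rnorm(40), 1),        # forces ties
                   mean_rt = round(rgamma(40, 5, 1/300)))
  r2 <- spearman_rt_certainty(s2)
  expect_equal(r2$rho, cor(rank(abs(s2$z_ftv)), rank(s2$mean_rt)),
               tolerance = 1e-12)
  expect_equal(r2$rho,
               suppressWarnings(cor.test(abs(s2$z_ftv), s2$mean_rt,
                                         method = "spearman"))$estimate[[1]],
               tolerance = 1e-12)
  expect_error(spearman_rt_certainty(
    data.frame(z_ftv = c(1, 1, 1), mean_rt = c(1, 2, 3))), "constant")
})

test_that("boxplot statistics follow the interpolated-quartile rules", {
  b <- boxplot_stats(1:7)
  expect_equal(b$median, 4)
  expect_equal(b$q1, 2.5)
  expect_equal(b$q3, 5.5)
  expect_equal(b$whisker_lo, 1)
  expect_equal(b$whisker_hi, 7)
  expect_length(b$outliers, 0)
  expect_equal(b$notch_lo, 4 - 1.57 * 3 / sqrt(7))

  one <- boxplot_stats(42)
  expect_equal(one$median, 42)
  expect_equal(one$q1, 42)
  expect_equal(one$whisker_hi, 42)
  expect_length(one$outliers, 0)

  x <- c(1:7, 5.5 + 10 * 3)  # one point 10 IQRs above q3
  bo <- boxplot_stats(x)
  expect_equal(bo$outliers, 35.5)
  expect_true(bo$q1 <= bo$median && bo$median <= bo$q3)
})
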