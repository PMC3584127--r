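test_that("trial aggregation tallies responses per level", {
  m <- observer_model("o1", "male", psa = 30, spread = 50, seed = 4L)
  sched <- build_schedule(default_levels(), 40, 40, seed = 1)
  counts <- aggregate_trials(simulate_trials(m, sched))
  expect_equal(nrow(counts), 13)
  expect_true(all(counts$n == 40))
  expect_equal(sum(counts$n), 520)

  toy <- data.frame(
    signed_fov = c(-10, -10, -10, 10, 10, 10),
    response = c("FTV", "FTV", "FA", "FA", "FA", "FTV"))
  tc <- aggregate_trials(toy)
  expect_equal(tc$k, c(2, 1))
  expect_equal(tc$n, c(3, 3))

  all_ftv <- data.frame(signed_fov = rep(c(-5, 5), 4),
                        response = "FTV")
  ac <- aggregate_trials(all_ftv)
  expect_equal(ac$k, ac$n)
  expect_error(aggregate_trials(toy[0, ]), "no analysable")
})

test_that("duplicate level rows are merged, not double-counted", {
  a <- level_counts(c(-10, 10), c(40, 40), c(30, 10))
  b <- level_counts(c(-10, 10, -10, 10), c(20, 20, 20, 20),
                    c(15, 5, 15, 5))
  expect_equal(a, b)
})

test_that("the fit recovers known parameters from near-noiseless data", {
  lev <- default_levels()
  p <- pnorm((47.3 - lev) / 50)
  counts <- level_counts(lev, rep(4000, 13), round(4000 * p))
  fit <- fit_psychometric(counts, lapse_bounds = c(0, 0),
                          guess_bounds = c(0, 0))
  expect_true(fit$converged)
  expect_lt(abs(fit$psa - 47.3), 1)
  expect_lt(abs(fit$spread - 50) / 50, 0.02)
  expect_false(fit$extreme_psa)
  expect_lt(abs(fit$slope_at_psa - slope_at_psa(50)), 2e-4)
})

test_that("a symmetric two-level toy has an analytic crossing", {
  # proportions 0.75/0.25 symmetric about 10 degrees: psa = 10 and
  # spread = 10 / qnorm(0.75) by the closed-form symmetry argument
  counts <- level_counts(c(0, 20), c(4000, 4000), c(3000, 1000))
  fit <- fit_psychometric(counts, lapse_bounds = c(0, 0),
                          guess_bounds = c(0, 0))
  expect_equal(fit$psa, 10, tolerance = 1e-4)
  expect_equal(fit$spread, 14.82602218505602, tolerance = 1e-3)
})

test_that("saturated all-FTV data is flagged as an extreme PSA", {
  counts <- level_counts(default_levels(), rep(40, 13), rep(40, 13))
  fit <- fit_psychometric(counts)
  expect_true(fit$extreme_psa)
})

test_that("the fit is invariant to level ordering and row splitting", {
  counts <- simulate_counts(20, 60, default_levels(), 40, seed = 31)
  fit <- fit_psychometric(counts)
  shuffled <- counts[sample(nrow(counts)), ]
  fit2 <- fit_psychometric(shuffled)
  expect_equal(fit2$psa, fit$psa, tolerance = 1e-6)
  expect_equal(fit2$spread, fit$spread, tolerance = 1e-6)
  split_rows <- level_counts(
    c(counts$signed_fov, counts$signed_fov),
    rep(counts$n / 2, 2), c(ceiling(counts$k / 2), floor(counts$k / 2)))
  fit3 <- fit_psychometric(split_rows)
  expect_equal(fit3$psa, fit$psa, tolerance = 1e-6)
})

test_that("an inverse observer is fit with a positive slope", {
  lev <- default_levels()
  p <- pnorm((lev - 5) / 40)  # increasing curve
  counts <- level_counts(lev, rep(400, 13), round(400 * p))
  fit <- fit_psychometric(counts, lapse_bounds = c(0, 0),
                          guess_bounds = c(0, 0))
  expect_gt(fit$slope_at_psa, 0)
  expect_lt(abs(fit$psa - 5), 2)
})

test_that("deviance follows the binomial formula and likelihood identity", {
  # frozen: n = 10, k = 7, p = 0.5 -> 2*(7*ln(1.4) + 3*ln(0.6))
  counts <- level_counts(0, 10, 7)
  expect_equal(psy_deviance(counts, 0.5), 1.645657570101036,
               tolerance = 1e-12)
  expect_equal(psy_deviance(counts, 0.7), 0, tolerance = 1e-12)
  # 0 * ln(0) convention and infinite deviance on impossible fits
  expect_equal(psy_deviance(level_counts(0, 10, 0), 0), 0)
  expect_true(is.infinite(psy_deviance(level_counts(0, 10, 3), 0)))

  # identity: deviance = 2 * (saturated loglik - model loglik), with the
  # saturated/model logliks computed independently through dbinom
  set.seed(99)
  for (i in 1:5) {
    n <- sample(10:80, 6, replace = TRUE)
    k <- rbinom(6, n, runif(6))
    p_hat <- pmin(pmax(runif(6), 0.05), 0.95)
    counts <- level_counts(seq(-50, 50, length.out = 6), n, k)
    ll_sat <- sum(dbinom(counts$k, counts$n, counts$k / counts$n,
                         log = TRUE))
    ll_mod <- sum(dbinom(counts$k, counts$n, p_hat, log = TRUE))
    expect_equal(psy_deviance(counts, p_hat), 2 * (ll_sat - ll_mod),
                 tolerance = 1e-9)
  }
})

test_that("perfectly fitting data gives a Monte-Carlo p of 1", {
  counts <- level_counts(c(0, 20), c(4000, 4000), c(3000, 1000))
  fit <- fit_psychometric(counts, lapse_bounds = c(0, 0),
                          guess_bounds = c(0, 0))
  expect_lt(fit$deviance, 1e-6)
  fit <- mc_goodness_of_fit(fit, n_sim = 100, seed = 5)
  expect_equal(fit$mc_p_value, 1)
})

test_that("a grossly non-monotone observer is rejected by the MC test", {
  lev <- default_levels()
  p_v <- 0.15 + 0.75 * (abs(lev) / 90)  # V-shaped in FOV
  set.seed(21)
  counts <- level_counts(lev, rep(40, 13), rbinom(13, 40, p_v))
  fit <- fit_psychometric(counts)
  fit <- mc_goodness_of_fit(fit, n_sim = 200, seed = 6)
  expect_lt(fit$mc_p_value, 0.05)
})

test_that("pooling is weight-invariant and reduces to the single fit", {
  counts <- simulate_counts(30, 55, default_levels(), 40, seed = 17)
  single <- fit_psychometric(counts)
  pooled1 <- pooled_fit(list(counts))
  expect_equal(pooled1$psa, single$psa, tolerance = 1e-8)
  pooled2 <- pooled_fit(list(counts, counts))
  expect_equal(pooled2$psa, single$psa, tolerance = 1e-4)
  expect_equal(pooled2$spread, single$spread, tolerance = 1e-4)
  pooled_w <- pooled_fit(list(counts, counts), weights = c(2.5, 2.5))
  expect_equal(pooled_w$psa, pooled2$psa, tolerance = 1e-6)
  expect_error(pooled_fit(list(counts), weights = -1), "non-negative")
})

test_that("bootstrap slope intervals are ordered and shrink with data", {
  counts_small <- simulate_counts(10, 55, default_levels(), 40, seed = 8)
  fit_small <- fit_psychometric(counts_small, lapse_bounds = c(0, 0),
                                guess_bounds = c(0, 0))
  ci_small <- bootstrap_slope_ci(fit_small, n_boot = 120, seed = 3)
  expect_lte(ci_small$lo, ci_small$hi)
  expect_gte(fit_small$slope_at_psa, ci_small$lo - 1e-9)
  expect_lte(fit_small$slope_at_psa, ci_small$hi + 1e-9)

  counts_big <- simulate_counts(10, 55, default_levels(), 4000, seed = 8)
  fit_big <- fit_psychometric(counts_big, lapse_bounds = c(0, 0),
                              guess_bounds = c(0, 0))
  ci_big <- bootstrap_slope_ci(fit_big, n_boot = 120, seed = 3)
  expect_lt(ci_big$hi - ci_big$lo, ci_small$hi - ci_small$lo)
})
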