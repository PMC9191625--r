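test_that("Pearson CI matches the closed-form Fisher oracle", {
  p <- make_corr_pair(0.5, 50)
  res <- pearson_with_ci(p$x, p$y)
  expect_equal(res$r, 0.5, tolerance = 1e-12)
  # independent closed-form computation
  lo <- tanh(atanh(0.5) - qnorm(0.975) / sqrt(47))
  hi <- tanh(atanh(0.5) + qnorm(0.975) / sqrt(47))
  expect_equal(res$ci_lo, lo, tolerance = 1e-10)
  expect_equal(res$ci_hi, hi, tolerance = 1e-10)
  expect_equal(round(c(res$ci_lo, res$ci_hi), 4), round(c(lo, hi), 4))
  tt <- 0.5 * sqrt(48 / 0.75)
  expect_equal(res$p, 2 * pt(-tt, 48), tolerance = 1e-12)

  x <- 1:20
  perfect <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)
  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_with_ci(1:3, 3:1), "n < 4")
})

test_that("the age-partialled correlation equals the residual-residual
          Pearson and uses the one-covariate CI", {
  set.seed(11)
  n <- 40
  age <- rnorm(n, 75, 8)
  x <- 0.3 * age + rnorm(n)
  y <- -0.2 * age + rnorm(n)
  res <- partial_corr_age(x, y, age)
  r_direct <- cor(residuals(lm(x ~ age)), residuals(lm(y ~ age)))
  expect_equal(res$r, r_direct, tolerance = 1e-12)
  z <- atanh(r_direct)
  expect_equal(res$ci_lo, tanh(z - qnorm(0.975) / sqrt(n - 4)),
               tolerance = 1e-10)
  expect_equal(res$ci_hi, tanh(z + qnorm(0.975) / sqrt(n - 4)),
               tolerance = 1e-10)
  expect_error(partial_corr_age(x, age, age), "zero residual variance")
})

test_that("partialling out an independent covariate barely moves r", {
  set.seed(12)
  n <- 1000
  x <- rnorm(n); y <- 0.4 * x + rnorm(n); age <- rnorm(n)
  plain <- pearson_with_ci(x, y)$r
  part <- partial_corr_age(x, y, age)$r
  expect_lt(abs(part - plain), 0.05)
})

test_that("the dependent-correlation z matches an independent scalar
          implementation", {
  cases <- list(c(0.6, 0.3, 0.5, 50), c(-0.2, 0.4, 0.1, 30),
                c(0.8, 0.75, 0.9, 120), c(0.1, -0.1, 0, 25))
  for (cs in cases) {
    res <- compare_dependent_corrs(cs[1], cs[2], cs[3], cs[4])
    orc <- meng_oracle(cs[1], cs[2], cs[3], cs[4])
    expect_equal(res$z, orc$z, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
    # antisymmetry
    swapped <- compare_dependent_corrs(cs[2], cs[1], cs[3], cs[4])
    expect_equal(swapped$z, -res$z, tolerance = 1e-12)
  }
  eq <- compare_dependent_corrs(0.4, 0.4, 0.2, 60)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_error(compare_dependent_corrs(1.0, 0.5, 0.2, 30), "bound")
  expect_error(compare_dependent_corrs(0.9, -0.9, 0.9, 30), "non-PSD")
})

test_that("Welch t-tests match the formula oracle in raw and summary mode", {
  # Table-style summary input: means 74.77 (8.05, n 17) vs 79.26 (8.57, n 17)
  res <- welch_ttest(list(mean = 74.77, sd = 8.05, n = 17),
                     list(mean = 79.26, sd = 8.57, n = 17))
  va <- 8.05^2 / 17; vb <- 8.57^2 / 17
  expect_equal(res$t, (74.77 - 79.26) / sqrt(va + vb), tolerance = 1e-12)
  expect_equal(res$df, (va + vb)^2 / (va^2 / 16 + vb^2 / 16),
               tolerance = 1e-12)
  expect_equal(round(res$t, 3), -1.574)
  expect_equal(round(res$df, 1), 31.9)

  set.seed(13)
  a <- rnorm(20, 1); b <- rnorm(25, 1.4, 2)
  ours <- welch_ttest(a, b)
  ref <- t.test(a, b)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  same <- welch_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_ttest(1, c(1, 2)), "n < 2")
})

test_that("BH adjustment matches the hand-computed step-up and ordering
          properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    bh <- bh_adjust(p)
    bonf <- pmin(1, length(p) * p)
    expect_true(all(bh >= p - 1e-12))
    expect_true(all(bonf >= bh - 1e-12))
    expect_true(all(diff(bh[order(p)]) >= -1e-12))   # order preserving
  }
})

test_that("Tukey post-hocs agree with TukeyHSD and handle ties", {
  set.seed(15)
  g <- factor(rep(letters[1:4], times = c(8, 10, 9, 7)))
  y <- rnorm(length(g)) + as.integer(g) * 0.7
  ours <- posthoc_pairwise(y, g, "tukey")
  expect_identical(nrow(ours), 6L)
  ref <- TukeyHSD(aov(y ~ g))$g
  expect_equal(ours$p, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_equal(ours$diff, unname(ref[, "diff"]), tolerance = 1e-10)

  y2 <- rep(c(1, 2, 3), times = 4)
  g2 <- rep(letters[1:4], each = 3)
  eqp <- posthoc_pairwise(y2, g2, "tukey")
  expect_true(all(eqp$p > 0.999))
  expect_error(posthoc_pairwise(y, factor(rep("a", length(y)))),
               "at least 2 groups")
})

test_that("Bonferroni post-hocs dominate the raw Welch p-values", {
  set.seed(16)
  y <- rnorm(60); g <- rep(letters[1:3], 20)
  bon <- posthoc_pairwise(y, g, "bonferroni")
  for (i in seq_len(nrow(bon))) {
    parts <- strsplit(bon$contrast[i], " - ")[[1]]
    raw <- welch_ttest(y[g == parts[1]], y[g == parts[2]])$p
    expect_gte(bon$p[i] + 1e-12, raw)
  }
})

test_that("the BCa bootstrap is deterministic, keeps k = 1000 by default,
          and reduces to percentile limits when unbiased", {
  expect_identical(formals(bca_bootstrap_partial_vs_unadjusted)$k, 1000)
  set.seed(17)
  n <- 60
  age <- rnorm(n); x <- rnorm(n); y <- 0.4 * x + rnorm(n)
  b1 <- bca_bootstrap_partial_vs_unadjusted(x, y, age, k = 300, seed = 9)
  b2 <- bca_bootstrap_partial_vs_unadjusted(x, y, age, k = 300, seed = 9)
  expect_identical(b1[c("ci_lo", "ci_hi", "z0", "accel")],
                   b2[c("ci_lo", "ci_hi", "z0", "accel")])
  if (abs(b1$z0) < 0.05 && abs(b1$accel) < 0.01) {
    expect_lt(abs(b1$ci_lo - b1$percentile_lo), 0.01)
    expect_lt(abs(b1$ci_hi - b1$percentile_hi), 0.01)
  }
  expect_error(bca_bootstrap_partial_vs_unadjusted(x[1:5], y[1:5], age[1:5]),
               "n < 10")
})

test_that("BCa agrees with an independent bootstrap implementation on a
          fixed dataset", {
  skip_if_not_installed("boot")
  set.seed(18)
  n <- 80
  age <- rnorm(n); x <- 0.5 * age + rnorm(n); y <- 0.3 * age + rnorm(n)
  ours <- bca_bootstrap_partial_vs_unadjusted(x, y, age, k = 2000, seed = 4)
  stat <- function(d, idx) {
    d2 <- d[idx, ]
    rxy <- cor(d2$x, d2$y); rxz <- cor(d2$x, d2$age); ryz <- cor(d2$y, d2$age)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)) - rxy
  }
  set.seed(5)
  bt <- boot::boot(data.frame(x = x, y = y, age = age), stat, R = 2000)
  ci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_lt(abs(ours$ci_lo - ci[1]), 0.04)
  expect_lt(abs(ours$ci_hi - ci[2]), 0.04)
})

test_that("mixed-model fits collapse to OLS without grouping variance and
          flag degenerate input", {
  set.seed(19)
  d <- simulate_lmm_dataset(n_per_group = 5, reps = 6, b_task = 2,
                            young_only_task = 0, slope_sd = 0,
                            int_sd = 0, sigma = 1, seed = 19)
  fit <- fit_lmm(d, "additive", "intercept")
  ols <- lm(value ~ group + task, data = d)
  expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$AIC, 2 * fit$npar - 2 * fit$logLik, tolerance = 1e-8)
  one <- d[d$participant == d$participant[1], ]
  expect_error(fit_lmm(one), "at least 2 participants")
})

test_that("fixed-effect p-values carry Satterthwaite degrees of freedom", {
  d <- simulate_lmm_dataset(n_per_group = 6, reps = 8, b_task = 1,
                            young_only_task = 0, slope_sd = 0.5,
                            int_sd = 1, sigma = 2, seed = 20)
  fit <- fit_lmm(d, "additive", "task_slope")
  expect_true(all(is.finite(fit$fixed$df)))
  expect_true(all(fit$fixed$df > 1))
  expect_true(all(fit$fixed$df < nrow(d)))
})

test_that("the selection ladder has one row per step and recovers planted
          structure", {
  d_int <- simulate_lmm_dataset(n_per_group = 8, reps = 10, b_task = 0,
                                young_only_task = 1.5, slope_sd = 0.4,
                                int_sd = 1, sigma = 1.5, seed = 21)
  sel <- select_model(d_int)
  expect_identical(nrow(sel$table), 4L)
  expect_true(sel$interaction)
  expect_true(sel$slope)
  expect_identical(sel$chosen$formula, "interaction")

  d_null <- simulate_lmm_dataset(n_per_group = 8, reps = 10, b_task = 0.5,
                                 young_only_task = 0, slope_sd = 0,
                                 int_sd = 1, sigma = 1.5, seed = 22)
  sel0 <- select_model(d_null)
  expect_false(sel0$interaction)
})
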