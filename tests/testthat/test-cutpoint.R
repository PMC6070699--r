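test_that("IQR outlier removal matches the brute-force fence", {
  out <- remove_iqr_outliers(c(1, 2, 3, 4, 100))
  expect_equal(out$removed, 100)
  expect_equal(out$retained, c(1, 2, 3, 4))

  same <- remove_iqr_outliers(rep(2.5, 6))
  expect_length(same$removed, 0)

  sym <- remove_iqr_outliers(c(-2, -1, 0, 1, 2))
  expect_length(sym$removed, 0)

  expect_error(remove_iqr_outliers(c(1, 2, 3)), "at least 4")

  set.seed(99)
  for (i in 1:200) {
    x <- rlnorm(sample(4:80, 1), sdlog = runif(1, 0.1, 1.5))
    expect_equal(sort(remove_iqr_outliers(x)$retained),
                 sort(oracle_iqr_filter(x)))
  }
})

test_that("percentile routines agree with their sort-and-interpolate oracles", {
  # cut-point percentile at position 0.95 * (100 + 1) = 95.95
  expect_equal(screening_cutpoint_inhibited(1:100)$cut_point, 95.95)
  set.seed(7)
  for (i in 1:200) {
    x <- runif(sample(3:200, 1), -5, 5)
    p <- runif(1)
    # quartile convention (1 + p(n-1)) used by the outlier fence
    expect_equal(adatier:::interp_percentile(x, p), oracle_percentile(x, p))
    # Weibull convention (p(n+1), clamped) used by percentile cut points
    expect_equal(adatier:::tail_percentile(x, p),
                 oracle_tail_percentile(x, p))
  }
  # 2-point set: position 0.95 * 3 = 2.85 clamps to the maximum
  expect_equal(adatier:::tail_percentile(c(0, 1), 0.95), 1)
  # quartile convention interpolates at 1 + 0.95 * 1 = 1.95
  expect_equal(adatier:::interp_percentile(c(0, 1), 0.95), 0.95)
})

test_that("Shapiro-Wilk assessment is calibrated and detects skew", {
  set.seed(11)
  p_norm <- replicate(500, assess_normality(rnorm(48)))
  # uniform p-values: ~90% should exceed 0.10 (binomial band)
  expect_gt(mean(p_norm > 0.10), 0.81)
  expect_lt(mean(p_norm > 0.10), 0.99)
  p_lnorm <- replicate(200, assess_normality(rlnorm(48, sdlog = 1)))
  expect_gt(mean(p_lnorm < 0.10), 0.90)
  expect_error(assess_normality(rep(1, 10)), "constant")
})

test_that("parametric screening cut point follows exp(mean + 1.645 sd) of logs", {
  # degenerate: constant input has SD 0 (and a small-n warning)
  expect_warning(cp0 <- screening_cutpoint_untreated(rep(0.5, 20)),
                 "fewer than 48")
  expect_equal(cp0$cut_point, 0.5)
  expect_error(suppressWarnings(
    screening_cutpoint_untreated(c(rep(0.5, 19), -0.1))), "positive")

  # closed-form limit: large log-normal sample
  set.seed(21)
  x <- rlnorm(4000, meanlog = -1, sdlog = 0.3)
  cp <- screening_cutpoint_untreated(x)
  expect_equal(cp$method, "parametric_log")
  # IQR trimming of a large sample shrinks the SD slightly; the limit is
  # approached with a modest tolerance
  expect_equal(cp$cut_point, exp(-1 + 1.645 * 0.3), tolerance = 0.02)

  # strongly non-normalizable data trigger the nonparametric fallback
  set.seed(22)
  y <- c(rlnorm(40, -1, 0.2), runif(8, 5, 6))
  cpf <- screening_cutpoint_untreated(y)
  expect_equal(cpf$method, "nonparametric_p95")
  expect_match(cpf$notes, "95th percentile")
})

test_that("inhibited-method cut point is an outlier-trimmed 95th percentile", {
  expect_equal(
    suppressWarnings(screening_cutpoint_inhibited(rep(0.3, 12)))$cut_point,
    0.3)
  set.seed(31)
  x <- rlnorm(48, -1, 0.4)
  cp <- screening_cutpoint_inhibited(x)
  expect_equal(cp$cut_point,
               oracle_tail_percentile(oracle_iqr_filter(x), 0.95))
})

test_that("percent inhibition is the percentage decrease in OD", {
  expect_equal(percent_inhibition(1.000, 0.253), 74.7)
  expect_equal(percent_inhibition(0.8, 0.8), 0)
  expect_equal(percent_inhibition(1.0, 1.2), -20)
  expect_error(percent_inhibition(0, 0.5), "untreated")
})

test_that("confirmatory cut point is mean + 1.645 sd after outlier removal", {
  expect_equal(suppressWarnings(confirmatory_cutpoint(rep(10, 15)))$cut_point,
               10)
  x <- c(1, 2, 3, 4, 100, 2, 3, 1, 4, 2, 3)
  cp <- suppressWarnings(confirmatory_cutpoint(x))
  kept <- oracle_iqr_filter(x)
  expect_false(100 %in% kept)
  expect_equal(cp$cut_point, mean(kept) + 1.645 * sd(kept))
  expect_equal(cp$n_outliers_removed, 1L)

  # closed form vs simulation: for normal inhibitions mu 30, sd 20 the
  # untrimmed statistic has mean 30 + 1.645 * 20 = 62.9; the trimmed
  # pipeline sits slightly below it because the adaptive fence shrinks
  # the retained SD
  set.seed(41)
  sims <- replicate(400, {
    x <- rnorm(48, 30, 20)
    c(mean(x) + 1.645 * sd(x), confirmatory_cutpoint(x)$cut_point)
  })
  expect_equal(mean(sims[1, ]), 62.9, tolerance = 0.01)
  expect_lt(mean(sims[2, ]), mean(sims[1, ]))
  expect_equal(mean(sims[2, ]), 62.9, tolerance = 0.05)
})

test_that("cut points are permutation-invariant and scale-equivariant", {
  set.seed(51)
  x <- rlnorm(48, -1, 0.35)
  for (f in list(screening_cutpoint_untreated,
                 screening_cutpoint_inhibited)) {
    a <- f(x)$cut_point
    expect_equal(f(sample(x))$cut_point, a)
    for (c_scale in c(0.1, 3, 42)) {
      expect_equal(f(c_scale * x)$cut_point, c_scale * a,
                   tolerance = 1e-12)
    }
  }
})

test_that("train_cutpoints wires the three pipelines together", {
  cfg <- sim_config(n_donors = 48, prevalence_sa = 0.1, seed = 61)
  samples <- training_samples(cfg, "SaCas9")
  cps <- train_cutpoints(samples)
  expect_s3_class(cps$untreated, "cutpoint_result")
  expect_equal(cps$inhibited$method, "nonparametric_p95")
  expect_equal(cps$confirmatory$method, "confirmatory_linear")
  expect_true(all(c(cps$untreated$cut_point, cps$inhibited$cut_point) > 0))
  expect_lt(cps$confirmatory$cut_point, 100)
})
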