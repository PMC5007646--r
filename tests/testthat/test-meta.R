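test_that("per-study odds ratios are the present-vs-null cross product", {
  # Roy 2001 GSTM1: cases 17 null / 16 present, controls 8 null / 25 present
  eff <- study_effects(toy_studies(17, 16, 8, 25))
  expect_equal(eff$or, 128 / 425, tolerance = 1e-12)
  expect_equal(eff$se, sqrt(1 / 16 + 1 / 25 + 1 / 17 + 1 / 8))
  expect_false(eff$corrected)

  sym <- study_effects(toy_studies(9, 9, 9, 9))
  expect_equal(sym$log_or, 0)

  zero <- study_effects(toy_studies(0, 10, 5, 5))
  expect_true(zero$corrected)
  expect_equal(zero$or, (10.5 * 5.5) / (0.5 * 5.5), tolerance = 1e-12)

  expect_error(study_effects(toy_studies(0, 10, 0, 5)), "margin")
})

test_that("per-study chi-square reproduces the published footnote p-values", {
  roy <- genotype_chisq(toy_studies(17, 16, 8, 25))
  expect_equal(round(roy$p, 3), 0.022)
  harada <- genotype_chisq(toy_studies(57, 30, 87, 89))
  expect_equal(round(harada$p, 3), 0.014)
  # equal proportions: no association at all
  flat <- genotype_chisq(toy_studies(10, 20, 30, 60))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  # pinned convention: uncorrected Pearson, as stats::chisq.test reports
  ct <- stats::chisq.test(matrix(c(16, 25, 17, 8), 2), correct = FALSE)
  expect_equal(roy$p, unname(ct$p.value), tolerance = 1e-12)
})

test_that("Cochran's Q matches a term-by-term hand computation", {
  same <- study_effects(toy_studies(rep(20, 3), rep(10, 3), rep(40, 3),
                                    rep(20, 3)))
  q0 <- cochran_q(same)
  expect_equal(q0$Q, 0)
  expect_equal(q0$p, 1)

  eff <- data.frame(log_or = c(-0.4, 0.1, 0.3), se = c(0.2, 0.25, 0.4))
  w <- c(1 / 0.04, 1 / 0.0625, 1 / 0.16)
  ybar <- sum(w * eff$log_or) / sum(w)
  Q_hand <- w[1] * (-0.4 - ybar)^2 + w[2] * (0.1 - ybar)^2 +
    w[3] * (0.3 - ybar)^2
  q <- cochran_q(eff)
  expect_equal(q$Q, Q_hand)
  expect_equal(q$df, 2L)
  expect_equal(q$p, pchisq(Q_hand, 2, lower.tail = FALSE))
  expect_error(cochran_q(eff[1, ]), "at least 2")
})

test_that("I-squared and its Higgins-Thompson interval are reproduced", {
  expect_equal(i_squared(13, 13)$i2, 0)
  expect_equal(i_squared(0, 5)$i2, 0)
  expect_equal(i_squared(20.3, 13)$i2, (20.3 - 13) / 20.3 * 100)
  # large-Q branch, checked against the closed form
  Q <- 15.331; df <- 4
  se <- 0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * df - 1))
  H <- sqrt(Q / df)
  zc <- qnorm(0.975)
  lo <- exp(log(H) - zc * se); hi <- exp(log(H) + zc * se)
  ci <- i_squared(Q, df)
  expect_equal(ci$ci_low, (lo^2 - 1) / lo^2 * 100, tolerance = 1e-6)
  expect_equal(ci$ci_high, (hi^2 - 1) / hi^2 * 100, tolerance = 1e-6)
  expect_error(i_squared(3, 0), "df")
})

test_that("DerSimonian-Laird pooling agrees with metafor's DL fit", {
  d <- load_fixture("gstm1_atdh")
  eff <- study_effects(d)
  pooled <- pool_dl(eff)
  fit <- metafor::rma(yi = eff$log_or, vi = eff$se^2, method = "DL")
  expect_equal(pooled$log_or, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(pooled$se, fit$se, tolerance = 1e-10)
  expect_equal(pooled$tau2, fit$tau2, tolerance = 1e-10)
  expect_equal(pooled$Q, fit$QE, tolerance = 1e-10)
  expect_equal(pooled$i2, fit$I2, tolerance = 1e-6)

  # no-heterogeneity limit: identical null studies pool to OR 1, tau2 0
  flat <- pool_dl(study_effects(toy_studies(rep(20, 4), rep(10, 4),
                                            rep(40, 4), rep(20, 4))))
  expect_equal(flat$pooled_or, 1)
  expect_equal(flat$tau2, 0)
  # with tau2 = 0 DL reduces to inverse-variance fixed effect
  w <- 1 / eff$se^2
  fe <- sum(w * eff$log_or) / sum(w)
  flat2 <- pool_dl(study_effects(d[c(1, 1, 1), ]))
  expect_equal(flat2$tau2, 0)
  expect_equal(flat2$log_or, study_effects(d[1, ])$log_or)
  expect_true(fe >= min(eff$log_or) && fe <= max(eff$log_or))
})

test_that("pooled log OR stays inside the per-study range (convexity)", {
  withr::with_seed(14, {
    for (i in 1:5) {
      sim <- simulate_meta_studies(k = 8, seed = 100 + i)
      eff <- study_effects(sim$studies)
      pooled <- pool_dl(eff)
      expect_gte(pooled$log_or, min(eff$log_or) - 1e-12)
      expect_lte(pooled$log_or, max(eff$log_or) + 1e-12)
    }
  })
})

test_that("Mantel-Haenszel pooling matches hand sums and metafor", {
  # a single stratum replicated: MH OR equals that stratum's OR
  one <- toy_studies(rep(17, 5), rep(16, 5), rep(8, 5), rep(25, 5))
  expect_equal(pool_mh(one)$pooled_or, 128 / 425, tolerance = 1e-12)

  two <- toy_studies(c(20, 8), c(12, 30), c(35, 14), c(18, 40))
  # a = present cases, d = null controls; n = stratum total
  n <- c(20 + 12 + 35 + 18, 8 + 30 + 14 + 40)
  R <- sum(c(12, 30) * c(35, 14) / n)
  S <- sum(c(18, 40) * c(20, 8) / n)
  expect_equal(pool_mh(two)$pooled_or, R / S, tolerance = 1e-12)

  d <- load_fixture("gstm1_atdh")
  mh <- pool_mh(d)
  fit <- metafor::rma.mh(ai = d$case_present, bi = d$case_null,
                         ci = d$control_present, di = d$control_null,
                         measure = "OR")
  expect_equal(mh$log_or, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(mh$se, fit$se, tolerance = 1e-10)
  # crude Total-row cross product (331*981)/(348*1308) ~ 0.713 brackets it
  expect_gt(mh$pooled_or, 0.6)
  expect_lt(mh$pooled_or, 0.8)
})

test_that("model selection switches at twenty studies", {
  expect_identical(select_model(14), "DL_random")
  expect_identical(select_model(2), "DL_random")
  expect_identical(select_model(19), "DL_random")
  expect_identical(select_model(20), "MH_fixed")
  expect_error(select_model(1), "at least 2")
})

test_that("leave-one-out re-pools the complement under the alternate model", {
  d <- load_fixture("gstm1_atdh")
  loo <- leave_one_out(d)  # 14 studies -> primary DL, sensitivity MH
  expect_identical(attr(loo, "model"), "MH_fixed")
  expect_equal(nrow(loo), 14L)
  # every omission keeps the association significant, as published
  expect_lt(max(loo$p), 0.05)

  # three studies: each row equals pooling the complementary pair
  tri <- toy_studies(c(20, 15, 30), c(10, 25, 12), c(40, 30, 50),
                     c(20, 35, 28))
  l3 <- leave_one_out(tri, model = "DL_random")
  for (i in 1:3) {
    ref <- pool_studies(tri[-i, ], model = "DL_random")
    expect_equal(l3$pooled_or[i], ref$pooled_or)
    expect_equal(l3$p[i], ref$p)
  }
  same <- toy_studies(rep(20, 4), rep(10, 4), rep(40, 4), rep(20, 4))
  ls <- leave_one_out(same, model = "DL_random")
  expect_equal(ls$pooled_or, rep(1, 4))
  expect_error(leave_one_out(tri[1:2, ]), "at least 3")
})

test_that("Harbord's regression matches the normal-equations oracle", {
  d <- toy_studies(c(20, 8, 33, 15), c(12, 30, 21, 45),
                   c(35, 14, 40, 22), c(18, 40, 29, 61))
  a <- d$case_present; b <- d$control_present
  cc <- d$case_null; dd <- d$control_null
  n <- a + b + cc + dd
  Z <- a - (a + b) * (a + cc) / n
  V <- (a + b) * (cc + dd) * (a + cc) * (b + dd) / (n^2 * (n - 1))
  y <- Z / sqrt(V); x <- sqrt(V)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - slope * mean(x)
  res <- y - alpha - slope * x
  s2 <- sum(res^2) / (4 - 2)
  se_alpha <- sqrt(s2 * (1 / 4 + mean(x)^2 / sum((x - mean(x))^2)))
  ht <- harbord_test(d)
  expect_equal(ht$intercept, alpha, tolerance = 1e-10)
  expect_equal(ht$se, se_alpha, tolerance = 1e-10)
  expect_equal(ht$t, alpha / se_alpha, tolerance = 1e-10)
  expect_equal(ht$p, 2 * pt(-abs(alpha / se_alpha), 2), tolerance = 1e-10)

  # independence tables have zero efficient score: intercept exactly 0
  nul <- toy_studies(c(20, 40, 10), c(10, 20, 5), c(40, 80, 30),
                     c(20, 40, 15))
  expect_equal(harbord_test(nul)$intercept, 0, tolerance = 1e-12)
  expect_error(harbord_test(d[1:2, ]), "at least 3")
})

test_that("genotype summary reports published totals and frequencies", {
  gs <- genotype_summary(load_fixture("gstm1_atdh"))
  expect_equal(unname(gs$totals),
               c(348, 331, 981, 1308))
  expect_equal(gs$n_minor, 1329)
  expect_identical(gs$minor_genotype, "null")
  expect_equal(gs$null_freq_cases, 100 * 348 / 679)
})
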