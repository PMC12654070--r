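test_that("the Wald ratio and its delta-method SEs follow the closed forms", {
  wr <- wald_ratio(0.5, 0.05, 0.25, 0.1)
  expect_equal(wr$beta_mr, 0.5)
  expect_equal(wr$se_mr, 0.2)

  wr2 <- wald_ratio(0.5, 0.05, 0.25, 0.1, se_method = "second_order")
  expect_equal(wr2$se_mr, sqrt(0.04 + 0.0025))

  expect_error(wald_ratio(0, 0.05, 0.25, 0.1), "nonzero")
})

test_that("second-order SE dominates first-order and matches a bootstrap oracle", {
  set.seed(101)
  for (i in 1:20) {
    bx <- runif(1, 0.1, 1) * sample(c(-1, 1), 1)
    se_x <- abs(bx) / runif(1, 11, 50)  # strong instrument: |bx|/se_x > 10
    by <- runif(1, -0.5, 0.5)
    se_y <- runif(1, 0.05, 0.3)
    first <- wald_ratio(bx, se_x, by, se_y)$se_mr
    second <- wald_ratio(bx, se_x, by, se_y, "second_order")$se_mr
    expect_gte(second, first)
  }
  # parametric bootstrap of the ratio at one strong-instrument setting
  set.seed(202)
  bx <- 0.5; se_x <- 0.02; by <- 0.25; se_y <- 0.1
  draws <- rnorm(1e6, by, se_y) / rnorm(1e6, bx, se_x)
  expect_equal(wald_ratio(bx, se_x, by, se_y)$se_mr, sd(draws),
               tolerance = 0.02)
})

test_that("Wald ratio is sign-symmetric and scale-equivariant", {
  set.seed(11)
  for (i in 1:20) {
    bx <- runif(1, 0.1, 1)
    se_x <- runif(1, 0.01, 0.1)
    by <- runif(1, -0.5, 0.5)
    se_y <- runif(1, 0.01, 0.3)
    base <- wald_ratio(bx, se_x, by, se_y)
    neg <- wald_ratio(-bx, se_x, by, se_y)
    expect_equal(neg$beta_mr, -base$beta_mr)
    expect_equal(neg$se_mr, base$se_mr)
    cc <- runif(1, 0.2, 5)
    scaled <- wald_ratio(cc * bx, cc * se_x, by, se_y)
    expect_equal(scaled$beta_mr, base$beta_mr / cc)
    expect_equal(scaled$se_mr, base$se_mr / cc)
  }
})

test_that("odds-ratio conversion reproduces the headline CLL estimate", {
  # SE implied by the reported interval (1.45, 3.31)
  se <- (log(3.31) - log(1.45)) / (2 * qnorm(0.975))
  orci <- to_odds_ratio(log(2.19), se)
  expect_equal(orci$or, 2.19)
  expect_equal(orci$ci_low, 1.45, tolerance = 0.005)
  expect_equal(orci$ci_high, 3.31, tolerance = 0.005)
  expect_equal(signif(orci$pval, 1), 2e-4)

  # null estimate: OR 1, p 1, CI symmetric about 1 on the log scale
  null <- to_odds_ratio(0, 0.2)
  expect_equal(null$or, 1)
  expect_equal(null$pval, 1)
  expect_equal(null$ci_low * null$ci_high, 1, tolerance = 1e-12)

  # negation maps OR to its reciprocal and mirrors the CI
  a <- to_odds_ratio(0.7, 0.21)
  b <- to_odds_ratio(-0.7, 0.21)
  expect_equal(b$or, 1 / a$or)
  expect_equal(b$ci_low, 1 / a$ci_high)
  expect_equal(b$ci_high, 1 / a$ci_low)
  expect_equal(b$pval, a$pval)
})

test_that("significance tiers follow the Bonferroni-within-outcome rule", {
  cfg <- multiplicity_config(83)
  expect_equal(cfg$bonferroni_threshold, 0.05 / 83)
  expect_equal(classify_significance(2e-4, cfg), "significant")
  expect_equal(classify_significance(0.01, cfg), "suggestive")
  expect_equal(classify_significance(0.2, cfg), "null")
  # boundary: exactly the threshold is not significant
  expect_equal(classify_significance(cfg$bonferroni_threshold, cfg),
               "suggestive")
  expect_error(multiplicity_config(0), "at least 1")
})

test_that("CI consistency recovers printed ORs as geometric means", {
  d <- ci_consistency(2.19, 1.45, 3.31)
  expect_equal(d$implied_or, sqrt(1.45 * 3.31))
  expect_true(d$pass)

  d2 <- ci_consistency(2.83, 1.01, 7.93)
  expect_equal(round(d2$implied_or, 2), 2.83)

  # inverting the interval inverts the implied OR exactly
  a <- ci_consistency(2.19, 1.45, 3.31)
  b <- ci_consistency(1 / 2.19, 1 / 3.31, 1 / 1.45)
  expect_equal(b$implied_or, 1 / a$implied_or)
  expect_equal(b$implied_p, a$implied_p)

  expect_error(ci_consistency(1, 2, 1), "ci_low")
})

test_that("mr_wald sizes the Bonferroni family by the tests performed", {
  sen <- select_sentinels(make_table(list(
    make_record(rsid = "rs1", trait_id = "m1", beta = 0.5, se = 0.02),
    make_record(rsid = "rs2", trait_id = "m2", beta = 0.5, se = 0.02),
    make_record(rsid = "rs3", trait_id = "m3", effect_allele = "A",
                other_allele = "T", eaf = 0.5, beta = 0.5, se = 0.02)
  )))
  sen <- find_proxies(sen, paste0("rs", 1:3), ld = NULL)
  outcomes <- validate_summary_stats(make_table(list(
    make_record(rsid = "rs1", trait_id = "CLL", beta = 0.40, se = 0.05,
                n = 5e4, n_cases = 100),
    make_record(rsid = "rs2", trait_id = "CLL", beta = 0.01, se = 0.05,
                n = 5e4, n_cases = 100),
    make_record(rsid = "rs3", trait_id = "CLL", effect_allele = "A",
                other_allele = "T", eaf = 0.5, beta = 0.1, se = 0.05,
                n = 5e4, n_cases = 100)
  )), trait_kind = "outcome_binary")
  pairs <- harmonize_all(sen, outcomes)
  res <- mr_wald(pairs, outcome_id = "CLL")
  # the palindromic-ambiguous pair is not a test
  expect_equal(nrow(res), 2)
  expect_equal(unique(res$n_tests), 2)
  expect_equal(res$beta_mr, c(0.40, 0.01) / 0.5, tolerance = 1e-12)
  expect_equal(res$or, exp(res$beta_mr))
  expect_true(all(res$ci_low < res$or & res$or < res$ci_high))
  expect_equal(res$method, rep("wald_ratio", 2))
  expect_equal(res$n_snv, rep(1L, 2))
})
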