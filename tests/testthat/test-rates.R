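test_that("the survival model recovers generating coefficients within 2 SE", {
  coefs <- table1_survival_coefs()
  by <- simulate_survival_data(5000, coefs, seed = 3)
  fs <- fit_survival(by)
  tab <- fs$coefficients
  est <- tab$estimate[tab$term == "tacticT25"]
  se <- tab$se[tab$term == "tacticT25"]
  expect_lt(abs(est - coefs[["tactic25"]]), 2 * se)
  expect_equal(fs$family, "binomial")
  expect_equal(nrow(tab), 6)
  # the additive model was selected: interaction LRT not significant here
  expect_true(is.null(fs$interaction_lrt) || fs$interaction_lrt$p >= 0.05 ||
                length(fs$beta) == 10)
})

test_that("all-identical outcomes stop the survival fit with a separation message", {
  by <- simulate_survival_data(200, table1_survival_coefs(), seed = 4)
  by$survived <- TRUE
  by$cause_of_death <- "none"
  expect_error(fit_survival(by), "separation")
})

test_that("the recruitment model recovers the tactic contrast within 2 SE", {
  br <- simulate_recruit_data(500, 4, intercept = -0.923, tactic25 = -0.425,
                              seed = 5)
  fr <- fit_recruitment(br)
  tab <- fr$coefficients
  est <- tab$estimate[tab$term == "tacticT25"]
  se <- tab$se[tab$term == "tacticT25"]
  expect_lt(abs(est - (-0.425)), 2 * se)
  expect_equal(fr$link, "log")
  expect_error(fit_recruitment(br[0, ]), "no adult")
  zero <- br
  zero$recruits <- 0L
  expect_error(fit_recruitment(zero), "all counts are zero")
})

test_that("likelihood-ratio comparison matches a brute-force deviance difference", {
  set.seed(6)
  d <- data.frame(
    y = stats::rbinom(50, 1, 0.6),
    x = rep(c(0, 1), 25)
  )
  f_full <- stats::glm(y ~ x, data = d, family = stats::binomial)
  f_red <- stats::glm(y ~ 1, data = d, family = stats::binomial)
  mk <- function(fit, form) caretactics:::new_model_fit(
    fit, form, "binomial", "logit", character(), nrow(d))
  lrt <- lrt_compare(mk(f_full, "y ~ x"), mk(f_red, "y ~ 1"))
  # oracle: binomial log-likelihood computed from predicted probabilities
  ll <- function(fit) {
    p <- stats::fitted(fit)
    sum(d$y * log(p) + (1 - d$y) * log(1 - p))
  }
  expect_equal(lrt$statistic, 2 * (ll(f_full) - ll(f_red)),
               tolerance = 1e-8)
  expect_equal(lrt$df, 1)
  # identical models: zero statistic, p = 1
  same <- lrt_compare(mk(f_red, "y ~ 1"), mk(f_red, "y ~ 1"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(lrt_compare(mk(f_red, "y ~ 1"), mk(f_full, "y ~ x")),
               "nested")
})

test_that("zero coefficient uncertainty collapses the rate table to point values", {
  fs <- manual_model_fit(table1_survival_coefs())
  fr <- manual_model_fit(table1_recruitment_coefs(), family = "nb",
                         link = "log")
  rt <- bootstrap_rates(fs, fr, n_bootstrap = 200, seed = 1)
  expect_equal(rt$mean, rt$point, tolerance = 1e-12)
  expect_equal(rt$ci_low, rt$mean, tolerance = 1e-12)
  expect_equal(rt$ci_high, rt$mean, tolerance = 1e-12)
  # closed-form values from the printed coefficients
  s1_t15 <- rt$point[rt$tactic == "T15" & rt$cell == "S1"]
  s1_t25 <- rt$point[rt$tactic == "T25" & rt$cell == "S1"]
  expect_equal(s1_t15, stats::plogis(1.430), tolerance = 1e-12)
  expect_equal(round(s1_t15, 3), 0.807)
  expect_equal(s1_t25, stats::plogis(1.430 + 0.761), tolerance = 1e-12)
  expect_equal(round(s1_t25, 3), 0.899)
  r15 <- rt$point[rt$tactic == "T15" & rt$cell == "R5-9"]
  expect_equal(r15, exp(-0.923), tolerance = 1e-12)
  # the two recruitment age classes share one value within a tactic
  expect_equal(rt$mean[rt$cell == "R5-9"], rt$mean[rt$cell == "R10+"])
})

test_that("rate CI width shrinks monotonically as coefficient uncertainty vanishes", {
  by <- simulate_survival_data(2000, table1_survival_coefs(), seed = 7)
  fs <- fit_survival(by, test_interaction = FALSE)
  br <- simulate_recruit_data(200, 4, seed = 7)
  fr <- fit_recruitment(br)
  widths <- sapply(c(1, 0.25, 0), function(sc) {
    rt <- bootstrap_rates(fs, fr, n_bootstrap = 2000, seed = 2,
                          scale_vcov = sc)
    mean(rt$ci_high - rt$ci_low)
  })
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[3], 0, tolerance = 1e-12)
})

test_that("bootstrap draws are deterministic given the seed and stay in range", {
  fs <- manual_model_fit(table1_survival_coefs(),
                         vcov = diag(0.05, 6))
  fr <- manual_model_fit(table1_recruitment_coefs(), vcov = diag(0.02, 2))
  r1 <- bootstrap_rates(fs, fr, n_bootstrap = 500, seed = 9)
  r2 <- bootstrap_rates(fs, fr, n_bootstrap = 500, seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  s <- r1[grepl("^S", r1$cell), ]
  expect_true(all(s$mean > 0 & s$mean < 1))
  expect_true(all(r1$ci_low <= r1$mean & r1$mean <= r1$ci_high))
  expect_true(all(r1$mean[grepl("^R", r1$cell)] > 0))
})

test_that("family-group status decomposes mortality as in the monitoring data", {
  # 55 hunting + 10 other deaths among 407 solitary bear-years,
  # 9 hunting + 3 other among 207 family-group bear-years
  by <- rbind(status_records(407, 55, 10, "solitary", "S"),
              status_records(207, 9, 3, "with_offspring", "F"))
  pe <- protection_effect(by)
  r <- pe$rates
  sol <- r[r$status == "solitary", ]
  fam <- r[r$status == "family_group", ]
  expect_equal(round(sol$hunting_mortality, 2), 0.14)
  expect_equal(round(fam$hunting_mortality, 2), 0.04)
  expect_equal(round(c(sol$hunting_low, sol$hunting_high), 2),
               c(0.10, 0.17))
  expect_equal(round(c(fam$hunting_low, fam$hunting_high), 2),
               c(0.02, 0.07))
  # hunting mortality never exceeds total mortality, by construction
  expect_true(all(r$hunting_mortality <= r$mortality))
  expect_true(pe$odds_ratio < 1) # being solitary reduces survival odds
  expect_gt(pe$hunting_odds_ratio, 1)
})

test_that("degenerate status data yield rates without an odds ratio", {
  by <- status_records(50, 0, 0, "solitary")
  pe <- protection_effect(by)
  expect_equal(pe$rates$mortality, 0)
  expect_match(pe$flag, "single status")
  expect_null(pe$odds_ratio)
})
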