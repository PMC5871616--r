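test_that("the Leslie matrix has the documented fecundity row and survival band", {
  A <- table2_leslie("T15")
  M <- unclass(A)
  F48 <- 0.973 * 0.384
  expect_equal(M[1, ], c(0, 0, 0, rep(F48, 5), 0.841 * 0.384))
  expect_equal(M[cbind(2:9, 1:8)],
               c(0.809, 0.844, 0.916, rep(0.973, 5)))
  expect_equal(M[9, 9], 0.841)
  expect_equal(sum(M != 0), 6 + 8 + 1)
  expect_error(build_leslie(1.2, 0.8, 0.8, 0.9, 0.8, 0.3), "\\[0, 1\\]")
  expect_error(build_leslie(0.8, 0.8, 0.8, 0.9, 0.8, -0.1), ">= 0")
})

test_that("zero recruitment empties the fecundity row and zero survival kills growth", {
  A0 <- build_leslie(0.8, 0.8, 0.9, 0.95, 0.85, 0)
  expect_equal(unclass(A0)[1, ], rep(0, 9))
  expect_warning(l <- leslie_lambda(A0), "reducible")
  dead <- build_leslie(0, 0, 0, 0, 0, 0.5)
  expect_equal(suppressWarnings(leslie_lambda(dead)), 0)
})

test_that("with no fertility the dominant eigenvalue is the 9+ self-loop survival", {
  A <- build_leslie(0.6, 0.7, 0.8, 0.85, 0.9, 0)
  expect_equal(suppressWarnings(leslie_lambda(A)), 0.9, tolerance = 1e-12)
})

test_that("the growth rate satisfies the renewal (Euler-Lotka) equation", {
  A <- table2_leslie("T15")
  lam <- leslie_lambda(A)
  expect_lt(abs(euler_lotka_residual(A, lam)), 1e-10)
  set.seed(42)
  for (i in 1:25) {
    B <- random_leslie()
    expect_lt(abs(euler_lotka_residual(B, leslie_lambda(B))), 1e-10)
  }
})

test_that("R0 by fundamental matrix equals the closed-form lifetime sum", {
  A <- table2_leslie("T15")
  expect_lt(abs(net_reproductive_rate(A, "fundamental") -
                  net_reproductive_rate(A, "lifetime")), 1e-10)
  expect_equal(net_reproductive_rate(build_leslie(0.8, 0.8, 0.9, 0.95,
                                                  0.85, 0)), 0)
  expect_error(net_reproductive_rate(build_leslie(0.8, 0.8, 0.9, 0.95, 1,
                                                  0.3)), "diverges")
})

test_that("generation time satisfies its defining identity", {
  expect_equal(generation_time(2, 2), 1) # lambda = R0 by definition
  A <- table2_leslie("T25")
  lam <- leslie_lambda(A)
  R0 <- net_reproductive_rate(A)
  T_ <- generation_time(lam, R0)
  expect_lt(abs(lam^T_ - R0), 1e-12)
  expect_equal(generation_time(A), T_)
  expect_error(generation_time(1, 2), "indeterminate")
})

test_that("the stable age vector matches long-run projection", {
  A <- table2_leslie("T15")
  sa <- stable_age(A)
  expect_equal(sum(sa$w), 1, tolerance = 1e-12)
  expect_true(all(sa$w >= 0))
  v <- rep(1, 9)
  M <- unclass(A)
  for (i in 1:500) {
    v <- M %*% v
    v <- v / sum(v)
  }
  expect_equal(as.numeric(v), sa$w, tolerance = 1e-6)
  expect_equal(sa$adult_fraction, sum(sa$w[4:9]))
})

test_that("lambda increases in every survival and recruitment entry", {
  set.seed(7)
  A <- random_leslie()
  r <- attr(A, "rates")
  lam0 <- leslie_lambda(A)
  eps <- 1e-4
  for (k in 1:6) {
    rr <- r
    rr[k] <- rr[k] + eps
    B <- build_leslie(rr[1], rr[2], rr[3], rr[4], rr[5], rr[6], rr[6])
    expect_gt(leslie_lambda(B), lam0)
  }
})

test_that("lambda and R0 sit on the same side of 1", {
  set.seed(13)
  for (i in 1:200) {
    A <- random_leslie()
    lam <- leslie_lambda(A)
    R0 <- net_reproductive_rate(A)
    expect_equal(sign(lam - 1), sign(R0 - 1))
  }
})

test_that("elasticities are a non-negative unit-sum perturbation budget", {
  A <- table2_leslie("T25")
  E <- leslie_elasticity(A)
  expect_equal(sum(E), 1, tolerance = 1e-10)
  expect_true(all(E >= -1e-12))
  expect_true(all(E[unclass(A) == 0] == 0))
  # survival transitions dominate reproduction in this long-lived system
  expect_gt(sum(E[-1, ]), sum(E[1, ]))
})

test_that("bootstrap demography collapses to point summaries without uncertainty", {
  fs <- manual_model_fit(table1_survival_coefs())
  fr <- manual_model_fit(table1_recruitment_coefs())
  rt <- bootstrap_rates(fs, fr, n_bootstrap = 100, seed = 1)
  bd <- bootstrap_demography(rt)
  for (tac in c("T15", "T25")) {
    s <- bd$summary[bd$summary$tactic == tac, ]
    p <- bd$point[[tac]]
    expect_equal(s$mean[s$metric == "lambda"], p$lambda, tolerance = 1e-10)
    expect_equal(s$ci_low[s$metric == "T"], p$T, tolerance = 1e-10)
    expect_equal(s$ci_high[s$metric == "T"], p$T, tolerance = 1e-10)
  }
  expect_equal(bd$n_dropped, 0)
})

test_that("identical tactics give an exceedance probability of one half", {
  beta <- table1_survival_coefs()
  beta["tactic25"] <- 0
  fs <- manual_model_fit(beta)
  fr <- manual_model_fit(c(intercept = -0.923, tactic25 = 0))
  rt <- bootstrap_rates(fs, fr, n_bootstrap = 100, seed = 1)
  bd <- bootstrap_demography(rt)
  expect_equal(bd$p_T25_longer_T, 0.5)
})

test_that("demographic uncertainty propagates to interval summaries", {
  fs <- manual_model_fit(table1_survival_coefs(), vcov = diag(0.04, 6))
  fr <- manual_model_fit(table1_recruitment_coefs(), vcov = diag(0.02, 2))
  rt <- bootstrap_rates(fs, fr, n_bootstrap = 3000, seed = 3)
  bd <- bootstrap_demography(rt)
  s <- bd$summary
  expect_true(all(s$ci_low < s$ci_high))
  lam15 <- s[s$tactic == "T15" & s$metric == "lambda", ]
  expect_true(lam15$ci_low < bd$point$T15$lambda &
                bd$point$T15$lambda < lam15$ci_high)
})
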