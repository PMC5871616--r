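test_that("the pressure index equals brute-force counting", {
  by <- rbind(
    status_records(20, 0, 0, "solitary", "A"),      # 0 shot of 20
    status_records(12, 3, 0, "solitary", "B"),      # 3 shot of 12
    status_records(5, 0, 1, "with_offspring", "C")  # protected: excluded
  )
  by$year <- c(rep(2001L, 20), rep(2002L, 12), rep(2002L, 5))
  pr <- pressure_index(by)
  expect_equal(pr$h[pr$year == 2001], 0)
  expect_equal(pr$h[pr$year == 2002], 0.25)
  expect_equal(pr$n_available[pr$year == 2002], 12)
  expect_true(all(pr$n_shot <= pr$n_available))
})

test_that("years with no available bears get a missing index, not zero", {
  by <- status_records(8, 0, 0, "with_offspring")
  by$year <- 2003L
  pr <- pressure_index(by)
  expect_true(is.na(pr$h))
})

test_that("accidental kills of protected females do not enter the index", {
  by <- rbind(status_records(10, 0, 0, "solitary", "A"),
              status_records(10, 2, 0, "with_offspring", "B"))
  by$year <- 2001L
  pr <- pressure_index(by)
  expect_equal(pr$n_shot, 0)
  expect_equal(pr$n_available, 10)
})

test_that("the simulator reproduces its configured pressure in the index", {
  press <- 0.2
  cfg <- simulation_config(
    n_initial_females = 500, n_years = 12, seed = 19,
    hunting_pressure = press,
    survival_by = matrix(rep(c(0.75, 0.78, 0.78, 0.88, 0.80), 2), 5, 2)
  )
  sim <- simulate_population(cfg)
  pr <- pressure_index(sim$bear_years)
  for (i in seq_len(nrow(pr))) {
    se <- sqrt(press * (1 - press) / pr$n_available[i])
    expect_lt(abs(pr$h[i] - press), 3 * se)
  }
})

test_that("protected classes show no pressure response while exposed classes decline", {
  press <- rep(seq(0.02, 0.30, length.out = 8), length.out = 28)
  cfg <- simulation_config(
    n_initial_females = 300, n_years = 28, seed = 5,
    hunting_pressure = press, calibration_pressure = 0,
    survival_by = matrix(rep(c(0.93, 0.93, 0.95, 0.99, 0.93), 2), 5, 2)
  )
  sim <- simulate_population(cfg)
  pr <- pressure_index(sim$bear_years)
  pm <- fit_pressure_models(sim$bear_years, pr, n_draws = 200, seed = 2)
  slope <- function(key) unname(pm$cells[[key]]$coef[2])
  # T25 yearlings ride with their mother: immune to pressure
  expect_gt(slope("T25.1"), -1)
  # exposed yearlings and adults decline steeply
  expect_lt(slope("T15.1"), -2)
  expect_lt(slope("T15.4-8"), -2)
  # T25 adults are shielded 2 of 3 years: attenuated but negative response
  expect_lt(slope("T25.4-8"), 0)
  expect_gt(slope("T25.4-8"), slope("T15.4-8"))
})

test_that("constant pressure is flagged non-estimable", {
  cfg <- simulation_config(n_initial_females = 150, n_years = 10, seed = 3)
  sim <- simulate_population(cfg) # default pressure is constant
  pr <- pressure_index(sim$bear_years)
  pr$h <- 0.05
  expect_warning(pm <- fit_pressure_models(sim$bear_years, pr,
                                           n_draws = 50, seed = 1),
                 "non-estimable")
  expect_true(all(!vapply(pm$cells, `[[`, TRUE, "estimable")))
})

test_that("null pressure slopes cover zero at close to nominal rate", {
  # survival unrelated to pressure: the slope CI should cover 0 in >= 90%
  # of replicates
  set.seed(77)
  covered <- vapply(1:100, function(i) {
    h <- rep(stats::runif(12, 0, 0.3), each = 25)
    surv <- stats::rbinom(length(h), 1, 0.9)
    fit <- stats::glm(surv ~ h, family = stats::binomial)
    ci <- suppressMessages(stats::confint.default(fit)["h", ])
    ci[1] <= 0 && 0 <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("zero slopes make lambda flat in pressure; negative slopes make it fall", {
  mk_cell <- function(int, slope, n = 100) {
    list(tactic = "x", age_class = "x", n_obs = 500, estimable = TRUE,
         coef = c(int, slope),
         draws = matrix(rep(c(int, slope), each = n), n, 2))
  }
  cells <- list()
  for (tac in c("T15", "T25")) {
    for (cls in c("1", "2", "3", "4-8", "9+")) {
      slope <- if (tac == "T15") -4 else 0
      cells[[paste(tac, cls, sep = ".")]] <- mk_cell(2.2, slope)
    }
  }
  pm <- structure(list(cells = cells, n_draws = 100),
                  class = "pressure_models")
  lv <- lambda_vs_pressure(pm, c(T15 = 0.384, T25 = 0.251), n_draws = 100)
  q <- lv$quantiles
  flat <- q$median[q$tactic == "T25"]
  expect_equal(max(flat) - min(flat), 0, tolerance = 1e-12)
  falling <- q$median[q$tactic == "T15"]
  expect_true(all(diff(falling) < 0))
})

test_that("the fitness gap between tactics widens with hunting pressure", {
  press <- rep(seq(0.02, 0.30, length.out = 8), length.out = 28)
  cfg <- simulation_config(
    n_initial_females = 300, n_years = 28, seed = 5,
    hunting_pressure = press, calibration_pressure = 0,
    survival_by = matrix(rep(c(0.93, 0.93, 0.95, 0.99, 0.93), 2), 5, 2)
  )
  sim <- simulate_population(cfg)
  pm <- fit_pressure_models(sim$bear_years, pressure_index(sim$bear_years),
                            n_draws = 500, seed = 2)
  lv <- lambda_vs_pressure(pm, c(T15 = 0.384, T25 = 0.251), n_draws = 500)
  q <- lv$quantiles
  gap <- q$median[q$tactic == "T25"] - q$median[q$tactic == "T15"]
  expect_true(all(diff(gap) > -1e-9))
  expect_gt(gap[length(gap)], gap[1])
})
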