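make_history <- function(mother, durations, start = 2000L) {
  n <- length(durations)
  birth <- start + 3L * seq_len(n)
  data.frame(
    litter_id = paste0(mother, "-", seq_len(n)), mother_id = mother,
    birth_year = birth,
    weaning_year = birth + ifelse(durations == 2.5, 2L, 1L),
    care_duration = as.character(durations), litter_size = 2L,
    mother_primiparous = c("true", rep("false", n - 1)),
    stringsAsFactors = FALSE
  )
}

test_that("tactic classification applies the mean-care >= 2 rule", {
  li <- rbind(make_history("A", c(1.5, 2.5, 2.5)),
              make_history("B", c(1.5, 1.5)),
              make_history("C", 2.5),
              make_history("D", c(1.5, 2.5))) # mean exactly 2.0
  asg <- assign_tactics(li)
  a <- asg[match(c("A", "B", "C", "D"), asg$bear_id), ]
  expect_equal(a$mean_care_duration, c(13 / 6, 1.5, 2.5, 2.0))
  expect_equal(a$tactic, c("T25", "T15", "T25", "T25"))
  expect_equal(a$consistent, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(a$n_litters, c(3L, 2L, 1L, 2L))
})

test_that("classification is idempotent and order-independent", {
  sim <- simulate_population(simulation_config(n_initial_females = 40,
                                               n_years = 15, seed = 8))
  asg1 <- suppressWarnings(assign_tactics(sim$litters))
  shuffled <- sim$litters[sample(nrow(sim$litters)), ]
  asg2 <- suppressWarnings(assign_tactics(shuffled))
  expect_equal(asg1[order(asg1$bear_id), ], asg2[order(asg2$bear_id), ],
               ignore_attr = TRUE)
  expect_warning(
    asg3 <- assign_tactics(rbind(sim$litters,
                                 litter_row(mother_id = "ghost",
                                            care_duration = "lost",
                                            weaning_year = NA_integer_))),
    "no weaned litter")
  expect_false("ghost" %in% asg3$bear_id)
})

test_that("the weaning trend model recovers a known annual odds ratio", {
  # single-fit sanity at a generous size; the replicate-averaged version
  # lives in the acceptance suite
  li <- simulate_care_histories(300, 3, mu = -1, sigma2_ind = 0.8,
                                slope = log(1.17), seed = 21)
  tr <- weaning_trend(li)
  expect_true(tr$estimable)
  expect_gt(tr$annual_odds_ratio, 1.05)
  expect_lt(tr$annual_odds_ratio, 1.30)
  expect_true(tr$ci_low <= tr$annual_odds_ratio &
                tr$annual_odds_ratio <= tr$ci_high)
})

test_that("the trend odds ratio is invariant to shifting all years", {
  li <- simulate_care_histories(80, 3, mu = -0.5, sigma2_ind = 1,
                                slope = log(1.1), seed = 9)
  tr1 <- weaning_trend(li)
  li2 <- li
  li2$birth_year <- li2$birth_year + 7L
  li2$weaning_year <- li2$weaning_year + 7L
  tr2 <- weaning_trend(li2)
  expect_equal(tr1$annual_odds_ratio, tr2$annual_odds_ratio,
               tolerance = 1e-8)
})

test_that("degenerate trend inputs are flagged, not fatal", {
  one_year <- make_history("A", 1.5)
  for (m in c("B", "C")) one_year <- rbind(one_year, make_history(m, 2.5))
  one_year$birth_year <- 2005L
  one_year$weaning_year <- 2005L + ifelse(one_year$care_duration == "2.5",
                                          2L, 1L)
  expect_false(weaning_trend(one_year)$estimable)
  all_t15 <- rbind(make_history("A", c(1.5, 1.5)),
                   make_history("B", c(1.5, 1.5), start = 2005L))
  expect_false(weaning_trend(all_t15)$estimable)
})

test_that("repeatability detects no signal in exchangeable litters", {
  li <- simulate_care_histories(150, 3, mu = -0.5, sigma2_ind = 0,
                                seed = 10)
  r <- care_repeatability(li, n_bootstrap = 50, seed = 1)
  expect_lt(r$r_original, 0.1)
  expect_lte(r$ci_low, 0.05)
})

test_that("perfectly consistent females give repeatability at the upper boundary", {
  li <- rbind(
    do.call(rbind, lapply(1:8, function(i)
      make_history(paste0("A", i), c(1.5, 1.5, 1.5)))),
    do.call(rbind, lapply(1:8, function(i)
      make_history(paste0("B", i), c(2.5, 2.5, 2.5))))
  )
  r <- care_repeatability(li, n_bootstrap = 20, seed = 1)
  expect_gt(r$r_original, 0.8)
  expect_lte(r$r_original, 1)
})

test_that("repeatability is invariant to relabeling the binary response", {
  li <- simulate_care_histories(60, 3, mu = -0.4, sigma2_ind = 1.6,
                                seed = 12)
  swapped <- li
  swapped$care_duration <- ifelse(li$care_duration == "2.5", "1.5", "2.5")
  swapped$weaning_year <- swapped$birth_year +
    ifelse(swapped$care_duration == "2.5", 2L, 1L)
  r1 <- care_repeatability(li, n_bootstrap = 10, seed = 1)
  r2 <- care_repeatability(swapped, n_bootstrap = 10, seed = 1)
  expect_equal(r1$r_original, r2$r_original, tolerance = 0.02)
})

test_that("repeatability refuses samples with fewer than five repeat females", {
  li <- rbind(make_history("A", c(1.5, 2.5)), make_history("B", c(2.5, 2.5)),
              make_history("C", 1.5))
  expect_error(care_repeatability(li), ">= 5 females")
})

test_that("primiparity effect: null case covers 1, separation is flagged", {
  set.seed(31)
  li <- simulate_care_histories(120, 3, mu = -0.7, sigma2_ind = 0.8,
                                seed = 31)
  li$mother_primiparous <- ifelse(!duplicated(li$mother_id), "true", "false")
  pe <- primiparity_effect(li)
  expect_true(pe$estimable)
  expect_true(pe$ci_low < 1 & 1 < pe$ci_high)
  # all primiparous litters one tactic, all multiparous the other
  sep <- rbind(
    do.call(rbind, lapply(1:6, function(i) {
      h <- make_history(paste0("P", i), c(1.5, 2.5))
      h$mother_primiparous <- c("true", "false")
      h
    }))
  )
  expect_false(primiparity_effect(sep)$estimable)
})

test_that("consistency summary reports percentages and a pooled-variance t-test", {
  li <- rbind(make_history("A", c(1.5, 1.5)), make_history("B", c(2.5, 2.5)),
              make_history("C", c(1.5, 1.5)), make_history("D", c(1.5, 1.5)),
              make_history("E", c(2.5, 2.5)), make_history("F", c(1.5, 2.5)),
              make_history("G", c(1.5, 2.5)), make_history("H", c(2.5, 1.5)))
  asg <- assign_tactics(li)
  ages <- c(A = 8, B = 10, C = 9, D = 12, E = 7, F = 11, G = 10, H = 9)
  by <- do.call(rbind, lapply(names(ages), function(id)
    bear_year_row(bear_id = id, age = as.integer(ages[[id]]),
                  recruits = NA_integer_)))
  cs <- consistency_summary(asg, by)
  expect_equal(cs$pct_consistent_multi, 62.5) # 5 of 8 multi-litter females
  expect_equal(cs$n_multi, 8)
  # oracle: textbook pooled-variance two-sample t on the same groups
  g1 <- ages[c("A", "B", "C", "D", "E")]; g2 <- ages[c("F", "G", "H")]
  sp2 <- ((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) /
    (length(g1) + length(g2) - 2)
  t_manual <- (mean(g1) - mean(g2)) /
    sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
  expect_equal(cs$t_statistic, t_manual, tolerance = 1e-10)
  expect_equal(cs$df, length(g1) + length(g2) - 2)
})

test_that("identical age distributions give t = 0, p = 1", {
  li <- rbind(make_history("A", c(1.5, 1.5)), make_history("B", c(1.5, 1.5)),
              make_history("C", c(1.5, 2.5)), make_history("D", c(2.5, 1.5)))
  asg <- assign_tactics(li)
  by <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(id)
    bear_year_row(bear_id = id, age = 10L, recruits = NA_integer_)))
  cs <- consistency_summary(asg, by)
  expect_equal(cs$t_statistic, 0)
  expect_equal(cs$p_value, 1)
})
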