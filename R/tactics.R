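# Classification of maternal-care tactics and analysis of their trend,
# repeatability and correlates.

#' Classify females into maternal-care tactics
#'
#' Each female is classified by the average duration of maternal care over
#' her weaned litters: mean care >= 2 years is the 2.5-year tactic (`T25`),
#' mean care < 2 years the 1.5-year tactic (`T15`). Litters lost before
#' weaning are excluded; single-litter females are classified by that one
#' litter. Females with no weaned litters are excluded with a warning.
#'
#' @param litters Validated litter data frame.
#' @return Data frame with one row per female: `bear_id`,
#'   `mean_care_duration`, `tactic`, `n_litters`, `consistent` (all weaned
#'   litters had the same duration).
#' @export
assign_tactics <- function(litters) {
  litters <- validate_litters(litters)
  weaned <- litters[litters$care_duration != "lost", , drop = FALSE]
  dropped <- setdiff(unique(litters$mother_id), unique(weaned$mother_id))
  if (length(dropped) > 0) {
    warning(length(dropped),
            " female(s) with no weaned litter excluded from classification")
  }
  if (nrow(weaned) == 0) {
    return(data.frame(bear_id = character(), mean_care_duration = numeric(),
                      tactic = character(), n_litters = integer(),
                      consistent = logical()))
  }
  dur <- care_years(weaned)
  sp <- split(dur, weaned$mother_id)
  out <- data.frame(
    bear_id = names(sp),
    mean_care_duration = vapply(sp, mean, 0),
    n_litters = vapply(sp, length, 0L),
    consistent = vapply(sp, function(d) length(unique(d)) == 1, TRUE),
    row.names = NULL
  )
  out$tactic <- ifelse(out$mean_care_duration >= 2, "T25", "T15")
  out[, c("bear_id", "mean_care_duration", "tactic", "n_litters",
          "consistent")]
}

#' Temporal trend in the 2.5-year maternal-care tactic
#'
#' Fits a binomial mixed model of the probability that a weaned litter
#' received 2.5 years of care on calendar year (fixed effect) with a
#' female-identity random intercept, and returns the annual odds ratio
#' `exp(year coefficient)` with a Wald 95% CI.
#'
#' @param litters Validated litter data frame; lost litters are excluded.
#' @return List of class `trend_result`: `annual_odds_ratio`, `ci_low`,
#'   `ci_high`, `n_litters`, `n_females`, `estimable`. Complete separation
#'   (all litters one tactic) or a single observation year yields
#'   `estimable = FALSE` rather than an error.
#' @export
weaning_trend <- function(litters) {
  litters <- validate_litters(litters)
  d <- litters[litters$care_duration != "lost", , drop = FALSE]
  d$resp <- as.integer(d$care_duration == "2.5")
  d$year_c <- d$birth_year - stats::median(d$birth_year)
  res <- list(annual_odds_ratio = NA_real_, ci_low = NA_real_,
              ci_high = NA_real_, n_litters = nrow(d),
              n_females = length(unique(d$mother_id)), estimable = FALSE)
  class(res) <- "trend_result"
  if (length(unique(d$birth_year)) < 2 || length(unique(d$resp)) < 2) {
    res$reason <- "non-estimable: single year or complete separation"
    return(res)
  }
  fit <- suppressMessages(lme4::glmer(
    resp ~ year_c + (1 | mother_id), data = d, family = stats::binomial
  ))
  ft <- fixef_table(fit)
  i <- match("year_c", ft$table$term)
  res$annual_odds_ratio <- exp(ft$table$estimate[i])
  res$ci_low <- exp(ft$table$ci_low[i])
  res$ci_high <- exp(ft$table$ci_high[i])
  res$estimable <- TRUE
  res$fit <- fit
  res
}

#' @export
print.trend_result <- function(x, ...) {
  if (!x$estimable) {
    cat("Weaning trend: non-estimable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "Weaning trend: annual OR = %.2f (95%% CI [%.2f, %.2f]), %d litters from %d females\n",
      x$annual_odds_ratio, x$ci_low, x$ci_high, x$n_litters, x$n_females))
  }
  invisible(x)
}

# Exact original-scale (observation-level) repeatability of a binary trait
# under a logit-normal model: with p(b) = plogis(mu + b), b ~ N(0, s2),
# ICC_obs = (E[p^2] - E[p]^2) / (E[p](1 - E[p])), the between-female share
# of observed binary variance. Integrals by adaptive quadrature.
logit_normal_icc <- function(mu, s2) {
  if (s2 <= 0) return(0)
  s <- sqrt(s2)
  m0 <- stats::integrate(function(x) stats::plogis(mu + x) * stats::dnorm(x, 0, s),
                         -Inf, Inf)$value
  m2 <- stats::integrate(function(x) stats::plogis(mu + x)^2 * stats::dnorm(x, 0, s),
                         -Inf, Inf)$value
  icc <- (m2 - m0^2) / (m0 * (1 - m0))
  min(max(icc, 0), 1)
}

#' Repeatability of maternal-care duration
#'
#' GLMM-based repeatability of the binary care-duration trait (2.5-year
#' litter vs 1.5-year litter) for females with at least two weaned litters.
#' A logit-link mixed model with a female random intercept is fitted; the
#' latent-scale repeatability is
#' `sigma2_ind / (sigma2_ind + sigma2_resid + pi^2/3)` (for binary data the
#' multiplicative overdispersion is fixed at 1, so `sigma2_resid = 0`), and
#' the original-scale repeatability is obtained by exact integration of the
#' logit-normal model (the observation-level intraclass correlation of the
#' binary responses). The 95% CI is a percentile bootstrap resampling
#' females with replacement.
#'
#' @param litters Validated litter data frame.
#' @param n_bootstrap Bootstrap iterations for the CI (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `repeatability_result`: `r_original`, `r_latent`,
#'   `sigma2_individual`, `sigma2_residual`, `ci_low`, `ci_high`,
#'   `n_bootstrap`, `n_females`, `boundary` (variance estimated at zero).
#' @export
care_repeatability <- function(litters, n_bootstrap = 1000, seed = 1) {
  litters <- validate_litters(litters)
  d <- litters[litters$care_duration != "lost", , drop = FALSE]
  d$resp <- as.integer(d$care_duration == "2.5")
  multi <- names(which(table(d$mother_id) >= 2))
  d <- d[d$mother_id %in% multi, , drop = FALSE]
  if (length(multi) < 5) {
    stop("repeatability requires >= 5 females with at least two observed ",
         "care periods (have ", length(multi), ")", call. = FALSE)
  }
  point <- rpt_point(d)
  set.seed(seed)
  idx_by_fem <- split(seq_len(nrow(d)), d$mother_id)[multi]
  boots <- vapply(seq_len(n_bootstrap), function(i) {
    fem <- sample(seq_along(multi), length(multi), replace = TRUE)
    idx <- idx_by_fem[fem]
    db <- d[unlist(idx), , drop = FALSE]
    db$mother_id <- rep(seq_along(fem), lengths(idx))
    tryCatch(rpt_point(db)["r_original"], error = function(e) NA_real_)
  }, 0)
  boots <- boots[is.finite(boots)]
  res <- list(
    r_original = unname(point["r_original"]),
    r_latent = unname(point["r_latent"]),
    sigma2_individual = unname(point["s2_ind"]),
    sigma2_residual = 0,
    ci_low = unname(stats::quantile(boots, 0.025)),
    ci_high = unname(stats::quantile(boots, 0.975)),
    n_bootstrap = n_bootstrap,
    n_females = length(multi),
    boundary = unname(point["s2_ind"]) < 1e-6
  )
  class(res) <- "repeatability_result"
  res
}

rpt_point <- function(d) {
  fit <- suppressMessages(lme4::glmer(
    resp ~ 1 + (1 | mother_id), data = d, family = stats::binomial,
    control = lme4::glmerControl(calc.derivs = FALSE)
  ))
  s2 <- unname(lme4::VarCorr(fit)$mother_id[1, 1])
  mu <- unname(lme4::fixef(fit)[1])
  c(s2_ind = s2,
    r_latent = s2 / (s2 + pi^2 / 3),
    r_original = logit_normal_icc(mu, s2))
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(
    "Repeatability of care duration: r_original = %.2f (95%% CI [%.2f, %.2f]), r_latent = %.2f, %d females\n",
    x$r_original, x$ci_low, x$ci_high, x$r_latent, x$n_females))
  invisible(x)
}

#' Effect of primiparity on the maternal-care tactic
#'
#' Binomial mixed model of the per-litter tactic (2.5-year = 1) on the
#' mother's parity (primiparous vs multiparous) with a female random
#' intercept. Litters with unknown parity are removed.
#'
#' @param litters Validated litter data frame.
#' @return List: `odds_ratio` (primiparous vs multiparous), `ci_low`,
#'   `ci_high`, `n_litters`, `estimable` (FALSE under complete separation).
#' @export
primiparity_effect <- function(litters) {
  litters <- validate_litters(litters)
  d <- litters[litters$care_duration != "lost" &
                 litters$mother_primiparous != "unknown", , drop = FALSE]
  d$resp <- as.integer(d$care_duration == "2.5")
  d$primi <- d$mother_primiparous == "true"
  res <- list(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              n_litters = nrow(d), estimable = FALSE)
  tab <- table(d$primi, d$resp)
  if (nrow(tab) < 2 || ncol(tab) < 2 || any(rowSums(tab > 0) < 2)) {
    res$reason <- "non-estimable: complete separation or single group"
    return(res)
  }
  fit <- suppressMessages(lme4::glmer(
    resp ~ primi + (1 | mother_id), data = d, family = stats::binomial
  ))
  ft <- fixef_table(fit)
  i <- grep("^primi", ft$table$term)
  if (abs(ft$table$estimate[i]) > 10) { # quasi-separation
    res$reason <- "non-estimable: separation"
    return(res)
  }
  res$odds_ratio <- exp(ft$table$estimate[i])
  res$ci_low <- exp(ft$table$ci_low[i])
  res$ci_high <- exp(ft$table$ci_high[i])
  res$estimable <- TRUE
  res
}

#' Consistency of tactic use and its relation to female age
#'
#' Reports the percentage of females whose weaned litters all had the same
#' care duration -- among multi-litter females and among all classified
#' females -- and compares mean ages of consistent vs flexible females with
#' a two-sample Student's t-test (pooled variance).
#'
#' @param assignments Output of [assign_tactics()].
#' @param bear_years Validated bear-year records (used for female ages; each
#'   female's age is her mean recorded age).
#' @return List: `pct_consistent_multi`, `pct_consistent_all`,
#'   `n_multi`, `t_statistic`, `df`, `p_value`, `mean_age_consistent`,
#'   `mean_age_flexible`. The t-test entries are `NA` with a `note` when a
#'   group is empty.
#' @export
consistency_summary <- function(assignments, bear_years) {
  bear_years <- validate_bear_years(bear_years)
  multi <- assignments[assignments$n_litters >= 2, , drop = FALSE]
  res <- list(
    pct_consistent_multi = if (nrow(multi) > 0)
      100 * mean(multi$consistent) else NA_real_,
    pct_consistent_all = 100 * mean(assignments$consistent),
    n_multi = nrow(multi)
  )
  mean_age <- tapply(bear_years$age, bear_years$bear_id, mean)
  ages <- mean_age[assignments$bear_id]
  g1 <- ages[assignments$consistent]
  g2 <- ages[!assignments$consistent]
  g1 <- g1[is.finite(g1)]; g2 <- g2[is.finite(g2)]
  if (length(g1) < 2 || length(g2) < 2) {
    res$t_statistic <- NA_real_; res$df <- NA_real_; res$p_value <- NA_real_
    res$note <- "t-test skipped: fewer than two females in a group"
  } else {
    # pooled-variance two-sample t; degenerate zero-variance samples give
    # t = 0 (equal means) rather than an error
    n1 <- length(g1); n2 <- length(g2)
    sp2 <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) /
      (n1 + n2 - 2)
    dm <- mean(g1) - mean(g2)
    res$df <- n1 + n2 - 2
    if (sp2 == 0) {
      res$t_statistic <- if (dm == 0) 0 else sign(dm) * Inf
      res$p_value <- if (dm == 0) 1 else 0
    } else {
      res$t_statistic <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
      res$p_value <- 2 * stats::pt(-abs(res$t_statistic), res$df)
    }
  }
  res$mean_age_consistent <- mean(g1)
  res$mean_age_flexible <- mean(g2)
  res
}
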