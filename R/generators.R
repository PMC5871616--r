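# Model-based data generators.
#
# Complementary to the individual-based simulator: these draw records
# directly from the fitted-model families (logistic survival, negative
# binomial recruitment, logit-normal care histories) with known
# coefficients, which makes parameter-recovery and interval-coverage
# experiments exact and cheap.

#' Generate bear-year survival records from known logistic coefficients
#'
#' Survival is Bernoulli with
#' `logit(p) = intercept + tactic25 + age-class effect + year effect`,
#' the linear predictor of the survival model the package fits.
#'
#' @param n Number of bear-years.
#' @param coefs Named vector with elements `intercept`, `tactic25`,
#'   `age2`, `age3`, `age48`, `age9p` (log-odds; reference: yearling,
#'   1.5-year tactic).
#' @param p_t25 Probability a record belongs to the 2.5-year tactic.
#' @param age_class_probs Probabilities of the five age classes.
#' @param n_years Number of years (shared random year effects).
#' @param year_sd SD of the normal year effect on the log-odds.
#' @param seed Integer seed.
#' @return Bear-year data frame (validated) with survival outcomes; statuses
#'   are set to `solitary` and recruits to missing.
#' @export
simulate_survival_data <- function(n, coefs, p_t25 = 0.35,
                                   age_class_probs = c(0.15, 0.12, 0.1, 0.45, 0.18),
                                   n_years = 20, year_sd = 0.15, seed = 1) {
  set.seed(seed)
  tactic <- ifelse(stats::runif(n) < p_t25, "T25", "T15")
  cls <- sample(age_class_levels(), n, replace = TRUE, prob = age_class_probs)
  year <- sample(seq_len(n_years), n, replace = TRUE)
  year_eff <- stats::rnorm(n_years, 0, year_sd)
  eta <- coefs[["intercept"]] +
    (tactic == "T25") * coefs[["tactic25"]] +
    (cls == "2") * coefs[["age2"]] + (cls == "3") * coefs[["age3"]] +
    (cls == "4-8") * coefs[["age48"]] + (cls == "9+") * coefs[["age9p"]] +
    year_eff[year]
  survived <- stats::runif(n) < stats::plogis(eta)
  age_for <- c("1" = 1L, "2" = 2L, "3" = 3L, "4-8" = 6L, "9+" = 10L)
  validate_bear_years(data.frame(
    bear_id = sprintf("B%05d", seq_len(n)), year = 2000L + year,
    age = age_for[cls], tactic = tactic, status = "solitary",
    survived = survived,
    cause_of_death = ifelse(survived, "none", "other"),
    available_for_hunting = TRUE, recruits = NA_integer_,
    stringsAsFactors = FALSE
  ))
}

#' Generate adult recruitment records from known count-model coefficients
#'
#' Counts of yearling daughters per female-year are negative binomial with
#' `log(mu) = intercept + tactic25 + female effect + year effect`, truncated
#' at 3 (the observable range).
#'
#' @param n_females Number of females.
#' @param obs_per_female Observations (years) per female.
#' @param intercept,tactic25 Log-scale coefficients (reference: 1.5-year
#'   tactic).
#' @param theta Negative-binomial size (dispersion) parameter.
#' @param female_sd,year_sd SDs of normal random effects on the log scale.
#' @param p_t25 Probability a female uses the 2.5-year tactic.
#' @param seed Integer seed.
#' @return Bear-year data frame of adult female-years with `recruits` set.
#' @export
simulate_recruit_data <- function(n_females, obs_per_female = 4,
                                  intercept = -0.923, tactic25 = -0.425,
                                  theta = 8, female_sd = 0.1, year_sd = 0.1,
                                  p_t25 = 0.35, seed = 1) {
  set.seed(seed)
  n <- n_females * obs_per_female
  fem <- rep(seq_len(n_females), each = obs_per_female)
  tactic <- rep(ifelse(stats::runif(n_females) < p_t25, "T25", "T15"),
                each = obs_per_female)
  n_years <- max(10, obs_per_female)
  year <- sample(seq_len(n_years), n, replace = TRUE)
  fem_eff <- stats::rnorm(n_females, 0, female_sd)
  year_eff <- stats::rnorm(n_years, 0, year_sd)
  mu <- exp(intercept + (tactic == "T25") * tactic25 +
              fem_eff[fem] + year_eff[year])
  recruits <- pmin(stats::rnbinom(n, mu = mu, size = theta), 3L)
  validate_bear_years(data.frame(
    bear_id = sprintf("B%05d", fem), year = 2000L + year, age = 6L,
    tactic = tactic, status = "solitary", survived = TRUE,
    cause_of_death = "none", available_for_hunting = TRUE,
    recruits = as.integer(recruits), stringsAsFactors = FALSE
  ))
}

#' Generate care-duration histories from a logit-normal female model
#'
#' Each female has a latent propensity `b_i ~ N(0, sigma2_ind)` for the
#' 2.5-year tactic; litter `j` of female `i` is a 2.5-year litter with
#' probability `plogis(mu + slope * year_ij + b_i)`. The latent-scale
#' repeatability of the generated binary trait is
#' `sigma2_ind / (sigma2_ind + pi^2 / 3)`, so `sigma2_ind` can be chosen to
#' hit any target repeatability exactly.
#'
#' @param n_females Number of females.
#' @param litters_per_female Litters per female (scalar or vector).
#' @param mu Log-odds intercept of the 2.5-year tactic.
#' @param sigma2_ind Between-female variance on the logit scale.
#' @param slope Annual log-odds trend (year covariate centered at 0).
#' @param n_years Span of years litters are spread over.
#' @param start_year First year.
#' @param seed Integer seed.
#' @return Validated litter data frame.
#' @export
simulate_care_histories <- function(n_females, litters_per_female = 3,
                                    mu = -1, sigma2_ind = 1.62,
                                    slope = 0, n_years = 20,
                                    start_year = 1993, seed = 1) {
  set.seed(seed)
  k <- rep_len(litters_per_female, n_females)
  fem <- rep(seq_len(n_females), k)
  n <- length(fem)
  b <- stats::rnorm(n_females, 0, sqrt(sigma2_ind))
  yr_idx <- sample(seq_len(n_years), n, replace = TRUE) - 1L
  eta <- mu + slope * yr_idx + b[fem]
  is25 <- stats::runif(n) < stats::plogis(eta)
  birth <- start_year + yr_idx
  validate_litters(data.frame(
    litter_id = sprintf("L%05d", seq_len(n)),
    mother_id = sprintf("B%05d", fem),
    birth_year = birth,
    weaning_year = birth + ifelse(is25, 2L, 1L),
    care_duration = ifelse(is25, "2.5", "1.5"),
    litter_size = sample(1:4, n, replace = TRUE, prob = c(0.1, 0.4, 0.4, 0.1)),
    mother_primiparous = "unknown",
    stringsAsFactors = FALSE
  ))
}

#' Latent-scale variance for a target repeatability
#'
#' Inverts `r = sigma2 / (sigma2 + pi^2 / 3)`, the latent-scale
#' repeatability of a binary trait under a logit-link mixed model.
#'
#' @param r Target repeatability in `[0, 1)`.
#' @return Between-individual variance on the logit scale.
#' @export
#' @examples
#' sigma2_for_repeatability(0.33)
sigma2_for_repeatability <- function(r) {
  stopifnot(r >= 0, r < 1)
  r / (1 - r) * pi^2 / 3
}
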