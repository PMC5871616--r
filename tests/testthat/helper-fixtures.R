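# Fixtures built in code; no data files.

# Mean tactic- and age-class-specific rates of the study population
# (survival per class, yearling daughters per female-year).
table2_rates <- function() {
  list(
    T15 = list(s = c(0.809, 0.844, 0.916, 0.973, 0.841), r = 0.384),
    T25 = list(s = c(0.903, 0.922, 0.961, 0.988, 0.920), r = 0.251)
  )
}

# Final survival-model coefficients (log-odds; reference yearling, T15)
# and recruitment-model coefficients (log scale; reference T15).
table1_survival_coefs <- function() {
  c(intercept = 1.430, tactic25 = 0.761, age2 = 0.238, age3 = 0.932,
    age48 = 2.124, age9p = 0.224)
}
table1_recruitment_coefs <- function() {
  c(intercept = -0.923, tactic25 = -0.425)
}

table2_leslie <- function(tactic = "T15") {
  p <- table2_rates()[[tactic]]
  build_leslie(p$s[1], p$s[2], p$s[3], p$s[4], p$s[5], p$r, tactic = tactic)
}

# One valid bear-year row, with overridable fields.
bear_year_row <- function(...) {
  row <- list(bear_id = "F1", year = 2000L, age = 5L, tactic = "T15",
              status = "solitary", survived = TRUE, cause_of_death = "none",
              available_for_hunting = TRUE, recruits = 0L)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

litter_row <- function(...) {
  row <- list(litter_id = "L1", mother_id = "F1", birth_year = 2000L,
              weaning_year = 2001L, care_duration = "1.5", litter_size = 2L,
              mother_primiparous = "false")
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

# Bear-year records realizing exact death counts by status, for rate
# arithmetic: n rows of a status with k hunting deaths (and optionally m
# other-cause deaths).
status_records <- function(n, hunting_deaths, other_deaths = 0,
                           status = "solitary", id_prefix = "S") {
  survived <- rep(TRUE, n)
  cause <- rep("none", n)
  idx <- seq_len(hunting_deaths + other_deaths)
  survived[idx] <- FALSE
  cause[seq_len(hunting_deaths)] <- "hunting"
  if (other_deaths > 0) {
    cause[hunting_deaths + seq_len(other_deaths)] <- "other"
  }
  data.frame(
    bear_id = paste0(id_prefix, seq_len(n)),
    year = 2000L + (seq_len(n) %% 8L), age = 6L, tactic = "T15",
    status = status, survived = survived, cause_of_death = cause,
    available_for_hunting = status == "solitary",
    recruits = NA_integer_, stringsAsFactors = FALSE
  )
}

# Random valid Leslie matrix (survivals away from 0/1, positive fertility).
random_leslie <- function() {
  s <- stats::runif(5, 0.3, 0.98)
  r <- stats::runif(1, 0.05, 0.8)
  build_leslie(s[1], s[2], s[3], s[4], s[5], r)
}

# Euler-Lotka renewal residual at a candidate growth rate: equals zero at
# the true dominant eigenvalue of a matrix built by build_leslie().
euler_lotka_residual <- function(A, lambda) {
  r <- attr(A, "rates")
  l <- c(1, cumprod(c(r[["s1"]], r[["s2"]], r[["s3"]], rep(r[["s48"]], 5))))
  F48 <- r[["s48"]] * r[["r59"]]
  F9 <- r[["s9p"]] * r[["r10p"]]
  F48 * sum(l[4:8] * lambda^-(4:8)) +
    F9 * l[9] * lambda^-9 / (1 - r[["s9p"]] / lambda) - 1
}
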