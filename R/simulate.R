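# Individual-based annual-cycle simulator.
#
# Emulates the monitoring design of a hunted brown-bear population in which
# females wean litters after either 1.5 or 2.5 years and family groups
# (mothers with dependent cubs or yearlings, and yearlings still with their
# mother) are legally protected from hunting. The simulator generates
# bear-year and litter records with the statistical structure the analysis
# modules assume, so every downstream stage is testable without field data.
#
# Annual event order (census anchored at the hunting season):
#   new yearlings enter -> births (January) -> hunting season ->
#   other-cause mortality -> litter fates -> age increment.
# One seeded RNG drives all draws; within a year, draws occur in the order
# above, vectorized over individuals in id order.

#' Configuration for the life-history simulator
#'
#' Defaults reproduce the magnitudes of the tactic- and age-class-specific
#' rates estimated for the study population: survival means per tactic and
#' age class, recruitment 0.384 (1.5-year tactic) and 0.251 (2.5-year
#' tactic) yearling daughters per female-year, and an annual log-odds trend
#' of `log(1.17)` in the probability that a litter receives 2.5 years of
#' care.
#'
#' Other-cause mortality is derived as the residual hazard so that total
#' annual survival equals `survival_by` at the calibration pressure
#' (default: the mean of `hunting_pressure`); at other pressures realized
#' survival responds to hunting, which is what the hunting-response module
#' estimates. Cub-to-yearling survival per litter tactic is calibrated by
#' an exact dynamic program over the adult care cycle so that the expected
#' number of yearling daughters per recorded adult female-year equals
#' `recruitment_by` for each tactic, accounting for the birth intervals
#' (2 years for the 1.5-year tactic, 3 for the 2.5-year tactic), occasional
#' tactic switches, entry phase, and mortality being concentrated in
#' hunting-exposed years.
#'
#' @param n_initial_females Number of females alive in the first year.
#' @param n_years Number of simulated years.
#' @param seed Integer seed; all draws flow from it.
#' @param survival_by 5 x 2 matrix of annual survival probabilities, rows
#'   age classes (`1`, `2`, `3`, `4-8`, `9+`), columns `T15`, `T25`.
#' @param recruitment_by Named vector `c(T15, T25)` of mean yearling
#'   daughters per breeding female-year.
#' @param litter_size_probs Probabilities of litter sizes 1-4; must sum to 1.
#' @param p25_intercept,p25_trend Log-odds intercept (first simulated year)
#'   and annual slope of the probability a litter is raised with the
#'   2.5-year tactic.
#' @param tactic_consistency Probability a female repeats her dominant
#'   tactic at each reproduction. The default is calibrated so that the
#'   GLMM repeatability of care duration in simulated data is near the
#'   value observed in the study population (about 0.33).
#' @param hunting_pressure Annual probability that an available (solitary)
#'   marked female is shot; scalar or vector of length `n_years`.
#' @param accidental_kill_prob Probability a protected family-group female
#'   is shot anyway (hunter error).
#' @param calibration_pressure Pressure at which `survival_by` holds exactly
#'   in expectation; defaults to `mean(hunting_pressure)`.
#' @param year_effect_sd SD of a shared annual perturbation on the log-odds
#'   of other-cause survival (justifies the year random effect in fitted
#'   models).
#' @param start_year First calendar year.
#' @param max_age Oldest monitored age; records stop after this age.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_initial_females = 60,
                              n_years = 23,
                              seed = 1,
                              survival_by = default_survival(),
                              recruitment_by = c(T15 = 0.384, T25 = 0.251),
                              litter_size_probs = c(0.1, 0.4, 0.4, 0.1),
                              p25_intercept = -3.5,
                              p25_trend = log(1.17),
                              tactic_consistency = 0.82,
                              hunting_pressure = 0.025,
                              accidental_kill_prob = 0.002,
                              calibration_pressure = NULL,
                              year_effect_sd = 0.1,
                              start_year = 1993,
                              max_age = 24) {
  survival_by <- as.matrix(survival_by)
  dimnames(survival_by) <- list(age_class_levels(), tactic_levels())
  cfg <- list(
    n_initial_females = n_initial_females, n_years = n_years, seed = seed,
    survival_by = survival_by, recruitment_by = recruitment_by,
    litter_size_probs = litter_size_probs,
    p25_intercept = p25_intercept, p25_trend = p25_trend,
    tactic_consistency = tactic_consistency,
    hunting_pressure = rep_len(hunting_pressure, n_years),
    accidental_kill_prob = accidental_kill_prob,
    calibration_pressure = calibration_pressure %||%
      mean(rep_len(hunting_pressure, n_years)),
    year_effect_sd = year_effect_sd,
    start_year = start_year, max_age = max_age
  )
  class(cfg) <- "simulation_config"
  validate_config(cfg)
}

default_survival <- function() {
  m <- cbind(
    T15 = c(0.809, 0.844, 0.916, 0.973, 0.841),
    T25 = c(0.903, 0.922, 0.961, 0.988, 0.920)
  )
  rownames(m) <- age_class_levels()
  m
}

# Fraction of years a female of a given age class and tactic is legally
# available for hunting under the care cycle: 2.5-year mothers are exposed
# about 1 year in 3, 1.5-year mothers about every second year; their
# yearlings are protected (2.5) or independent and exposed (1.5); 2- and
# 3-year-olds are always independent. Adult fractions are the nominal cycle
# values used as the starting point of the lifecycle calibration, which
# refines them for entry phase and for mortality being concentrated in
# exposed years.
availability_fraction <- function() {
  m <- cbind(T15 = c(1, 1, 1, 1 / 2, 1 / 2), T25 = c(0, 1, 1, 1 / 3, 1 / 3))
  rownames(m) <- age_class_levels()
  m
}

# Dynamic program over the adult care cycle for one dominant tactic.
# States at the start of each age 4..max_age: B (gives birth this year,
# protected), C2 (second care year of a 2.5-year litter, protected),
# A (solitary, available). Returns expected availability share per adult
# age class, expected recorded adult(5+) years, and the expected
# recruit-mass per litter tactic (probability-weighted litters that survive
# the cub year, times 0.5 * E[litter size]), all per female entering the
# cycle at age 4.
cycle_dp <- function(dominant, s_other, cfg, lambda = 1) {
  c_keep <- cfg$tactic_consistency
  p25 <- if (dominant == "T25") c_keep else 1 - c_keep
  h <- cfg$calibration_pressure
  a <- cfg$accidental_kill_prob
  mean_half_l <- 0.5 * sum(1:4 * cfg$litter_size_probs)
  ages <- 4:cfg$max_age
  p <- matrix(0, length(ages), 3, dimnames = list(ages, c("B", "C2", "A")))
  p[1, "B"] <- 1
  alive_years <- stats::setNames(numeric(2), c("4-8", "9+"))
  avail_years <- alive_years
  recruit_mass <- stats::setNames(numeric(2), c("1.5", "2.5"))
  for (i in seq_along(ages)) {
    age <- ages[i]
    cls <- if (age >= 9) "9+" else "4-8"
    s_o <- s_other[cls, dominant]
    s_prot <- (1 - a) * s_o
    s_avail <- (1 - h) * s_o
    alive_now <- sum(p[i, ])
    # weight ages as in the cross-section of a population growing at rate
    # lambda (stable-age weighting), not per cohort
    w <- lambda^-(age - 4)
    if (age >= 5) {
      alive_years[cls] <- alive_years[cls] + alive_now * w
      avail_years[cls] <- avail_years[cls] + p[i, "A"] * w
    }
    if (age < cfg$max_age) { # recruits need the mother alive next year
      w1 <- lambda^-(age + 1 - 4) # recruits appear on the next year's row
      recruit_mass["2.5"] <- recruit_mass["2.5"] +
        p[i, "B"] * p25 * s_prot * mean_half_l * w1
      recruit_mass["1.5"] <- recruit_mass["1.5"] +
        p[i, "B"] * (1 - p25) * s_prot * mean_half_l * w1
    }
    if (i < length(ages)) {
      p[i + 1, "C2"] <- p[i, "B"] * p25 * s_prot
      p[i + 1, "A"] <- p[i, "B"] * (1 - p25) * s_prot +
        p[i, "C2"] * s_prot
      p[i + 1, "B"] <- p[i, "A"] * s_avail
    }
  }
  list(alive_years = alive_years, avail_years = avail_years,
       recruit_mass = recruit_mass)
}

# Lifecycle calibration: iterates the residual-hazard computation with the
# DP-implied adult availability shares to a fixed point, then solves the
# 2x2 linear system for per-litter-tactic cub survival such that expected
# recruits per recorded adult (5+) female-year equal recruitment_by for
# each dominant tactic.
lifecycle_calibration <- function(cfg) {
  af <- availability_fraction()
  s_other <- NULL
  lam <- vapply(tactic_levels(), function(tac) {
    A <- suppressWarnings(build_leslie(
      cfg$survival_by[1, tac], cfg$survival_by[2, tac],
      cfg$survival_by[3, tac], cfg$survival_by[4, tac],
      cfg$survival_by[5, tac], cfg$recruitment_by[[tac]]))
    suppressWarnings(leslie_lambda(A))
  }, 0)
  for (iter in 1:4) {
    s_other <- residual_survival(cfg, af)
    dps <- lapply(stats::setNames(tactic_levels(), tactic_levels()),
                  function(tac) cycle_dp(tac, s_other, cfg, lam[[tac]]))
    for (tac in tactic_levels()) {
      ay <- dps[[tac]]$alive_years
      sh <- dps[[tac]]$avail_years / pmax(ay, 1e-12)
      af["4-8", tac] <- sh[["4-8"]]
      af["9+", tac] <- sh[["9+"]]
    }
  }
  # A[d, tau]: expected recruits per recorded adult(5+) year of a
  # d-dominant female, per unit cub survival of litter tactic tau
  A <- matrix(0, 2, 2, dimnames = list(tactic_levels(), c("1.5", "2.5")))
  for (tac in tactic_levels()) {
    A[tac, ] <- dps[[tac]]$recruit_mass / sum(dps[[tac]]$alive_years)
  }
  s0 <- solve(A, cfg$recruitment_by[tactic_levels()])
  s0 <- stats::setNames(as.numeric(s0), c("T15", "T25"))
  if (any(!is.finite(s0)) || any(s0 < 0) || any(s0 > 1 + 1e-9)) {
    stop("configuration error: recruitment_by unattainable for tactic ",
         tactic_levels()[which(s0 > 1 | s0 < 0 | !is.finite(s0))[1]],
         " given the litter-size distribution and survival regime",
         call. = FALSE)
  }
  list(s_other = s_other, cub_survival = pmin(s0, 1),
       availability = af)
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_years >= 1, cfg$n_initial_females >= 1,
    all(dim(cfg$survival_by) == c(5, 2)),
    all(cfg$survival_by >= 0 & cfg$survival_by <= 1),
    all(cfg$recruitment_by >= 0),
    length(cfg$litter_size_probs) == 4,
    abs(sum(cfg$litter_size_probs) - 1) < 1e-8,
    cfg$tactic_consistency >= 0, cfg$tactic_consistency <= 1,
    all(cfg$hunting_pressure >= 0 & cfg$hunting_pressure <= 1),
    cfg$accidental_kill_prob >= 0, cfg$accidental_kill_prob <= 1,
    cfg$year_effect_sd >= 0
  )
  lifecycle_calibration(cfg) # errors if hazards or recruitment inconsistent
  cfg
}

# Residual other-cause survival per (age class, tactic) such that total
# annual survival equals survival_by at the calibration pressure, given
# availability shares af.
residual_survival <- function(cfg, af = availability_fraction()) {
  p_hunt <- cfg$calibration_pressure * af +
    cfg$accidental_kill_prob * (1 - af)
  s_other <- cfg$survival_by / (1 - p_hunt)
  bad <- which(s_other > 1 + 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("configuration error: hunting hazard exceeds the mortality ",
         "allowance for age class ", rownames(s_other)[bad[1, 1]],
         ", tactic ", colnames(s_other)[bad[1, 2]],
         " (total survival ", cfg$survival_by[bad[1, 1], bad[1, 2]],
         " cannot hold at calibration pressure ",
         signif(cfg$calibration_pressure, 3), ")", call. = FALSE)
  }
  pmin(s_other, 1)
}

#' Ground-truth record of all generating parameters
#'
#' Machine-readable summary of a simulation configuration, including the
#' derived internal parameters (residual other-cause survival and
#' cub-to-yearling survival), for parameter-recovery tests and provenance
#' files. Round-trips through JSON.
#'
#' @param config A `simulation_config`.
#' @return Named list of plain values.
#' @export
truth_record <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  out <- unclass(config)
  cal <- lifecycle_calibration(config)
  out$derived <- list(
    other_cause_survival = cal$s_other,
    cub_survival = cal$cub_survival,
    availability_fraction = cal$availability
  )
  out
}

#' Simulate an individually monitored female bear population
#'
#' Runs the annual cycle for every female: tactic drawn at first
#' reproduction from the year-dependent logistic trend, then repeated with
#' probability `tactic_consistency`; reproduction blocked until the current
#' litter is weaned; family-group members protected during the hunting
#' season; hunting mortality (pressure times availability, plus the
#' accidental-kill hazard when protected) followed by residual other-cause
#' mortality; yearling daughters recruited into the monitored population.
#' Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with elements `bear_years` and `litters`, both validated
#'   record tables, plus `truth` (the [truth_record()]).
#' @export
simulate_population <- function(config) {
  cfg <- validate_config(config)
  set.seed(cfg$seed)
  cal <- lifecycle_calibration(cfg)
  s_other <- cal$s_other
  s0 <- cal$cub_survival
  years <- cfg$start_year + seq_len(cfg$n_years) - 1

  # individual state (parallel vectors)
  n0 <- cfg$n_initial_females
  id <- sprintf("F%04d", seq_len(n0))
  age <- sample(1:12, n0, replace = TRUE, prob = 0.82^(0:11))
  alive <- rep(TRUE, n0)
  p25_0 <- stats::plogis(cfg$p25_intercept)
  received <- ifelse(stats::runif(n0) < p25_0, "T25", "T15")
  dominant <- rep(NA_character_, n0)
  # randomize the breeding phase of initial adults to avoid cohort synchrony
  next_eligible <- years[1] + ifelse(age >= 4, sample(0:1, n0, TRUE), 0L)
  protected_until <- rep(years[1] - 1L, n0)
  dependent_year <- ifelse(age == 1 & received == "T25",
                           years[1], years[1] - 1L)
  n_litters <- rep(0L, n0)
  next_id <- n0 + 1L

  # litter store (grown per year)
  lit <- list(mother = character(), birth_year = integer(),
              tactic = character(), size = integer(), d_rec = integer(),
              primiparous = logical(), protected_until = integer(),
              fate = character(), weaning_year = integer())
  rows <- vector("list", cfg$n_years)

  for (ti in seq_len(cfg$n_years)) {
    y <- years[ti]
    eps <- stats::rnorm(1, 0, cfg$year_effect_sd)
    h <- cfg$hunting_pressure[ti]

    # --- 1. yearling daughters from last year's litters enter at age 1 ---
    recruits_now <- integer(0)
    # litters born last year whose mother survived the cub year (a lost
    # litter implies the mother died while the cubs were dependent)
    spawn_from <- which(lit$birth_year == y - 1 & lit$fate != "lost" &
                          lit$d_rec > 0)
    if (length(spawn_from) > 0) {
      mother_alive <- alive[match(lit$mother[spawn_from], id)]
      spawn_from <- spawn_from[mother_alive]
    }
    if (length(spawn_from) > 0) {
      k <- lit$d_rec[spawn_from]
      recruits_now <- stats::setNames(k, lit$mother[spawn_from])
      tot <- sum(k)
      new_ids <- sprintf("F%04d", seq(next_id, length.out = tot))
      next_id <- next_id + tot
      rec_tac <- ifelse(rep(lit$tactic[spawn_from], k) == "2.5",
                        "T25", "T15")
      id <- c(id, new_ids)
      age <- c(age, rep(1L, tot))
      alive <- c(alive, rep(TRUE, tot))
      received <- c(received, rec_tac)
      dominant <- c(dominant, rep(NA_character_, tot))
      next_eligible <- c(next_eligible, rep(years[1], tot))
      protected_until <- c(protected_until, rep(years[1] - 1L, tot))
      dependent_year <- c(dependent_year,
                          ifelse(rec_tac == "T25", y, years[1] - 1L))
      n_litters <- c(n_litters, rep(0L, tot))
    }

    # --- 2. births (January): eligible adults not currently caring ---
    breed <- which(alive & age >= 4 & y >= next_eligible)
    if (length(breed) > 0) {
      p25 <- stats::plogis(cfg$p25_intercept + cfg$p25_trend * (ti - 1))
      first <- breed[is.na(dominant[breed])]
      if (length(first) > 0) {
        dominant[first] <- ifelse(stats::runif(length(first)) < p25,
                                  "T25", "T15")
      }
      # first litter realizes the dominant tactic; later litters repeat it
      # with probability tactic_consistency
      keep <- stats::runif(length(breed)) < cfg$tactic_consistency |
        n_litters[breed] == 0L
      lit_tac <- ifelse(keep, dominant[breed],
                        ifelse(dominant[breed] == "T25", "T15", "T25"))
      sizes <- sample(1:4, length(breed), replace = TRUE,
                      prob = cfg$litter_size_probs)
      d_fem <- stats::rbinom(length(breed), sizes, 0.5)
      d_rec <- pmin(stats::rbinom(length(breed), d_fem,
                                  s0[ifelse(lit_tac == "T25", "T25", "T15")]),
                    3L)
      is25 <- lit_tac == "T25"
      lit$mother <- c(lit$mother, id[breed])
      lit$birth_year <- c(lit$birth_year, rep(y, length(breed)))
      lit$tactic <- c(lit$tactic, ifelse(is25, "2.5", "1.5"))
      lit$size <- c(lit$size, sizes)
      lit$d_rec <- c(lit$d_rec, d_rec)
      lit$primiparous <- c(lit$primiparous, n_litters[breed] == 0L)
      lit$protected_until <- c(lit$protected_until, y + is25)
      lit$fate <- c(lit$fate, rep("pending", length(breed)))
      lit$weaning_year <- c(lit$weaning_year, rep(NA_integer_, length(breed)))
      protected_until[breed] <- y + is25
      next_eligible[breed] <- y + 2L + is25
      n_litters[breed] <- n_litters[breed] + 1L
    }

    # --- 3. hunting-season status and availability ---
    live <- which(alive)
    with_off <- protected_until[live] >= y
    with_mom <- dependent_year[live] == y & age[live] == 1
    status <- ifelse(with_off, "with_offspring",
                     ifelse(with_mom, "with_mother", "solitary"))
    protected <- with_off | with_mom
    avail <- !protected

    # --- 4. hunting season ---
    u_hunt <- stats::runif(length(live))
    shot <- (avail & u_hunt < h) | (protected & u_hunt < cfg$accidental_kill_prob)

    # --- 5. other-cause mortality among season survivors ---
    tac <- ifelse(age[live] >= 4 & !is.na(dominant[live]),
                  dominant[live], received[live])
    cls <- as.character(age_class(age[live]))
    s_oth <- stats::plogis(stats::qlogis(s_other[cbind(cls, tac)]) + eps)
    died_other <- !shot & stats::runif(length(live)) > s_oth
    survived <- !shot & !died_other

    # --- 6. records ---
    rec <- rep(NA_integer_, length(live))
    adult5 <- age[live] >= 5
    rec[adult5] <- 0L
    hit <- match(names(recruits_now), id[live])
    rec[hit[!is.na(hit)]] <- as.integer(recruits_now[!is.na(hit)])
    rec[!adult5] <- NA_integer_
    rows[[ti]] <- data.frame(
      bear_id = id[live], year = y, age = age[live], tactic = tac,
      status = status, survived = survived,
      cause_of_death = ifelse(survived, "none",
                              ifelse(shot, "hunting", "other")),
      available_for_hunting = avail & alive[live], recruits = rec,
      stringsAsFactors = FALSE
    )

    # --- 7. litter fates ---
    alive[live] <- survived
    pending <- which(lit$fate == "pending")
    if (length(pending) > 0) {
      mom_alive <- alive[match(lit$mother[pending], id)]
      done <- lit$protected_until[pending] <= y
      lost <- pending[!mom_alive]
      lit$fate[lost] <- "lost"
      weaned <- pending[mom_alive & done]
      lit$fate[weaned] <- "weaned"
      lit$weaning_year[weaned] <- lit$protected_until[weaned] + 1L
    }

    # --- 8. age increment and monitoring cap ---
    age[alive] <- age[alive] + 1L
    alive[age > cfg$max_age] <- FALSE
  }

  bear_years <- do.call(rbind, rows)
  bear_years <- validate_bear_years(bear_years)

  decided <- lit$fate != "pending"
  litters <- data.frame(
    litter_id = sprintf("L%04d", which(decided)),
    mother_id = lit$mother[decided],
    birth_year = lit$birth_year[decided],
    weaning_year = lit$weaning_year[decided],
    care_duration = ifelse(lit$fate[decided] == "lost", "lost",
                           lit$tactic[decided]),
    litter_size = lit$size[decided],
    mother_primiparous = ifelse(lit$primiparous[decided], "true", "false"),
    stringsAsFactors = FALSE
  )
  litters <- validate_litters(litters)

  list(bear_years = bear_years, litters = litters, truth = truth_record(cfg))
}
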