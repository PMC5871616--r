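# Hunting-pressure index and the tactic-specific response of survival --
# and hence population growth -- to hunting pressure.

#' Annual hunting-pressure index
#'
#' For each year, the number of marked females shot divided by the number
#' of marked females legally available for hunting that year. Family-group
#' members are not available and are excluded from both numerator and
#' denominator (an accidental kill of a protected female does not enter the
#' index); years with no available females get a missing index, not zero.
#'
#' @param bear_years Validated bear-year records.
#' @return Data frame of class `pressure_series`: `year`, `n_available`,
#'   `n_shot`, `h`.
#' @export
pressure_index <- function(bear_years) {
  d <- validate_bear_years(bear_years)
  yrs <- sort(unique(d$year))
  avail <- d$available_for_hunting
  n_av <- vapply(yrs, function(y) sum(avail & d$year == y), 0L)
  n_sh <- vapply(yrs, function(y)
    sum(avail & d$year == y & d$cause_of_death == "hunting"), 0L)
  out <- data.frame(year = yrs, n_available = n_av, n_shot = n_sh,
                    h = ifelse(n_av > 0, n_sh / n_av, NA_real_))
  class(out) <- c("pressure_series", "data.frame")
  out
}

#' Per-cell models of survival against hunting pressure
#'
#' For every tactic-by-age-class cell, fits a logistic regression of
#' individual annual survival on the annual hunting-pressure index (a
#' year-level covariate shared by all individuals in that year) and draws
#' `n_draws` coefficient vectors from the asymptotic sampling distribution
#' of the fit (a parametric bootstrap of the MLE) to represent estimation
#' uncertainty. Cells with fewer than two distinct pressure values or with
#' a single outcome are flagged non-estimable.
#'
#' @param bear_years Validated bear-year records with known tactic.
#' @param pressure A `pressure_series` from [pressure_index()]; rows with a
#'   missing index are dropped.
#' @param n_draws Number of coefficient draws per cell (default 1000).
#' @param seed Integer seed.
#' @return List of class `pressure_models`; element `cells` maps
#'   `"tactic.age_class"` to a list with `coef` (intercept, slope on the
#'   log-odds scale), `vcov`, `draws` (`n_draws` x 2), `n_obs` and
#'   `estimable`.
#' @export
fit_pressure_models <- function(bear_years, pressure, n_draws = 1000,
                                seed = 1) {
  d <- validate_bear_years(bear_years)
  d <- d[d$tactic %in% tactic_levels(), , drop = FALSE]
  pr <- pressure[!is.na(pressure$h), c("year", "h")]
  d <- merge(d, pr, by = "year")
  d$age_class <- age_class(d$age)
  set.seed(seed)
  cells <- list()
  for (tac in tactic_levels()) {
    for (cls in age_class_levels()) {
      key <- paste(tac, cls, sep = ".")
      sub <- d[d$tactic == tac & d$age_class == cls, , drop = FALSE]
      cell <- list(tactic = tac, age_class = cls, n_obs = nrow(sub),
                   estimable = FALSE)
      if (nrow(sub) >= 10 && length(unique(sub$h)) >= 2 &&
          length(unique(sub$survived)) >= 2) {
        fit <- suppressWarnings(stats::glm(survived ~ h, data = sub,
                                           family = stats::binomial))
        beta <- stats::coef(fit)
        V <- stats::vcov(fit)
        if (all(is.finite(beta)) && all(is.finite(V)) &&
            max(abs(beta)) < 50) {
          cell$coef <- beta
          cell$vcov <- V
          cell$draws <- MASS::mvrnorm(n_draws, beta, V)
          cell$estimable <- TRUE
        } else {
          cell$reason <- "separation"
        }
      } else {
        cell$reason <- "too few observations or single pressure/outcome"
      }
      cells[[key]] <- cell
    }
  }
  flagged <- names(cells)[!vapply(cells, `[[`, TRUE, "estimable")]
  if (length(flagged) > 0) {
    warning("non-estimable pressure cells excluded downstream: ",
            paste(flagged, collapse = ", "))
  }
  out <- list(cells = cells, n_draws = n_draws)
  class(out) <- "pressure_models"
  out
}

#' Population growth rate as a function of hunting pressure
#'
#' For each tactic, pressure value and coefficient draw, predicts the five
#' age-class survival probabilities from the per-cell pressure models,
#' builds the tactic's Leslie matrix with recruitment held fixed (hunting
#' acts on survival components only), and computes the asymptotic growth
#' rate. Returns the full draw-level distribution plus quantile summaries.
#'
#' @param models A `pressure_models` from [fit_pressure_models()]; all five
#'   age classes must be estimable for a tactic to be included.
#' @param recruitment Named vector `c(T15 = , T25 = )` of recruitment
#'   values.
#' @param pressures Pressure grid; default 12 evenly spaced values over
#'   `[0, 0.33]`, the observed range.
#' @param n_draws Draws used per pressure (at most the draws stored in
#'   `models`).
#' @return List of class `lambda_pressure`: `draws` (long data frame:
#'   tactic, pressure, draw, lambda), `quantiles` (per tactic and pressure:
#'   2.5, 25, 50, 75, 97.5 percentiles of lambda), `n_invalid`.
#' @export
lambda_vs_pressure <- function(models, recruitment,
                               pressures = seq(0, 0.33, length.out = 12),
                               n_draws = 1000) {
  stopifnot(inherits(models, "pressure_models"),
            all(tactic_levels() %in% names(recruitment)))
  n_draws <- min(n_draws, models$n_draws)
  n_invalid <- 0L
  rows <- list()
  for (tac in tactic_levels()) {
    keys <- paste(tac, age_class_levels(), sep = ".")
    cls_cells <- models$cells[keys]
    if (!all(vapply(cls_cells, `[[`, TRUE, "estimable"))) {
      warning("tactic ", tac, " skipped: not all age classes estimable")
      next
    }
    # draw j, class k: survival at pressure p
    ints <- vapply(cls_cells, function(c) c$draws[seq_len(n_draws), 1],
                   numeric(n_draws))
    slps <- vapply(cls_cells, function(c) c$draws[seq_len(n_draws), 2],
                   numeric(n_draws))
    r <- recruitment[[tac]]
    for (p in pressures) {
      S <- stats::plogis(ints + slps * p) # n_draws x 5
      lam <- rep(NA_real_, n_draws)
      for (j in seq_len(n_draws)) {
        s <- S[j, ]
        if (any(!is.finite(s)) || any(s <= 0 | s >= 1)) {
          n_invalid <- n_invalid + 1L
          next
        }
        A <- build_leslie(s[1], s[2], s[3], s[4], s[5], r)
        lam[j] <- dominant_eigen(A)$lambda
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tactic = tac, pressure = p, draw = seq_len(n_draws), lambda = lam)
    }
  }
  draws <- do.call(rbind, rows)
  qu <- do.call(rbind, lapply(split(
    draws, list(draws$tactic, draws$pressure), drop = TRUE),
    function(g) {
      q <- stats::quantile(g$lambda, c(0.025, 0.25, 0.5, 0.75, 0.975),
                           na.rm = TRUE)
      data.frame(tactic = g$tactic[1], pressure = g$pressure[1],
                 q2.5 = q[1], q25 = q[2], median = q[3], q75 = q[4],
                 q97.5 = q[5], row.names = NULL)
    }))
  qu <- qu[order(qu$tactic, qu$pressure), ]
  rownames(qu) <- NULL
  out <- list(draws = draws, quantiles = qu, n_invalid = n_invalid)
  class(out) <- "lambda_pressure"
  out
}

#' @export
print.lambda_pressure <- function(x, ...) {
  cat("Growth rate vs hunting pressure (medians):\n")
  print(round(x$quantiles[, c("pressure", "median")], 3))
  invisible(x)
}
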