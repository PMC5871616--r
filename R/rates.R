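# Tactic- and age-class-specific demographic rates: mixed-model fits,
# likelihood-ratio model simplification, parametric-bootstrap rate tables,
# and the protective effect of family-group status.

new_model_fit <- function(fit, formula, family, link, random_terms, n_obs,
                          flags = character()) {
  ft <- fixef_table(fit)
  out <- list(
    formula = formula, family = family, link = link,
    random_terms = random_terms, n_obs = n_obs,
    coefficients = ft$table, beta = ft$beta, vcov = ft$vcov,
    logLik = as.numeric(stats::logLik(fit)),
    df = attr(stats::logLik(fit), "df"),
    flags = flags, fit = fit
  )
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Model fit:", x$formula, "\n")
  cat("  family:", x$family, "(", x$link, "link ), n =", x$n_obs, "\n")
  if (length(x$random_terms)) {
    cat("  random terms:", paste(x$random_terms, collapse = ", "), "\n")
  }
  print(cbind(round(x$coefficients[, c("estimate", "ci_low", "ci_high",
                                       "z")], 3),
              p = signif(x$coefficients$p, 3)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Assemble a model fit from explicit coefficients
#'
#' Builds a `model_fit` directly from a coefficient vector and covariance
#' matrix, e.g. published estimates, so that downstream machinery
#' ([bootstrap_rates()], [bootstrap_demography()]) can be driven by known
#' values. A zero covariance matrix gives degenerate (point-mass) draws.
#'
#' @param beta Named coefficient vector on the link scale.
#' @param vcov Covariance matrix (defaults to all zeros).
#' @param formula,family,link Descriptive strings.
#' @return A `model_fit` (without a stored fitted object or likelihood).
#' @export
manual_model_fit <- function(beta, vcov = NULL, formula = "manual",
                             family = "binomial", link = "logit") {
  p <- length(beta)
  if (is.null(vcov)) vcov <- matrix(0, p, p)
  se <- sqrt(diag(vcov))
  z <- ifelse(se > 0, beta / se, NA_real_)
  out <- list(
    formula = formula, family = family, link = link,
    random_terms = character(), n_obs = NA_integer_,
    coefficients = data.frame(
      term = names(beta) %||% paste0("b", seq_len(p)),
      estimate = unname(beta), se = se,
      ci_low = unname(beta - stats::qnorm(0.975) * se),
      ci_high = unname(beta + stats::qnorm(0.975) * se),
      z = unname(z), p = unname(2 * stats::pnorm(-abs(z)))),
    beta = beta, vcov = vcov, logLik = NA_real_, df = p,
    flags = character(), fit = NULL
  )
  class(out) <- "model_fit"
  out
}

#' Fit the tactic- and age-class survival model
#'
#' Logistic mixed model of annual survival on maternal-care tactic and age
#' class with a year random intercept (reference level: yearling, 1.5-year
#' tactic). The tactic-by-age-class interaction is included only if a
#' likelihood-ratio test against the additive model is significant at
#' `interaction_alpha`.
#'
#' @param bear_years Validated bear-year records with known tactic.
#' @param interaction_alpha LRT significance threshold for keeping the
#'   interaction (default 0.05).
#' @param test_interaction Set `FALSE` to skip the interaction model and
#'   fit the additive model directly (e.g. inside replicate loops).
#' @return A `model_fit` with coefficient table, covariance matrix and the
#'   interaction LRT stored in `$interaction_lrt`. Empty tactic-by-age
#'   cells and separation are reported in `$flags`, not fatal.
#' @export
fit_survival <- function(bear_years, interaction_alpha = 0.05,
                         test_interaction = TRUE) {
  d <- validate_bear_years(bear_years)
  d <- d[d$tactic %in% tactic_levels(), , drop = FALSE]
  if (nrow(d) == 0) stop("no records with known tactic", call. = FALSE)
  d$age_class <- age_class(d$age)
  d$tactic <- factor(d$tactic, levels = tactic_levels())
  d$year <- factor(d$year)
  flags <- character()
  cells <- table(d$tactic, d$age_class)
  if (any(cells == 0)) {
    flags <- c(flags, paste("empty tactic x age-class cell(s):",
                            paste(which(cells == 0), collapse = ",")))
  }
  if (length(unique(d$survived)) < 2) {
    flags <- c(flags, "separation: all records share one outcome")
    stop("survival model not estimable: ", flags[length(flags)],
         call. = FALSE)
  }
  add <- suppressMessages(lme4::glmer(
    survived ~ tactic + age_class + (1 | year), data = d,
    family = stats::binomial))
  fit_add <- new_model_fit(add, "survived ~ tactic + age_class + (1|year)",
                           "binomial", "logit", "year", nrow(d), flags)
  lrt <- NULL
  if (test_interaction && all(cells > 0)) {
    full <- try(suppressMessages(suppressWarnings(lme4::glmer(
      survived ~ tactic * age_class + (1 | year), data = d,
      family = stats::binomial))), silent = TRUE)
    if (!inherits(full, "try-error")) {
      fit_full <- new_model_fit(full,
                                "survived ~ tactic * age_class + (1|year)",
                                "binomial", "logit", "year", nrow(d), flags)
      lrt <- lrt_compare(fit_full, fit_add)
      if (is.finite(lrt$p) && lrt$p < interaction_alpha) {
        fit_full$interaction_lrt <- lrt
        return(fit_full)
      }
    }
  }
  fit_add$interaction_lrt <- lrt
  fit_add
}

#' Fit the tactic-specific recruitment model
#'
#' Negative-binomial (NB2, log link) mixed model of the number of yearling
#' daughters produced per adult female-year on maternal-care tactic, with
#' female-identity and year random intercepts. Age class is not included:
#' recruitment is estimated jointly for all producing ages (5 years and
#' older) and the 5-9 and 10+ classes share the fitted value downstream.
#'
#' @param bear_years Validated bear-year records; rows with age >= 5,
#'   known tactic and non-missing `recruits` are used.
#' @return A `model_fit`. A dispersion estimate at the Poisson limit is
#'   flagged, not fatal; all-zero recruits yield a flagged non-estimable
#'   tactic contrast.
#' @export
fit_recruitment <- function(bear_years) {
  d <- validate_bear_years(bear_years)
  d <- d[d$age >= 5 & d$tactic %in% tactic_levels() & !is.na(d$recruits), ,
         drop = FALSE]
  if (nrow(d) == 0) stop("no adult female-years with recruitment data",
                         call. = FALSE)
  d$tactic <- factor(d$tactic, levels = tactic_levels())
  d$year <- factor(d$year)
  flags <- character()
  if (all(d$recruits == 0)) {
    stop("recruitment model not estimable: all counts are zero",
         call. = FALSE)
  }
  # random-effect variances can sit on the boundary in small samples and
  # leave the Hessian singular; drop random terms until the fixed-effect
  # covariance is well defined
  forms <- list(
    recruits ~ tactic + (1 | bear_id) + (1 | year),
    recruits ~ tactic + (1 | bear_id),
    recruits ~ tactic
  )
  rterms <- list(c("bear_id", "year"), "bear_id", character())
  fit <- NULL
  for (k in seq_along(forms)) {
    cand <- try(suppressWarnings(glmmTMB::glmmTMB(
      forms[[k]], data = d, family = glmmTMB::nbinom2)), silent = TRUE)
    if (inherits(cand, "try-error")) next
    V <- try(stats::vcov(cand)$cond, silent = TRUE)
    if (!inherits(V, "try-error") && all(is.finite(V))) {
      fit <- cand
      if (k > 1) flags <- c(flags, paste(
        "random term(s) dropped (boundary fit):",
        paste(setdiff(rterms[[1]], rterms[[k]]), collapse = ", ")))
      random_terms <- rterms[[k]]
      formula_txt <- paste(deparse(forms[[k]]), collapse = "")
      break
    }
  }
  if (is.null(fit)) {
    stop("recruitment model not estimable: no fit with a finite ",
         "fixed-effect covariance", call. = FALSE)
  }
  theta <- stats::sigma(fit)
  if (!is.finite(theta) || theta > 1e4) {
    flags <- c(flags, "dispersion at the Poisson limit")
  }
  out <- new_model_fit(fit, formula_txt, "negative-binomial", "log",
                       random_terms, nrow(d), flags)
  out$dispersion <- theta
  out
}

#' Likelihood-ratio test between nested model fits
#'
#' @param fit_full,fit_reduced `model_fit` objects on the same data, the
#'   reduced model nested in the full one.
#' @return List: `statistic` (`2 * (llik_full - llik_reduced)`), `df`
#'   (parameter-count difference), `p` (chi-square upper tail).
#' @export
lrt_compare <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "model_fit"),
            inherits(fit_reduced, "model_fit"))
  if (fit_full$n_obs != fit_reduced$n_obs) {
    stop("models fitted to different data (n differs)", call. = FALSE)
  }
  df <- fit_full$df - fit_reduced$df
  if (df < 0) stop("fit_full has fewer parameters than fit_reduced; ",
                   "models must be nested full vs reduced", call. = FALSE)
  if (!all(fit_reduced$coefficients$term %in% fit_full$coefficients$term)) {
    stop("models are not nested: reduced model has terms absent from ",
         "the full model", call. = FALSE)
  }
  stat <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  list(statistic = stat, df = df,
       p = if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

# Design rows mapping survival coefficients (intercept, tactic25, age2,
# age3, age48, age9p) to the 10 tactic x age-class survival cells.
survival_design <- function() {
  cells <- expand.grid(age_class = age_class_levels(),
                       tactic = tactic_levels(), stringsAsFactors = FALSE)
  X <- cbind(
    1,
    cells$tactic == "T25",
    cells$age_class == "2", cells$age_class == "3",
    cells$age_class == "4-8", cells$age_class == "9+"
  )
  list(cells = cells, X = X)
}

#' Parametric-bootstrap table of tactic- and age-class-specific rates
#'
#' Draws coefficient vectors from the asymptotic normal sampling
#' distribution of each model's fixed effects (random effects at zero:
#' population-level prediction), back-transforms every draw to the rate
#' cells -- five survival probabilities per tactic and one recruitment
#' value per tactic shared by the 5-9 and 10+ classes -- and summarizes
#' each cell by its mean and 2.5/97.5 percentiles. With coefficient
#' uncertainty set to zero the intervals collapse to the point predictions.
#'
#' @param fit_survival A `model_fit` from [fit_survival()] (additive model).
#' @param fit_recruitment A `model_fit` from [fit_recruitment()].
#' @param n_bootstrap Number of draws (default 10000).
#' @param seed Integer seed.
#' @param scale_vcov Multiplier on the covariance matrices (0 collapses the
#'   intervals; used for degenerate-uncertainty checks).
#' @return A `rate_table`: data frame with columns `tactic`, `cell`
#'   (`S1`, `S2`, `S3`, `S4-8`, `S9+`, `R5-9`, `R10+`), `mean`, `ci_low`,
#'   `ci_high`, `point`; the per-draw matrices are kept in
#'   `attr(, "draws")` for downstream demographic propagation.
#' @export
bootstrap_rates <- function(fit_survival, fit_recruitment,
                            n_bootstrap = 10000, seed = 1,
                            scale_vcov = 1) {
  stopifnot(inherits(fit_survival, "model_fit"),
            inherits(fit_recruitment, "model_fit"))
  if (length(fit_survival$beta) != 6) {
    stop("bootstrap_rates requires the additive survival model ",
         "(6 coefficients)", call. = FALSE)
  }
  set.seed(seed)
  bs <- draw_coefs(fit_survival$beta, fit_survival$vcov * scale_vcov,
                   n_bootstrap)
  br <- draw_coefs(fit_recruitment$beta[1:2],
                   fit_recruitment$vcov[1:2, 1:2] * scale_vcov, n_bootstrap)
  des <- survival_design()
  s_draws <- stats::plogis(bs %*% t(des$X))            # n x 10
  r_draws <- cbind(T15 = exp(br[, 1]), T25 = exp(br[, 1] + br[, 2]))
  bad <- !is.finite(rowSums(s_draws)) | !is.finite(rowSums(r_draws))
  if (mean(bad) > 0.01) {
    stop("more than 1% of bootstrap draws were non-finite", call. = FALSE)
  }
  if (any(bad)) {
    s_draws <- s_draws[!bad, , drop = FALSE]
    r_draws <- r_draws[!bad, , drop = FALSE]
  }
  s_point <- stats::plogis(des$X %*% fit_survival$beta)[, 1]
  r_point <- c(T15 = exp(fit_recruitment$beta[[1]]),
               T25 = exp(fit_recruitment$beta[[1]] +
                           fit_recruitment$beta[[2]]))
  qs <- function(m) apply(m, 2, stats::quantile, c(0.025, 0.975))
  sq <- qs(s_draws); rq <- qs(r_draws)
  tab <- rbind(
    data.frame(tactic = des$cells$tactic,
               cell = paste0("S", des$cells$age_class),
               mean = colMeans(s_draws),
               ci_low = sq[1, ], ci_high = sq[2, ], point = s_point),
    data.frame(tactic = rep(tactic_levels(), each = 2),
               cell = rep(c("R5-9", "R10+"), 2),
               mean = rep(colMeans(r_draws), each = 2),
               ci_low = rep(rq[1, ], each = 2),
               ci_high = rep(rq[2, ], each = 2),
               point = rep(r_point, each = 2))
  )
  rownames(tab) <- NULL
  attr(tab, "draws") <- list(survival = s_draws, recruitment = r_draws,
                             cells = des$cells)
  attr(tab, "n_bootstrap") <- nrow(s_draws)
  class(tab) <- c("rate_table", "data.frame")
  tab
}

draw_coefs <- function(beta, V, n) {
  if (any(!is.finite(V))) {
    stop("coefficient covariance contains non-finite entries; ",
         "the fit did not converge", call. = FALSE)
  }
  if (all(V == 0)) {
    matrix(rep(beta, each = n), nrow = n,
           dimnames = list(NULL, names(beta)))
  } else {
    MASS::mvrnorm(n, beta, V)
  }
}

# Extract the (S1, S2, S3, S4-8, S9+, R) vector for one tactic from a rate
# table, using the requested column ("mean" or "point").
rates_for_tactic <- function(rate_table, tactic, column = "mean") {
  rt <- rate_table[rate_table$tactic == tactic, , drop = FALSE]
  get <- function(cell) rt[[column]][match(cell, rt$cell)]
  list(s = c(get("S1"), get("S2"), get("S3"), get("S4-8"), get("S9+")),
       r59 = get("R5-9"), r10p = get("R10+"))
}

#' Protective effect of family-group status on adult female survival
#'
#' For adult (>= 4 y.o.) bear-years with known status, fits a logistic
#' mixed model of survival on hunting-season status (solitary vs member of
#' a family group) controlling for age (linear fixed effect) with a year
#' random intercept, and decomposes the finite mortality rate of each
#' status by cause with binomial CIs (see [rate_ci()]).
#'
#' @param bear_years Validated bear-year records.
#' @param ci_method CI method for the raw rates, `"wald"` (default,
#'   reproduces the reported intervals) or `"wilson"`.
#' @return List of class `protection_result`: `odds_ratio` (solitary vs
#'   family group, with CI), `rates` (data frame of per-status total and
#'   hunting-induced mortality with CIs, events and exposures), and
#'   `hunting_odds_ratio` (odds of hunting death, solitary vs family).
#'   With a single status present, rates only and a flag.
#' @export
protection_effect <- function(bear_years, ci_method = "wald") {
  d <- validate_bear_years(bear_years)
  d <- d[d$age >= 4 & d$status %in% c("solitary", "with_offspring"), ,
         drop = FALSE]
  if (nrow(d) == 0) stop("no adult records with known status", call. = FALSE)
  d$family <- d$status == "with_offspring"
  mk_rates <- function(sub, label) {
    n <- nrow(sub)
    deaths <- sum(!sub$survived)
    hunt <- sum(sub$cause_of_death == "hunting")
    tot <- rate_ci(deaths, n, method = ci_method)
    hu <- rate_ci(hunt, n, method = ci_method)
    data.frame(status = label, n = n, deaths = deaths, hunting_deaths = hunt,
               mortality = tot["rate"], mortality_low = tot["lower"],
               mortality_high = tot["upper"], hunting_mortality = hu["rate"],
               hunting_low = hu["lower"], hunting_high = hu["upper"],
               row.names = NULL)
  }
  rates <- rbind(
    if (any(sub <- !d$family)) mk_rates(d[sub, ], "solitary"),
    if (any(sub <- d$family)) mk_rates(d[sub, ], "family_group")
  )
  res <- list(rates = rates, n_obs = nrow(d))
  class(res) <- "protection_result"
  if (length(unique(d$family)) < 2) {
    res$flag <- "single status present; odds ratio not estimable"
    return(res)
  }
  d$year <- factor(d$year)
  fit <- suppressMessages(lme4::glmer(
    survived ~ family + age + (1 | year), data = d,
    family = stats::binomial))
  ft <- fixef_table(fit)
  i <- grep("^familyFALSE|^family", ft$table$term)[1]
  # coefficient is for family membership; solitary-vs-family OR on survival
  # is its negation
  res$odds_ratio <- exp(-ft$table$estimate[i])
  res$or_ci_low <- exp(-ft$table$ci_high[i])
  res$or_ci_high <- exp(-ft$table$ci_low[i])
  res$model <- new_model_fit(fit, "survived ~ family + age + (1|year)",
                             "binomial", "logit", "year", nrow(d))
  ps <- rates$hunting_mortality[rates$status == "solitary"]
  pf <- rates$hunting_mortality[rates$status == "family_group"]
  res$hunting_odds_ratio <- if (pf > 0 && ps < 1) {
    (ps / (1 - ps)) / (pf / (1 - pf))
  } else NA_real_
  res
}

#' @export
print.protection_result <- function(x, ...) {
  cat("Protective effect of family-group status (n =", x$n_obs, "bear-years)\n")
  if (!is.null(x$odds_ratio)) {
    cat(sprintf("  survival OR solitary vs family: %.2f [%.2f, %.2f]\n",
                x$odds_ratio, x$or_ci_low, x$or_ci_high))
  }
  print(cbind(x$rates[, c("status", "n", "deaths", "hunting_deaths")],
              round(x$rates[, c("mortality", "mortality_low",
                                "mortality_high", "hunting_mortality",
                                "hunting_low", "hunting_high")], 3)))
  invisible(x)
}
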