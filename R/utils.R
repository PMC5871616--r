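# Internal helpers shared across modules.

#' Age class of a female bear
#'
#' Maps integer age (years, >= 1) to the five-class age structure used for
#' survival estimation: yearling (1), 2 y.o., 3 y.o., prime-age adults
#' (4-8 y.o.) and older adults (9+ y.o.).
#'
#' @param age Integer vector of ages in years, all >= 1.
#' @return Factor with levels `"1"`, `"2"`, `"3"`, `"4-8"`, `"9+"`.
#' @export
#' @examples
#' age_class(c(1, 2, 5, 8, 9, 20))
age_class <- function(age) {
  if (any(!is.na(age) & (age < 1 | age != floor(age)))) {
    stop("ages must be integers >= 1", call. = FALSE)
  }
  cls <- ifelse(age >= 9, "9+", ifelse(age >= 4, "4-8", as.character(age)))
  factor(cls, levels = age_class_levels())
}

age_class_levels <- function() c("1", "2", "3", "4-8", "9+")

tactic_levels <- function() c("T15", "T25")

#' Binomial confidence interval for a finite rate
#'
#' Events over exposure with a two-sided 95% interval. The default normal
#' (Wald) interval reproduces the reported mortality-rate intervals for this
#' study system at two decimals; the Wilson score interval is available for
#' small-count robustness.
#'
#' @param x Number of events.
#' @param n Exposure (trials).
#' @param method `"wald"` or `"wilson"`.
#' @param conf Confidence level, default 0.95.
#' @return Named numeric vector `c(rate, lower, upper)`, truncated to `[0, 1]`.
#' @export
#' @examples
#' rate_ci(9, 207)   # hunting deaths among family-group bear-years
#' rate_ci(55, 407)  # hunting deaths among solitary bear-years
rate_ci <- function(x, n, method = c("wald", "wilson"), conf = 0.95) {
  method <- match.arg(method)
  stopifnot(n > 0, x >= 0, x <= n)
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "wald") {
    hw <- z * sqrt(p * (1 - p) / n)
    ci <- c(p - hw, p + hw)
  } else {
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    ci <- c(ctr - hw, ctr + hw)
  }
  c(rate = p, lower = max(0, ci[1]), upper = min(1, ci[2]))
}

# Wald CI on the link scale for a fitted coefficient.
coef_ci <- function(est, se, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(est - z * se, est + z * se)
}

# Coefficient table (link scale) from an lme4 / glmmTMB fit.
fixef_table <- function(fit) {
  if (inherits(fit, "glmmTMB")) {
    co <- summary(fit)$coefficients$cond
    beta <- glmmTMB::fixef(fit)$cond
    V <- stats::vcov(fit)$cond
  } else if (inherits(fit, "merMod")) {
    co <- summary(fit)$coefficients
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
  } else {
    co <- summary(fit)$coefficients
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
  }
  se <- co[, "Std. Error"]
  z <- beta / se
  tab <- data.frame(
    term = names(beta),
    estimate = unname(beta),
    se = unname(se),
    ci_low = unname(beta - stats::qnorm(0.975) * se),
    ci_high = unname(beta + stats::qnorm(0.975) * se),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    row.names = NULL
  )
  list(table = tab, beta = beta, vcov = as.matrix(V))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
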