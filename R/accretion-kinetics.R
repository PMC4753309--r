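# Exponential accretion/biomass kinetics: nonlinear least-squares fit of
# x = x0 * exp(k t) plus the secondary quantities derived from it.

# deterministic starting values from log-linear regression on positive points
.loglinear_start <- function(t, x) {
  pos <- x > 0
  if (sum(pos) >= 2 && length(unique(t[pos])) >= 2) {
    co <- stats::coef(stats::lm(log(x[pos]) ~ t[pos]))
    list(x0 = exp(co[[1]]), k = co[[2]])
  } else {
    list(x0 = max(mean(x), .Machine$double.eps), k = 0)
  }
}

#' Fit the exponential accretion model
#'
#' Nonlinear least squares fit of \eqn{x = x_0 e^{kt}} (Levenberg-Marquardt),
#' initialised deterministically from a log-linear regression on the positive
#' points. The standard error of `k` comes from the Jacobian-based covariance
#' matrix and its p-value from a two-sided Wald t-test of \eqn{k = 0} on the
#' residual degrees of freedom, as in a standard nonlinear-regression
#' summary. Censored (below-detection) points are excluded by default or can
#' be substituted at half the detection limit.
#'
#' @param series an [AccretionSeries-class], or a data.frame with columns
#'   `t_days` (or `t`), `x` and optionally `censored`.
#' @param init optional named list/vector with starting `x0` and `k`.
#' @param censored_action `"exclude"` drops censored points;
#'   `"substitute"` replaces them by `detection_limit / 2`.
#' @param detection_limit required when `censored_action = "substitute"`.
#' @param vcov covariance estimator behind `se_k`: `"iid"` (default, the
#'   homoscedastic covariance of a standard NLS summary) or `"robust"` (HC3
#'   sandwich). Field accretion data typically carry multiplicative,
#'   mean-proportional error, under which the iid standard errors are
#'   anticonservative; use `"robust"` when interval coverage matters.
#'
#' @return An [ExponentialFit-class]. `converged` is `FALSE` (with a warning)
#'   if the optimizer failed.
#' @examples
#' s <- genAccretionSeries(siteConfig("osp"))
#' fitExponential(s)
#' @export
fitExponential <- function(series, init = NULL,
                           censored_action = c("exclude", "substitute"),
                           detection_limit = NULL,
                           vcov = c("iid", "robust")) {
  censored_action <- match.arg(censored_action)
  vcov <- match.arg(vcov)
  if (is.data.frame(series)) {
    tcol <- if ("t_days" %in% names(series)) "t_days" else "t"
    series <- accretionSeries(series[[tcol]], series$x,
                              censored = if ("censored" %in% names(series))
                                series$censored else rep(FALSE, nrow(series)),
                              units = "")
  }
  stopifnot(is(series, "AccretionSeries"))
  t <- obsTimes(series); x <- obsValues(series); cens <- isCensored(series)
  if (all(cens)) stop("all points are censored; nothing to fit")
  if (censored_action == "exclude") {
    t <- t[!cens]; x <- x[!cens]
  } else {
    if (is.null(detection_limit))
      stop("detection_limit is required for censored_action = 'substitute'")
    x[cens] <- detection_limit / 2
  }
  if (length(t) < 3) stop("need >= 3 usable points")
  if (length(unique(t)) < 2) stop("need >= 2 distinct times")

  start <- if (is.null(init)) .loglinear_start(t, x)
           else list(x0 = init[["x0"]], k = init[["k"]])
  # exact fit at the starting values (noiseless data): nothing to optimise,
  # and Levenberg-Marquardt would stall on an all-zero residual vector
  r0 <- x - start$x0 * exp(start$k * t)
  if (sum(r0^2) <= 1e-24 * max(1, sum(x^2))) {
    return(new("ExponentialFit", x0 = start$x0, k = start$k, se_x0 = 0,
               se_k = 0, p_value_k = NA_real_,
               residual_df = length(t) - 2L, converged = TRUE,
               units = series@units))
  }
  df <- data.frame(t = t, x = x)
  fit <- tryCatch(
    minpack.lm::nlsLM(x ~ x0 * exp(k * t), data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("exponential fit did not converge: ", conditionMessage(fit))
    return(new("ExponentialFit", x0 = start$x0, k = start$k,
               se_x0 = NA_real_, se_k = NA_real_, p_value_k = NA_real_,
               residual_df = length(t) - 2L, converged = FALSE,
               units = series@units))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  rdf <- sm$df[2]
  if (vcov == "robust") {
    se <- .hc3_se(t, x, co["x0", "Estimate"], co["k", "Estimate"])
    se_x0 <- se[["x0"]]; se_k <- se[["k"]]
  } else {
    se_x0 <- co["x0", "Std. Error"]; se_k <- co["k", "Std. Error"]
  }
  p_k <- if (is.finite(se_k) && se_k > 0)
    2 * stats::pt(abs(co["k", "Estimate"] / se_k), df = rdf,
                  lower.tail = FALSE)
  else NA_real_
  new("ExponentialFit", x0 = co["x0", "Estimate"], k = co["k", "Estimate"],
      se_x0 = se_x0, se_k = se_k, p_value_k = p_k,
      residual_df = as.integer(rdf), converged = TRUE, units = series@units)
}

# HC3 sandwich standard errors for the exponential model at the NLS estimate
.hc3_se <- function(t, x, x0, k) {
  r <- x - x0 * exp(k * t)
  J <- cbind(x0 = exp(k * t), k = x0 * t * exp(k * t))
  bread <- solve(crossprod(J))
  h <- pmin(rowSums((J %*% bread) * J), 1 - 1e-8)
  V <- bread %*% crossprod(J * (r / (1 - h))) %*% bread
  stats::setNames(sqrt(diag(V)), c("x0", "k"))
}

#' @describeIn fitExponential Predicted value \eqn{x_0 e^{kt}} at new times.
#' @param object an [ExponentialFit-class].
#' @param t times (days) at which to predict.
#' @param ... unused.
#' @export
setMethod("predict", "ExponentialFit", function(object, t, ...) {
  object@x0 * exp(object@k * t)
})

#' Instantaneous accretion rate
#'
#' Time derivative of the fitted exponential, \eqn{dx/dt = k x_0 e^{kt}}, in
#' series units per day. Peaks at the end of the incubation for \eqn{k > 0}
#' (maximum observed accretion rate).
#'
#' @param fit an [ExponentialFit-class].
#' @param t time (days), vectorised.
#' @return Rate in series units day\eqn{^{-1}}.
#' @examples
#' f <- fitExponential(genAccretionSeries(siteConfig("osp")))
#' instantaneousRate(f, 70)
#' @export
instantaneousRate <- function(fit, t) {
  stopifnot(is(fit, "ExponentialFit"))
  fit@k * fit@x0 * exp(fit@k * t)
}

#' Apparent lag time before detectable accretion
#'
#' Time for the pure exponential to reach a detection limit:
#' \eqn{\ln(\mathrm{limit}/x_0)/k} when the limit exceeds \eqn{x_0}, else 0.
#' The "lag" is apparent: growth is exponential throughout, but the product
#' is undetectable early on.
#'
#' @param fit an [ExponentialFit-class].
#' @param detection_limit limit in series units.
#' @return Days, or `NA` when \eqn{k \le 0} and the limit is never reached.
#' @export
lagTime <- function(fit, detection_limit) {
  stopifnot(is(fit, "ExponentialFit"))
  if (detection_limit <= fit@x0) return(0)
  if (fit@k <= 0) return(NA_real_)
  log(detection_limit / fit@x0) / fit@k
}

#' Convert a vertical mat growth rate to micrometres per day
#'
#' @param thickness_mm_per_month vertical accretion in mm per month.
#' @param days_per_month month length used for conversion (default 30).
#' @return \eqn{\mu}m day\eqn{^{-1}}.
#' @examples
#' verticalGrowthRate(0.5)  # 0.5 mm/month ~ 17 um/day
#' @export
verticalGrowthRate <- function(thickness_mm_per_month, days_per_month = 30) {
  thickness_mm_per_month * 1000 / days_per_month
}

#' Compare endpoint accretion between two sites
#'
#' Two-sided two-sample t-test on endpoint measurements (e.g. day-70 Fe
#' loads at two springs). Defaults to the pooled-variance Student form; set
#' `welch = TRUE` for the unequal-variance variant.
#'
#' @param groupA,groupB numeric vectors, >= 2 values each.
#' @param welch use the Welch correction.
#' @return list with `t_stat`, `p_value`, `df`.
#' @examples
#' compareEndpoints(c(15.2, 16.8, 17.1), c(7.4, 8.9, 8.1))
#' @export
compareEndpoints <- function(groupA, groupB, welch = FALSE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs >= 2 values")
  ht <- stats::t.test(groupA, groupB, var.equal = !welch)
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
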