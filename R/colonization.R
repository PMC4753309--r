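# Early-colonization estimates from SEM field-of-view cell counts.

.check_counts_df <- function(observations) {
  need <- setdiff(c("t_days", "field_area_cm2", "morphotype", "count"),
                  names(observations))
  if (length(need))
    stop("count table is missing columns: ", paste(need, collapse = ", "))
  if (any(observations$count < 0)) stop("counts must be >= 0")
  if (any(observations$field_area_cm2 <= 0))
    stop("field areas must be > 0")
  invisible(observations)
}

#' Areal cell density per field of view
#'
#' @param observations data.frame of field counts with columns `t_days`,
#'   `field_id`, `field_area_cm2`, `morphotype`, `count` (the format
#'   [genCountFields()] emits).
#' @return The same data.frame with a `density_cm2` column (cells
#'   cm\eqn{^{-2}}).
#' @examples
#' arealDensity(genCountFields(3.7e6, times = c(5, 10), field_area = 1e-5))
#' @export
arealDensity <- function(observations) {
  .check_counts_df(observations)
  observations$density_cm2 <- observations$count /
    observations$field_area_cm2
  observations
}

#' Colonization rate of a morphotype
#'
#' Through-origin least-squares slope of mean areal density against
#' incubation time (density is necessarily zero at deployment, so the line
#' is forced through the origin). The spread is the standard deviation of
#' the per-field slopes (density / t per field), reflecting between-field
#' heterogeneity.
#'
#' @param observations data.frame of field counts (see [arealDensity()]).
#' @param morphotype which morphotype to estimate (default: the only one
#'   present; required if several).
#' @return list with `rate` (cells cm\eqn{^{-2}} day\eqn{^{-1}}), `sd`,
#'   `n_fields`.
#' @examples
#' obs <- genCountFields(3.7e6, times = c(5, 10, 15), field_area = 1e-5)
#' colonizationRate(obs)
#' @export
colonizationRate <- function(observations, morphotype = NULL) {
  .check_counts_df(observations)
  if (is.null(morphotype)) {
    morphotype <- unique(observations$morphotype)
    if (length(morphotype) > 1)
      stop("several morphotypes present; specify one of: ",
           paste(morphotype, collapse = ", "))
  }
  obs <- observations[observations$morphotype == morphotype, , drop = FALSE]
  if (!nrow(obs)) stop("no observations for morphotype '", morphotype, "'")
  obs <- arealDensity(obs)
  obs <- obs[obs$t_days > 0, , drop = FALSE]
  if (!nrow(obs)) stop("all observations are at t = 0; rate is undefined")
  dbar <- stats::aggregate(density_cm2 ~ t_days, data = obs, FUN = mean)
  rate <- sum(dbar$t_days * dbar$density_cm2) / sum(dbar$t_days^2)
  per_field <- obs$density_cm2 / obs$t_days
  list(rate = rate,
       sd = if (length(per_field) > 1) stats::sd(per_field) else 0,
       n_fields = nrow(obs))
}

#' Ratio of two colonization rates
#'
#' @param rate_a,rate_b rates in the same units; `rate_b` must be non-zero.
#' @return Dimensionless ratio `rate_a / rate_b`.
#' @examples
#' rateRatio(3.7e6, 9.2e5)  # rod vs coccus
#' @export
rateRatio <- function(rate_a, rate_b) {
  if (rate_b == 0) stop("denominator rate is zero; ratio undefined")
  rate_a / rate_b
}
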