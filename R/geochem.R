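# Oxalate-extraction geochemistry: areal elemental loadings, oxyanion:Fe
# molar ratios, and channel-hydrodynamics context.

#' Areal elemental loading from an oxalate extraction
#'
#' Converts a solution concentration to the amount of element per unit slide
#' area: `mg L-1 x L / (g mol-1) / cm2`, expressed in \eqn{\mu}mol
#' cm\eqn{^{-2}}. Additive over split extractions of the same slide.
#'
#' @param record an [ExtractionSet-class].
#' @param element element symbol present in the record.
#' @param molar_mass g mol\eqn{^{-1}}; defaults to the packaged value from
#'   [molarMasses()].
#' @return data.frame with columns `t_days`, `element`, `umol_cm2`.
#' @examples
#' es <- genExtractionTable(siteConfig("osp"))
#' arealLoading(es, "Fe")
#' @export
arealLoading <- function(record, element, molar_mass = NULL) {
  stopifnot(is(record, "ExtractionSet"))
  if (is.null(molar_mass)) {
    mm <- molarMasses()
    if (!element %in% names(mm))
      stop("no packaged molar mass for '", element,
           "'; supply molar_mass explicitly")
    molar_mass <- mm[[element]]
  }
  df <- record@data[record@data$element == element, , drop = FALSE]
  if (!nrow(df)) stop("element '", element, "' not present in the record")
  # mg / (g mol-1) = mmol; x 1000 = umol
  data.frame(t_days = df$t_days, element = element,
             umol_cm2 = df$mg_per_L * record@extraction_volume /
               molar_mass * 1000 / record@slide_area)
}

#' Oxyanion-to-iron molar ratio series
#'
#' Ratio of molar areal loadings of two elements at each extraction time
#' point. Volume and area cancel, so the ratio depends only on the solution
#' concentrations and molar masses. Time points where the denominator
#' loading is zero are reported as `NA` (absent), and a zero numerator gives
#' a ratio of 0.
#'
#' @param record an [ExtractionSet-class].
#' @param numerator,denominator element symbols (e.g. `"As"`, `"Fe"`).
#' @param molar_masses optional named override of [molarMasses()].
#' @return data.frame with columns `t_days`, `ratio`, plus attributes `pair`
#'   and summary columns via [summary()] of the caller's choosing.
#' @examples
#' es <- genExtractionTable(siteConfig("beowulf"))
#' mean(molarRatio(es, "As", "Fe")$ratio)  # 0.67
#' @export
molarRatio <- function(record, numerator, denominator = "Fe",
                       molar_masses = NULL) {
  mm <- molarMasses()
  if (!is.null(molar_masses)) mm[names(molar_masses)] <- molar_masses
  num <- arealLoading(record, numerator, mm[[numerator]])
  den <- arealLoading(record, denominator, mm[[denominator]])
  m <- merge(num, den, by = "t_days", suffixes = c("_num", "_den"))
  ratio <- ifelse(m$umol_cm2_den > 0, m$umol_cm2_num / m$umol_cm2_den,
                  NA_real_)
  out <- data.frame(t_days = m$t_days, ratio = ratio)
  attr(out, "pair") <- c(numerator, denominator)
  out
}

#' Summary of a molar-ratio series
#'
#' Per-series mean and standard error, the summary form in which constant
#' sorption ratios are usually reported.
#'
#' @param ratios data.frame from [molarRatio()].
#' @return list with `mean`, `se`, `n`.
#' @export
ratioSummary <- function(ratios) {
  r <- ratios$ratio[!is.na(ratios$ratio)]
  list(mean = mean(r),
       se = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0,
       n = length(r))
}

#' Channel Reynolds number
#'
#' \eqn{Re = vL/\nu} for the outflow channel; distinguishes the quiescent
#' (~10\eqn{^3}) from the turbulent (~10\eqn{^4}) spring channels, which
#' correlates with how much oxide is retained on slides.
#'
#' @param velocity channel velocity, cm s\eqn{^{-1}}.
#' @param characteristic_length e.g. water depth, cm.
#' @param kinematic_viscosity cm\eqn{^2} s\eqn{^{-1}} (about 4.2e-3 for
#'   water near 70 degC... supply the value for the relevant temperature).
#' @return Dimensionless Reynolds number.
#' @examples
#' reynoldsNumber(25, 2, 4.2e-3)  # ~1.2e4, a turbulent channel
#' @export
reynoldsNumber <- function(velocity, characteristic_length,
                           kinematic_viscosity) {
  if (any(c(velocity, characteristic_length, kinematic_viscosity) <= 0))
    stop("velocity, length and viscosity must all be > 0")
  velocity * characteristic_length / kinematic_viscosity
}
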