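#' @import methods
NULL

#' Accretion / biomass time series
#'
#' Areal time series measured on slides incubated in a spring outflow channel:
#' oxalate-extractable Fe(III)-oxide (\eqn{\mu}mol cm\eqn{^{-2}}) or total DNA
#' (ng cm\eqn{^{-2}}) as a function of incubation time. Points that fall below
#' an analytical detection limit are carried with a censoring flag rather than
#' being dropped, mirroring slides recovered without visible oxide deposition.
#'
#' @slot t numeric, incubation time in days (non-negative, increasing).
#' @slot x numeric, measured areal quantity; same length as `t`.
#' @slot censored logical, TRUE where the value is below detection.
#' @slot units character scalar, units of `x`.
#' @slot what character scalar, analyte label (e.g. `"Fe"`, `"DNA"`).
#'
#' @seealso [genAccretionSeries()], [fitExponential()]
#' @export
setClass("AccretionSeries",
  representation(t = "numeric", x = "numeric", censored = "logical",
                 units = "character", what = "character"),
  prototype(units = "umol cm-2", what = "Fe"))

setValidity("AccretionSeries", function(object) {
  msg <- NULL
  if (length(object@t) != length(object@x))
    msg <- c(msg, "t and x must have equal length")
  if (length(object@censored) != length(object@x))
    msg <- c(msg, "censored flag must match length of x")
  if (length(object@t) && any(object@t < 0))
    msg <- c(msg, "times must be non-negative")
  if (length(object@t) > 1 && any(diff(object@t) < 0))
    msg <- c(msg, "times must be non-decreasing")
  if (any(object@x[!object@censored] < 0, na.rm = TRUE))
    msg <- c(msg, "non-censored values must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Fitted exponential accretion model
#'
#' Result of a nonlinear least-squares fit of \eqn{x = x_0 e^{kt}} to an
#' [AccretionSeries-class]. Standard errors come from the Jacobian-based
#' covariance of the fit; the p-value is a two-sided Wald t-test of
#' \eqn{k = 0} on the residual degrees of freedom.
#'
#' @slot x0 numeric, fitted initial quantity (units of the series).
#' @slot k numeric, first-order rate constant (day\eqn{^{-1}}).
#' @slot se_x0,se_k numeric, asymptotic standard errors.
#' @slot p_value_k numeric, Wald p-value for k = 0.
#' @slot residual_df integer, residual degrees of freedom.
#' @slot converged logical.
#' @slot units character scalar, units of `x0`.
#'
#' @export
setClass("ExponentialFit",
  representation(x0 = "numeric", k = "numeric", se_x0 = "numeric",
                 se_k = "numeric", p_value_k = "numeric",
                 residual_df = "integer", converged = "logical",
                 units = "character"))

setValidity("ExponentialFit", function(object) {
  msg <- NULL
  if (length(object@se_k) && !is.na(object@se_k) && object@se_k < 0)
    msg <- c(msg, "se_k must be >= 0")
  p <- object@p_value_k
  if (length(p) && !is.na(p) && (p < 0 || p > 1))
    msg <- c(msg, "p_value_k must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Oxygen microprofile
#'
#' Depth profile of dissolved O2 measured with a Clark-type microelectrode.
#' Depth is in micrometres, zero at the mat-water interface and positive into
#' the mat.
#'
#' @slot z numeric, depth in \eqn{\mu}m (increasing, zero at the interface).
#' @slot conc numeric, O2 concentration in \eqn{\mu}M; same length as `z`.
#' @slot c_bulk numeric scalar, bulk-water O2 (\eqn{\mu}M), used to
#'   non-dimensionalise the profile.
#' @slot temperature numeric scalar, degrees C (NA if unknown).
#'
#' @seealso [genMicroprofile()], [estimateFlux()], [fitProfile()]
#' @export
setClass("Microprofile",
  representation(z = "numeric", conc = "numeric", c_bulk = "numeric",
                 temperature = "numeric"),
  prototype(c_bulk = 1, temperature = NA_real_))

setValidity("Microprofile", function(object) {
  msg <- NULL
  if (length(object@z) != length(object@conc))
    msg <- c(msg, "z and conc must have equal length")
  if (length(object@z) > 1 && any(diff(object@z) <= 0))
    msg <- c(msg, "depths must be strictly increasing")
  if (any(object@conc < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (length(object@c_bulk) != 1 || object@c_bulk <= 0)
    msg <- c(msg, "c_bulk must be a single positive value")
  if (is.null(msg)) TRUE else msg
})

#' Steady-state reaction-diffusion model of a mat slab
#'
#' Parameters of the dimensionless steady-state O2 balance in a mat of
#' thickness \eqn{L_f} with effective diffusivity \eqn{D_e}: first-order
#' consumption (rate constant \eqn{k_1}, s\eqn{^{-1}}) gives
#' \eqn{u(\zeta) = \cosh(\phi(1-\zeta))/\cosh(\phi)}; zero-order consumption
#' (rate \eqn{k_0}, \eqn{\mu}M s\eqn{^{-1}}) gives the quadratic
#' \eqn{u = \phi^2\zeta^2/2 - \phi^2\zeta + 1} clipped at zero. In both cases
#' \eqn{u = C/C_0} and \eqn{\zeta = z/L_f}; the Thiele modulus is
#' \eqn{\phi^2 = k_1 L_f^2 / D_e}.
#'
#' @slot kinetic_order character, `"first"` or `"zero"`.
#' @slot rate_constant numeric, \eqn{k_1} (s\eqn{^{-1}}) for first order or
#'   \eqn{k_0} (\eqn{\mu}M s\eqn{^{-1}}) for zero order.
#' @slot D_e numeric, effective diffusion coefficient (cm\eqn{^2}
#'   s\eqn{^{-1}}).
#' @slot L_f numeric, mat thickness (cm).
#' @slot C0 numeric, interface concentration (\eqn{\mu}M).
#'
#' @export
setClass("ReactionDiffusionModel",
  representation(kinetic_order = "character", rate_constant = "numeric",
                 D_e = "numeric", L_f = "numeric", C0 = "numeric"))

setValidity("ReactionDiffusionModel", function(object) {
  msg <- NULL
  if (!object@kinetic_order %in% c("first", "zero"))
    msg <- c(msg, "kinetic_order must be 'first' or 'zero'")
  if (object@D_e <= 0) msg <- c(msg, "D_e must be > 0")
  if (object@L_f <= 0) msg <- c(msg, "L_f must be > 0")
  if (object@rate_constant < 0) msg <- c(msg, "rate constant must be >= 0")
  if (object@C0 < 0) msg <- c(msg, "C0 must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Diffusive flux estimate at the mat-water interface
#'
#' Fick's-first-law flux \eqn{J = D_e |dC/dz|_{z=0}} with the interface
#' gradient estimated from the uppermost profile points. J is reported
#' positive for O2 moving into the mat (consumption).
#'
#' @slot J numeric, flux in \eqn{\mu}mol cm\eqn{^{-2}} s\eqn{^{-1}}.
#' @slot gradient numeric, interface gradient in \eqn{\mu}M
#'   \eqn{\mu}m\eqn{^{-1}} (signed; negative when C decreases with depth).
#' @slot window integer, indices of the profile points used.
#' @slot D_e numeric, diffusivity used (cm\eqn{^2} s\eqn{^{-1}}).
#' @slot method character, gradient estimator used.
#'
#' @export
setClass("FluxEstimate",
  representation(J = "numeric", gradient = "numeric", window = "integer",
                 D_e = "numeric", method = "character"))

#' Fitted dimensionless profile model
#'
#' @slot phi numeric, fitted Thiele modulus.
#' @slot rate_constant numeric, rate constant back-computed from `phi` with
#'   the supplied `L_f` and `D_e` (\eqn{k_1 = \phi^2 D_e / L_f^2} for first
#'   order).
#' @slot rmse numeric, root-mean-square residual in dimensionless u units.
#' @slot kinetic_order character.
#' @slot D_e,L_f numeric, values supplied to the fit (cm\eqn{^2}
#'   s\eqn{^{-1}}, cm).
#'
#' @export
setClass("ProfileFit",
  representation(phi = "numeric", rate_constant = "numeric", rmse = "numeric",
                 kinetic_order = "character", D_e = "numeric",
                 L_f = "numeric"))

#' Taxon-by-sample community table
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] holding a taxon x
#' sample abundance matrix (assay `"abundance"`), per-taxon 16S rRNA gene
#' copy numbers in `rowData(x)$copy_number`, and per-sample metadata columns
#' `site`, `day` and `depth_zone` (one of `"top"`, `"middle"`, `"bottom"`,
#' `"none"`). `metadata(x)$mode` records whether the assay holds raw
#' `"counts"` or `"proportions"`; proportion columns must each sum to 1.
#'
#' @seealso [MatCommunity()], [relativeAbundance()], [brayCurtisMatrix()]
#' @export
setClass("MatCommunity", contains = "SummarizedExperiment")

setValidity("MatCommunity", function(object) {
  msg <- NULL
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"copy_number" %in% colnames(rd))
    msg <- c(msg, "rowData must contain 'copy_number'")
  else if (any(rd$copy_number < 1))
    msg <- c(msg, "copy numbers must be >= 1")
  cd <- SummarizedExperiment::colData(object)
  need <- setdiff(c("site", "day", "depth_zone"), colnames(cd))
  if (length(need))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  mode <- S4Vectors::metadata(object)$mode
  if (is.null(mode) || !mode %in% c("counts", "proportions"))
    msg <- c(msg, "metadata(x)$mode must be 'counts' or 'proportions'")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "abundances must be >= 0")
  if (identical(mode, "proportions") && ncol(a) && !anyNA(a) &&
      any(abs(colSums(a) - 1) > 1e-9))
    msg <- c(msg, "proportion columns must each sum to 1 (tolerance 1e-9)")
  if (is.null(msg)) TRUE else msg
})

#' Observed state of a developing mat
#'
#' Minimal description of a mat at one time point, sufficient for the
#' four-stage developmental classification: physical depth, whether
#' Fe(III)-oxide deposition is visible, the lithoautotroph/heterotroph split
#' of the community, and whether a vertical O2 gradient has formed.
#'
#' @slot day numeric, days since substrate deployment.
#' @slot mat_depth_mm numeric, mat thickness in mm (>= 0).
#' @slot visible_fe logical, visible oxide accretion.
#' @slot lithoautotroph_fraction numeric in [0, 1]; the heterotroph fraction
#'   is its complement.
#' @slot o2_gradient_present logical.
#'
#' @seealso [matState()], [classifyStage()]
#' @export
setClass("MatState",
  representation(day = "numeric", mat_depth_mm = "numeric",
                 visible_fe = "logical",
                 lithoautotroph_fraction = "numeric",
                 o2_gradient_present = "logical"))

setValidity("MatState", function(object) {
  msg <- NULL
  if (object@mat_depth_mm < 0) msg <- c(msg, "mat depth must be >= 0")
  f <- object@lithoautotroph_fraction
  if (is.na(f) || f < 0 || f > 1)
    msg <- c(msg, "lithoautotroph_fraction must lie in [0, 1]")
  if (object@day < 0) msg <- c(msg, "day must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Oxalate-extraction elemental data for a slide series
#'
#' Long-format ICP element concentrations from acid ammonium-oxalate
#' extractions of slide-grown Fe(III)-oxide, together with the extraction
#' volume and the slide area scraped, which convert solution concentrations
#' to areal loadings.
#'
#' @slot data data.frame with columns `t_days`, `element`, `mg_per_L`.
#' @slot extraction_volume numeric, litres (default 0.05 L).
#' @slot slide_area numeric, cm\eqn{^2}.
#' @slot site character scalar.
#'
#' @seealso [genExtractionTable()], [arealLoading()], [molarRatio()]
#' @export
setClass("ExtractionSet",
  representation(data = "data.frame", extraction_volume = "numeric",
                 slide_area = "numeric", site = "character"))

setValidity("ExtractionSet", function(object) {
  msg <- NULL
  need <- setdiff(c("t_days", "element", "mg_per_L"), colnames(object@data))
  if (length(need))
    msg <- c(msg, paste("data must contain columns:",
                        paste(need, collapse = ", ")))
  else if (any(object@data$mg_per_L < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (object@extraction_volume <= 0)
    msg <- c(msg, "extraction_volume must be > 0")
  if (object@slide_area <= 0) msg <- c(msg, "slide_area must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Per-site generating configuration
#'
#' Bundles every site-level default the synthetic-data generators use: the
#' exponential Fe and DNA kinetics, early colonization rates per morphotype,
#' bulk O2 and reaction-diffusion profile parameters, oxyanion:Fe molar
#' ratios, channel hydrodynamics, and the parametric community trajectory.
#' Defaults for the two packaged sites (`"osp"`, `"beowulf"`) are read from
#' `inst/extdata/site_defaults.yaml` by [siteConfig()].
#'
#' @slot site_name character, `"osp"` or `"beowulf"` (free for custom sites).
#' @slot fe_k,fe_x0 numeric, Fe accretion rate constant (day\eqn{^{-1}}) and
#'   initial loading (\eqn{\mu}mol cm\eqn{^{-2}}).
#' @slot dna_r,dna_x0 numeric, DNA accumulation rate constant
#'   (day\eqn{^{-1}}) and initial areal DNA (ng cm\eqn{^{-2}}).
#' @slot coloniz_rate_rod,coloniz_rate_coccus numeric, cells cm\eqn{^{-2}}
#'   day\eqn{^{-1}}.
#' @slot o2_bulk numeric, bulk O2 (\eqn{\mu}M).
#' @slot profile_params named numeric `c(k1 =, d_e =, l_f =)`
#'   (s\eqn{^{-1}}, cm\eqn{^2} s\eqn{^{-1}}, cm).
#' @slot as_fe_ratio,p_fe_ratio,w_fe_ratio numeric molar ratios in (0, 2].
#' @slot velocity numeric, channel velocity (cm s\eqn{^{-1}}).
#' @slot community list describing the per-taxon mean trajectory (see
#'   [genCommunityTable()]).
#'
#' @export
setClass("SiteConfig",
  representation(site_name = "character", fe_k = "numeric", fe_x0 = "numeric",
                 dna_r = "numeric", dna_x0 = "numeric",
                 coloniz_rate_rod = "numeric", coloniz_rate_coccus = "numeric",
                 o2_bulk = "numeric", profile_params = "numeric",
                 as_fe_ratio = "numeric", p_fe_ratio = "numeric",
                 w_fe_ratio = "numeric", velocity = "numeric",
                 community = "list"))

setValidity("SiteConfig", function(object) {
  msg <- NULL
  rates <- c(object@fe_k, object@fe_x0, object@dna_r, object@dna_x0,
             object@coloniz_rate_rod, object@coloniz_rate_coccus,
             object@o2_bulk)
  if (any(rates < 0)) msg <- c(msg, "rates and concentrations must be >= 0")
  ratios <- c(object@as_fe_ratio, object@p_fe_ratio, object@w_fe_ratio)
  if (any(ratios <= 0 | ratios > 2))
    msg <- c(msg, "molar ratios must lie in (0, 2]")
  need <- setdiff(c("k1", "d_e", "l_f"), names(object@profile_params))
  if (length(need))
    msg <- c(msg, paste("profile_params must be named:",
                        paste(need, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Noise specification for the synthetic generators
#'
#' @slot kind character, one of `"none"`, `"lognormal"`, `"gaussian"`,
#'   `"poisson"`, `"dirichlet"`.
#' @slot scale numeric >= 0; coefficient of variation for lognormal/gaussian
#'   noise, Dirichlet concentration for compositional noise; ignored for
#'   `"none"` and `"poisson"`.
#' @slot seed integer RNG seed; every generator draw is a deterministic
#'   function of it (no global RNG state is consumed or disturbed).
#'
#' @seealso [noiseSpec()]
#' @export
setClass("NoiseSpec",
  representation(kind = "character", scale = "numeric", seed = "integer"),
  prototype(kind = "none", scale = 0, seed = 1L))

setValidity("NoiseSpec", function(object) {
  msg <- NULL
  if (!object@kind %in% c("none", "lognormal", "gaussian", "poisson",
                          "dirichlet"))
    msg <- c(msg, "unknown noise kind")
  if (is.na(object@scale) || object@scale < 0)
    msg <- c(msg, "scale must be >= 0")
  if (is.null(msg)) TRUE else msg
})
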