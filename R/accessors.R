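# Accessor generics and methods; slot access stays internal to the package.

#' @rdname AccretionSeries-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("obsTimes", function(x) standardGeneric("obsTimes"))
#' @rdname AccretionSeries-class
#' @export
setGeneric("obsValues", function(x) standardGeneric("obsValues"))
#' @rdname AccretionSeries-class
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))

#' @rdname AccretionSeries-class
setMethod("obsTimes", "AccretionSeries", function(x) x@t)
#' @rdname AccretionSeries-class
setMethod("obsValues", "AccretionSeries", function(x) x@x)
#' @rdname AccretionSeries-class
setMethod("isCensored", "AccretionSeries", function(x) x@censored)

#' @rdname AccretionSeries-class
#' @param row.names,optional,... passed through (see [base::as.data.frame]).
#' @export
setMethod("as.data.frame", "AccretionSeries",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(t_days = x@t, x = x@x, censored = x@censored)
  })

#' @export
setMethod("show", "AccretionSeries", function(object) {
  cat("AccretionSeries (", object@what, ", ", object@units, "): ",
      length(object@t), " points over ",
      if (length(object@t)) paste0(min(object@t), "-", max(object@t)) else "-",
      " days; ", sum(object@censored), " censored\n", sep = "")
})

#' @rdname ExponentialFit-class
#' @param object an `ExponentialFit`.
#' @param ... unused.
#' @export
setMethod("coef", "ExponentialFit", function(object, ...) {
  c(x0 = object@x0, k = object@k)
})

#' @rdname ExponentialFit-class
#' @param parm parameter name(s), `"k"` and/or `"x0"`.
#' @param level confidence level.
#' @export
setMethod("confint", "ExponentialFit",
  function(object, parm = "k", level = 0.95, ...) {
    if (missing(parm)) parm <- "k"
    est <- c(k = object@k, x0 = object@x0)
    se <- c(k = object@se_k, x0 = object@se_x0)
    parm <- match.arg(parm, names(est), several.ok = TRUE)
    tq <- stats::qt(1 - (1 - level) / 2, df = object@residual_df)
    out <- cbind(lower = est[parm] - tq * se[parm],
                 upper = est[parm] + tq * se[parm])
    rownames(out) <- parm
    out
  })

#' @rdname ExponentialFit-class
#' @export
setGeneric("rateConstant", function(x) standardGeneric("rateConstant"))
#' @rdname ExponentialFit-class
#' @param x an `ExponentialFit` or `ProfileFit`.
setMethod("rateConstant", "ExponentialFit", function(x) x@k)
#' @rdname ProfileFit-class
setMethod("rateConstant", "ProfileFit", function(x) x@rate_constant)

setMethod("show", "ExponentialFit", function(object) {
  cat("ExponentialFit: x = x0 * exp(k t)\n",
      sprintf("  x0 = %.6g %s (se %.3g)\n", object@x0, object@units,
              object@se_x0),
      sprintf("  k  = %.6g day-1 (se %.3g, p = %.3g, df = %d)\n",
              object@k, object@se_k, object@p_value_k, object@residual_df),
      if (!object@converged) "  [did not converge]\n" else "", sep = "")
})

#' @rdname Microprofile-class
#' @export
setGeneric("profileDepths", function(x) standardGeneric("profileDepths"))
#' @rdname Microprofile-class
#' @export
setGeneric("profileConc", function(x) standardGeneric("profileConc"))
#' @rdname Microprofile-class
#' @export
setGeneric("bulkConc", function(x) standardGeneric("bulkConc"))

#' @rdname Microprofile-class
#' @param x a `Microprofile`.
setMethod("profileDepths", "Microprofile", function(x) x@z)
#' @rdname Microprofile-class
setMethod("profileConc", "Microprofile", function(x) x@conc)
#' @rdname Microprofile-class
setMethod("bulkConc", "Microprofile", function(x) x@c_bulk)

#' @rdname Microprofile-class
#' @param row.names,optional,... passed through (see [base::as.data.frame]).
#' @export
setMethod("as.data.frame", "Microprofile",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(z_um = x@z, c_uM = x@conc)
  })

setMethod("show", "Microprofile", function(object) {
  cat("Microprofile: ", length(object@z), " depths, 0-",
      max(object@z), " um; C_bulk = ", object@c_bulk, " uM",
      if (!is.na(object@temperature))
        paste0("; ", object@temperature, " C"), "\n", sep = "")
})

setMethod("show", "ReactionDiffusionModel", function(object) {
  cat("ReactionDiffusionModel (", object@kinetic_order, "-order)\n",
      "  rate constant = ", signif(object@rate_constant, 4),
      if (object@kinetic_order == "first") " s-1" else " uM s-1",
      "; D_e = ", signif(object@D_e, 4), " cm2 s-1; L_f = ",
      signif(object@L_f, 4), " cm; C0 = ", object@C0, " uM\n", sep = "")
})

#' @rdname FluxEstimate-class
#' @export
setGeneric("fluxValue", function(x) standardGeneric("fluxValue"))
#' @rdname FluxEstimate-class
#' @param x a `FluxEstimate`.
setMethod("fluxValue", "FluxEstimate", function(x) x@J)

setMethod("show", "FluxEstimate", function(object) {
  cat(sprintf(
    "FluxEstimate: J = %.4g umol cm-2 s-1 (gradient %.4g uM um-1, %s over %d points)\n",
    object@J, object@gradient, object@method, length(object@window)))
})

#' @rdname ProfileFit-class
#' @export
setGeneric("thiele", function(x) standardGeneric("thiele"))
#' @rdname ProfileFit-class
#' @param x a `ProfileFit`.
setMethod("thiele", "ProfileFit", function(x) x@phi)

setMethod("show", "ProfileFit", function(object) {
  cat(sprintf(
    "ProfileFit (%s-order): phi = %.4g, rate constant = %.4g, rmse(u) = %.3g\n",
    object@kinetic_order, object@phi, object@rate_constant, object@rmse))
})

#' @rdname MatCommunity-class
#' @export
setGeneric("copyNumbers", function(x) standardGeneric("copyNumbers"))
#' @rdname MatCommunity-class
#' @param x a `MatCommunity`.
setMethod("copyNumbers", "MatCommunity", function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$copy_number, rownames(x))
})

#' @rdname MatCommunity-class
#' @export
setGeneric("abundanceMode", function(x) standardGeneric("abundanceMode"))
#' @rdname MatCommunity-class
setMethod("abundanceMode", "MatCommunity", function(x) {
  S4Vectors::metadata(x)$mode
})

#' @rdname MatCommunity-class
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname MatCommunity-class
setMethod("abundances", "MatCommunity", function(x) {
  SummarizedExperiment::assay(x, "abundance")
})

setMethod("show", "MatCommunity", function(object) {
  cat("MatCommunity (", S4Vectors::metadata(object)$mode, "): ",
      nrow(object), " taxa x ", ncol(object), " samples\n", sep = "")
  callNextMethod()
})

setMethod("show", "MatState", function(object) {
  cat(sprintf(
    "MatState: day %g, depth %g mm, visible Fe: %s, lithoautotrophs %.0f%%, O2 gradient: %s\n",
    object@day, object@mat_depth_mm, object@visible_fe,
    100 * object@lithoautotroph_fraction, object@o2_gradient_present))
})

#' @rdname ExtractionSet-class
#' @param x an `ExtractionSet`.
#' @param row.names,optional,... passed through (see [base::as.data.frame]).
#' @export
setMethod("as.data.frame", "ExtractionSet",
  function(x, row.names = NULL, optional = FALSE, ...) x@data)

setMethod("show", "ExtractionSet", function(object) {
  cat("ExtractionSet (", object@site, "): ",
      length(unique(object@data$t_days)), " time points, elements: ",
      paste(unique(object@data$element), collapse = ", "),
      "; volume ", object@extraction_volume, " L, area ",
      object@slide_area, " cm2\n", sep = "")
})

setMethod("show", "SiteConfig", function(object) {
  p <- object@profile_params
  cat("SiteConfig '", object@site_name, "'\n",
      sprintf("  Fe: k = %g day-1, x0 = %g umol cm-2 | DNA: r = %g day-1, x0 = %g ng cm-2\n",
              object@fe_k, object@fe_x0, object@dna_r, object@dna_x0),
      sprintf("  colonization: rod %.3g, coccus %.3g cells cm-2 day-1\n",
              object@coloniz_rate_rod, object@coloniz_rate_coccus),
      sprintf("  O2: bulk %g uM; k1 = %.4g s-1, D_e = %g cm2 s-1, L_f = %.4g cm\n",
              object@o2_bulk, p[["k1"]], p[["d_e"]], p[["l_f"]]),
      sprintf("  molar ratios As:Fe %g, P:Fe %g, W:Fe %g\n",
              object@as_fe_ratio, object@p_fe_ratio, object@w_fe_ratio),
      sep = "")
})

setMethod("show", "NoiseSpec", function(object) {
  cat("NoiseSpec: ", object@kind,
      if (object@kind %in% c("lognormal", "gaussian", "dirichlet"))
        paste0(" (scale ", object@scale, ")"),
      ", seed ", object@seed, "\n", sep = "")
})
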