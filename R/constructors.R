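#' Construct an accretion/biomass time series
#'
#' @param t numeric vector of incubation times (days).
#' @param x numeric vector of areal measurements.
#' @param censored logical vector flagging below-detection points.
#' @param units units label for `x`.
#' @param what analyte label (`"Fe"`, `"DNA"`, ...).
#'
#' @return An [AccretionSeries-class] object.
#' @examples
#' accretionSeries(c(0, 7, 14), c(0.5, 0.71, 1.01))
#' @export
accretionSeries <- function(t, x, censored = rep(FALSE, length(x)),
                            units = "umol cm-2", what = "Fe") {
  new("AccretionSeries", t = as.numeric(t), x = as.numeric(x),
      censored = as.logical(censored), units = units, what = what)
}

#' Construct an oxygen microprofile
#'
#' @param z depths in \eqn{\mu}m, strictly increasing, 0 at the interface.
#' @param C O2 concentrations in \eqn{\mu}M.
#' @param C_bulk bulk-water O2 concentration (\eqn{\mu}M).
#' @param temperature water temperature (degrees C), optional.
#'
#' @return A [Microprofile-class] object.
#' @examples
#' microprofile(z = c(0, 100, 200), C = c(55, 30, 10), C_bulk = 55)
#' @export
microprofile <- function(z, C, C_bulk, temperature = NA_real_) {
  new("Microprofile", z = as.numeric(z), conc = as.numeric(C),
      c_bulk = as.numeric(C_bulk), temperature = as.numeric(temperature))
}

#' Construct a reaction-diffusion slab model
#'
#' @param kinetic_order `"first"` (cosh solution, the default throughout) or
#'   `"zero"` (quadratic solution clipped at zero).
#' @param rate_constant \eqn{k_1} in s\eqn{^{-1}} (first order) or \eqn{k_0}
#'   in \eqn{\mu}M s\eqn{^{-1}} (zero order).
#' @param D_e effective O2 diffusivity (cm\eqn{^2} s\eqn{^{-1}}).
#' @param L_f mat thickness (cm).
#' @param C0 interface O2 concentration (\eqn{\mu}M).
#'
#' @return A [ReactionDiffusionModel-class] object.
#' @examples
#' reactionDiffusionModel("first", rate_constant = 0.095, D_e = 4.5e-5,
#'                        L_f = 0.61, C0 = 55)
#' @export
reactionDiffusionModel <- function(kinetic_order = c("first", "zero"),
                                   rate_constant, D_e, L_f, C0) {
  kinetic_order <- match.arg(kinetic_order)
  new("ReactionDiffusionModel", kinetic_order = kinetic_order,
      rate_constant = as.numeric(rate_constant), D_e = as.numeric(D_e),
      L_f = as.numeric(L_f), C0 = as.numeric(C0))
}

#' Construct a taxon-by-sample community table
#'
#' @param abundance numeric matrix, taxa in rows, samples in columns. Row and
#'   column names are required (taxon and sample labels).
#' @param copy_number per-taxon 16S rRNA gene copy numbers (recycled scalar
#'   allowed; default 1 for every taxon).
#' @param site,day,depth_zone per-sample metadata vectors (recycled scalars
#'   allowed). `depth_zone` is one of `"top"`, `"middle"`, `"bottom"`,
#'   `"none"`.
#' @param mode `"counts"` or `"proportions"`.
#'
#' @return A [MatCommunity-class] object.
#' @examples
#' m <- matrix(c(100, 50, 80, 70), 2,
#'             dimnames = list(c("A", "B"), c("s1", "s2")))
#' MatCommunity(m, copy_number = c(2, 1), site = "osp", day = c(4, 70))
#' @export
MatCommunity <- function(abundance, copy_number = 1, site = "unknown",
                         day = NA_real_, depth_zone = "none",
                         mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance matrix must have taxon rownames and sample colnames")
  if (anyDuplicated(colnames(abundance)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(abundance)[duplicated(colnames(abundance))]),
               collapse = ", "))
  n <- ncol(abundance)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = S4Vectors::DataFrame(
      copy_number = rep_len(copy_number, nrow(abundance)),
      row.names = rownames(abundance)),
    colData = S4Vectors::DataFrame(
      site = rep_len(site, n), day = rep_len(day, n),
      depth_zone = rep_len(depth_zone, n),
      row.names = colnames(abundance)))
  S4Vectors::metadata(se)$mode <- mode
  new("MatCommunity", se)
}

#' Construct a mat developmental state
#'
#' @param day days since deployment.
#' @param mat_depth_mm mat thickness (mm).
#' @param visible_fe logical, visible Fe(III)-oxide accretion.
#' @param lithoautotroph_fraction fraction of the community that is
#'   lithoautotrophic, in [0, 1]; heterotrophs are the complement.
#' @param o2_gradient_present logical, vertical O2 gradient observed.
#'
#' @return A [MatState-class] object.
#' @examples
#' matState(day = 20, mat_depth_mm = 0.7, visible_fe = TRUE,
#'          lithoautotroph_fraction = 0.9)
#' @export
matState <- function(day, mat_depth_mm = 0, visible_fe = FALSE,
                     lithoautotroph_fraction = 1,
                     o2_gradient_present = FALSE) {
  new("MatState", day = as.numeric(day),
      mat_depth_mm = as.numeric(mat_depth_mm),
      visible_fe = as.logical(visible_fe),
      lithoautotroph_fraction = as.numeric(lithoautotroph_fraction),
      o2_gradient_present = as.logical(o2_gradient_present))
}

#' Construct an oxalate-extraction elemental data set
#'
#' @param data data.frame with columns `t_days`, `element`, `mg_per_L`.
#' @param extraction_volume extraction volume in litres (default 0.05,
#'   i.e. the standard 50 mL oxalate extraction).
#' @param slide_area slide area scraped, cm\eqn{^2}.
#' @param site site label.
#'
#' @return An [ExtractionSet-class] object.
#' @export
extractionSet <- function(data, extraction_volume = 0.05, slide_area = 18.75,
                          site = "unknown") {
  data$element <- as.character(data$element)
  new("ExtractionSet", data = as.data.frame(data),
      extraction_volume = as.numeric(extraction_volume),
      slide_area = as.numeric(slide_area), site = site)
}

#' Construct a noise specification
#'
#' @param kind noise family: `"none"`, `"lognormal"`, `"gaussian"`,
#'   `"poisson"` or `"dirichlet"`.
#' @param scale coefficient of variation (lognormal/gaussian) or Dirichlet
#'   concentration; ignored for `"none"`/`"poisson"`.
#' @param seed integer RNG seed. Generators restore the caller's RNG state,
#'   so identical `(kind, scale, seed)` always reproduce the same draw.
#'
#' @return A [NoiseSpec-class] object.
#' @examples
#' noiseSpec("lognormal", scale = 0.2, seed = 42)
#' @export
noiseSpec <- function(kind = c("none", "lognormal", "gaussian", "poisson",
                               "dirichlet"),
                      scale = 0, seed = 1L) {
  kind <- match.arg(kind)
  new("NoiseSpec", kind = kind, scale = as.numeric(scale),
      seed = as.integer(seed))
}
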