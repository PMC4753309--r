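# Synthetic generators for every input type the pipeline consumes. Each
# generator draws around the deterministic mean implied by a SiteConfig (or
# explicit parameters); with noiseSpec("none") the output lies exactly on the
# mean curve, which the round-trip tests exploit.

#' Generate a synthetic Fe(III)-oxide accretion series
#'
#' Mean curve \eqn{x(t) = x_0 e^{kt}} with optional multiplicative lognormal
#' noise (the natural error family for a strictly positive areal loading).
#' Values falling below `detection_limit` are flagged as censored, mimicking
#' slides recovered before visible oxide deposition.
#'
#' @param config a [SiteConfig-class]; `fe_x0` and `fe_k` set the mean curve.
#' @param times sampling days, non-negative and strictly increasing.
#' @param noise a [NoiseSpec-class]; `"none"` or `"lognormal"` (scale = CV).
#' @param detection_limit censoring threshold in \eqn{\mu}mol cm\eqn{^{-2}}.
#'
#' @return An [AccretionSeries-class].
#' @examples
#' genAccretionSeries(siteConfig("osp"), times = seq(0, 70, 7))
#' @export
genAccretionSeries <- function(config, times = seq(0, 70, by = 7),
                               noise = noiseSpec("none"),
                               detection_limit = 0.05) {
  .gen_exp_series(config@fe_x0, config@fe_k, times, noise, detection_limit,
                  units = "umol cm-2", what = "Fe")
}

#' Generate a synthetic DNA-biomass series
#'
#' As [genAccretionSeries()] but for areal DNA (ng cm\eqn{^{-2}}) with mean
#' curve \eqn{x_0 e^{rt}} from the site's `dna_x0` and `dna_r`.
#'
#' @inheritParams genAccretionSeries
#' @param detection_limit censoring threshold in ng cm\eqn{^{-2}} (default 0:
#'   DNA is quantifiable on all slides).
#'
#' @return An [AccretionSeries-class] with `what = "DNA"`.
#' @export
genDnaSeries <- function(config, times = seq(0, 70, by = 7),
                         noise = noiseSpec("none"), detection_limit = 0) {
  .gen_exp_series(config@dna_x0, config@dna_r, times, noise, detection_limit,
                  units = "ng cm-2", what = "DNA")
}

.gen_exp_series <- function(x0, k, times, noise, detection_limit, units,
                            what) {
  .assert_times(times)
  stopifnot(is(noise, "NoiseSpec"))
  mu <- x0 * exp(k * times)
  x <- switch(noise@kind,
    none = mu,
    lognormal = {
      sdlog <- sqrt(log(1 + noise@scale^2))
      .with_noise_seed(noise,
        mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    },
    stop("noise kind '", noise@kind, "' not supported for series generation"))
  accretionSeries(times, x, censored = x < detection_limit, units = units,
                  what = what)
}

#' Generate a synthetic oxygen microprofile
#'
#' Evaluates the dimensionless steady-state solution of the configured
#' [ReactionDiffusionModel-class] on a depth grid and rescales by the
#' interface concentration: \eqn{C(z) = C_0\,u(z/L_f)}. Optional gaussian
#' noise (sd = scale x local mean) is added and the result clipped at zero.
#'
#' @param model a [ReactionDiffusionModel-class].
#' @param z_grid depths in \eqn{\mu}m within `[0, L_f]` (in \eqn{\mu}m).
#' @param noise a [NoiseSpec-class]; `"none"` or `"gaussian"`.
#' @param temperature recorded water temperature, degrees C.
#'
#' @return A [Microprofile-class] with `C_bulk = C0`.
#' @examples
#' m <- siteProfileModel(siteConfig("osp"))
#' genMicroprofile(m, z_grid = seq(0, 1000, 10))
#' @export
genMicroprofile <- function(model, z_grid = seq(0, 1000, by = 10),
                            noise = noiseSpec("none"),
                            temperature = NA_real_) {
  stopifnot(is(model, "ReactionDiffusionModel"), is(noise, "NoiseSpec"))
  if (model@C0 < 0) stop("C0 must be >= 0")
  lf_um <- model@L_f * .UM_PER_CM
  if (any(z_grid < 0) || any(z_grid > lf_um + 1e-9))
    stop("z_grid must lie within [0, L_f] = [0, ", signif(lf_um, 4), "] um")
  phi <- thieleModulus(
    if (model@kinetic_order == "first") model@rate_constant
    else model@rate_constant / max(model@C0, .Machine$double.eps),
    model@L_f, model@D_e)
  u <- dimensionlessProfile(model@kinetic_order, phi, z_grid / lf_um)
  C <- model@C0 * u
  if (noise@kind == "gaussian") {
    C <- .with_noise_seed(noise,
      C + stats::rnorm(length(C), sd = noise@scale * C))
    C <- pmax(C, 0)
  } else if (noise@kind != "none") {
    stop("noise kind '", noise@kind, "' not supported for profiles")
  }
  microprofile(z_grid, C, C_bulk = model@C0, temperature = temperature)
}

#' Generate synthetic SEM field-of-view cell counts
#'
#' Expected count per field is `rate * t * field_area`. With Poisson noise
#' each field is an independent draw at that mean; with `"none"` the rounded
#' deterministic mean is returned for every field.
#'
#' @param rate colonization rate, cells cm\eqn{^{-2}} day\eqn{^{-1}} (>= 0).
#' @param times sampling days.
#' @param field_area area of one SEM field of view, cm\eqn{^2}.
#' @param n_fields number of random fields per time point (>= 1).
#' @param noise a [NoiseSpec-class]; `"none"` or `"poisson"`.
#' @param morphotype label attached to the counts (e.g. `"rod"`).
#'
#' @return data.frame with columns `t_days`, `field_id`, `field_area_cm2`,
#'   `morphotype`, `count`.
#' @examples
#' genCountFields(3.7e6, times = c(5, 10, 15), field_area = 1e-5)
#' @export
genCountFields <- function(rate, times = c(5, 10, 15), field_area = 1e-5,
                           n_fields = 4, noise = noiseSpec("none"),
                           morphotype = "rod") {
  if (rate < 0) stop("rate must be >= 0")
  if (field_area <= 0) stop("field_area must be > 0")
  if (n_fields < 1) stop("n_fields must be >= 1")
  .assert_times(times)
  stopifnot(is(noise, "NoiseSpec"))
  grid <- expand.grid(field = seq_len(n_fields), t_days = times,
                      KEEP.OUT.ATTRS = FALSE)
  mu <- rate * grid$t_days * field_area
  counts <- switch(noise@kind,
    none = round(mu),
    poisson = .with_noise_seed(noise, stats::rpois(length(mu), lambda = mu)),
    stop("noise kind '", noise@kind, "' not supported for counts"))
  data.frame(t_days = grid$t_days,
             field_id = paste0("d", grid$t_days, "_f", grid$field),
             field_area_cm2 = field_area, morphotype = morphotype,
             count = as.numeric(counts))
}

# mean community composition at one time point; exact simplex point
.community_mean <- function(community, day) {
  cm <- community
  rod <- max(cm$rod_start - cm$rod_decline_per_day * (day - cm$start_day),
             cm$rod_floor)
  feox <- cm$feox_fraction
  if (rod + feox > 1)
    stop("community trajectory produces negative heterotroph mass at day ",
         day)
  het_mass <- 1 - rod - feox
  w <- vapply(cm$heterotrophs, function(h)
    stats::plogis((day - h$midpoint) / h$width), numeric(1))
  if (sum(w) == 0) w <- rep(1, length(w))
  het <- het_mass * w / sum(w)
  p <- c(rod, feox, het)
  names(p) <- c(cm$rod_taxon, cm$feox_taxon,
                vapply(cm$heterotrophs, `[[`, character(1), "taxon"))
  p / sum(p)
}

#' Generate a synthetic community succession table
#'
#' Mean trajectory: the rod-shaped lithoautotroph starts dominant (default
#' 0.85 at day 4) and declines linearly (default 1 percentage point per day,
#' floored at 0.01); the Fe(II)-oxidizer stays constant (default 0.15); the
#' remaining mass is split among the configured heterotroph taxa with
#' logistic weights (default midpoints around day 45), and each sample is
#' renormalized to sum to exactly 1. Dirichlet noise (concentration =
#' `scale`) draws compositions around the mean.
#'
#' @param config a [SiteConfig-class]; `config@community` holds the
#'   trajectory parameters.
#' @param times sampling days within [0, 100].
#' @param noise a [NoiseSpec-class]; `"none"` or `"dirichlet"`.
#'
#' @return A [MatCommunity-class] in proportions mode with samples named
#'   `<site>_dayNN`.
#' @examples
#' genCommunityTable(siteConfig("osp"), times = c(4, 20, 40, 70))
#' @export
genCommunityTable <- function(config, times = c(4, 11, 20, 29, 40, 52, 70),
                              noise = noiseSpec("none")) {
  stopifnot(is(config, "SiteConfig"), is(noise, "NoiseSpec"))
  if (any(times < 0) || any(times > 100))
    stop("times must lie within [0, 100] days")
  mean_mat <- vapply(times, function(d) .community_mean(config@community, d),
                     numeric(2 + length(config@community$heterotrophs)))
  if (noise@kind == "dirichlet") {
    taxa <- rownames(mean_mat)
    mean_mat <- .with_noise_seed(noise, {
      apply(mean_mat, 2, function(p) .rdirichlet(noise@scale * p))
    })
    rownames(mean_mat) <- taxa
  } else if (noise@kind != "none") {
    stop("noise kind '", noise@kind, "' not supported for community tables")
  }
  colnames(mean_mat) <- sprintf("%s_day%02d", config@site_name, times)
  MatCommunity(mean_mat, copy_number = 1, site = config@site_name,
               day = times, depth_zone = "none", mode = "proportions")
}

#' Generate a synthetic oxalate-extraction element table
#'
#' Fe solution concentrations track the site's accretion curve through the
#' extraction volume and slide area; As, P and W concentrations are set so
#' the molar ratios equal the site's configured `as_fe_ratio`, `p_fe_ratio`
#' and `w_fe_ratio`. Lognormal noise (if requested) perturbs each element
#' independently.
#'
#' @param config a [SiteConfig-class].
#' @param times extraction days, strictly increasing (default 14-70 d, the
#'   window with measurable oxide loads).
#' @param noise a [NoiseSpec-class]; `"none"` or `"lognormal"`.
#' @param extraction_volume litres (default 0.05).
#' @param slide_area cm\eqn{^2} scraped per slide (default 18.75, one
#'   2.5 x 7.5 cm slide face).
#'
#' @return An [ExtractionSet-class] with elements Fe, As, P, W.
#' @examples
#' genExtractionTable(siteConfig("beowulf"))
#' @export
genExtractionTable <- function(config, times = seq(14, 70, by = 7),
                               noise = noiseSpec("none"),
                               extraction_volume = 0.05, slide_area = 18.75) {
  stopifnot(is(config, "SiteConfig"), is(noise, "NoiseSpec"))
  .assert_times(times)
  if (extraction_volume <= 0) stop("extraction_volume must be > 0")
  if (slide_area <= 0) stop("slide_area must be > 0")
  mm <- molarMasses()
  fe_umol_cm2 <- config@fe_x0 * exp(config@fe_k * times)
  fe_umol <- fe_umol_cm2 * slide_area
  # umol x (g mol-1) = ug; /1000 = mg; / volume = mg L-1
  conc <- function(umol, mass) umol * mass / 1000 / extraction_volume
  ratios <- c(Fe = 1, As = config@as_fe_ratio, P = config@p_fe_ratio,
              W = config@w_fe_ratio)
  df <- do.call(rbind, lapply(names(ratios), function(el) {
    data.frame(t_days = times, element = el,
               mg_per_L = conc(fe_umol * ratios[[el]], mm[[el]]))
  }))
  if (noise@kind == "lognormal") {
    sdlog <- sqrt(log(1 + noise@scale^2))
    df$mg_per_L <- .with_noise_seed(noise,
      df$mg_per_L * stats::rlnorm(nrow(df), meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog))
  } else if (noise@kind != "none") {
    stop("noise kind '", noise@kind, "' not supported for extraction tables")
  }
  extractionSet(df, extraction_volume = extraction_volume,
                slide_area = slide_area, site = config@site_name)
}
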