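#' Load a per-site generating configuration
#'
#' Reads the packaged YAML of site defaults (or a user-supplied file with the
#' same schema) and returns a [SiteConfig-class]. The two packaged sites are
#' `"osp"` (One Hundred Spring Plain, 70-75 degC, pH 3.5) and `"beowulf"`
#' (65-70 degC, pH 2.9), with Fe/DNA kinetics, colonization rates, O2 and
#' geochemistry defaults equal to each site's measured values.
#'
#' The reaction-diffusion profile parameters are not stored directly:
#' the YAML carries the site's net areal O2 flux `o2_flux`, Thiele modulus
#' `thiele`, bulk O2 `o2_bulk` and diffusivity `d_e`, and `siteConfig()`
#' solves the two closed-form first-order relations
#' \deqn{J = D_e C_0 \phi \tanh(\phi) / L_f, \qquad \phi^2 = k_1 L_f^2 / D_e}
#' for the mat thickness \eqn{L_f} and rate constant \eqn{k_1}, so that a
#' noiseless profile generated from the configuration reproduces the site's
#' flux and Thiele modulus exactly.
#'
#' @param site site key in the YAML file, e.g. `"osp"` or `"beowulf"`.
#' @param file optional path to an alternative YAML config.
#' @param ... named scalar overrides for any YAML field (e.g. `fe_k = 0.06`).
#'
#' @return A [SiteConfig-class] object.
#' @examples
#' cfg <- siteConfig("osp")
#' cfg@fe_k
#' profileParams(cfg)
#' @export
siteConfig <- function(site = c("osp", "beowulf"), file = NULL, ...) {
  if (is.null(file)) {
    site <- match.arg(site)
    file <- system.file("extdata", "site_defaults.yaml", package = "ferromat",
                        mustWork = TRUE)
  }
  all <- yaml::read_yaml(file)
  if (!site %in% names(all))
    stop("site '", site, "' not found in ", file)
  y <- all[[site]]
  dots <- list(...)
  for (nm in names(dots)) y[[nm]] <- dots[[nm]]

  C0_mol <- y$o2_bulk * 1e-3                 # uM -> umol cm-3
  l_f <- y$d_e * C0_mol * y$thiele * tanh(y$thiele) / y$o2_flux
  k1 <- y$thiele^2 * y$d_e / l_f^2

  new("SiteConfig", site_name = site,
      fe_k = y$fe_k, fe_x0 = y$fe_x0, dna_r = y$dna_r, dna_x0 = y$dna_x0,
      coloniz_rate_rod = y$coloniz_rate_rod,
      coloniz_rate_coccus = y$coloniz_rate_coccus,
      o2_bulk = y$o2_bulk,
      profile_params = c(k1 = k1, d_e = y$d_e, l_f = l_f),
      as_fe_ratio = y$as_fe_ratio, p_fe_ratio = y$p_fe_ratio,
      w_fe_ratio = y$w_fe_ratio, velocity = y$velocity,
      community = y$community)
}

#' Reaction-diffusion parameters of a site configuration
#'
#' @param config a [SiteConfig-class].
#' @return Named numeric vector `c(k1, d_e, l_f)` (s\eqn{^{-1}}, cm\eqn{^2}
#'   s\eqn{^{-1}}, cm).
#' @export
profileParams <- function(config) {
  stopifnot(is(config, "SiteConfig"))
  config@profile_params
}

#' Reaction-diffusion model from a site configuration
#'
#' Convenience wrapper assembling a [ReactionDiffusionModel-class] from the
#' site's derived profile parameters and bulk O2.
#'
#' @param config a [SiteConfig-class].
#' @param kinetic_order `"first"` (default) or `"zero"`.
#' @return A [ReactionDiffusionModel-class].
#' @examples
#' siteProfileModel(siteConfig("osp"))
#' @export
siteProfileModel <- function(config, kinetic_order = c("first", "zero")) {
  kinetic_order <- match.arg(kinetic_order)
  p <- profileParams(config)
  reactionDiffusionModel(kinetic_order, rate_constant = p[["k1"]],
                         D_e = p[["d_e"]], L_f = p[["l_f"]],
                         C0 = config@o2_bulk)
}
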