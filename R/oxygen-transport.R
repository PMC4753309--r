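# Steady-state O2 reaction-diffusion modelling: dimensionless slab
# solutions, interface flux by Fick's first law, Thiele modulus, profile
# fitting and penetration depth.

#' Dimensionless steady-state concentration in a reactive slab
#'
#' First-order consumption gives \eqn{u(\zeta) =
#' \cosh(\phi(1-\zeta))/\cosh(\phi)} (always in (0, 1]); zero-order gives the
#' quadratic \eqn{u = \phi^2\zeta^2/2 - \phi^2\zeta + 1}, clipped at 0 where
#' the slab goes anoxic. Both satisfy \eqn{u(0) = 1} and a zero-gradient
#' bottom boundary at \eqn{\zeta = 1} (the quadratic by construction where it
#' is positive). Here \eqn{u = C/C_0} and \eqn{\zeta = z/L_f}.
#'
#' @param order `"first"` or `"zero"`.
#' @param phi Thiele modulus (>= 0).
#' @param zeta dimensionless depth in [0, 1], vectorised.
#' @return Dimensionless concentration values.
#' @examples
#' dimensionlessProfile("first", phi = 2, zeta = 1)   # 1/cosh(2)
#' dimensionlessProfile("zero", phi = sqrt(2), zeta = 1)  # exactly 0
#' @export
dimensionlessProfile <- function(order = c("first", "zero"), phi, zeta) {
  order <- match.arg(order)
  if (phi < 0) stop("phi must be >= 0")
  if (any(zeta < 0 | zeta > 1)) stop("zeta must lie in [0, 1]")
  switch(order,
    first = .cosh_ratio(phi * (1 - zeta), phi),
    zero = pmax(phi^2 * zeta^2 / 2 - phi^2 * zeta + 1, 0))
}

#' Thiele modulus
#'
#' \eqn{\phi = \sqrt{k_1 L_f^2 / D_e}}: the ratio of the first-order reaction
#' rate to the diffusive supply rate in a slab of thickness \eqn{L_f}.
#'
#' @param k1 first-order rate constant, s\eqn{^{-1}}.
#' @param L_f slab (mat) thickness, cm.
#' @param D_e effective diffusivity, cm\eqn{^2} s\eqn{^{-1}}.
#' @return Dimensionless \eqn{\phi}.
#' @examples
#' thieleModulus(7.84e-3, 1, 1e-5)  # 28
#' @export
thieleModulus <- function(k1, L_f, D_e) {
  if (any(c(k1, L_f, D_e) < 0) || L_f <= 0 || D_e <= 0)
    stop("k1 must be >= 0 and L_f, D_e > 0")
  sqrt(k1 * L_f^2 / D_e)
}

#' Classify diffusion vs reaction limitation
#'
#' \eqn{\phi} above the threshold means consumption outruns diffusive supply
#' (diffusion-limited); below, the reaction is limiting; at the threshold the
#' two are balanced.
#'
#' @param phi Thiele modulus.
#' @param threshold decision boundary (default 1).
#' @return `"diffusion_limited"`, `"reaction_limited"` or `"balanced"`.
#' @examples
#' classifyLimitation(28)
#' @export
classifyLimitation <- function(phi, threshold = 1) {
  if (phi < 0) stop("phi must be >= 0")
  if (phi > threshold) "diffusion_limited"
  else if (phi < threshold) "reaction_limited"
  else "balanced"
}

#' Diffusive O2 flux at the mat-water interface
#'
#' Fick's-first-law estimate \eqn{J = D_e |dC/dz|_{z=0}} from the uppermost
#' profile points. The default gradient estimator fits a quadratic through
#' the window and evaluates its derivative at the first window point, which
#' removes the first-order curvature bias a straight line incurs on steep,
#' curved profiles; `method = "linear"` gives the plain OLS slope through the
#' window. Units are reconciled internally (\eqn{\mu}M \eqn{\to} \eqn{\mu}mol
#' cm\eqn{^{-3}}, \eqn{\mu}m \eqn{\to} cm), so J is in \eqn{\mu}mol
#' cm\eqn{^{-2}} s\eqn{^{-1}}, positive for O2 moving into the mat.
#'
#' @param profile a [Microprofile-class].
#' @param D_e effective diffusivity, cm\eqn{^2} s\eqn{^{-1}}.
#' @param window indices of profile points to use (default the first 3 at
#'   z >= 0).
#' @param method `"quadratic"` (default) or `"linear"`.
#' @return A [FluxEstimate-class].
#' @examples
#' p <- genMicroprofile(siteProfileModel(siteConfig("osp")),
#'                      z_grid = seq(0, 1000, 10))
#' estimateFlux(p, D_e = 4.5e-5)
#' @export
estimateFlux <- function(profile, D_e, window = NULL,
                         method = c("quadratic", "linear")) {
  stopifnot(is(profile, "Microprofile"))
  method <- match.arg(method)
  z <- profileDepths(profile); C <- profileConc(profile)
  if (is.null(window)) window <- which(z >= 0)[seq_len(min(3, sum(z >= 0)))]
  window <- as.integer(window)
  zw <- z[window]; Cw <- C[window]
  if (length(unique(zw)) < 2)
    stop("flux window must span >= 2 distinct depths")
  if (method == "quadratic" && length(window) >= 3) {
    z0 <- zw - zw[1]
    co <- stats::coef(stats::lm(Cw ~ z0 + I(z0^2)))
    gradient <- co[[2]]                  # dC/dz at the first window point
  } else {
    gradient <- stats::coef(stats::lm(Cw ~ zw))[[2]]
  }
  J <- D_e * abs(gradient) * .UM_TO_UMOL_CM3 * .UM_PER_CM
  new("FluxEstimate", J = J, gradient = gradient, window = window,
      D_e = D_e, method = method)
}

#' Fit the dimensionless reaction-diffusion solution to a profile
#'
#' Normalises the profile by its bulk concentration (\eqn{u = C/C_{bulk}},
#' \eqn{\zeta = z/L_f}) and finds the Thiele modulus minimising the residual
#' sum of squares against the chosen dimensionless solution. Only \eqn{\phi}
#' is identifiable from profile shape; `L_f` and `D_e` must be supplied and
#' are used to back-compute the rate constant \eqn{k_1 = \phi^2 D_e / L_f^2}
#' (first order) or \eqn{k_0 = \phi^2 D_e C_0 / L_f^2} (zero order).
#'
#' @param profile a [Microprofile-class] with `C_bulk > 0`.
#' @param order `"first"` (default) or `"zero"`.
#' @param L_f mat thickness, cm.
#' @param D_e effective diffusivity, cm\eqn{^2} s\eqn{^{-1}}.
#' @param phi_max upper bound of the search interval.
#' @return A [ProfileFit-class].
#' @examples
#' cfg <- siteConfig("osp")
#' p <- genMicroprofile(siteProfileModel(cfg),
#'                      z_grid = seq(0, 6000, 10))
#' fitProfile(p, L_f = profileParams(cfg)[["l_f"]], D_e = 4.5e-5)
#' @export
fitProfile <- function(profile, order = c("first", "zero"), L_f, D_e,
                       phi_max = 1e3) {
  stopifnot(is(profile, "Microprofile"))
  order <- match.arg(order)
  if (bulkConc(profile) <= 0) stop("C_bulk must be > 0")
  u <- profileConc(profile) / bulkConc(profile)
  if (all(u == 0)) stop("all-zero profile cannot be fitted")
  zeta <- profileDepths(profile) / (L_f * .UM_PER_CM)
  if (any(zeta > 1 + 1e-9))
    stop("profile extends below L_f; increase L_f or truncate the profile")
  zeta <- pmin(zeta, 1)
  sse <- function(phi) sum((dimensionlessProfile(order, phi, zeta) - u)^2)
  # the SSE is flat wherever the solution is fully clipped, so bracket the
  # optimum on a coarse log grid before the local search
  grid <- c(0, 10^seq(-3, log10(phi_max), length.out = 120))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(sse, interval = c(lo, hi), tol = 1e-10)
  phi <- if (sse(0) <= opt$objective) 0 else opt$minimum
  rate <- if (order == "first") phi^2 * D_e / L_f^2
          else phi^2 * D_e * bulkConc(profile) / L_f^2
  new("ProfileFit", phi = phi, rate_constant = rate,
      rmse = sqrt(sse(phi) / length(u)), kinetic_order = order,
      D_e = D_e, L_f = L_f)
}

#' Oxygen penetration depth
#'
#' Depth of the first crossing below the electrode detection limit, located
#' by linear interpolation between the bracketing points.
#'
#' @param profile a [Microprofile-class].
#' @param detection_limit \eqn{\mu}M (default 0.3, a typical Clark-electrode
#'   detection limit).
#' @return Depth in \eqn{\mu}m, or `NA` if the profile never falls below the
#'   limit.
#' @examples
#' penetrationDepth(microprofile(c(0, 500, 1000), c(55, 27.5, 0), 55))
#' @export
penetrationDepth <- function(profile, detection_limit = 0.3) {
  stopifnot(is(profile, "Microprofile"))
  z <- profileDepths(profile); C <- profileConc(profile)
  below <- which(C < detection_limit)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(z[1])
  # interpolate the crossing between i-1 and i
  z[i - 1] + (detection_limit - C[i - 1]) * (z[i] - z[i - 1]) /
    (C[i] - C[i - 1])
}

#' Closed-form interface flux of the first-order slab solution
#'
#' \eqn{J = C_0 \sqrt{D_e k_1}\,\tanh(\phi)}, the analytical surface flux of
#' the cosh solution, unit-converted to \eqn{\mu}mol cm\eqn{^{-2}}
#' s\eqn{^{-1}}. Used as the reference the windowed estimator converges to.
#'
#' @param model a first-order [ReactionDiffusionModel-class].
#' @return Flux in \eqn{\mu}mol cm\eqn{^{-2}} s\eqn{^{-1}}.
#' @export
closedFormFlux <- function(model) {
  stopifnot(is(model, "ReactionDiffusionModel"),
            model@kinetic_order == "first")
  phi <- thieleModulus(model@rate_constant, model@L_f, model@D_e)
  model@C0 * .UM_TO_UMOL_CM3 * sqrt(model@D_e * model@rate_constant) *
    tanh(phi)
}
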