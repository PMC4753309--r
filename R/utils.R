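# Internal helpers and shared constants.

# unit conversions, centralized
.UM_TO_UMOL_CM3 <- 1e-3   # uM (umol L-1) -> umol cm-3
.UM_PER_CM <- 1e4         # um in one cm

# evaluate expr under a fixed seed without touching the caller's RNG stream
.with_noise_seed <- function(noise, expr) {
  withr::with_seed(noise@seed, expr)
}

# numerically stable cosh(a)/cosh(b) for large arguments
.cosh_ratio <- function(a, b) {
  ifelse(pmax(abs(a), abs(b)) < 300,
         cosh(a) / cosh(b),
         exp(abs(a) - abs(b)) * (1 + exp(-2 * abs(a))) /
           (1 + exp(-2 * abs(b))))
}

# Dirichlet draw via normalized gammas; alpha a vector per draw
.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {                      # degenerate guard
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

.assert_times <- function(times) {
  if (length(times) == 0) stop("times must be non-empty")
  if (any(times < 0)) stop("times must be non-negative")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  invisible(times)
}

#' Molar masses of the elements tracked in oxalate extractions
#'
#' Named vector of molar masses (g mol\eqn{^{-1}}) used by [arealLoading()]
#' and [molarRatio()]; pass an element not listed here via those functions'
#' `molar_mass` argument.
#'
#' @return Named numeric vector of g mol\eqn{^{-1}}.
#' @examples
#' molarMasses()[["Fe"]]
#' @export
molarMasses <- function() {
  c(Fe = 55.845, As = 74.922, P = 30.974, W = 183.84, S = 32.06, Si = 28.086)
}
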