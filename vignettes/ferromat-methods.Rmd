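---
title: "Models and methods behind ferromat"
author: "ferromat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ferromat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferromat)
```

`ferromat` analyses the development of biomineralized Fe(III)-oxide
microbial mats in hot, acidic spring outflow channels: how fast oxide and
biomass accrete on a fresh surface, how oxygen moves into and is consumed
by the thickening mat, how fast different morphotypes colonize, how the
community successes from lithoautotrophs to heterotrophic archaea, and
which oxyanions the accreting oxide scavenges. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical and
design choices, so that results can be interpreted — and questioned — with
full knowledge of what the code does.

## Exponential accretion kinetics

Areal Fe(III)-oxide and DNA both grow as first-order (exponential)
processes over the 0–70 day window the package targets:
$x(t) = x_0 e^{kt}$, with $x$ in µmol cm⁻² (Fe) or ng cm⁻² (DNA), $k$ in
day⁻¹. The model assumes growth proportional to standing stock — sensible
while the mat is thin and neither light, space nor O₂ yet limits — and is
deliberately not extended with a saturating term: the data window ends
before water depth caps vertical growth, and fitting a logistic to data
that never bend would only destabilise the rate estimate.

`fitExponential()` minimises the unweighted residual sum of squares with
Levenberg–Marquardt (`minpack.lm::nlsLM`), started deterministically from
a log-linear regression on the positive points. Plain Gauss–Newton `nls()`
fails on exactly exponential (zero-residual) input, which the synthetic
round-trip tests exercise on purpose; when the starting values already fit
exactly, the optimiser is skipped and the start is returned with zero
standard errors.

Two covariance estimators are offered. `vcov = "iid"` (default) is the
homoscedastic Jacobian-based covariance of every standard NLS summary, and
is what field studies conventionally report. But areal accretion
measurements err multiplicatively — scatter grows with the mean — and
under mean-proportional noise the iid intervals are anticonservative *at
any noise scale* (the misweighting is scale-free): in simulation their
95% intervals cover the true rate constant in only ~77% of replicates.
`vcov = "robust"` substitutes an HC3 sandwich covariance built from the
same Jacobian, which restores near-nominal (~95%) coverage; use it
whenever interval coverage matters more than convention. Censored
(below-detection) points are excluded by default; substituting half the
detection limit is available but biases $k$ and is provided only for
comparability with that common field practice.

Secondary quantities follow in closed form: instantaneous rate $kx(t)$,
apparent lag $\ln(\mathrm{limit}/x_0)/k$ (time until a pure exponential
becomes detectable — there is no mechanistic lag phase in the model),
vertical growth conversion with a 30-day month, and a pooled-variance
Student t (Welch optional) for endpoint comparisons between springs.

## Oxygen reaction–diffusion modelling

A steady-state O₂ balance in a mat slab of thickness $L_f$ (cm) with
effective diffusivity $D_e$ (cm² s⁻¹) and first-order volumetric
consumption $k_1$ (s⁻¹) gives, in dimensionless form
($u = C/C_0$, $\zeta = z/L_f$):

$$u(\zeta) = \frac{\cosh(\varphi(1-\zeta))}{\cosh\varphi},
\qquad \varphi^2 = \frac{k_1 L_f^2}{D_e},$$

with $u(0)=1$ and a no-flux bottom boundary. The Thiele modulus $\varphi$
compares reaction to diffusion: $\varphi \gg 1$ means O₂ is consumed long
before it can reach the mat base (diffusion limitation), the regime these
mats occupy. A zero-order variant
$u = \varphi^2\zeta^2/2 - \varphi^2\zeta + 1$, clipped at 0 where the slab
goes anoxic, is selectable; the first-order cosh solution is the default
for both generation and fitting because the $\varphi^2 = k_1L_f^2/D_e$
parameterisation is dimensionally first-order. For large arguments the
cosh ratio is evaluated in log space to avoid overflow.

**Interface flux.** `estimateFlux()` applies Fick's first law,
$J = D_e\,|dC/dz|_{z=0}$, over a window of near-surface points (default:
the first three). The default gradient estimator fits a quadratic through
the window and takes its derivative *at the interface*. The obvious
alternative — an OLS straight line through the window — estimates the
slope at the window's centre, not its edge; on a steeply curved profile
(decay length ≈ 217 µm for the packaged OSP defaults) that centring bias
is ≈ 4.5% at 10-µm electrode steps, whereas the quadratic's residual bias
is < 0.1%. `method = "linear"` retains the straight-line estimator for
flat, noisy windows where its variance advantage matters. Units are
reconciled internally (µM → µmol cm⁻³, µm → cm), and J is reported
positive into the mat.

**Profile fitting.** Only $\varphi$ is identifiable from the shape of
$u(\zeta)$; $L_f$ and $D_e$ must be supplied and convert $\varphi$ back to
$k_1 = \varphi^2 D_e/L_f^2$. `fitProfile()` minimises the residual sum of
squares over $\varphi$; because the clipped zero-order solution makes the
objective flat wherever the profile is fully anoxic, the optimum is first
bracketed on a coarse logarithmic grid (120 points up to
$\varphi_{max} = 1000$) before the local golden-section refinement, and a
flat profile is assigned $\varphi = 0$ explicitly. Penetration depth is
the linearly interpolated first crossing below the electrode detection
limit (default 0.3 µM), reported absent if never crossed.

**Packaged OSP profile defaults.** The effective diffusivity is set to
$D_e = 4.5\times10^{-5}$ cm² s⁻¹, a literature-typical value for O₂ in a
porous biofilm near 70–75 °C. $k_1$ and $L_f$ are then *derived*, not
stored: the configuration loader solves the two closed-form first-order
relations $J = D_e C_0 \varphi\tanh(\varphi)/L_f$ and
$\varphi^2 = k_1L_f^2/D_e$ for the site's measured flux
($1.14\times10^{-4}$ µmol cm⁻² s⁻¹), Thiele modulus (28) and bulk O₂
(55 µM), giving $L_f = 0.608$ cm and $k_1 = 0.095$ s⁻¹. A noiseless
generated profile therefore reproduces the measured flux and $\varphi$
exactly. The implied penetration depth (~1130 µm) is *not* separately
constrained to the measured ~950 µm — flux, $\varphi$, $C_0$ and $D_e$
already fix it, and matching all four simultaneously is impossible without
the original profile data. Users with their own estimates can override any
of the four inputs.

## Colonization rates

Cell counts in SEM fields of view (area $A$, typically 3–5 random fields
per slide) become areal densities $n/A$ and a colonization rate via a
through-origin least-squares slope of mean density against time — through
the origin because a sterile substrate necessarily starts at zero density.
The quoted spread is the standard deviation of per-field slopes
(density/t), an honest between-field heterogeneity measure rather than a
regression standard error. The default synthetic sampling design counts
4 fields of $10^{-5}$ cm² on days 5, 10 and 15: counts are still feasible
by eye at these early times (oxide encrustation later obscures cells), and
the day grid makes the deterministic expected counts integral for both
packaged morphotype rates, so the noiseless round trip is exact. Counting
noise is Poisson, the natural model for counts of randomly placed cells.

## Community succession

Community tables are `SummarizedExperiment`s (taxa × samples) carrying
per-taxon 16S rRNA gene copy numbers and per-sample site/day/depth-zone
metadata. `relativeAbundance()` divides counts by copy number *before*
normalising — with two rRNA operons in the dominant rod-shaped
lithoautotroph this correction alone moves its share by almost a factor of
two in young mats — and resets copy numbers to 1 so the correction cannot
be applied twice.

Bray–Curtis dissimilarity is computed on copy-corrected proportions (so
sequencing depth cancels) via `vegan`, with an element-wise oracle in the
test suite guarding the surface; clustering is agglomerative
(`stats::hclust`), complete linkage by default to match the dendrogram
convention of heatmap figures, average linkage available, ties broken by
input label order. Trees serialise to Newick through `ape`.

The dominant early taxon's decline is summarised by an OLS slope of
percent vs day, reported as a positive %/day and extrapolated linearly
with a floor at zero — an extrapolation device, not a mechanistic model;
the window over which "the" decline rate is computed is the caller's
choice. `primerBias()` compares amplicon against reference (e.g. random
metagenome) proportions per taxon, flagging over/under-representation and
reporting taxa missing from one table as `absent` rather than inventing a
0 or an infinite ratio; the packaged mature-mat table shows the effect at
its starkest (an 8-fold amplicon overcall of the rod lithoautotroph and a
30-fold undercall of the Fe(II)-oxidizer from a single primer mismatch).

The four-stage developmental classifier is a transparent rule cascade over
a mat-state record: Stage IV at depth ≥ 5 mm (approaching the "mature"
0.5–2 cm regime), Stage III at ≥ 2 mm or heterotroph fraction ≥ 0.25
(heterotrophs establish as mm-scale O₂ gradients appear), Stage II once
oxide is visible, Stage I otherwise. The thresholds are anchored to the
qualitative stage descriptions (visible accretion between ~7 and 30 days;
gradients at mm depths) and are all configurable; the cascade is monotone
in depth by construction.

## Geochemistry

Oxalate-extraction ICP concentrations (mg L⁻¹) convert to areal loadings
as $c \cdot V / M / A$ (µmol cm⁻²; default $V = 0.05$ L, the standard
50-mL extraction) and to molar ratios in which $V$ and $A$ cancel —
ratios are therefore robust to uncertain scraping areas. Molar masses are
packaged (Fe 55.845, As 74.922, P 30.974, W 183.84, S 32.06, Si 28.086
g mol⁻¹) and overridable. Ratio series are reported both per time point
and as mean ± standard error, since sorption ratios in these systems are
near-constant in time. The Reynolds number $vL/\nu$ takes velocity,
characteristic length and kinematic viscosity as explicit inputs — no
hidden temperature–viscosity table.

## The synthetic-data generator

The generator exists so that every analysis stage can be exercised, and
its estimators validated by parameter recovery, without access to field
data. Defaults are the packaged per-site values: Fe rate constants 0.05
(OSP) and 0.047 (Beowulf) day⁻¹; DNA 0.028 and 0.043 day⁻¹; rod/coccus
colonization rates 3.7 × 10⁶ / 9.2 × 10⁵ (OSP) and 6.8 × 10⁶ / 8.6 × 10⁵
(Beowulf) cells cm⁻² day⁻¹; As:Fe 0.5 / 0.67, P:Fe 0.01, W:Fe 0.002; bulk
O₂ 55 / 44 µM with the profile parameters derived as above. The community
trajectory is parametric: the rod lithoautotroph starts at 0.85 at day 4
and declines 1 percentage point per day (floor 0.01), the Fe(II)-oxidizer
holds at 0.15, and the remaining mass is split among four site-specific
heterotroph taxa with logistic weights (midpoints 35–55 d) — linear
decline, constancy and logistic rise being the simplest forms consistent
with the observed succession.

Noise families match each variable's support: multiplicative lognormal
(mean-1, CV 0.2) for strictly positive areal series; additive gaussian
(sd = 5% of the local mean) clipped at zero for profiles; Poisson for
counts; Dirichlet (concentration 200) for compositions. The scales are
one-time choices representing realistic field scatter — the source data
report no replicate structure to calibrate against. Every generator takes
an explicit seed and restores the caller's RNG state, so draws are
bit-reproducible and never interact with user code.

What the generator does *not* emulate: spatial structure (microterracette
geometry, 2-D heterogeneity), temporal autocorrelation between sampling
days, electrode response smoothing, compositional count sparsity
(zero-inflation), or inter-season variability. Parameter-recovery tests
passing on this generator therefore demonstrate estimator correctness
under the stated error models, not robustness to every pathology of real
field data.

## Numerical conventions and problem sizes

Depths are stored in µm and model lengths in cm, with the two conversion
constants defined once; detection limits default to 0.05 µmol cm⁻² (Fe
censoring) and 0.3 µM (O₂). Writers emit numbers at 10 significant digits
with stable column order, so outputs are diffable; metadata travel as
`#`-prefixed comment lines in otherwise plain CSV/TSV. The test-suite and
acceptance computations use 11-point accretion series (0–70 d), ~600-point
microprofiles at 10-µm spacing, 200-replicate coverage simulations and
100-replicate Poisson recovery simulations — sizes chosen so the full
suite completes in seconds while keeping Monte-Carlo standard errors well
inside the asserted tolerances.

## Known limitations

The exponential fit has no saturating alternative; the reaction–diffusion
model is steady-state, one-dimensional and ignores the diffusive boundary
layer above the mat; colonization rates assume constant areal accumulation
over the counted window; the stage classifier is deliberately coarse; and
the generator's trajectories are smooth parametric stand-ins. Each of
these is a faithful reflection of what slide-incubation field data of this
kind can support, not an oversight.
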